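#' Filter SNPs by minor allele frequency and call rate
#'
#' Retains SNPs with minor allele frequency strictly greater than `min_maf`
#' and call rate strictly greater than `min_callrate`, computed from the
#' analyzed sample.
#'
#' @param genotypes dogs x SNPs dosage matrix with values in
#'   \{0, 1, 2, NA\}.
#' @param min_maf MAF threshold (default 0.01).
#' @param min_callrate call-rate threshold (default 0.95).
#' @return the genotype matrix restricted to passing SNPs, with a
#'   `"filter_report"` attribute (data.frame of dropped SNPs, their MAF and
#'   call rate).
#' @export
filter_snps <- function(genotypes, min_maf = 0.01, min_callrate = 0.95) {
  g <- as.matrix(genotypes)
  bad_vals <- !(g %in% c(0, 1, 2) | is.na(g))
  if (any(bad_vals)) .stopf("dosages must be 0, 1, 2 or missing")
  callrate <- colMeans(!is.na(g))
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf > min_maf & callrate > min_callrate
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) .stopf("no SNPs survive MAF/call-rate filtering")
  report <- data.frame(snp = colnames(g)[!keep] %||%
                         which(!keep), maf = maf[!keep],
                       callrate = callrate[!keep], row.names = NULL)
  out <- g[, keep, drop = FALSE]
  attr(out, "filter_report") <- report
  out
}

#' Compute the variance-standardized genomic relatedness matrix
#'
#' `K[i, j] = (1/m) * sum_k z[i, k] z[j, k]` where
#' `z[i, k] = (g[i, k] - 2 p_k) / sqrt(2 p_k (1 - p_k))` and `p_k` is the
#' sample allele frequency of SNP k. Residual missing dosages are imputed
#' with `2 p_k` (i.e. z = 0) before standardization. K is returned as
#' computed, not forced positive semi-definite; downstream model code
#' floors tiny negative eigenvalues at zero.
#'
#' @param genotypes dogs x SNPs dosage matrix (ideally post
#'   [filter_snps()]).
#' @return object of class `kinship_matrix`: list with `K` (dogs x dogs,
#'   symmetric, dog ids as dimnames), `dog_ids`, `n_markers`.
#' @export
compute_grm <- function(genotypes) {
  g <- as.matrix(genotypes)
  p <- colMeans(g, na.rm = TRUE) / 2
  v <- 2 * p * (1 - p)
  if (any(v <= 0))
    .stopf("internal error: zero-variance SNP reached compute_grm (run filter_snps first)")
  z <- sweep(g, 2L, 2 * p, `-`)
  z[is.na(z)] <- 0                       # mean imputation: g = 2p => z = 0
  z <- sweep(z, 2L, sqrt(v), `/`)
  m <- ncol(z)
  K <- tcrossprod(z) / m
  K <- (K + t(K)) / 2                    # enforce exact symmetry
  ids <- rownames(g) %||% sprintf("dog%04d", seq_len(nrow(g)))
  dimnames(K) <- list(ids, ids)
  kinship_matrix(K, ids, m)
}

#' Construct a kinship-matrix object
#'
#' @param K dogs x dogs symmetric relatedness matrix.
#' @param dog_ids ordered identifiers (default taken from `rownames(K)`).
#' @param n_markers number of SNPs used to build K (NA if unknown).
#' @return object of class `kinship_matrix`.
#' @export
kinship_matrix <- function(K, dog_ids = rownames(K), n_markers = NA_integer_) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) .stopf("K must be square")
  if (max(abs(K - t(K))) > 1e-10) .stopf("K must be symmetric (tol 1e-10)")
  if (is.null(dog_ids)) dog_ids <- sprintf("dog%04d", seq_len(nrow(K)))
  dimnames(K) <- list(dog_ids, dog_ids)
  structure(list(K = K, dog_ids = dog_ids,
                 n_markers = as.integer(n_markers)),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix> %d dogs, %s markers, mean diag %.3f\n",
              nrow(x$K),
              ifelse(is.na(x$n_markers), "?", x$n_markers),
              mean(diag(x$K))))
  invisible(x)
}

## principal submatrix aligned to a set of dog ids
.kin_subset <- function(kin, ids) {
  idx <- match(ids, kin$dog_ids)
  if (anyNA(idx)) .stopf("dogs absent from kinship matrix: %s",
                         paste(utils::head(ids[is.na(idx)]), collapse = ", "))
  kinship_matrix(kin$K[idx, idx, drop = FALSE], ids, kin$n_markers)
}

#' Classify dogs as purebred by ancestry threshold
#'
#' A dog is labeled with its maximum-ancestry breed when that proportion is
#' at least `threshold` (inclusive). Breeds are kept as analysis levels
#' only when at least `min_dogs` qualifying dogs carry the label and, when
#' `require_both_sexes` and a `sex` vector is given, both sexes are
#' represented; all other dogs are labeled `"remaining"`.
#'
#' @param ancestry data.frame from [simulate_genotypes()] (or any table
#'   with per-breed proportion columns plus `max_breed`, `max_proportion`).
#' @param threshold purebred ancestry cut (default 0.85, inclusive).
#' @param min_dogs minimum qualifying dogs per retained breed (default 8).
#' @param require_both_sexes if TRUE, a breed with only one sex among its
#'   qualifying dogs is collapsed to "remaining".
#' @param sex optional per-dog sex vector aligned with `ancestry` rows.
#' @return character vector of breed labels ("remaining" otherwise).
#' @export
classify_purebred <- function(ancestry, threshold = 0.85, min_dogs = 8L,
                              require_both_sexes = FALSE, sex = NULL) {
  stopifnot(all(c("max_breed", "max_proportion") %in% names(ancestry)))
  lab <- ifelse(ancestry$max_proportion >= threshold,
                ancestry$max_breed, "remaining")
  for (b in setdiff(unique(lab), "remaining")) {
    idx <- lab == b
    ok <- sum(idx) >= min_dogs
    if (ok && require_both_sexes) {
      if (is.null(sex)) .stopf("require_both_sexes needs a sex vector")
      ok <- length(unique(sex[idx])) >= 2L
    }
    if (!ok) lab[idx] <- "remaining"
  }
  lab
}

#' Write a relatedness matrix in PLINK-style .rel layout
#'
#' @param kin a `kinship_matrix`.
#' @param prefix file path prefix; writes `<prefix>.rel` (square
#'   tab-delimited matrix) and `<prefix>.rel.id` (one dog id per line).
#' @return the prefix, invisibly.
#' @export
write_rel <- function(kin, prefix) {
  utils::write.table(format(kin$K, digits = 17, trim = TRUE, scientific = TRUE),
                     paste0(prefix, ".rel"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(kin$dog_ids, paste0(prefix, ".rel.id"))
  invisible(prefix)
}

#' Read a relatedness matrix in PLINK-style .rel layout
#'
#' @param prefix file path prefix as in [write_rel()].
#' @return a `kinship_matrix`.
#' @export
read_rel <- function(prefix) {
  K <- as.matrix(utils::read.table(paste0(prefix, ".rel"), sep = "\t",
                                   header = FALSE))
  ids <- readLines(paste0(prefix, ".rel.id"))
  K <- unname(K)
  K <- (K + t(K)) / 2
  kinship_matrix(K, ids)
}
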