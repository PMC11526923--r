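#' Fully adjust metabolites for fixed and random effects
#'
#' Computes `y' = y - X beta_hat - u_hat` per metabolite, removing both
#' the fixed-effect predictions (BLUEs) and the kinship random-effect
#' predictions (BLUPs) from a fitted association scan. Metabolites
#' without a converged fit are excluded with a warning.
#'
#' @param mm the `tech_adjusted` [metabolite_matrix()] the scan was run on.
#' @param result an `mwas_result` from [mwas()].
#' @return object of class `adjusted_matrix`: list with `values`
#'   (samples x metabolites residuals) and `provenance`.
#' @export
adjust <- function(mm, result) {
  .check_state(mm, "tech_adjusted")
  stopifnot(inherits(result, "mwas_result"))
  X <- result$design$X
  mets <- colnames(mm$values)
  ok <- mets[vapply(mets, function(m) !is.null(result$fits[[m]]) &&
                      isTRUE(result$fits[[m]]$converged), logical(1))]
  if (length(ok) < length(mets))
    .warnf("excluding %d metabolite(s) without a converged fit",
           length(mets) - length(ok))
  out <- sapply(ok, function(m) {
    f <- result$fits[[m]]
    mm$values[, m] - drop(X %*% f$beta) - f$blups
  })
  rownames(out) <- rownames(mm$values)
  structure(list(values = out, provenance = "mwas_result"),
            class = "adjusted_matrix")
}

#' Pairwise residual correlations with FDR
#'
#' Pearson correlations among adjusted metabolite values; two-sided
#' p-values from the exact t-transform of r on n - 2 degrees of freedom;
#' Benjamini-Hochberg FDR across all unordered pairs. Zero-variance
#' metabolites yield `NA` for their pairs.
#'
#' @param adjusted an `adjusted_matrix` (or plain matrix).
#' @param alpha FDR level used for the `n_partners` summary.
#' @return list of class `correlation_result`: `r`, `p`, `q` (symmetric
#'   matrices, unit/NA diagonals), `n_partners` (per metabolite, count of
#'   partners with q < alpha and r > 0), `alpha`.
#' @export
correlate_fdr <- function(adjusted, alpha = 0.05) {
  v <- if (inherits(adjusted, "adjusted_matrix")) adjusted$values
       else as.matrix(adjusted)
  n <- nrow(v)
  if (n < 3) .stopf("correlation requires >= 3 samples")
  sds <- .col_sds(v)
  r <- suppressWarnings(stats::cor(v))
  r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA
  q <- p
  up <- upper.tri(p)
  q[up] <- fdr_adjust(p[up])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  n_partners <- colSums(q < alpha & r > 0, na.rm = TRUE)
  structure(list(r = r, p = p, q = q, n_partners = n_partners,
                 alpha = alpha), class = "correlation_result")
}

#' UPGMA clustering of a correlation matrix
#'
#' Average-linkage (UPGMA) agglomeration on the distance `1 - r` (not
#' `1 - |r|`: the sign of covariation matters). The full-distance height
#' convention is used: a merge is recorded at the average inter-cluster
#' distance, so two items merge at their distance (not half of it). Rows
#' are ordered lexicographically by label before agglomeration so ties
#' break by label order and the result is invariant to input permutation.
#'
#' @param r symmetric correlation matrix (e.g. from [correlate_fdr()]),
#'   or a `correlation_result`.
#' @return an `hclust` object with a `"newick"` attribute (Newick string
#'   with branch lengths derived from merge heights).
#' @export
upgma <- function(r) {
  if (inherits(r, "correlation_result")) r <- r$r
  if (anyNA(r)) .stopf("NA distances: remove zero-variance metabolites first")
  ord <- order(rownames(r))
  r <- r[ord, ord]
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = "average")
  if (any(diff(hc$height) < -1e-10))
    .stopf("internal error: non-monotone UPGMA merge heights")
  phy <- ape::as.phylo(hc)
  attr(hc, "newick") <- ape::write.tree(phy)
  hc
}

#' Annotate metabolites by class
#'
#' Attaches a class label (e.g. ptmAA, parent AA, ambiguous, N-waste,
#' other) to metabolite names for use in covariation reports.
#'
#' @param metabolites character vector of metabolite names.
#' @param classes named character vector mapping metabolite name to class;
#'   unnamed metabolites are labeled "other".
#' @return data.frame with columns `metabolite`, `class`.
#' @export
annotate_classes <- function(metabolites, classes = character()) {
  cls <- rep("other", length(metabolites))
  hit <- match(metabolites, names(classes))
  cls[!is.na(hit)] <- classes[hit[!is.na(hit)]]
  data.frame(metabolite = metabolites, class = cls)
}
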