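#' Principal component analysis of the normalized metabolome
#'
#' Exact singular value decomposition of the column-standardized matrix
#' (each metabolite centered and scaled to unit variance overall before
#' decomposition). The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making the decomposition
#' bit-stable across runs.
#'
#' @param mm a `tech_adjusted` [metabolite_matrix()] (or a plain numeric
#'   matrix, samples x metabolites, no missing values).
#' @return object of class `pca_decomp`: `scores` (samples x components),
#'   `loadings` (metabolites x components), `eigenvalues` (descending),
#'   `var_explained`, `n`, plus `tw_p`/`n_significant` once
#'   [tracy_widom_select()] has been applied.
#' @export
pca <- function(mm) {
  if (inherits(mm, "metab_matrix")) {
    .check_state(mm, "tech_adjusted")
    v <- mm$values
  } else v <- as.matrix(mm)
  if (anyNA(v)) .stopf("PCA input must be complete")
  s <- .col_sds(v)
  if (any(s == 0)) .stopf("zero-variance metabolite(s): %s",
                          paste(colnames(v)[s == 0], collapse = ", "))
  z <- scale(v, center = TRUE, scale = s)
  n <- nrow(z)
  sv <- svd(z)
  eig <- sv$d^2 / (n - 1)
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  loadings <- sv$v
  ## deterministic sign: largest-|loading| entry positive
  for (j in seq_along(sv$d)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(v), paste0("PC", seq_along(sv$d)))
  dimnames(loadings) <- list(colnames(v), paste0("PC", seq_along(sv$d)))
  structure(list(scores = scores, loadings = loadings, eigenvalues = eig,
                 var_explained = eig / sum(eig), n = n,
                 tw_p = NULL, n_significant = NA_integer_),
            class = "pca_decomp")
}

#' @export
print.pca_decomp <- function(x, ...) {
  cat(sprintf("<pca_decomp> %d samples, %d components; leading var explained: %s\n",
              x$n, length(x$eigenvalues),
              paste(sprintf("%.1f%%", 100 * utils::head(x$var_explained, 5)),
                    collapse = ", ")))
  if (!is.na(x$n_significant))
    cat(sprintf("  Tracy-Widom significant components: %d\n",
                x$n_significant))
  invisible(x)
}

## Tracy-Widom (beta = 1) upper-tail probability via the shifted-gamma
## moment approximation (accurate to ~1e-4 over the body of the
## distribution, ample for alpha-level component selection).
.ptw1_upper <- function(x) {
  k <- 46.44604884387
  theta <- 0.18605402228279
  shift <- 9.84801782549852          # k*theta - shift = E[TW1] = -1.2065336
  stats::pgamma(x + shift, shape = k, scale = theta, lower.tail = FALSE)
}

#' Tracy-Widom selection of non-random principal components
#'
#' Sequentially tests each leading eigenvalue against the Tracy-Widom
#' (beta = 1) null using the moment-matching effective-size normalization
#' of population-structure testing: at each step the remaining eigenvalues
#' estimate an effective sample count, the leading eigenvalue is
#' standardized by the corresponding Marchenko-Pastur edge location and
#' scale, and its upper-tail TW probability computed. Selection stops at
#' the first non-significant component.
#'
#' @param x a `pca_decomp` or a numeric vector of descending eigenvalues.
#' @param n number of samples (taken from the `pca_decomp` if omitted).
#' @param alpha significance level (default 0.05).
#' @return for a `pca_decomp` input, the object with `tw_p` and
#'   `n_significant` filled in; for a vector, a list with `tw_p`,
#'   `tw_stat`, `n_significant`.
#' @export
tracy_widom_select <- function(x, n = NULL, alpha = 0.05) {
  obj <- NULL
  if (inherits(x, "pca_decomp")) {
    obj <- x
    eig <- x$eigenvalues
    n <- n %||% x$n
  } else eig <- as.numeric(x)
  if (is.null(n) || n <= 2) .stopf("Tracy-Widom testing requires n > 2")
  eig <- eig[eig > 1e-12]
  L <- length(eig)
  tw_p <- rep(NA_real_, L)
  tw_stat <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    rem <- eig[i:L]
    mp <- length(rem)
    if (mp < 2) break
    S1 <- sum(rem)
    ## the sample count is known (observations are rows, assumed
    ## independent), so the Wishart degrees of freedom are n - 1; the
    ## moment-matched effective-size estimator of population-structure
    ## testing targets correlated markers and is anticonservative here
    n_eff <- n - 1
    ell <- mp * rem[1] / S1
    a <- sqrt(n_eff - 1); b <- sqrt(mp)
    mu <- (a + b)^2 / n_eff
    sg <- (a + b) / n_eff * (1 / a + 1 / b)^(1 / 3)
    tw_stat[i] <- (ell - mu) / sg
    tw_p[i] <- .ptw1_upper(tw_stat[i])
  }
  n_sig <- 0L
  for (i in seq_len(L)) {
    if (is.na(tw_p[i]) || tw_p[i] >= alpha) break
    n_sig <- i
  }
  if (!is.null(obj)) {
    obj$tw_p <- tw_p
    obj$tw_stat <- tw_stat
    obj$n_significant <- n_sig
    return(obj)
  }
  list(tw_p = tw_p, tw_stat = tw_stat, n_significant = n_sig)
}

#' Type III ANCOVA variance partition of principal components
#'
#' For each retained PC, fits a fixed-effects linear model on the listed
#' covariates with sum-to-zero factor contrasts and computes Type III
#' (marginal) sums of squares per covariate term via single-term
#' deletions. Because marginal sums of squares are not additive in
#' non-orthogonal designs, fractions are computed against the sum of all
#' marginal SS plus the residual SS, so covariate fractions and the
#' residual fraction sum to 1 for each PC. Aliased covariates are
#' reported and dropped.
#'
#' @param scores samples x components score matrix (or `pca_decomp`).
#' @param cohort aligned covariate table.
#' @param covariates cohort columns to partition over; factors are used as
#'   factors, numerics as numeric (age and weight are square-root
#'   transformed when named).
#' @param n_pcs number of leading PCs to partition (default all columns,
#'   or `n_significant` of a selected `pca_decomp`).
#' @return object of class `variance_partition`: long data.frame with
#'   columns `pc`, `term`, `ss`, `df`, `F`, `p`, `fraction`, including a
#'   `Residuals` row per PC.
#' @export
ancova_partition <- function(scores, cohort,
                             covariates = c("age", "weight", "sex",
                                            "sterilized", "life_stage",
                                            "fasting",
                                            grep("^cbc", names(cohort),
                                                 value = TRUE)),
                             n_pcs = NULL) {
  if (inherits(scores, "pca_decomp")) {
    if (is.null(n_pcs))
      n_pcs <- if (!is.na(scores$n_significant) && scores$n_significant > 0)
        scores$n_significant else ncol(scores$scores)
    scores <- scores$scores
  }
  n_pcs <- min(n_pcs %||% ncol(scores), ncol(scores))
  dat <- data.frame(row.names = seq_len(nrow(cohort)))
  for (v in covariates) {
    col <- cohort[[v]]
    if (is.null(col)) .stopf("unknown covariate '%s'", v)
    if (v %in% c("age", "weight")) col <- sqrt(as.numeric(col))
    if (is.character(col) || is.logical(col)) col <- factor(col)
    if (is.factor(col)) col <- droplevels(col)
    dat[[v]] <- col
  }
  ## drop aliased covariates (rank-deficient full design)
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op), add = TRUE)
  mmx <- stats::model.matrix(~ ., dat)
  qr_x <- qr(mmx)
  if (qr_x$rank < ncol(mmx)) {
    aliased_cols <- colnames(mmx)[-sort(qr_x$pivot[seq_len(qr_x$rank)])]
    bad_terms <- unique(unlist(lapply(names(dat), function(v)
      if (any(startsWith(aliased_cols, v))) v)))
    .warnf("dropping aliased covariate(s): %s",
           paste(bad_terms, collapse = ", "))
    dat <- dat[setdiff(names(dat), bad_terms)]
  }
  out <- list()
  for (k in seq_len(n_pcs)) {
    dat$.pc <- scores[, k]
    fit <- stats::lm(.pc ~ ., data = dat)
    d1 <- stats::drop1(fit, scope = stats::formula(fit), test = "F")
    d1 <- d1[-1, , drop = FALSE]                 # remove <none> row
    rss <- sum(stats::residuals(fit)^2)
    ss <- d1[["Sum of Sq"]]
    total <- sum(ss) + rss
    rows <- data.frame(pc = paste0("PC", k),
                       term = c(rownames(d1), "Residuals"),
                       ss = c(ss, rss), df = c(d1$Df, fit$df.residual),
                       F = c(d1$`F value`, NA), p = c(d1$`Pr(>F)`, NA),
                       fraction = c(ss, rss) / total, row.names = NULL)
    out[[k]] <- rows
    dat$.pc <- NULL
  }
  structure(do.call(rbind, out), class = c("variance_partition",
                                           "data.frame"))
}

#' Identity kinship matrix
#'
#' Convenience constructor for the no-relatedness comparison model
#' (diagonals 1, off-diagonals 0).
#'
#' @param ids dog identifiers.
#' @return a `kinship_matrix`.
#' @export
identity_kinship <- function(ids) {
  n <- length(ids)
  kinship_matrix(diag(n), ids, NA_integer_)
}

#' SNP-heritability of principal components
#'
#' Fits each retained PC with [fit_lmm()] (standard fixed-effect design,
#' no interactions) and reports the per-PC variance-component split.
#'
#' @param scores samples x components matrix or `pca_decomp`.
#' @param cohort aligned covariate table.
#' @param kin a [kinship_matrix] aligned to score rows.
#' @param n_pcs number of leading PCs (defaults as in
#'   [ancova_partition()]).
#' @param cbc_cols CBC covariate columns for the design.
#' @return data.frame with `pc`, `h_snp`, `sigma_g2`, `sigma_e2`,
#'   `loglik`, `boundary`.
#' @export
pc_heritability <- function(scores, cohort, kin, n_pcs = NULL,
                            cbc_cols = NULL) {
  if (inherits(scores, "pca_decomp")) {
    if (is.null(n_pcs))
      n_pcs <- if (!is.na(scores$n_significant) && scores$n_significant > 0)
        scores$n_significant else ncol(scores$scores)
    scores <- scores$scores
  }
  n_pcs <- min(n_pcs %||% ncol(scores), ncol(scores))
  des <- build_design(cohort, cbc_cols = cbc_cols, interactions = FALSE)
  eig <- .kin_eigen(kin$K)
  rows <- lapply(seq_len(n_pcs), function(k) {
    f <- fit_lmm(scores[, k], des, kin, eig = eig)
    data.frame(pc = paste0("PC", k), h_snp = f$h_snp,
               sigma_g2 = f$sigma_g2, sigma_e2 = f$sigma_e2,
               loglik = f$loglik, boundary = f$boundary)
  })
  do.call(rbind, rows)
}
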