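#' Drop metabolites with excess missingness
#'
#' Removes every metabolite missing in strictly more than `max_missing` of
#' samples (a metabolite missing in exactly the threshold fraction is
#' retained).
#'
#' @param mm a raw-state [metabolite_matrix()].
#' @param max_missing maximum tolerated missing fraction (default 0.10).
#' @return the filtered matrix (state `filtered`) with a `"dropped"`
#'   attribute: data.frame of dropped metabolite names and missing
#'   fractions.
#' @export
filter_missingness <- function(mm, max_missing = 0.10) {
  .check_state(mm, "raw")
  frac <- colMeans(is.na(mm$values))
  drop <- frac > max_missing
  report <- data.frame(metabolite = colnames(mm$values)[drop],
                       missing_fraction = unname(frac[drop]))
  if (all(drop)) .stopf("no metabolites survive the missingness filter")
  mm$values <- mm$values[, !drop, drop = FALSE]
  mm <- .set_state(mm, "filtered")
  attr(mm, "dropped") <- report
  mm
}

#' Drop hemolyzed samples
#'
#' Removes samples whose hemolysis grade exceeds `max_grade` (default 3,
#' i.e. grade-4 samples are removed).
#'
#' @param mm a [metabolite_matrix()] in state raw or filtered.
#' @param max_grade highest tolerated grade (default 3).
#' @return the filtered matrix (state `filtered`) with a `"dropped"`
#'   attribute listing removed sample ids and grades.
#' @export
filter_hemolysis <- function(mm, max_grade = 3L) {
  if (!mm$state %in% c("raw", "filtered"))
    .stopf("filter_hemolysis requires state raw or filtered, got '%s'",
           mm$state)
  grade <- mm$sample_meta$hemolysis
  if (anyNA(grade)) .stopf("every sample must carry a hemolysis grade")
  drop <- grade > max_grade
  report <- data.frame(sample_id = mm$sample_meta$sample_id[drop],
                       hemolysis = grade[drop])
  mm <- .mm_subset_samples(mm, !drop)
  mm <- .set_state(mm, "filtered")
  attr(mm, "dropped") <- report
  mm
}

#' Natural-log transform and center by sample
#'
#' Values are replaced by their natural logarithm minus the sample (row)
#' mean over non-missing metabolites, so per-sample loading differences are
#' removed. Missing cells stay missing and are excluded from row means.
#'
#' @param mm a [metabolite_matrix()] in state raw or filtered with strictly
#'   positive retained values.
#' @return the matrix in state `logged`.
#' @export
log_center <- function(mm) {
  if (!mm$state %in% c("raw", "filtered"))
    .stopf("log_center requires state raw or filtered, got '%s'", mm$state)
  v <- mm$values
  bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(bad))
    .stopf("non-positive intensity at sample '%s', metabolite '%s'",
           rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]])
  lv <- log(v)
  mm$values <- lv - rowMeans(lv, na.rm = TRUE)
  .set_state(mm, "logged")
}

#' Remove batch and run-order drift
#'
#' Per metabolite, values are replaced by the residuals of a linear model
#' with batch-specific intercepts and batch-specific linear run-order
#' slopes (the batch x run-order interaction model). Because batches
#' partition the samples, this is fitted batch by batch: within each batch
#' the metabolite is regressed on the within-batch run-order index and
#' residuals retained. Batches with fewer than 3 non-missing values for a
#' metabolite fall back to intercept-only (mean removal) with a warning.
#'
#' @param mm a [metabolite_matrix()] in state `logged`.
#' @return the matrix in state `batch_corrected`.
#' @export
batch_runorder_correct <- function(mm) {
  .check_state(mm, "logged")
  v <- mm$values
  batch <- mm$sample_meta$batch
  ro <- mm$sample_meta$run_order
  n_fallback <- 0L
  for (b in unique(batch)) {
    rows <- which(batch == b)
    x <- ro[rows]
    for (j in seq_len(ncol(v))) {
      y <- v[rows, j]
      obs <- !is.na(y)
      nobs <- sum(obs)
      if (nobs == 0L) next
      if (nobs >= 3L && stats::var(x[obs]) > 0) {
        fit <- stats::lm.fit(cbind(1, x[obs]), y[obs])
        v[rows[obs], j] <- fit$residuals
      } else {
        n_fallback <- n_fallback + 1L
        v[rows[obs], j] <- y[obs] - mean(y[obs])
      }
    }
  }
  if (n_fallback > 0L)
    .warnf("%d batch/metabolite cells had < 3 non-missing values; fell back to intercept-only correction",
           n_fallback)
  mm$values <- v
  .set_state(mm, "batch_corrected")
}

#' Scale each metabolite to unit variance within batch
#'
#' Divides each metabolite's non-missing values within a batch by their
#' sample standard deviation (denominator n - 1). Batches with at most one
#' non-missing value, or zero variance, are left unscaled with a warning.
#'
#' @param mm a [metabolite_matrix()] in state `batch_corrected`.
#' @return the matrix in state `scaled`.
#' @export
scale_by_batch <- function(mm) {
  .check_state(mm, "batch_corrected")
  v <- mm$values
  batch <- mm$sample_meta$batch
  n_skipped <- 0L
  for (b in unique(batch)) {
    rows <- which(batch == b)
    sub <- v[rows, , drop = FALSE]
    s <- apply(sub, 2L, stats::sd, na.rm = TRUE)
    nobs <- colSums(!is.na(sub))
    ok <- nobs >= 2L & !is.na(s) & s > 0
    n_skipped <- n_skipped + sum(!ok)
    sub[, ok] <- sweep(sub[, ok, drop = FALSE], 2L, s[ok], `/`)
    v[rows, ] <- sub
  }
  if (n_skipped > 0L)
    .warnf("%d batch/metabolite cells left unscaled (<=1 value or zero variance)",
           n_skipped)
  mm$values <- v
  .set_state(mm, "scaled")
}

#' k-nearest-neighbour mean imputation
#'
#' Each missing cell is replaced by the mean of that metabolite among the
#' k nearest samples. Distance between two samples is the mean squared
#' difference over metabolites observed in both (Euclidean scaled by the
#' number of shared metabolites); neighbours are drawn from samples with
#' the target metabolite observed, ties broken by sample order.
#'
#' @param mm a [metabolite_matrix()] in state `scaled`.
#' @param k neighbourhood size (default 10).
#' @return the matrix in state `imputed`, with no missing cells.
#' @export
knn_impute <- function(mm, k = 10L) {
  .check_state(mm, "scaled")
  mm$values <- .knn_impute_matrix(mm$values, k)
  .set_state(mm, "imputed")
}

## core k-NN imputation on a plain matrix (shared by metabolite and CBC use)
.knn_impute_matrix <- function(v, k = 10L) {
  if (!anyNA(v)) return(v)
  n <- nrow(v)
  obs <- !is.na(v)
  v0 <- v; v0[!obs] <- 0
  ## pairwise mean squared difference over shared observed metabolites
  shared <- tcrossprod(obs * 1)
  ss <- tcrossprod(v0^2, obs) + tcrossprod(obs, v0^2) - 2 * tcrossprod(v0)
  D <- ss / shared                      # NaN where no shared metabolites
  diag(D) <- Inf
  need <- which(rowSums(!obs) > 0L)
  for (i in need) {
    if (all(!is.finite(D[i, ]))) .stopf(
      "sample '%s' shares no observed metabolites with any other sample",
      rownames(v)[i] %||% i)
    miss_j <- which(!obs[i, ])
    ord <- order(D[i, ], seq_len(n))    # tie-break by sample order
    for (j in miss_j) {
      donors <- ord[obs[ord, j] & is.finite(D[i, ord])]
      if (!length(donors)) next         # column missing everywhere else
      v[i, j] <- mean(v[donors[seq_len(min(k, length(donors)))], j])
    }
  }
  if (anyNA(v)) .stopf("imputation failed: a metabolite is missing in all samples")
  v
}

#' Regress out technical covariates
#'
#' Per metabolite, values are replaced by the residuals of an additive
#' linear fit on the listed technical covariates (by default travel time,
#' arrival temperature and hemolysis grade from the sample metadata).
#' Constant covariates are dropped from the design with a warning;
#' collinear designs are handled by a rank-revealing QR solve.
#'
#' @param mm a [metabolite_matrix()] in state `imputed`.
#' @param covariates character vector of sample-metadata columns.
#' @return the matrix in state `tech_adjusted`.
#' @export
regress_technical <- function(mm, covariates = c("travel_time",
                                                 "arrival_temp",
                                                 "hemolysis")) {
  .check_state(mm, "imputed")
  miss <- setdiff(covariates, names(mm$sample_meta))
  if (length(miss)) .stopf("unknown technical covariate(s): %s",
                           paste(miss, collapse = ", "))
  Z <- as.matrix(mm$sample_meta[covariates])
  const <- apply(Z, 2L, function(z) stats::var(z) == 0)
  if (any(const)) {
    .warnf("dropping constant technical covariate(s): %s",
           paste(covariates[const], collapse = ", "))
    Z <- Z[, !const, drop = FALSE]
  }
  X <- cbind(`(Intercept)` = 1, Z)
  qr_x <- qr(X)
  X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
  dn <- dimnames(mm$values)
  mm$values <- stats::lm.fit(X, mm$values)$residuals
  dimnames(mm$values) <- dn
  .set_state(mm, "tech_adjusted")
}

#' Run the full technical-normalization pipeline
#'
#' filters -> log/center -> batch x run-order correction -> per-batch unit
#' variance -> k-NN imputation -> technical-covariate regression.
#'
#' @param mm a raw-state [metabolite_matrix()].
#' @param max_missing missingness filter threshold.
#' @param max_hemolysis_grade hemolysis filter threshold.
#' @param knn_k imputation neighbourhood size.
#' @return the matrix in state `tech_adjusted`, with a `"report"` attribute
#'   summarizing dropped metabolites and samples.
#' @export
preprocess_pipeline <- function(mm, max_missing = 0.10,
                                max_hemolysis_grade = 3L, knn_k = 10L) {
  mm1 <- filter_missingness(mm, max_missing)
  dropped_mets <- attr(mm1, "dropped")
  mm2 <- filter_hemolysis(mm1, max_hemolysis_grade)
  dropped_samples <- attr(mm2, "dropped")
  out <- regress_technical(knn_impute(scale_by_batch(
    batch_runorder_correct(log_center(mm2))), knn_k))
  attr(out, "report") <- list(dropped_metabolites = dropped_mets,
                              dropped_samples = dropped_samples)
  out
}
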