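#' Build the fixed-effect design matrix
#'
#' Standard design: intercept, sqrt(age), sqrt(weight), sex (0/1),
#' sterilization (0/1), fasting hours, the CBC covariate columns, and
#' optionally the age x weight and sex x sterilization interactions
#' (square-root transforms are applied before interactions are formed).
#' Extra numeric covariates are mean-centered and scaled to unit variance;
#' extra factors are dummy-coded against a stated reference level.
#' Degenerate (collinear or constant) columns are pruned by a
#' rank-revealing QR with a warning; the intercept is never pruned.
#'
#' @param cohort per-dog covariate data.frame (see [simulate_phenotypes()]).
#' @param cbc_cols names of CBC covariate columns (default: all columns
#'   matching `^cbc`).
#' @param interactions include age x weight and sex x sterilization.
#' @param age_weight_interaction include the age x weight term (set FALSE
#'   after the two-stage pruning rule removes it).
#' @param extra_numeric names of cohort columns added as standardized
#'   numeric covariates (e.g. urinalysis measures, a mediator).
#' @param extra_factor name of a cohort factor column added as dummy
#'   contrasts versus `reference`.
#' @param reference reference level for `extra_factor`.
#' @return object of class `design_matrix`: list with `X` (samples x p),
#'   `ledger` (character vector of applied transforms) and `pruned`
#'   (names of removed degenerate columns).
#' @export
build_design <- function(cohort, cbc_cols = NULL, interactions = TRUE,
                         age_weight_interaction = interactions,
                         extra_numeric = NULL, extra_factor = NULL,
                         reference = NULL) {
  if (is.null(cbc_cols))
    cbc_cols <- grep("^cbc", names(cohort), value = TRUE)
  ledger <- c("age: sqrt transform", "weight: sqrt transform",
              "sex, sterilized: 0/1 coding")
  X <- cbind(`(Intercept)` = 1,
             sqrt_age = sqrt(cohort$age),
             sqrt_weight = sqrt(cohort$weight),
             sex = as.numeric(cohort$sex),
             sterilized = as.numeric(cohort$sterilized),
             fasting = as.numeric(cohort$fasting))
  if (length(cbc_cols)) X <- cbind(X, as.matrix(cohort[cbc_cols]))
  if (interactions) {
    if (age_weight_interaction) {
      X <- cbind(X, `sqrt_age:sqrt_weight` = sqrt(cohort$age) *
                   sqrt(cohort$weight))
      ledger <- c(ledger, "interaction: sqrt_age x sqrt_weight")
    }
    X <- cbind(X, `sex:sterilized` = as.numeric(cohort$sex) *
                 as.numeric(cohort$sterilized))
    ledger <- c(ledger, "interaction: sex x sterilized")
  }
  for (v in extra_numeric) {
    z <- as.numeric(cohort[[v]])
    s <- stats::sd(z)
    if (is.na(s) || s == 0) .stopf("extra covariate '%s' is constant", v)
    zc <- (z - mean(z)) / s
    X <- cbind(X, zc)
    colnames(X)[ncol(X)] <- v
    ledger <- c(ledger, sprintf("%s: centered, unit variance", v))
  }
  if (!is.null(extra_factor)) {
    f <- factor(cohort[[extra_factor]])
    if (is.null(reference)) .stopf("extra_factor requires a reference level")
    if (!reference %in% levels(f))
      .stopf("reference level '%s' absent from '%s'", reference, extra_factor)
    f <- stats::relevel(f, ref = reference)
    dm <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(dm) <- paste0(extra_factor, "_", levels(f)[-1])
    X <- cbind(X, dm)
    ledger <- c(ledger, sprintf("%s: dummy-coded vs reference '%s'",
                                extra_factor, reference))
  }
  rownames(X) <- as.character(cohort$dog_id %||% seq_len(nrow(cohort)))
  ## rank-revealing prune, intercept protected by pivoting order
  qr_x <- qr(X)
  pruned <- character()
  if (qr_x$rank < ncol(X)) {
    keep <- sort(qr_x$pivot[seq_len(qr_x$rank)])
    pruned <- colnames(X)[-keep]
    .warnf("pruning degenerate design column(s): %s",
           paste(pruned, collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  structure(list(X = X, ledger = ledger, pruned = pruned),
            class = "design_matrix")
}

.design_X <- function(X) {
  if (inherits(X, "design_matrix")) X$X else as.matrix(X)
}

## eigendecomposition of K with negative eigenvalues floored at zero
.kin_eigen <- function(K) {
  if (inherits(K, "kinship_matrix")) K <- K$K
  e <- eigen(K, symmetric = TRUE)
  n_floored <- sum(e$values < 0)
  e$values <- pmax(e$values, 0)
  e$n_floored <- n_floored
  e
}

## Likelihood machinery. Parameterization follows the established
## eigendecomposition approach for single-kinship mixed models:
## V = sigma_g^2 (K + delta I) with delta = sigma_e^2 / sigma_g^2. The
## profiled (over beta and sigma_g^2) log-likelihood evaluates its RSS
## term in the eigenbasis of S K S (S the projection off the column space
## of X), which removes the degeneracy a centered, singular GRM would
## otherwise create along directions exactly fittable by X; the
## determinant term uses the full spectrum of K.
.lmm_prep <- function(X, K = NULL, eigK = NULL) {
  eigK <- eigK %||% .kin_eigen(K)
  n <- nrow(X); q <- ncol(X)
  qx <- qr(X)
  if (qx$rank < q) .stopf("design matrix is rank deficient")
  Qc <- qr.Q(qx, complete = TRUE)[, (q + 1L):n, drop = FALSE]
  A <- crossprod(Qc, eigK$vectors %*% (eigK$values *
                                         t(eigK$vectors)) %*% Qc)
  eA <- eigen((A + t(A)) / 2, symmetric = TRUE)
  list(eigK = eigK, lambda = pmax(eA$values, 0),
       Up = Qc %*% eA$vectors, X = X, n = n, q = q, qx = qx)
}

## profiled log-likelihood at log(delta)
.profile_ll <- function(logdelta, eta2, lambda, xi, n, q, reml = FALSE) {
  delta <- exp(logdelta)
  rss <- sum(eta2 / (lambda + delta))
  if (!reml)
    0.5 * (n * log(n / (2 * pi)) - n - n * log(rss) -
             sum(log(xi + delta)))
  else
    0.5 * ((n - q) * log((n - q) / (2 * pi)) - (n - q) -
             (n - q) * log(rss) - sum(log(lambda + delta)))
}

## log-likelihood at the sigma_g^2 = 0 boundary (plain OLS)
.ols_ll <- function(eta2, n, q, reml = FALSE) {
  rss <- sum(eta2)
  if (!reml) -0.5 * n * (log(2 * pi) + log(rss / n) + 1)
  else -0.5 * (n - q) * (log(2 * pi) + log(rss / (n - q)) + 1)
}

## fit one response given a prepared design/kinship system
.fit_lmm_core <- function(y, prep, reml = FALSE, interval = c(-25, 25)) {
  n <- prep$n; q <- prep$q
  eta2 <- drop(crossprod(prep$Up, y))^2
  xi <- prep$eigK$values
  lam <- prep$lambda
  ## coarse grid scan, then Brent refinement in the bracketing interval
  grid <- seq(interval[1], interval[2], length.out = 101L)
  llg <- vapply(grid, .profile_ll, numeric(1), eta2 = eta2, lambda = lam,
                xi = xi, n = n, q = q, reml = reml)
  i_best <- which.max(llg)
  opt <- stats::optimize(.profile_ll, maximum = TRUE,
                         interval = c(grid[max(1L, i_best - 1L)],
                                      grid[min(length(grid), i_best + 1L)]),
                         eta2 = eta2, lambda = lam, xi = xi, n = n, q = q,
                         reml = reml, tol = 1e-10)
  if (max(llg) > opt$objective)
    opt <- list(maximum = grid[i_best], objective = max(llg))
  ll0 <- .ols_ll(eta2, n, q, reml)
  boundary <- "none"
  if (ll0 >= opt$objective - 1e-8) {
    delta <- Inf; ll <- ll0; boundary <- "zero"
  } else {
    delta <- exp(opt$maximum); ll <- opt$objective
    if (opt$maximum <= interval[1] + 1e-6) boundary <- "upper"   # h -> 1
    if (opt$maximum >= interval[2] - 1e-6) boundary <- "zero"
  }
  X <- prep$X
  U <- prep$eigK$vectors
  if (is.infinite(delta)) {
    fit0 <- stats::lm.fit(X, y)
    beta <- fit0$coefficients
    rss0 <- sum(fit0$residuals^2)
    sigma_g2 <- 0
    sigma_e2 <- if (reml) rss0 / (n - q) else rss0 / n
    cov_beta <- sigma_e2 * chol2inv(qr.R(fit0$qr))[order(fit0$qr$pivot),
                                                   order(fit0$qr$pivot),
                                                   drop = FALSE]
    uhat <- rep(0, n)
    h <- 0
  } else {
    w <- 1 / (xi + delta)
    Xh <- crossprod(U, X); yh <- drop(crossprod(U, y))
    XtWX <- crossprod(Xh, Xh * w)
    XtWy <- crossprod(Xh, yh * w)
    beta <- drop(solve(XtWX, XtWy))
    sigma_g2 <- sum(eta2 / (lam + delta)) / (if (reml) n - q else n)
    sigma_e2 <- delta * sigma_g2
    cov_beta <- sigma_g2 * solve(XtWX)
    rh <- yh - Xh %*% beta
    uhat <- drop(U %*% ((xi / (xi + delta)) * rh))
    h <- 1 / (1 + delta)
  }
  names(beta) <- colnames(X)
  dimnames(cov_beta) <- list(colnames(X), colnames(X))
  se <- sqrt(pmax(diag(cov_beta), 0))
  names(uhat) <- rownames(X)
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df = n - q)
  structure(list(beta = beta, se = se, t = tstat, p = pval,
                 df = n - q, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 h_snp = h, delta = delta,
                 blups = uhat, loglik = ll, cov_beta = cov_beta,
                 converged = TRUE, boundary = boundary, reml = reml),
            class = "lmm_fit")
}

#' Fit a linear mixed model with one kinship random effect
#'
#' Exact fit of `y ~ N(X beta, sigma_g^2 K + sigma_e^2 I)`. K is
#' eigendecomposed once (tiny negative eigenvalues floored at zero) and
#' the 1-D profiled likelihood in the variance ratio
#' `delta = sigma_e^2 / sigma_g^2` is maximized on the log scale over a
#' wide bracket (grid scan plus Brent refinement), with an explicit check
#' of the `sigma_g^2 = 0` boundary; on a flat (unidentifiable) profile,
#' e.g. with K = I, the boundary solution is preferred, so `beta` reduces
#' to ordinary least squares and the BLUPs are zero. `beta` is the
#' generalized-least-squares solution at the optimum and
#' `u_hat = sigma_g^2 K V^{-1} (y - X beta)`.
#'
#' REML is the default: with a variance-standardized GRM (which is
#' centered and therefore singular) and an intercept, the exact ML
#' profile is degenerate — its determinant term diverges as
#' `sigma_e -> 0` along the K-null direction the intercept fits exactly —
#' whereas REML projects the fixed effects out of both likelihood terms
#' and is well-posed. ML (`reml = FALSE`) remains available and is exact
#' for strictly positive-definite kinship.
#'
#' @param y response vector.
#' @param X design matrix or [build_design()] object (full rank).
#' @param K a [kinship_matrix] or plain symmetric matrix.
#' @param reml use REML (default TRUE; see Details).
#' @param eig optional precomputed eigendecomposition of K (internal
#'   speed-up for panel fits).
#' @return object of class `lmm_fit` with elements `beta`, `se`, `t`, `p`
#'   (two-sided, n - p df), `sigma_g2`, `sigma_e2`, `h_snp`, `blups`,
#'   `loglik`, `converged`, `boundary`.
#' @export
fit_lmm <- function(y, X, K, reml = TRUE, eig = NULL) {
  X <- .design_X(X)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) .stopf("dimensions of y and X disagree")
  if (is.null(eig)) {
    Km <- if (inherits(K, "kinship_matrix")) K$K else as.matrix(K)
    if (nrow(Km) != n) .stopf("dimensions of y and K disagree")
    eig <- .kin_eigen(Km)
  }
  prep <- .lmm_prep(X, eigK = eig)
  out <- .fit_lmm_core(y, prep, reml = reml)
  out$n_floored_eigenvalues <- eig$n_floored %||% 0L
  out
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> h_snp = %.3f, sigma_g2 = %.4f, sigma_e2 = %.4f, loglik = %.4f%s\n",
              x$h_snp, x$sigma_g2, x$sigma_e2, x$loglik,
              if (x$boundary != "none") paste0(" [boundary: ", x$boundary, "]")
              else ""))
  print(data.frame(beta = x$beta, se = x$se, t = x$t, p = x$p))
  invisible(x)
}

#' Wald t-tests of fixed effects
#'
#' `t = beta / se` with the GLS standard errors at the ML variance
#' components; two-sided p-values on n - p degrees of freedom. A zero
#' standard error (degenerate column) yields `NA` with a warning.
#'
#' @param fit an `lmm_fit`.
#' @return named vector of p-values.
#' @export
test_fixed_effects <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!fit$converged) .stopf("fit did not converge")
  se <- fit$se
  p <- rep(NA_real_, length(se))
  names(p) <- names(se)
  bad <- is.na(se) | se == 0
  if (any(bad)) .warnf("zero/undefined standard error for: %s",
                       paste(names(se)[bad], collapse = ", "))
  p[!bad] <- 2 * stats::pt(-abs(fit$beta[!bad] / se[!bad]), df = fit$df)
  p
}

## fit every column of Y against a shared design and kinship eigensystem
.fit_panel <- function(Y, X, eig, reml = TRUE) {
  X <- .design_X(X)
  prep <- .lmm_prep(X, eigK = eig)
  fits <- vector("list", ncol(Y))
  names(fits) <- colnames(Y)
  for (j in seq_len(ncol(Y))) {
    fits[[j]] <- tryCatch(
      .fit_lmm_core(Y[, j], prep, reml = reml),
      error = function(e) {
        .warnf("metabolite '%s' failed to fit: %s", colnames(Y)[j],
               conditionMessage(e))
        NULL
      })
  }
  fits
}

## long-format coefficient table from a list of fits, FDR per coefficient
.panel_table <- function(fits) {
  ok <- !vapply(fits, is.null, logical(1))
  rows <- lapply(names(fits)[ok], function(m) {
    f <- fits[[m]]
    data.frame(metabolite = m, coefficient = names(f$beta),
               beta = unname(f$beta), se = unname(f$se), p = unname(f$p),
               sigma_g2 = f$sigma_g2, sigma_e2 = f$sigma_e2,
               h_snp = f$h_snp, loglik = f$loglik,
               converged = f$converged, row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  tab$q <- NA_real_
  for (cf in unique(tab$coefficient)) {
    idx <- tab$coefficient == cf
    tab$q[idx] <- fdr_adjust(tab$p[idx])
  }
  tab
}

## align metabolite matrix, cohort and kinship by sample id
.align_inputs <- function(mm, cohort, kin) {
  ids <- rownames(mm$values)
  if (!all(ids %in% cohort$dog_id) || !all(ids %in% kin$dog_ids)) {
    off <- unique(c(setdiff(ids, cohort$dog_id), setdiff(ids, kin$dog_ids)))
    .stopf("sample id mismatch between tables; offending ids: %s",
           paste(utils::head(off, 10), collapse = ", "))
  }
  cohort <- cohort[match(ids, cohort$dog_id), , drop = FALSE]
  kin <- .kin_subset(kin, ids)
  list(mm = mm, cohort = cohort, kin = kin)
}

#' Metabolome-wide association scan
#'
#' Fits every metabolite with [fit_lmm()] against the standard design and
#' applies the two-stage interaction rule: the model is first fitted with
#' the age x weight interaction and, if no metabolite's interaction
#' coefficient survives FDR at `alpha`, all metabolites are refitted
#' without it. FDR is applied per coefficient across metabolites.
#'
#' @param mm a `tech_adjusted` [metabolite_matrix()].
#' @param cohort aligned covariate table.
#' @param kin a [kinship_matrix].
#' @param alpha FDR level (default 0.05).
#' @param interactions include interaction terms in the first-stage model.
#' @param reml use REML (default FALSE).
#' @param cbc_cols CBC covariate columns passed to [build_design()].
#' @return object of class `mwas_result`: list with `table` (long
#'   data.frame, one row per metabolite x coefficient with q-values),
#'   `fits`, `design`, `interaction_removed`, `significant` (named list of
#'   metabolite sets with q <= alpha per coefficient), `alpha`.
#' @export
mwas <- function(mm, cohort, kin, alpha = 0.05, interactions = TRUE,
                 reml = TRUE, cbc_cols = NULL) {
  .check_state(mm, "tech_adjusted")
  al <- .align_inputs(mm, cohort, kin)
  eig <- .kin_eigen(al$kin$K)
  des <- build_design(al$cohort, cbc_cols = cbc_cols,
                      interactions = interactions)
  fits <- .fit_panel(al$mm$values, des, eig, reml = reml)
  tab <- .panel_table(fits)
  interaction_removed <- FALSE
  if (interactions && "sqrt_age:sqrt_weight" %in% tab$coefficient) {
    qi <- tab$q[tab$coefficient == "sqrt_age:sqrt_weight"]
    if (!any(qi <= alpha, na.rm = TRUE)) {
      interaction_removed <- TRUE
      des <- build_design(al$cohort, cbc_cols = cbc_cols,
                          interactions = TRUE,
                          age_weight_interaction = FALSE)
      fits <- .fit_panel(al$mm$values, des, eig, reml = reml)
      tab <- .panel_table(fits)
    }
  }
  sig <- lapply(split(tab, tab$coefficient), function(d)
    d$metabolite[!is.na(d$q) & d$q <= alpha])
  structure(list(table = tab, fits = fits, design = des,
                 interaction_removed = interaction_removed,
                 significant = sig, alpha = alpha, eig = eig,
                 cohort = al$cohort, kin = al$kin),
            class = "mwas_result")
}

#' Test one extra covariate across the metabolome
#'
#' Adds a covariate to the standard design (dummy-coded against a
#' reference level for factors, standardized for numerics) and reports its
#' coefficients with FDR across metabolites. One mechanism covers the
#' diet-contrast, urine-specific-gravity and bilirubin analyses.
#'
#' @param mm a `tech_adjusted` [metabolite_matrix()].
#' @param cohort aligned covariate table.
#' @param kin a [kinship_matrix].
#' @param covariate cohort column to test.
#' @param reference reference level (required for factor covariates).
#' @param alpha FDR level.
#' @param cbc_cols CBC covariate columns.
#' @return an `mwas_result` whose `significant` entries for the covariate
#'   coefficients carry the contrast results.
#' @export
contrast_covariate <- function(mm, cohort, kin, covariate, reference = NULL,
                               alpha = 0.05, cbc_cols = NULL) {
  .check_state(mm, "tech_adjusted")
  al <- .align_inputs(mm, cohort, kin)
  v <- al$cohort[[covariate]]
  if (is.null(v)) .stopf("unknown covariate '%s'", covariate)
  is_factor <- is.factor(v) || is.character(v)
  if (is_factor && length(unique(v)) < 2L)
    .stopf("covariate '%s' needs >= 2 levels", covariate)
  eig <- .kin_eigen(al$kin$K)
  des <- if (is_factor)
    build_design(al$cohort, cbc_cols = cbc_cols, interactions = TRUE,
                 age_weight_interaction = FALSE,
                 extra_factor = covariate, reference = reference)
  else
    build_design(al$cohort, cbc_cols = cbc_cols, interactions = TRUE,
                 age_weight_interaction = FALSE, extra_numeric = covariate)
  fits <- .fit_panel(al$mm$values, des, eig)
  tab <- .panel_table(fits)
  keep_cf <- grep(paste0("^", covariate), unique(tab$coefficient),
                  value = TRUE)
  sig <- lapply(split(tab, tab$coefficient), function(d)
    d$metabolite[!is.na(d$q) & d$q <= alpha])
  structure(list(table = tab, fits = fits, design = des,
                 covariate = covariate, contrast_coefficients = keep_cf,
                 significant = sig, alpha = alpha),
            class = "mwas_result")
}

#' Refit the association scan on a sample subset
#'
#' Subsets samples by a predicate, rebuilds the design and the principal
#' submatrix of K consistently, and reruns [mwas()].
#'
#' @param mm a `tech_adjusted` [metabolite_matrix()].
#' @param cohort aligned covariate table.
#' @param kin a [kinship_matrix].
#' @param predicate logical vector over cohort rows, or a function of the
#'   cohort returning one (e.g. `function(co) co$diet == "kibble"`).
#' @param ... passed to [mwas()].
#' @return an `mwas_result` on the subset.
#' @export
subset_refit <- function(mm, cohort, kin, predicate, ...) {
  .check_state(mm, "tech_adjusted")
  al <- .align_inputs(mm, cohort, kin)
  keep <- if (is.function(predicate)) predicate(al$cohort) else predicate
  keep <- as.logical(keep)
  if (length(keep) != nrow(al$cohort)) .stopf("predicate length mismatch")
  p_guess <- 6L + length(grep("^cbc", names(al$cohort))) + 2L
  if (sum(keep) < p_guess + 5L)
    .stopf("subset keeps %d dogs; need at least p + 5 = %d", sum(keep),
           p_guess + 5L)
  mm_s <- .mm_subset_samples(al$mm, keep)
  mwas(mm_s, al$cohort[keep, , drop = FALSE], .kin_subset(al$kin,
       rownames(mm_s$values)), ...)
}
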