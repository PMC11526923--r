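#' Causal mediation analysis for one metabolite
#'
#' Linear no-interaction mediation of the age effect through a mediator
#' (e.g. serum creatinine). Two ordinary linear fits share the covariate
#' design: the mediator model `M ~ age + X` and the outcome model
#' `y ~ age + M + X`. The average causal mediation effect (ACME) is the
#' product of coefficients `a_hat * b_hat`; the total effect is the age
#' coefficient of the outcome model with the mediator excluded, so
#' `acme + direct = total` holds exactly. Inference is by nonparametric
#' case-resampling bootstrap (dogs resampled with replacement, both models
#' refitted); percentile confidence intervals and a two-sided bootstrap
#' p-value are reported. A permutation-of-age null is available through
#' `null = "permute"`.
#'
#' @param y metabolite response vector.
#' @param age age regressor (the square-root-transformed ages in the
#'   standard pipeline).
#' @param mediator mediator vector (must not be constant).
#' @param X covariate matrix (without intercept column requirement; an
#'   intercept is added; collinear columns are pruned with a warning).
#' @param n_boot number of bootstrap resamples (>= 1000; default 10000).
#' @param seed integer seed for the bootstrap stream.
#' @param conf confidence level for the percentile interval.
#' @param null "bootstrap" (default) for case-resampling inference, or
#'   "permute" for a permutation-of-age null p-value.
#' @return object of class `mediation_fit`: `acme`, `direct`, `total`,
#'   `prop_mediated` (NA when total = 0), `ci`, `p`, `a`, `b`,
#'   `rho_tilde` (residual correlation used by [sensitivity()]),
#'   `sigma1`, `sigma2`, `n_boot`, `seed`.
#' @export
mediate <- function(y, age, mediator, X = NULL, n_boot = 10000L,
                    seed = 1L, conf = 0.95, null = c("bootstrap",
                                                     "permute")) {
  null <- match.arg(null)
  if (n_boot < 1000L) .stopf("n_boot must be >= 1000")
  n <- length(y)
  if (stats::sd(mediator) == 0) .stopf("mediator is constant")
  X <- if (is.null(X)) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
       else {
         Xm <- .design_X(X)
         if (!any(apply(Xm, 2, function(z) all(z == z[1])))) {
           Xm <- cbind(`(Intercept)` = 1, Xm)
         }
         Xm
       }
  ## prune collinear covariates (mediator collinear with X is an error)
  qr_x <- qr(cbind(X, mediator))
  if (qr_x$rank <= ncol(X)) {
    qr0 <- qr(X)
    if (qr0$rank == ncol(X))
      .stopf("mediator is collinear with the covariates")
  }
  qr0 <- qr(X)
  if (qr0$rank < ncol(X)) {
    keep <- sort(qr0$pivot[seq_len(qr0$rank)])
    .warnf("pruning collinear covariate column(s): %s",
           paste(colnames(X)[-keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }

  est <- .mediate_point(y, age, mediator, X)

  set.seed(seed %% .Machine$integer.max)
  boot <- matrix(NA_real_, n_boot, 3L)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    e <- tryCatch(.mediate_point(y[idx], age[idx], mediator[idx],
                                 X[idx, , drop = FALSE]),
                  error = function(err) NULL)
    if (!is.null(e)) boot[b, ] <- c(e$acme, e$direct, e$total)
  }
  boot <- boot[stats::complete.cases(boot), , drop = FALSE]
  alpha2 <- (1 - conf) / 2
  ci <- stats::quantile(boot[, 1], c(alpha2, 1 - alpha2), names = FALSE,
                        type = 7)
  if (null == "bootstrap") {
    ## percentile bootstrap two-sided p: smallest level at which the CI
    ## excludes zero
    frac <- mean(boot[, 1] <= 0)
    p <- 2 * min(frac, 1 - frac)
    p <- min(1, max(p, 1 / nrow(boot)))
  } else {
    perm <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      ap <- age[sample.int(n, n)]
      perm[b] <- .mediate_point(y, ap, mediator, X)$acme
    }
    p <- (1 + sum(abs(perm) >= abs(est$acme))) / (1 + n_boot)
  }
  structure(c(est, list(ci = ci, p = p, conf = conf, n_boot = nrow(boot),
                        seed = seed, null = null)),
            class = "mediation_fit")
}

## point estimates for one (sub)sample; shared by bootstrap
.mediate_point <- function(y, age, mediator, X) {
  Dm <- cbind(age = age, X)
  fm <- stats::lm.fit(Dm, mediator)
  a <- fm$coefficients["age"]
  Do <- cbind(age = age, mediator = mediator, X)
  fo <- stats::lm.fit(Do, y)
  b <- fo$coefficients["mediator"]
  d <- fo$coefficients["age"]
  ft <- stats::lm.fit(Dm, y)
  total <- ft$coefficients["age"]
  r1 <- fm$residuals; r2 <- ft$residuals
  s1 <- sqrt(sum(r1^2) / length(r1))
  s2 <- sqrt(sum(r2^2) / length(r2))
  rho_tilde <- sum(r1 * r2) / (length(r1) * s1 * s2)
  acme <- unname(a * b)
  list(acme = acme, direct = unname(d), total = unname(total),
       prop_mediated = if (abs(total) > 0) acme / unname(total) else
         NA_real_,
       a = unname(a), b = unname(b), rho_tilde = unname(rho_tilde),
       sigma1 = s1, sigma2 = s2)
}

#' Mediation analysis across a metabolite panel
#'
#' Runs [mediate()] per metabolite (typically restricted to responses with
#' a significant age effect), applies Benjamini-Hochberg FDR to the ACME
#' p-values, and attaches the sensitivity root from [sensitivity()].
#'
#' @param mm a `tech_adjusted` [metabolite_matrix()].
#' @param cohort aligned covariate table.
#' @param mediator cohort column used as mediator (default "creatinine").
#' @param metabolites metabolite names to analyze (default all).
#' @param alpha FDR level.
#' @param n_boot,seed,conf passed to [mediate()].
#' @param cbc_cols CBC columns for the covariate design (the kinship
#'   random effect is intentionally absent from mediation models).
#' @param sensitive_threshold |rho0| at or below which a mediation is
#'   flagged sensitive to unmeasured confounding (default 0.3).
#' @return list of class `mediation_panel`: `table` (one row per
#'   metabolite: acme, direct, total, prop_mediated, ci bounds, p, q,
#'   rho0, sensitive), `fits`, `alpha`.
#' @export
mediate_panel <- function(mm, cohort, mediator = "creatinine",
                          metabolites = NULL, alpha = 0.05,
                          n_boot = 10000L, seed = 1L, conf = 0.95,
                          cbc_cols = NULL, sensitive_threshold = 0.3) {
  .check_state(mm, "tech_adjusted")
  mets <- metabolites %||% colnames(mm$values)
  miss <- setdiff(mets, colnames(mm$values))
  if (length(miss)) .stopf("unknown metabolite(s): %s",
                           paste(miss, collapse = ", "))
  co <- cohort[match(rownames(mm$values), cohort$dog_id), , drop = FALSE]
  M <- co[[mediator]]
  if (is.null(M)) .stopf("unknown mediator column '%s'", mediator)
  des <- build_design(co, cbc_cols = cbc_cols, interactions = FALSE)
  X <- des$X[, setdiff(colnames(des$X), "sqrt_age"), drop = FALSE]
  age <- sqrt(co$age)
  fits <- list()
  rows <- list()
  for (i in seq_along(mets)) {
    m <- mets[i]
    f <- tryCatch(mediate(mm$values[, m], age, M, X, n_boot = n_boot,
                          seed = (seed + i) %% .Machine$integer.max,
                          conf = conf),
                  error = function(e) {
                    .warnf("mediation failed for '%s': %s", m,
                           conditionMessage(e))
                    NULL
                  })
    fits[[m]] <- f
    if (is.null(f)) next
    sens <- sensitivity(f)
    rows[[m]] <- data.frame(metabolite = m, acme = f$acme,
                            direct = f$direct, total = f$total,
                            prop_mediated = f$prop_mediated,
                            ci_lo = f$ci[1], ci_hi = f$ci[2], p = f$p,
                            rho0 = sens$rho0,
                            sensitive = !is.na(sens$rho0) &&
                              abs(sens$rho0) <= sensitive_threshold,
                            row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  tab$q <- fdr_adjust(tab$p)
  structure(list(table = tab, fits = fits, alpha = alpha,
                 mediator = mediator,
                 sensitive_threshold = sensitive_threshold),
            class = "mediation_panel")
}

#' Sensitivity of the ACME to unmeasured confounding
#'
#' Recomputes the ACME as a function of an assumed correlation rho between
#' the structural errors of the mediator and outcome models, using the
#' closed form for linear models:
#' `acme(rho) = a * (sigma2 / sigma1) * (rho_tilde - rho *
#' sqrt((1 - rho_tilde^2) / (1 - rho^2)))`,
#' where `rho_tilde` is the observed correlation between the residuals of
#' the mediator model and of the total-effect outcome model. The curve is
#' monotone in rho, equals the unadjusted ACME at rho = 0, and crosses
#' zero exactly at `rho0 = rho_tilde`.
#'
#' @param fit a `mediation_fit`.
#' @param rho_grid grid of rho values (default 39 points over
#'   \[-0.95, 0.95\]).
#' @return list with `rho0`, `curve` (data.frame rho, acme), `rho_grid`.
#' @export
sensitivity <- function(fit, rho_grid = (-19:19) / 20) {
  stopifnot(inherits(fit, "mediation_fit"))
  rt <- fit$rho_tilde
  acme_rho <- fit$a * (fit$sigma2 / fit$sigma1) *
    (rt - rho_grid * sqrt((1 - rt^2) / (1 - rho_grid^2)))
  rho0 <- if (rt >= min(rho_grid) && rt <= max(rho_grid)) rt else NA_real_
  list(rho0 = rho0, curve = data.frame(rho = rho_grid, acme = acme_rho),
       rho_grid = rho_grid)
}
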