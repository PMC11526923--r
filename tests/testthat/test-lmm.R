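test_that("identity kinship reduces to ordinary least squares", {
  set.seed(10)
  n <- 60
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  y <- drop(X %*% c(1, 0.5, -0.2)) + rnorm(n)
  fit <- fit_lmm(y, X, identity_kinship(sprintf("d%02d", 1:n)))
  ols <- lm.fit(X, y)
  expect_equal(unname(fit$beta), unname(ols$coefficients),
               tolerance = 1e-8)
  expect_equal(unname(fit$blups), rep(0, n))
  expect_identical(fit$boundary, "zero")
})

test_that("eigen-trick optimum matches the dense brute-force oracle", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(30:60, 1)
    kin <- random_pd_kinship(n)
    X <- cbind(1, rnorm(n), runif(n))
    colnames(X) <- c("(Intercept)", "x1", "x2")
    h2 <- runif(1, 0, 0.8)
    u <- drop(.psd_sqrt_test(kin$K) %*% rnorm(n)) * sqrt(h2)
    y <- drop(X %*% c(0.5, 1, -1)) + u + rnorm(n, sd = sqrt(1 - h2))
    fit <- fit_lmm(y, X, kin, reml = FALSE)
    oracle <- dense_grid_fit(y, X, kin$K, npts = 400)
    expect_gte(fit$loglik, oracle$loglik - 1e-6)
    ## eigen-trick likelihood agrees with the dense likelihood pointwise
    ## (dense parameterizes the ratio as lambda = sigma_g^2/sigma_e^2;
    ## the fast path uses delta = 1/lambda)
    prep <- metaboKin:::.lmm_prep(X, eigK = metaboKin:::.kin_eigen(kin$K))
    eta2 <- drop(crossprod(prep$Up, y))^2
    for (lam in c(0.1, 1, 5)) {
      ll_dense <- dense_profile_ll(lam, y, X, kin$K)
      ll_fast <- metaboKin:::.profile_ll(log(1 / lam), eta2, prep$lambda,
                                         prep$eigK$values, prep$n, prep$q)
      expect_equal(ll_fast, ll_dense, tolerance = 1e-6)
    }
  }
})

test_that("null genetic variance drives h_snp to the boundary", {
  set.seed(12)
  ## block-structured kinship (eigenvalue spread) keeps h2 identifiable
  sim <- get_sim()
  kin <- sim$kinship
  n <- nrow(kin$K)
  X <- cbind(1, rnorm(n))
  colnames(X) <- c("(Intercept)", "x")
  eig <- metaboKin:::.kin_eigen(kin$K)
  hs <- replicate(20, {
    y <- drop(X %*% c(1, 0.3)) + rnorm(n)
    fit_lmm(y, X, kin, eig = eig)$h_snp
  })
  expect_lt(mean(hs), 0.15)
  expect_gt(mean(hs == 0), 0.2)     # many replicates end on the boundary
})

test_that("scaling the response scales estimates, not p-values", {
  set.seed(13)
  n <- 50
  kin <- random_kinship(n)
  X <- cbind(1, rnorm(n))
  colnames(X) <- c("(Intercept)", "x")
  y <- rnorm(n) + 0.5 * X[, 2]
  f1 <- fit_lmm(y, X, kin)
  f2 <- fit_lmm(7 * y, X, kin)
  expect_equal(f2$beta, 7 * f1$beta, tolerance = 1e-6)
  expect_equal(f2$blups, 7 * f1$blups, tolerance = 1e-6)
  expect_lt(max(abs(f2$p - f1$p)), 1e-8)
})

test_that("adding the GRM never lowers the maximized log-likelihood", {
  set.seed(14)
  sim <- get_sim()
  mm <- get_mm()
  co <- sim$cohort[match(rownames(mm$values), sim$cohort$dog_id), ]
  X <- build_design(co, cbc_cols = sprintf("cbc%02d", 1:3))
  kin <- metaboKin:::.kin_subset(sim$kinship, rownames(mm$values))
  for (j in c(1, 20, 40)) {
    y <- mm$values[, j]
    f_k <- fit_lmm(y, X, kin)
    f_i <- fit_lmm(y, X, identity_kinship(rownames(mm$values)))
    expect_gte(f_k$loglik, f_i$loglik - 1e-8)
  }
})

test_that("fixed-effect tests are calibrated under the null", {
  set.seed(15)
  n <- 80
  kin <- random_kinship(n)
  eig <- metaboKin:::.kin_eigen(kin$K)
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("(Intercept)", "age", "z")
  sqK <- .psd_sqrt_test(kin$K)
  ## beta_age = 0 truth; 300 replicates (down from 500 for runtime)
  ps <- replicate(300, {
    y <- 1 + 0.5 * X[, 3] + drop(sqK %*% rnorm(n)) * sqrt(0.3) +
      rnorm(n, sd = sqrt(0.7))
    fit_lmm(y, X, kin, eig = eig)$p[["age"]]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  ## noise-free fixture: p -> 0
  yy <- drop(X %*% c(0, 2, 0)) + rnorm(n, sd = 1e-8)
  expect_lt(fit_lmm(yy, X, kin)$p[["age"]], 1e-20)
})

test_that("test_fixed_effects flags degenerate standard errors", {
  set.seed(16)
  n <- 40
  X <- cbind(1, rnorm(n))
  colnames(X) <- c("(Intercept)", "x")
  fit <- fit_lmm(rnorm(n), X, identity_kinship(as.character(1:n)))
  expect_equal(test_fixed_effects(fit), fit$p, tolerance = 1e-12)
  fit$se[2] <- 0
  expect_warning(p <- test_fixed_effects(fit), "standard error")
  expect_true(is.na(p[["x"]]))
})

test_that("BH adjustment matches hand computation and handles NAs", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_adjust(0.2), 0.2)
  q <- fdr_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], c(0.02, 0.04))   # m = 2 non-missing tests
  expect_true(all(fdr_adjust(runif(20)) >= sort(runif(20))[1]))
  expect_error(fdr_adjust(c(-0.1, 0.5)), "0, 1")
})

test_that("design builder applies transforms and prunes degeneracy", {
  sim <- get_sim()
  co <- sim$cohort
  des <- build_design(co, cbc_cols = sprintf("cbc%02d", 1:3))
  expect_true(all(c("(Intercept)", "sqrt_age", "sqrt_weight",
                    "sqrt_age:sqrt_weight", "sex:sterilized") %in%
                    colnames(des$X)))
  expect_equal(des$X[, "sqrt_age"], sqrt(co$age), ignore_attr = TRUE)
  ## duplicated covariate pruned with warning
  co2 <- co
  co2$dup <- sqrt(co$age)
  expect_warning(des2 <- build_design(co2, cbc_cols = NULL,
                                      extra_numeric = "dup"),
                 "pruning")
  expect_false("dup" %in% colnames(des2$X))
  ## extra numeric standardized
  des3 <- build_design(co, cbc_cols = NULL, extra_numeric = "creatinine")
  expect_equal(mean(des3$X[, "creatinine"]), 0, tolerance = 1e-12)
  expect_equal(sd(des3$X[, "creatinine"]), 1, tolerance = 1e-12)
  ## factor requires a present reference
  expect_error(build_design(co, extra_factor = "diet", reference = "nope"),
               "reference")
})

test_that("mwas applies the two-stage interaction rule", {
  sim <- get_sim()
  scan <- get_scan()
  ## default generator has no true interaction -> term removed
  expect_true(scan$interaction_removed)
  expect_false("sqrt_age:sqrt_weight" %in% scan$table$coefficient)
  ## q >= p elementwise and h_snp in [0, 1]
  ok <- !is.na(scan$table$p)
  expect_true(all(scan$table$q[ok] >= scan$table$p[ok] - 1e-12))
  expect_true(all(scan$table$h_snp >= 0 & scan$table$h_snp <= 1))
  ## planted age effects are recovered among the hits
  hits <- scan$significant[["sqrt_age"]]
  truth <- rownames(get_cfg()$effect_table)[
    get_cfg()$effect_table$age != 0]
  expect_gt(length(intersect(hits, truth)), 5)
})

test_that("mwas retains a truly present interaction", {
  set.seed(17)
  sim <- get_sim()
  mm <- get_mm()
  ## inject a strong age x weight interaction into 6 metabolites
  co <- sim$cohort[match(rownames(mm$values), sim$cohort$dog_id), ]
  mm2 <- mm
  ixn <- scale(sqrt(co$age) * sqrt(co$weight))
  for (j in 1:6) mm2$values[, j] <- mm2$values[, j] + 1.0 * drop(ixn)
  scan2 <- mwas(mm2, sim$cohort, sim$kinship,
                cbc_cols = sprintf("cbc%02d", 1:3))
  expect_false(scan2$interaction_removed)
  expect_true("sqrt_age:sqrt_weight" %in% scan2$table$coefficient)
})

test_that("contrast_covariate recovers an injected diet effect", {
  set.seed(18)
  sim <- get_sim()
  mm <- get_mm()
  co <- sim$cohort[match(rownames(mm$values), sim$cohort$dog_id), ]
  raw_idx <- co$diet == "raw_commercial"
  mm2 <- mm
  mm2$values[raw_idx, 2] <- mm2$values[raw_idx, 2] - 1.5
  res <- contrast_covariate(mm2, sim$cohort, sim$kinship, "diet",
                            reference = "kibble",
                            cbc_cols = sprintf("cbc%02d", 1:3))
  row <- res$table[res$table$metabolite == "met002" &
                     res$table$coefficient == "diet_raw_commercial", ]
  expect_lt(row$beta, -0.5)
  expect_lt(row$q, 0.05)
  ## absent reference level errors
  expect_error(contrast_covariate(mm, sim$cohort, sim$kinship, "diet",
                                  reference = "caviar"), "reference")
})

test_that("subset_refit with an all-true predicate reproduces the scan", {
  sim <- get_sim()
  mm <- get_mm()
  scan <- get_scan()
  full <- subset_refit(mm, sim$cohort, sim$kinship,
                       rep(TRUE, nrow(mm$values)),
                       cbc_cols = sprintf("cbc%02d", 1:5))
  expect_equal(full$table$beta, scan$table$beta, tolerance = 1e-10)
  expect_equal(full$table$loglik, scan$table$loglik, tolerance = 1e-10)
  ## a principal submatrix of K stays PSD
  sub <- subset_refit(mm, sim$cohort, sim$kinship,
                      function(co) co$diet == "kibble",
                      cbc_cols = sprintf("cbc%02d", 1:5))
  expect_s3_class(sub, "mwas_result")
  ## too-small subsets are rejected
  pred <- rep(FALSE, nrow(mm$values)); pred[1:5] <- TRUE
  expect_error(subset_refit(mm, sim$cohort, sim$kinship, pred), "at least")
})
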