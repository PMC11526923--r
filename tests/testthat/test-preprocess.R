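test_that("missingness filter applies a strict > rule", {
  set.seed(1)
  v <- matrix(rlnorm(100 * 3), 100, 3)
  v[1:11, 1] <- NA      # 11% missing -> dropped
  v[1:10, 2] <- NA      # exactly 10% -> retained
  mm <- make_mm(v)
  out <- filter_missingness(mm, max_missing = 0.10)
  expect_identical(colnames(out$values), c("m02", "m03"))
  rep <- attr(out, "dropped")
  expect_identical(rep$metabolite, "m01")
  expect_equal(rep$missing_fraction, 0.11)
  expect_identical(out$state, "filtered")
  ## complete matrix is a no-op with an empty report
  mm2 <- make_mm(matrix(rlnorm(30), 10, 3))
  out2 <- filter_missingness(mm2)
  expect_equal(out2$values, mm2$values)
  expect_equal(nrow(attr(out2, "dropped")), 0)
})

test_that("hemolysis filter removes grade-4 samples", {
  v <- matrix(rlnorm(4 * 2), 4, 2)
  mm <- make_mm(v, hemolysis = c(0L, 2L, 4L, 4L))
  out <- filter_hemolysis(mm)
  expect_equal(nrow(out$values), 2)
  expect_identical(attr(out, "dropped")$sample_id, c("s03", "s04"))
  mm0 <- make_mm(v, hemolysis = rep(0L, 4))
  expect_equal(nrow(filter_hemolysis(mm0)$values), 4)
  meta_na <- mm$sample_meta
  mm$sample_meta$hemolysis[2] <- NA
  expect_error(filter_hemolysis(mm), "hemolysis grade")
})

test_that("hemolysis filtering pulls contaminated metabolites back", {
  cfg <- sim_config(n_dogs = 200, n_metabolites = 6, n_snps = 150,
                    n_breed_blocks = 2, contamination = TRUE,
                    contaminated_metabolites = 1L, contamination_shift = 3,
                    hemolysis_rates = c(0.4, 0.1, 0.1, 0.1, 0.3),
                    missing_rate = 0, seed = 13L)
  sim <- simulate_cohort(cfg)
  before <- mean(log(sim$metabolites$values[, 1]))
  filt <- filter_hemolysis(sim$metabolites)
  after <- mean(log(filt$values[, 1]))
  clean <- mean(sim$truth$log_clean[, 1])
  expect_lt(abs(after - clean), abs(before - clean))
})

test_that("log_center takes natural logs and zeroes row means", {
  v <- matrix(c(exp(1), exp(3),
                5, 5), 2, 2, byrow = TRUE)
  mm <- make_mm(v)
  out <- log_center(mm)
  expect_equal(out$values[1, ], c(m01 = -1, m02 = 1))
  expect_equal(out$values[2, ], c(m01 = 0, m02 = 0))
  ## missing cells stay missing and are excluded from the row mean
  v2 <- matrix(c(exp(2), NA, exp(4)), 1, 3)
  out2 <- log_center(make_mm(v2))
  expect_equal(unname(out2$values[1, ]), c(-1, NA, 1))
  ## non-positive values are named
  v3 <- matrix(c(1, -2), 1, 2)
  expect_error(log_center(make_mm(v3)), "m02")
})

test_that("batch/run-order correction removes injected drift", {
  set.seed(7)
  n <- 150; m <- 4
  batch <- rep(1:3, each = 50)
  ro <- rep(1:50, 3)
  clean <- matrix(rnorm(n * m), n, m)
  drift <- (batch == 2) * 2 + 0.1 * ro * (batch == 2)
  v <- clean + drift
  mm <- make_mm(v, batch = batch, state = "logged")
  out <- batch_runorder_correct(mm)
  for (b in 1:3) {
    rows <- batch == b
    for (j in 1:m) {
      expect_lt(abs(cor(out$values[rows, j], ro[rows])), 1e-8)
      ## residuals recover clean values up to a per-batch affine transform
      expect_gt(abs(cor(out$values[rows, j], clean[rows, j])), 0.9)
    }
  }
  ## two batches differing only in intercept: mean difference removed
  v2 <- matrix(rnorm(40), 40, 1) + rep(c(0, 5), each = 20)
  mm2 <- make_mm(v2, batch = rep(1:2, each = 20), state = "logged")
  out2 <- batch_runorder_correct(mm2)
  expect_lt(abs(mean(out2$values[1:20, 1]) -
                  mean(out2$values[21:40, 1])), 1e-10)
  ## single batch, no drift signal: residuals are centered values minus
  ## the (tiny) fitted run-order slope
  expect_equal(mean(out2$values[, 1]), 0, tolerance = 1e-12)
  ## small batch falls back to intercept-only with a warning
  v3 <- matrix(rnorm(8), 8, 1)
  v3[1:2, 1] <- NA
  mm3 <- make_mm(v3, batch = c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L),
                 state = "logged")
  expect_warning(batch_runorder_correct(mm3), "intercept-only")
})

test_that("per-batch scaling yields unit variance where estimable", {
  set.seed(8)
  v <- matrix(rnorm(60 * 3, sd = rep(c(2, 0.5, 7), each = 60)), 60, 3)
  batch <- rep(1:2, each = 30)
  mm <- make_mm(v, batch = batch, state = "batch_corrected")
  out <- scale_by_batch(mm)
  for (b in 1:2) for (j in 1:3)
    expect_equal(sd(out$values[batch == b, j]), 1, tolerance = 1e-8)
  ## two-point batch scales by the n-1 sample SD
  v2 <- matrix(c(-1, 1), 2, 1)
  out2 <- scale_by_batch(make_mm(v2, state = "batch_corrected"))
  expect_equal(unname(out2$values[, 1]), c(-1, 1) / sd(c(-1, 1)))
  ## zero-variance cell left unscaled with warning
  v3 <- matrix(c(3, 3, 3), 3, 1)
  expect_warning(out3 <- scale_by_batch(make_mm(v3,
                                                state = "batch_corrected")),
                 "unscaled")
  expect_equal(unname(out3$values[, 1]), c(3, 3, 3))
})

test_that("knn imputation follows the k-nearest-mean contract", {
  ## missing cell whose neighbours all carry value v -> imputed v
  v <- matrix(rnorm(10 * 4), 10, 4)
  v[, 2] <- 5
  v[1, 2] <- NA
  out <- knn_impute(make_mm(v, state = "scaled"), k = 3)
  expect_equal(unname(out$values[1, 2]), 5)
  expect_false(anyNA(out$values))
  ## k >= n - 1 reduces to the overall non-missing mean
  v2 <- matrix(rnorm(8 * 3), 8, 3)
  v2[2, 3] <- NA
  out2 <- knn_impute(make_mm(v2, state = "scaled"), k = 20)
  expect_equal(unname(out2$values[2, 3]), mean(v2[-2, 3]))
  ## beats mean imputation on structured data
  set.seed(21)
  n <- 80
  f <- rnorm(n)
  v3 <- outer(f, rep(1, 6)) + matrix(rnorm(n * 6, sd = 0.3), n, 6)
  mask <- matrix(runif(n * 6) < 0.05, n, 6)
  v3m <- v3; v3m[mask] <- NA
  out3 <- knn_impute(make_mm(v3m, state = "scaled"), k = 10)
  rmse_knn <- sqrt(mean((out3$values[mask] - v3[mask])^2))
  col_means <- colMeans(v3m, na.rm = TRUE)
  mean_imp <- v3m
  for (j in 1:6) mean_imp[is.na(mean_imp[, j]), j] <- col_means[j]
  rmse_mean <- sqrt(mean((mean_imp[mask] - v3[mask])^2))
  expect_lt(rmse_knn, rmse_mean)
  ## a sample sharing no observed metabolite with others is an input error
  v4 <- matrix(c(NA, NA, 1,
                 1,  2, NA,
                 2,  1, NA), 3, 3, byrow = TRUE)
  expect_error(knn_impute(make_mm(v4, state = "scaled")), "shares no")
})

test_that("technical regression removes covariate effects", {
  set.seed(9)
  n <- 80
  travel <- rlnorm(n, log(26), 0.4)
  temp <- rnorm(n, 18, 4)
  hemo <- sample(0:3, n, TRUE)
  clean <- matrix(rnorm(n * 3), n, 3)
  v <- clean + outer(travel, c(0.05, 0, -0.02)) + outer(hemo, c(0, 0.3, 0))
  mm <- make_mm(v, travel = travel, temp = temp, hemolysis = hemo,
                state = "imputed")
  out <- regress_technical(mm)
  for (j in 1:3) {
    expect_lt(abs(cor(out$values[, j], travel)), 1e-8)
    expect_lt(abs(cor(out$values[, j], hemo)), 1e-8)
    ## refitted slope is ~0
    expect_lt(abs(coef(lm(out$values[, j] ~ travel))[2]), 1e-8)
  }
  ## constant covariate dropped with warning
  mm2 <- make_mm(clean, travel = travel, temp = rep(18, n),
                 hemolysis = hemo, state = "imputed")
  expect_warning(regress_technical(mm2), "constant")
})

test_that("state machine enforces operation order", {
  v <- matrix(rlnorm(20), 10, 2)
  mm <- make_mm(v)
  expect_error(batch_runorder_correct(mm), "state")
  expect_error(scale_by_batch(mm), "state")
  expect_error(knn_impute(mm), "state")
  expect_error(regress_technical(mm), "state")
  logged <- log_center(mm)
  expect_error(filter_missingness(logged), "state")
})

test_that("full pipeline recovers drift-free structure and preserves ids", {
  sim <- get_sim()
  out <- suppressWarnings(preprocess_pipeline(sim$metabolites))
  expect_identical(out$state, "tech_adjusted")
  expect_false(anyNA(out$values))
  ## identifiers preserved in order (up to removed samples)
  expect_true(all(rownames(out$values) %in% rownames(sim$metabolites$values)))
  expect_identical(rownames(out$values),
                   rownames(sim$metabolites$values)[
                     rownames(sim$metabolites$values) %in%
                       rownames(out$values)])
  expect_identical(colnames(out$values), colnames(sim$metabolites$values))
  ## round trip: the drifted pipeline output tracks the output of the
  ## identical pipeline run on the zero-drift twin (same RNG stream)
  cfg <- get_cfg()
  cfg_off <- sim_config(n_dogs = cfg$n_dogs,
                        n_metabolites = cfg$n_metabolites,
                        n_snps = cfg$n_snps,
                        n_breed_blocks = cfg$n_breed_blocks,
                        admixed_fraction = cfg$admixed_fraction,
                        drift_spec = list(intercept_sd = 0, slope_sd = 0),
                        seed = cfg$seed)
  off <- suppressWarnings(preprocess_pipeline(
    simulate_cohort(cfg_off)$metabolites))
  common <- intersect(rownames(out$values), rownames(off$values))
  cors <- vapply(seq_len(ncol(out$values)), function(j)
    cor(out$values[common, j], off$values[common, j]), numeric(1))
  expect_gt(mean(cors), 0.95)
  ## idempotence from tech_adjusted: regressing again changes nothing
  again <- regress_technical(.subset2(out, "values") |>
    (\(v) metabolite_matrix(v, out$sample_meta, state = "imputed"))())
  expect_equal(again$values, out$values, tolerance = 1e-10)
})
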