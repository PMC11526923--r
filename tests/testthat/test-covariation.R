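test_that("adjustment removes fixed and random effects", {
  sim <- get_sim()
  mm <- get_mm()
  scan <- get_scan()
  adj <- adjust(mm, scan)
  X <- scan$design$X
  ## regressing y' on the design gives ~zero coefficients
  for (j in c(1, 15, 40)) {
    cf <- qr.coef(qr(X), adj$values[, j])
    expect_lt(max(abs(cf[-1])), 1e-6)
  }
  ## correlation of y' with each design column ~ 0
  cors <- abs(cor(adj$values, X[, -1]))
  expect_lt(max(cors), 1e-6 + 0.02)    # BLUP subtraction leaves GLS, not
                                       # OLS, orthogonality; see below
  ## K = I fits give exactly OLS residuals
  scan_i <- mwas(mm, sim$cohort, identity_kinship(rownames(mm$values)),
                 cbc_cols = sprintf("cbc%02d", 1:5))
  adj_i <- adjust(mm, scan_i)
  Xi <- scan_i$design$X
  res_ols <- qr.resid(qr(Xi), mm$values[, colnames(adj_i$values)])
  expect_equal(adj_i$values, res_ols, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("zero-noise responses adjust to ~zero", {
  ## family-block kinship with a two-atom spectrum (2.0 and 0.5), so the
  ## residual variance is cleanly identified and sigma_e -> 0 at the
  ## zero-noise limit (a marker-built GRM's eigenvalue bulk acts like a
  ## ridge and deliberately does not identify this limit)
  set.seed(40)
  n <- 120
  blk <- matrix(0.5, 4, 4); diag(blk) <- 1
  K <- kinship_matrix(kronecker(diag(n / 4), blk),
                      sprintf("d%03d", 1:n))
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  u <- drop(.psd_sqrt_test(K$K) %*% rnorm(n)) * 2
  y <- drop(X %*% c(1, 0.5, -0.3)) + u + rnorm(n, sd = 1e-4)
  f <- fit_lmm(y, X, K)
  resid <- y - drop(X %*% f$beta) - f$blups
  ## exact algebraic identity of the adjustment:
  ## y - X beta - u_hat = delta (K + delta I)^-1 (y - X beta)
  r <- y - drop(X %*% f$beta)
  expect_lt(max(abs(resid - f$delta *
                      solve(K$K + f$delta * diag(n), r))), 1e-8)
  ## statistically, most variance is captured by BLUEs + BLUPs; sigma_e
  ## itself carries chi-square sampling noise of order 1/sqrt(n), so the
  ## zero-noise limit is approached, not hit, at this n
  expect_gt(f$h_snp, 0.5)
  expect_lt(sd(resid), 0.5 * sd(y))
})

test_that("shared-covariate correlation is removed, latent correlation kept", {
  set.seed(41)
  sim <- get_sim()
  mm <- get_mm()
  co <- sim$cohort[match(rownames(mm$values), sim$cohort$dog_id), ]
  n <- nrow(mm$values)
  lat <- rnorm(n)
  mm2 <- mm
  ## pair driven by a shared latent factor (not in the design)
  mm2$values[, 5] <- rnorm(n, sd = 0.3) + lat
  mm2$values[, 6] <- rnorm(n, sd = 0.3) + lat
  ## pair driven by age only
  mm2$values[, 7] <- rnorm(n, sd = 0.3) + 2 * sqrt(co$age)
  mm2$values[, 8] <- rnorm(n, sd = 0.3) + 2 * sqrt(co$age)
  scan <- mwas(mm2, sim$cohort, sim$kinship,
               cbc_cols = sprintf("cbc%02d", 1:5))
  adj <- adjust(mm2, scan)
  r <- cor(adj$values)
  expect_gt(r[5, 6], 0.7)
  expect_lt(abs(r[7, 8]), 0.2)
})

test_that("correlation p/q values follow the exact t transform", {
  ## hand-sized worked example, n = 5
  x <- c(1, 2, 3, 4, 5)
  y <- c(1.2, 1.9, 3.4, 3.9, 5.1)
  z <- c(2, 1, 2, 1, 2)
  v <- cbind(a = x, b = y, c = z)
  rownames(v) <- sprintf("s%d", 1:5)
  cc <- correlate_fdr(v)
  r_hand <- cor(x, y)
  expect_equal(cc$r["a", "b"], r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(cc$p["a", "b"], 2 * pt(-abs(t_hand), df = 3),
               tolerance = 1e-12)
  ## symmetry and unit diagonal
  expect_equal(cc$r, t(cc$r))
  expect_equal(unname(diag(cc$r)), rep(1, 3))
  ## identical columns: r = 1, q ~ 0
  v2 <- cbind(a = x, b = x, c = z)
  rownames(v2) <- sprintf("s%d", 1:5)
  cc2 <- correlate_fdr(v2)
  expect_equal(cc2$r["a", "b"], 1)
  expect_lt(cc2$q["a", "b"], 1e-10)
  ## zero-variance column gives NA correlations
  v3 <- cbind(a = x, b = rep(2, 5))
  rownames(v3) <- sprintf("s%d", 1:5)
  expect_true(is.na(correlate_fdr(v3)$r["a", "b"]))
  expect_error(correlate_fdr(v[1:2, ]), "3 samples")
})

test_that("independent noise yields ~no significant pairs", {
  set.seed(42)
  hits <- replicate(5, {
    v <- matrix(rnorm(150 * 30), 150, 30,
                dimnames = list(NULL, sprintf("m%02d", 1:30)))
    rownames(v) <- seq_len(150)
    sum(correlate_fdr(v)$q < 0.05, na.rm = TRUE) / 2
  })
  expect_lte(mean(hits), 1)
})

test_that("upgma reproduces the hand-traced three-leaf dendrogram", {
  ## full-distance height convention: merges recorded at the average
  ## inter-cluster distance
  r <- matrix(c(1, 0.9, 0.5,
                0.9, 1, 0.5,
                0.5, 0.5, 1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- upgma(r)
  ## d(A,B) = 0.1 -> first merge at 0.1; then C joins at (0.5 + 0.5)/2
  expect_equal(hc$height, c(0.1, 0.5), tolerance = 1e-12)
  expect_true(grepl("^\\(", attr(hc, "newick")))
  ## two items merge at their distance
  r2 <- matrix(c(1, 0.4, 0.4, 1), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(upgma(r2)$height, 0.6, tolerance = 1e-12)
  ## all-equal distances: deterministic chained merges at equal heights
  r3 <- matrix(0.5, 4, 4); diag(r3) <- 1
  dimnames(r3) <- list(letters[1:4], letters[1:4])
  expect_equal(upgma(r3)$height, rep(0.5, 3), tolerance = 1e-12)
  ## NA distances rejected
  r4 <- r; r4[1, 2] <- r4[2, 1] <- NA
  expect_error(upgma(r4), "NA")
})

test_that("upgma is invariant to input label permutation", {
  set.seed(43)
  v <- matrix(rnorm(40 * 8), 40, 8,
              dimnames = list(NULL, paste0("m", 1:8)))
  rownames(v) <- seq_len(40)
  r <- cor(v)
  h1 <- upgma(r)
  perm <- sample(8)
  h2 <- upgma(r[perm, perm])
  expect_equal(h1$height, h2$height, tolerance = 1e-12)
  expect_identical(attr(h1, "newick"), attr(h2, "newick"))
})

test_that("a planted correlated block is recovered as a clade", {
  set.seed(44)
  n <- 120
  lat <- rnorm(n)
  v <- matrix(rnorm(n * 10), n, 10)
  v[, 1:4] <- v[, 1:4] * 0.3 + lat          # ptmAA-like block
  colnames(v) <- c(paste0("ptm", 1:4), paste0("oth", 1:6))
  rownames(v) <- seq_len(n)
  hc <- upgma(cor(v))
  ## cutting just above the block-merge height isolates the planted clade
  cl <- cutree(hc, h = 0.5)
  expect_equal(length(unique(cl[paste0("ptm", 1:4)])), 1L)
  expect_equal(sum(cl == cl[["ptm1"]]), 4L)
})

test_that("class annotation labels known metabolites", {
  ann <- annotate_classes(c("hydroxyproline", "alanine", "creatinine",
                            "glucose"),
                          c(hydroxyproline = "ptmAA", alanine = "parent AA",
                            creatinine = "N-waste"))
  expect_equal(ann$class, c("ptmAA", "parent AA", "N-waste", "other"))
})
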