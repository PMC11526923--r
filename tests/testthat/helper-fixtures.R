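## Shared fixtures and independent oracles. Expensive objects are built
## once per test run and cached.

.fx <- new.env(parent = emptyenv())

## small synthetic cohort reused across module tests
get_sim <- function() {
  if (is.null(.fx$sim)) {
    ## test-scale cohort: smaller n than the default stated world, with
    ## proportionally larger planted effects so recovery tests stay powered
    eff <- default_effect_table(40)
    eff$age <- eff$age * 2.4          # +/- 0.6 per sqrt-year
    cfg <- sim_config(n_dogs = 200, n_metabolites = 40, n_snps = 800,
                      n_breed_blocks = 4, admixed_fraction = 0.6,
                      effect_table = eff, seed = 42L)
    .fx$cfg <- cfg
    .fx$sim <- simulate_cohort(cfg)
  }
  .fx$sim
}
get_cfg <- function() { get_sim(); .fx$cfg }

## normalized matrix + scan on the shared cohort
get_scan <- function() {
  if (is.null(.fx$scan)) {
    sim <- get_sim()
    mm <- suppressWarnings(preprocess_pipeline(sim$metabolites))
    .fx$mm <- mm
    .fx$scan <- mwas(mm, sim$cohort, sim$kinship,
                     cbc_cols = sprintf("cbc%02d", 1:5))
  }
  .fx$scan
}
get_mm <- function() { get_scan(); .fx$mm }

## ---- independent dense-matrix likelihood oracle (no eigen trick) ----------
## profile log-likelihood at variance ratio lambda = sigma_g^2 / sigma_e^2,
## evaluated with solve() and determinant() on the full covariance matrix.
dense_profile_ll <- function(lambda, y, Xmat, K) {
  n <- length(y)
  V0 <- lambda * K + diag(n)
  Vi <- solve(V0)
  XtVi <- crossprod(Xmat, Vi)
  beta <- solve(XtVi %*% Xmat, XtVi %*% y)
  r <- y - Xmat %*% beta
  s2 <- drop(crossprod(r, Vi %*% r)) / n
  ld <- as.numeric(determinant(V0, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + n * log(s2) + ld + n)
}

## brute-force ML over a dense grid in log-lambda plus the zero boundary
dense_grid_fit <- function(y, Xmat, K, npts = 1000) {
  grid <- exp(seq(-25, 25, length.out = npts))
  ll <- vapply(grid, dense_profile_ll, numeric(1), y = y, Xmat = Xmat,
               K = K)
  ll0 <- dense_profile_ll(0, y, Xmat, K)
  list(loglik = max(c(ll, ll0)), lambda = c(0, grid)[which.max(c(ll0, ll))])
}

## random PSD kinship-like matrix with unit-ish diagonal (centered GRM,
## singular: rank n-1)
random_kinship <- function(n, m = 5 * n) {
  g <- matrix(rbinom(n * m, 2, runif(n * m, 0.1, 0.9)), n, m)
  rownames(g) <- sprintf("d%03d", seq_len(n))
  compute_grm(g)
}

## strictly positive-definite kinship: genotypes standardized by their TRUE
## allele frequencies (external reference), so columns are not centered in
## sample and K has full rank almost surely; exact ML is well-posed here
random_pd_kinship <- function(n, m = 8 * n) {
  p <- runif(m, 0.15, 0.85)
  g <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  z <- sweep(g, 2, 2 * p) / rep(sqrt(2 * p * (1 - p)), each = n)
  K <- tcrossprod(z) / m
  K <- (K + t(K)) / 2
  kinship_matrix(K, sprintf("d%03d", seq_len(n)), m)
}

## symmetric PSD square root for drawing correlated effects in tests
.psd_sqrt_test <- function(K) {
  e <- eigen(K, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

## minimal metabolite matrix builder for hand fixtures
make_mm <- function(values, batch = rep(1L, nrow(values)),
                    run_order = NULL, hemolysis = rep(0L, nrow(values)),
                    travel = rep(24, nrow(values)),
                    temp = rep(18, nrow(values)), state = "raw") {
  n <- nrow(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("s%02d", 1:n)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("m%02d", seq_len(ncol(values)))
  if (is.null(run_order)) run_order <- stats::ave(seq_len(n), batch,
                                                  FUN = seq_along)
  meta <- data.frame(sample_id = rownames(values), batch = batch,
                     run = 1L, run_order = run_order,
                     hemolysis = hemolysis, travel_time = travel,
                     arrival_temp = temp)
  metabolite_matrix(values, meta, state = state)
}
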