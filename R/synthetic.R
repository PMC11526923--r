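#' Simulation configuration for a synthetic cohort
#'
#' Bundles every parameter of the synthetic-cohort generator. Defaults
#' emulate the cohort the pipeline is designed for: ~784 dogs measured on a
#' 137-metabolite targeted LC-MS panel, extraction batches of up to 40
#' samples spread over 5 LC-MS runs, ages 0.7-18 years, block-structured
#' genetic relatedness (breed-like clusters plus a majority of admixed
#' dogs), injected batch/run-order drift, sporadic missingness, hemolysis
#' grades 0-4, and a mediator chain age -> creatinine -> metabolite for a
#' small "ptmAA-like" metabolite subset.
#'
#' @param n_dogs number of dogs.
#' @param n_metabolites number of metabolites on the panel.
#' @param n_snps number of simulated biallelic SNPs.
#' @param n_breed_blocks number of breed-like ancestry blocks.
#' @param admixed_fraction fraction of dogs with mixed ancestry.
#' @param age_range numeric length-2, min and max age in years.
#' @param batch_size samples per extraction batch (>= 2).
#' @param n_runs number of LC-MS runs batches are distributed over.
#' @param effect_table per-metabolite true fixed effects; see
#'   [default_effect_table()]. `NULL` uses the default.
#' @param h2_table per-metabolite true heritability in \[0, 1);
#'   `NULL` spaces them evenly over \[0.05, 0.6\].
#' @param mediator_spec list with `a` (age -> mediator), per-metabolite
#'   vectors `b` (mediator -> metabolite) and `d` (direct age effect for
#'   mediated metabolites), and `sd_m` (mediator residual SD). `NULL` uses
#'   [default_mediator_spec()].
#' @param drift_spec list with `intercept_sd` and `slope_sd` for the
#'   per-metabolite, per-batch drift intercepts and within-batch run-order
#'   slopes (log scale).
#' @param missing_rate probability each cell is missing at random.
#' @param hemolysis_rates length-5 probability vector over grades 0-4.
#' @param contamination if `TRUE`, grade-4 hemolysis shifts the metabolites
#'   in `contaminated_metabolites` upward by `contamination_shift` log units.
#' @param contaminated_metabolites column indices affected in
#'   contamination mode.
#' @param contamination_shift log-scale shift for contaminated cells.
#' @param fst divergence of block allele frequencies (Balding-Nichols F).
#' @param n_cbc number of CBC-like standard-normal covariate columns.
#' @param seed integer random seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_dogs = 784L, n_metabolites = 137L, n_snps = 10000L,
                       n_breed_blocks = 40L, admixed_fraction = 0.81,
                       age_range = c(0.7, 18), batch_size = 40L, n_runs = 5L,
                       effect_table = NULL, h2_table = NULL,
                       mediator_spec = NULL,
                       drift_spec = list(intercept_sd = 0.5, slope_sd = 0.02),
                       missing_rate = 0.02,
                       hemolysis_rates = c(0.70, 0.12, 0.06, 0.04, 0.08),
                       contamination = FALSE,
                       contaminated_metabolites = 1:5,
                       contamination_shift = 1.0,
                       fst = 0.2, n_cbc = 17L, seed = 1L) {
  cfg <- list(n_dogs = as.integer(n_dogs),
              n_metabolites = as.integer(n_metabolites),
              n_snps = as.integer(n_snps),
              n_breed_blocks = as.integer(n_breed_blocks),
              admixed_fraction = admixed_fraction,
              age_range = age_range, batch_size = as.integer(batch_size),
              n_runs = as.integer(n_runs),
              effect_table = effect_table %||% default_effect_table(n_metabolites),
              h2_table = h2_table %||%
                seq(0.05, 0.6, length.out = n_metabolites),
              mediator_spec = mediator_spec %||%
                default_mediator_spec(n_metabolites),
              drift_spec = drift_spec, missing_rate = missing_rate,
              hemolysis_rates = hemolysis_rates,
              contamination = isTRUE(contamination),
              contaminated_metabolites = contaminated_metabolites,
              contamination_shift = contamination_shift,
              fst = fst, n_cbc = as.integer(n_cbc), seed = as.integer(seed))
  if (identical(rownames(cfg$effect_table),
                as.character(seq_len(nrow(cfg$effect_table)))))
    rownames(cfg$effect_table) <- sprintf("met%03d",
                                          seq_len(nrow(cfg$effect_table)))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (any(cfg$h2_table < 0 | cfg$h2_table >= 1))
    .stopf("h2 values must lie in [0, 1)")
  if (cfg$age_range[1] >= cfg$age_range[2])
    .stopf("age_range must satisfy min < max")
  if (cfg$batch_size < 2L) .stopf("batch_size must be >= 2")
  if (abs(sum(cfg$hemolysis_rates) - 1) > 1e-8)
    .stopf("hemolysis_rates must sum to 1")
  if (cfg$admixed_fraction < 0 || cfg$admixed_fraction > 1)
    .stopf("admixed_fraction must be a proportion")
  if (length(cfg$h2_table) != cfg$n_metabolites)
    .stopf("h2_table length must equal n_metabolites")
  invisible(cfg)
}

#' Default per-metabolite fixed-effect table
#'
#' Deterministic assignment of true fixed effects: 40 metabolites carry an
#' age effect of +/-0.25 per sqrt-year (the first 20 positive, the next 20
#' negative), 20 carry a weight effect of +/-0.1, 10 each carry sex,
#' sterilization and fasting effects, and one metabolite carries a
#' raw-commercial-diet contrast of -0.49 (versus the kibble reference).
#' The final 7 metabolites (the "ptmAA-like" block) have no direct entry in
#' the `age` column; their age effects arrive through the mediator chain.
#'
#' @param n_metabolites panel size.
#' @return data.frame with columns `age`, `weight`, `sex`, `sterilized`,
#'   `fasting`, `diet_raw` and rownames `met001`, ...
#' @export
default_effect_table <- function(n_metabolites) {
  m <- n_metabolites
  eff <- data.frame(age = numeric(m), weight = numeric(m), sex = numeric(m),
                    sterilized = numeric(m), fasting = numeric(m),
                    diet_raw = numeric(m))
  rownames(eff) <- sprintf("met%03d", seq_len(m))
  n_age <- min(40L, m)
  eff$age[seq_len(n_age)] <- c(rep(0.25, ceiling(n_age / 2)),
                               rep(-0.25, floor(n_age / 2)))
  if (m >= 60) eff$weight[41:60] <- rep(c(0.1, -0.1), 10)
  if (m >= 70) eff$sex[61:70] <- 0.3
  if (m >= 80) eff$sterilized[71:80] <- -0.3
  if (m >= 90) eff$fasting[81:90] <- 0.02
  if (m >= 8) eff$diet_raw[m - 7L] <- -0.49
  eff
}

#' Default mediator specification
#'
#' The last 7 metabolites form the mediated ("ptmAA-like") block: six have a
#' nonzero mediator path with true proportions mediated spanning 0.45-0.68,
#' and the seventh (a hydroxyproline-like metabolite) is age-associated with
#' no mediation (`b = 0`). The mediator (a creatinine-like column) is
#' `a * sqrt(age) + Normal(0, sd_m)`, independent of the polygenic term.
#'
#' @param n_metabolites panel size.
#' @param a age-to-mediator coefficient (per sqrt-year).
#' @param sd_m mediator residual SD.
#' @return list with `a`, `sd_m`, and per-metabolite vectors `b`, `d`.
#' @export
default_mediator_spec <- function(n_metabolites, a = 0.5, sd_m = 1.0) {
  b <- numeric(n_metabolites)
  d <- numeric(n_metabolites)
  if (n_metabolites >= 7) {
    idx <- (n_metabolites - 6L):n_metabolites
    props <- c(0.45, 0.50, 0.55, 0.60, 0.65, 0.68)
    b[idx[1:6]] <- 1.0
    d[idx[1:6]] <- a * 1.0 * (1 - props) / props
    b[idx[7]] <- 0
    d[idx[7]] <- -0.3           # age-associated but unmediated
  }
  list(a = a, sd_m = sd_m, b = b, d = d)
}

#' Simulate block-structured genotypes and breed ancestry
#'
#' Dogs belong either to one of `n_breed_blocks` breed-like clusters
#' (purebred, ancestry 1 in one block) or are admixed with Dirichlet
#' mixture weights over two or more blocks. Block allele frequencies follow
#' a Balding-Nichols model around ancestral frequencies, so blocks are
#' genetically diverged; every returned SNP has minor allele frequency
#' above 1% in the realized sample (failing SNPs are regenerated).
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (dogs x SNPs dosage matrix, values 0/1/2)
#'   and `ancestry` (data.frame of per-dog block proportions plus
#'   `max_breed`, `max_proportion`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_breed_blocks < 1L) .stopf("n_breed_blocks must be >= 1")
  if (config$n_snps < 100L) .stopf("n_snps must be >= 100")
  if (config$n_dogs < 2L * config$n_breed_blocks)
    .stopf("degenerate config: n_dogs (%d) < 2 * n_breed_blocks (%d)",
           config$n_dogs, 2L * config$n_breed_blocks)
  set.seed(config$seed)
  n <- config$n_dogs; m <- config$n_snps; B <- config$n_breed_blocks
  Fst <- config$fst

  ## ancestry weights: breed popularity is Zipf-like (a handful of common
  ## breeds, a long tail), so purebreds concentrate in the leading blocks;
  ## admixed dogs mix 2-8 blocks with Dirichlet weights
  n_adm <- round(config$admixed_fraction * n)
  n_pure <- n - n_adm
  pop <- 1 / seq_len(B)
  W <- matrix(0, n, B)
  if (n_pure > 0) {
    blk <- if (B == 1L) rep(1L, n_pure)
           else sample.int(B, n_pure, replace = TRUE, prob = pop)
    W[cbind(seq_len(n_pure), blk)] <- 1
  }
  if (n_adm > 0) {
    if (B == 1L) {
      W[(n_pure + 1):n, 1] <- 1
    } else {
      for (i in (n_pure + 1):n) {
        k <- sample(2:min(8L, B), 1L)
        blocks <- sample.int(B, k, prob = pop)
        W[i, blocks] <- as.vector(.rdirichlet(1, rep(1, k)))
      }
    }
  }

  draw_block_freqs <- function(m) {
    p0 <- stats::runif(m, 0.1, 0.9)
    if (Fst <= 0) return(matrix(rep(p0, each = B), B, m))
    sh <- (1 - Fst) / Fst
    matrix(stats::rbeta(B * m, rep(p0, each = B) * sh,
                        rep(1 - p0, each = B) * sh), B, m)
  }
  draw_geno <- function(P) {
    Q <- W %*% P                                 # per-dog allele freqs
    matrix(stats::rbinom(length(Q), 2L, Q), nrow(Q), ncol(Q))
  }

  P <- draw_block_freqs(m)
  G <- draw_geno(P)
  for (iter in 1:25) {                           # regenerate low-MAF SNPs
    p_hat <- colMeans(G) / 2
    bad <- pmin(p_hat, 1 - p_hat) <= 0.01
    if (!any(bad)) break
    Pb <- draw_block_freqs(sum(bad))
    G[, bad] <- draw_geno(Pb)
  }
  p_hat <- colMeans(G) / 2
  if (any(pmin(p_hat, 1 - p_hat) <= 0.01))
    .stopf("could not generate %d SNPs passing the MAF filter",
           sum(pmin(p_hat, 1 - p_hat) <= 0.01))

  dog_ids <- sprintf("dog%04d", seq_len(n))
  dimnames(G) <- list(dog_ids, sprintf("snp%05d", seq_len(m)))
  colnames(W) <- sprintf("breed%02d", seq_len(B))
  ancestry <- data.frame(dog_id = dog_ids, W, check.names = FALSE)
  ancestry$max_breed <- colnames(W)[max.col(W, ties.method = "first")]
  ancestry$max_proportion <- apply(W, 1, max)
  list(genotypes = G, ancestry = ancestry)
}

#' Simulate phenotypes, covariates and technical structure
#'
#' Builds the raw metabolite matrix and the per-dog covariate table on top
#' of a relatedness matrix: each log-scale metabolite is
#' `y = X beta_true + b*M + d*sqrt(age) + u + eps` with
#' `u ~ MVN(0, sigma_g^2 K)` and `sigma_g^2 / (sigma_g^2 + sigma_e^2)`
#' equal to the configured heritability; the mediator M (creatinine-like)
#' is `a*sqrt(age) + noise`, independent of the polygenic term, so the
#' product-of-coefficients mediation effect is exact ground truth. Batch
#' intercepts, within-batch run-order slopes, technical-covariate effects
#' and per-sample loading shifts are added on the log scale, then the
#' matrix is exponentiated; missing cells and hemolysis grades are injected
#' at the configured rates.
#'
#' @param config a [sim_config()].
#' @param genotypes dogs x SNPs dosage matrix (used only for dog ids when a
#'   kinship matrix is supplied).
#' @param kinship a [kinship_matrix] (see [compute_grm()]) aligned to the
#'   rows of `genotypes`.
#' @return list with `metabolites` (a raw-state [metabolite_matrix()]),
#'   `cohort` (data.frame), and `truth` (list with `true_beta`, `true_h2`,
#'   `true_acme`, `true_prop_mediated`, `breeding_values`, `log_clean`,
#'   the drift- and technical-effect-free log-scale matrix).
#' @export
simulate_phenotypes <- function(config, genotypes, kinship) {
  stopifnot(inherits(config, "sim_config"))
  K <- kinship$K
  n <- nrow(K)
  if (n != config$n_dogs) .stopf("kinship dimension != n_dogs")
  if (max(abs(K - t(K))) > 1e-8) .stopf("kinship matrix must be symmetric")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    .stopf("kinship matrix is not positive semi-definite (min eigenvalue %g)",
           min(ev))
  set.seed((config$seed + 104729L) %% .Machine$integer.max)  # phenotype stream
  m <- config$n_metabolites
  met_ids <- rownames(config$effect_table)
  dog_ids <- rownames(K)

  ## --- cohort covariates ---------------------------------------------------
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  weight <- stats::rlnorm(n, log(18), 0.55)
  sex <- stats::rbinom(n, 1, 0.5)                     # 1 = male
  sterilized <- stats::rbinom(n, 1, 0.87)
  fasting <- pmax(0, round(stats::rnorm(n, 8, 3)))
  life_stage <- cut(age, c(-Inf, 1, 3, 7, 11, Inf),
                    labels = c("puppy", "adolescent", "young_adult",
                               "mature_adult", "senior"), right = FALSE)
  diet_levels <- c("kibble", "raw_commercial", "home_cooked", "canned",
                   "freeze_dried")
  diet <- factor(sample(diet_levels, n, replace = TRUE,
                        prob = c(0.86, 0.05, 0.04, 0.03, 0.02)),
                 levels = diet_levels)
  cbc <- matrix(stats::rnorm(n * config$n_cbc), n, config$n_cbc,
                dimnames = list(NULL, sprintf("cbc%02d",
                                              seq_len(config$n_cbc))))
  s_age <- sqrt(age)
  ms <- config$mediator_spec
  creatinine <- ms$a * s_age + stats::rnorm(n) * ms$sd_m
  bun <- 0.5 * creatinine + stats::rnorm(n, 0, 1)

  cohort <- data.frame(dog_id = dog_ids, age = age, weight = weight,
                       sex = sex, sterilized = sterilized, fasting = fasting,
                       life_stage = life_stage, diet = diet,
                       creatinine = creatinine, bun = bun, cbc,
                       stringsAsFactors = FALSE)

  ## --- genetic + residual signal -------------------------------------------
  h2 <- config$h2_table
  sqrtK <- .psd_sqrt(K)
  U <- sqrtK %*% matrix(stats::rnorm(n * m), n, m)
  U <- sweep(U, 2L, sqrt(h2), `*`)                    # breeding values
  E <- matrix(stats::rnorm(n * m), n, m)
  E <- sweep(E, 2L, sqrt(1 - h2), `*`)

  eff <- config$effect_table
  Xt <- cbind(age = s_age, weight = sqrt(weight), sex = sex,
              sterilized = sterilized, fasting = fasting,
              diet_raw = as.numeric(diet == "raw_commercial"))
  fixed <- Xt %*% t(as.matrix(eff[, colnames(Xt)]))
  med_part <- outer(creatinine, ms$b) + outer(s_age, ms$d)
  baseline <- matrix(stats::runif(m, 8, 12), n, m, byrow = TRUE)
  Ylog_clean <- baseline + fixed + med_part + U + E

  ## --- technical structure --------------------------------------------------
  batch <- ceiling(seq_len(n) / config$batch_size)
  n_batch <- max(batch)
  run <- ceiling(batch / (n_batch / config$n_runs))
  run_order <- stats::ave(seq_len(n), batch, FUN = seq_along)
  ## draw standard normals then scale, so the RNG stream is identical
  ## whatever the drift SDs (including zero)
  drift_int <- matrix(stats::rnorm(n_batch * m), n_batch, m) *
    config$drift_spec$intercept_sd
  drift_slo <- matrix(stats::rnorm(n_batch * m), n_batch, m) *
    config$drift_spec$slope_sd
  drift <- drift_int[batch, , drop = FALSE] +
    drift_slo[batch, , drop = FALSE] * run_order

  travel_time <- pmin(pmax(stats::rlnorm(n, log(26.3), 0.45), 14.2), 168.7)
  arrival_temp <- pmin(pmax(stats::rnorm(n, 18.8, 4), 1.8), 28.7)
  hemolysis <- sample(0:4, n, replace = TRUE, prob = config$hemolysis_rates)
  tech_coef <- cbind(travel = stats::rnorm(m, 0, 0.005),
                     temp = stats::rnorm(m, 0, 0.01),
                     hemo = stats::rnorm(m, 0, 0.05))
  tech <- cbind(travel_time, arrival_temp, hemolysis) %*% t(tech_coef)

  sample_shift <- stats::rnorm(n, 0, 0.2)
  Ylog <- Ylog_clean + drift + tech + sample_shift
  if (config$contamination) {
    idx <- config$contaminated_metabolites
    Ylog[hemolysis == 4, idx] <- Ylog[hemolysis == 4, idx] +
      config$contamination_shift
  }
  raw <- exp(Ylog)
  miss <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
  raw[miss] <- NA_real_
  dimnames(raw) <- list(dog_ids, met_ids)
  dimnames(Ylog_clean) <- dimnames(raw)
  dimnames(U) <- dimnames(raw)

  meta <- data.frame(sample_id = dog_ids, batch = batch, run = run,
                     run_order = run_order, hemolysis = hemolysis,
                     travel_time = travel_time, arrival_temp = arrival_temp,
                     stringsAsFactors = FALSE)
  mm <- metabolite_matrix(raw, meta, state = "raw")

  total_age <- eff$age + ms$a * ms$b + ms$d
  true_beta <- as.matrix(eff)
  true_beta[, "age"] <- total_age
  acme <- ms$a * ms$b
  prop <- ifelse(abs(acme + ms$d) > 0, acme / (acme + ms$d), NA_real_)
  prop[acme == 0 & ms$d == 0] <- NA_real_
  truth <- list(true_beta = true_beta, true_h2 = h2, true_acme = acme,
                true_prop_mediated = prop, breeding_values = U,
                log_clean = Ylog_clean, mediator_spec = ms)
  list(metabolites = mm, cohort = cohort, truth = truth)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: genotypes, GRM, phenotypes in one call.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes`, `ancestry`, `kinship`, `metabolites`,
#'   `cohort`, `truth`.
#' @export
simulate_cohort <- function(config) {
  g <- simulate_genotypes(config)
  kin <- compute_grm(g$genotypes)
  ph <- simulate_phenotypes(config, g$genotypes, kin)
  c(list(genotypes = g$genotypes, ancestry = g$ancestry, kinship = kin), ph)
}
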