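#' Run the full analysis pipeline
#'
#' Orchestrates every stage on either a synthetic cohort or user tables:
#' simulate/load -> technical normalization -> GRM -> PCA with Tracy-Widom
#' selection, Type III ANCOVA and per-PC SNP-heritability -> mixed-model
#' metabolome-wide association -> full adjustment, residual correlation
#' and UPGMA clustering -> diet contrast and kibble-only subset refit ->
#' creatinine mediation of the age hits. All intermediates are persisted
#' as plain delimited text plus a machine-readable JSON manifest; a
#' separate plain-text log carries stage timings (excluded from the
#' determinism contract, since wall-clock times differ between runs).
#' With a fixed seed the manifest and every result table are
#' byte-reproducible.
#'
#' @param config a [sim_config()] (used for synthetic runs and for
#'   thresholds).
#' @param out_dir output directory (created if needed).
#' @param seed overrides `config$seed` when given.
#' @param synthetic generate the cohort from `config`; if `FALSE`,
#'   `inputs` must name user tables.
#' @param inputs list with paths `metabolites` (prefix for
#'   [read_metabolites()]), `cohort` (TSV), and `grm` (prefix for
#'   [read_rel()]) or `genotypes` (dosage TSV).
#' @param alpha FDR level used across stages.
#' @param max_missing,max_hemolysis_grade,knn_k normalization thresholds.
#' @param mediator cohort column mediating the age effect.
#' @param n_boot bootstrap resamples for mediation.
#' @param report also render figures via [make_report()].
#' @return (invisibly) a list with every stage result and the manifest.
#' @export
run_all <- function(config = sim_config(), out_dir, seed = NULL,
                    synthetic = TRUE, inputs = NULL, alpha = 0.05,
                    max_missing = 0.10, max_hemolysis_grade = 3L,
                    knn_k = 10L, mediator = "creatinine",
                    n_boot = 10000L, report = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  t0 <- proc.time()[["elapsed"]]
  log_path <- file.path(out_dir, "pipeline.log")
  cat(sprintf("pipeline start (%s)\n", format(Sys.time())), file = log_path)
  stages <- character()
  tick <- function(stage) {
    cat(sprintf("%-22s t=%.1fs\n", stage, proc.time()[["elapsed"]] - t0),
        file = log_path, append = TRUE)
    stages <<- c(stages, stage)
  }
  counts <- list()

  ## --- stage: inputs --------------------------------------------------------
  if (synthetic) {
    sim <- simulate_cohort(config)
    mm_raw <- sim$metabolites; cohort <- sim$cohort; kin <- sim$kinship
    write_metabolites(mm_raw, file.path(out_dir, "metabolites_raw"))
    .write_tsv(cohort, file.path(out_dir, "cohort.tsv"))
    write_rel(kin, file.path(out_dir, "grm"))
    truth <- sim$truth
  } else {
    if (is.null(inputs)) .stopf("non-synthetic runs require input paths")
    mm_raw <- read_metabolites(inputs$metabolites)
    cohort <- .read_tsv(inputs$cohort)
    kin <- if (!is.null(inputs$grm)) read_rel(inputs$grm)
           else compute_grm(filter_snps(read_genotypes(inputs$genotypes)))
    truth <- NULL
    bad <- unique(c(setdiff(rownames(mm_raw$values), cohort$dog_id),
                    setdiff(cohort$dog_id, rownames(mm_raw$values))))
    if (length(bad))
      .stopf("cohort/metabolite id mismatch; offending ids: %s",
             paste(utils::head(bad, 10), collapse = ", "))
  }
  counts$input <- c(dogs = nrow(mm_raw$values),
                    metabolites = ncol(mm_raw$values))
  tick("inputs")

  ## --- stage: preprocess ----------------------------------------------------
  mm <- preprocess_pipeline(mm_raw, max_missing = max_missing,
                            max_hemolysis_grade = max_hemolysis_grade,
                            knn_k = knn_k)
  prep_report <- attr(mm, "report")
  counts$preprocess <- c(dogs = nrow(mm$values),
                         metabolites = ncol(mm$values),
                         dropped_metabolites =
                           nrow(prep_report$dropped_metabolites),
                         dropped_samples = nrow(prep_report$dropped_samples))
  write_metabolites(mm, file.path(out_dir, "metabolites_normalized"))
  tick("preprocess")

  ids <- rownames(mm$values)
  cohort_f <- cohort[match(ids, cohort$dog_id), , drop = FALSE]
  kin_f <- .kin_subset(kin, ids)

  ## --- stage: multivariate --------------------------------------------------
  pc <- tracy_widom_select(pca(mm), alpha = alpha)
  n_pcs <- max(pc$n_significant, 1L)
  vp <- ancova_partition(pc, cohort_f, n_pcs = n_pcs)
  ph <- pc_heritability(pc, cohort_f, kin_f, n_pcs = n_pcs)
  .write_tsv(data.frame(sample_id = ids,
                        pc$scores[, seq_len(n_pcs), drop = FALSE],
                        check.names = FALSE),
             file.path(out_dir, "pc_scores.tsv"))
  .write_tsv(data.frame(component = paste0("PC",
                          seq_along(pc$eigenvalues)),
                        eigenvalue = pc$eigenvalues,
                        var_explained = pc$var_explained,
                        tw_p = pc$tw_p),
             file.path(out_dir, "pca_eigenvalues.tsv"))
  .write_tsv(vp, file.path(out_dir, "variance_partition.tsv"))
  .write_tsv(ph, file.path(out_dir, "pc_heritability.tsv"))
  counts$pca <- c(significant_pcs = pc$n_significant)
  tick("multivariate")

  ## --- stage: mwas ----------------------------------------------------------
  scan <- mwas(mm, cohort_f, kin_f, alpha = alpha)
  .write_tsv(scan$table, file.path(out_dir, "mwas.tsv"))
  age_hits <- scan$significant[["sqrt_age"]] %||% character()
  counts$mwas <- c(age_hits = length(age_hits),
                   interaction_removed = scan$interaction_removed)
  tick("mwas")

  ## --- stage: covariation ---------------------------------------------------
  adj <- adjust(mm, scan)
  cc <- correlate_fdr(adj, alpha = alpha)
  .write_tsv(data.frame(metabolite = rownames(cc$r), cc$r,
                        check.names = FALSE),
             file.path(out_dir, "residual_correlation.tsv"))
  tree <- upgma(cc$r)
  writeLines(attr(tree, "newick"), file.path(out_dir, "dendrogram.nwk"))
  tick("covariation")

  ## --- stage: contrasts -----------------------------------------------------
  diet_res <- kibble <- NULL
  if ("diet" %in% names(cohort_f) && length(unique(cohort_f$diet)) > 1L) {
    diet_res <- contrast_covariate(mm, cohort_f, kin_f, "diet",
                                   reference = "kibble", alpha = alpha)
    .write_tsv(diet_res$table, file.path(out_dir, "diet_contrast.tsv"))
    kibble <- tryCatch(
      subset_refit(mm, cohort_f, kin_f,
                   function(co) co$diet == "kibble", alpha = alpha),
      error = function(e) { .warnf("kibble subset skipped: %s",
                                   conditionMessage(e)); NULL })
    if (!is.null(kibble))
      .write_tsv(kibble$table, file.path(out_dir, "mwas_kibble.tsv"))
  }
  tick("contrasts")

  ## --- stage: mediation -----------------------------------------------------
  med <- NULL
  med_mets <- age_hits
  if (length(med_mets)) {
    med <- mediate_panel(mm, cohort_f, mediator = mediator,
                         metabolites = med_mets, alpha = alpha,
                         n_boot = n_boot, seed = config$seed)
    .write_tsv(med$table, file.path(out_dir, "mediation.tsv"))
    counts$mediation <- c(tested = nrow(med$table),
                          mediated = sum(med$table$q <= alpha,
                                         na.rm = TRUE))
  }
  tick("mediation")

  ## --- manifest -------------------------------------------------------------
  input_files <- c("metabolites_raw.tsv", "metabolites_raw.meta.tsv",
                   "cohort.tsv", "grm.rel", "grm.rel.id")
  input_files <- input_files[file.exists(file.path(out_dir, input_files))]
  checksums <- as.list(tools::md5sum(file.path(out_dir, input_files)))
  names(checksums) <- input_files
  manifest <- list(
    package = "metaboKin",
    version = as.character(utils::packageVersion("metaboKin")),
    seed = config$seed,
    synthetic = synthetic,
    config = unclass(config),
    thresholds = list(alpha = alpha, max_missing = max_missing,
                      max_hemolysis_grade = max_hemolysis_grade,
                      knn_k = knn_k, n_boot = n_boot, mediator = mediator),
    input_checksums = checksums,
    counts = lapply(counts, as.list),
    stages = stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tick("manifest")

  results <- list(metabolites = mm, cohort = cohort_f, kinship = kin_f,
                  pca = pc, variance_partition = vp, pc_heritability = ph,
                  mwas = scan, adjusted = adj, correlation = cc,
                  tree = tree, diet = diet_res, kibble = kibble,
                  mediation = med, truth = truth, manifest = manifest,
                  out_dir = out_dir)
  if (report) make_report(results, out_dir)
  invisible(results)
}

#' Render report figures and figure-data tables
#'
#' Volcano plot of the age effect, stacked variance-partition bars, per-PC
#' SNP-heritability bars, correlation heatmap with UPGMA dendrogram, and
#' the proportion-mediated bar chart with bootstrap CIs. Every figure's
#' underlying numbers are emitted as a TSV alongside the PDF so the
#' figures are bit-testable; missing stages are omitted with a notice and
#' empty significant sets yield empty-but-valid figures.
#'
#' @param results the list returned by [run_all()].
#' @param out_dir directory receiving `figures/`.
#' @return invisibly, the figure directory.
#' @export
make_report <- function(results, out_dir) {
  fig_dir <- file.path(out_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE, recursive = TRUE)
  notice <- function(what) message("make_report: no ", what,
                                   " results; section omitted")
  ## volcano
  if (!is.null(results$mwas)) {
    tab <- results$mwas$table
    aged <- tab[tab$coefficient == "sqrt_age", ]
    fdr_line <- suppressWarnings(max(aged$p[!is.na(aged$q) &
                                              aged$q <= results$mwas$alpha],
                                     na.rm = TRUE))
    vd <- data.frame(metabolite = aged$metabolite, beta_age = aged$beta,
                     neglog10_p = -log10(aged$p), q = aged$q)
    .write_tsv(vd, file.path(fig_dir, "volcano_data.tsv"))
    grDevices::pdf(file.path(fig_dir, "volcano.pdf"), width = 6, height = 5)
    plot(vd$beta_age, vd$neglog10_p, pch = 19, cex = 0.6,
         col = ifelse(!is.na(vd$q) & vd$q <= results$mwas$alpha,
                      "firebrick", "grey50"),
         xlab = expression(beta[age]), ylab = expression(-log[10](p)),
         main = "Age effects across the metabolome")
    if (is.finite(fdr_line)) graphics::abline(h = -log10(fdr_line),
                                              col = "red", lty = 2)
    grDevices::dev.off()
  } else notice("association")
  ## variance partition
  if (!is.null(results$variance_partition)) {
    vp <- results$variance_partition
    .write_tsv(vp, file.path(fig_dir, "variance_partition_data.tsv"))
    wide <- tapply(vp$fraction, list(vp$term, vp$pc), sum)
    wide <- wide[setdiff(rownames(wide), "Residuals"), , drop = FALSE]
    wide[is.na(wide)] <- 0
    grDevices::pdf(file.path(fig_dir, "variance_partition.pdf"),
                   width = 7, height = 5)
    graphics::barplot(wide, col = grDevices::hcl.colors(nrow(wide)),
                      las = 2, ylab = "fraction of PC variance",
                      legend.text = rownames(wide),
                      args.legend = list(cex = 0.5, x = "topright"))
    grDevices::dev.off()
  } else notice("variance-partition")
  ## H_SNP bars
  if (!is.null(results$pc_heritability)) {
    ph <- results$pc_heritability
    .write_tsv(ph, file.path(fig_dir, "pc_heritability_data.tsv"))
    grDevices::pdf(file.path(fig_dir, "pc_heritability.pdf"),
                   width = 7, height = 4)
    graphics::barplot(ph$h_snp, names.arg = ph$pc, las = 2,
                      ylab = expression(H[SNP]))
    grDevices::dev.off()
  } else notice("PC-heritability")
  ## heatmap + dendrogram
  if (!is.null(results$correlation)) {
    r <- results$correlation$r
    grDevices::pdf(file.path(fig_dir, "correlation_heatmap.pdf"),
                   width = 7, height = 7)
    if (nrow(r) >= 3 && !anyNA(r)) {
      dend <- stats::as.dendrogram(upgma(r))
      stats::heatmap(r, Rowv = dend, Colv = dend, scale = "none",
                     col = grDevices::hcl.colors(50, "RdBu", rev = TRUE))
    } else graphics::plot.new()
    grDevices::dev.off()
  } else notice("correlation")
  ## proportion mediated
  if (!is.null(results$mediation) && nrow(results$mediation$table)) {
    mt <- results$mediation$table
    .write_tsv(mt, file.path(fig_dir, "mediation_data.tsv"))
    grDevices::pdf(file.path(fig_dir, "proportion_mediated.pdf"),
                   width = 7, height = 4)
    bp <- graphics::barplot(mt$prop_mediated, names.arg = mt$metabolite,
                            las = 2, ylab = "proportion mediated",
                            col = ifelse(!is.na(mt$q) & mt$q <= 0.05,
                                         "steelblue", "grey80"))
    tot <- mt$total
    graphics::segments(bp, mt$ci_lo / tot, bp, mt$ci_hi / tot)
    grDevices::dev.off()
  } else notice("mediation")
  invisible(fig_dir)
}
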