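## Delimited-text I/O: TSV matrices with header row = metabolite names and
## first column = sample id, sidecar sample-metadata TSV, JSON config.

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write a metabolite matrix and its sidecar metadata
#'
#' @param mm a [metabolite_matrix()].
#' @param prefix path prefix; writes `<prefix>.tsv` (first column
#'   `sample_id`, remaining columns metabolites) and `<prefix>.meta.tsv`
#'   (sample metadata plus the normalization state).
#' @return the prefix, invisibly.
#' @export
write_metabolites <- function(mm, prefix) {
  d <- data.frame(sample_id = rownames(mm$values), mm$values,
                  check.names = FALSE)
  .write_tsv(d, paste0(prefix, ".tsv"))
  meta <- mm$sample_meta
  meta$state <- mm$state
  .write_tsv(meta, paste0(prefix, ".meta.tsv"))
  invisible(prefix)
}

#' Read a metabolite matrix written by [write_metabolites()]
#'
#' @param prefix path prefix.
#' @return a [metabolite_matrix()].
#' @export
read_metabolites <- function(prefix) {
  d <- .read_tsv(paste0(prefix, ".tsv"))
  meta <- .read_tsv(paste0(prefix, ".meta.tsv"))
  state <- unique(meta$state) %||% "raw"
  meta$state <- NULL
  v <- as.matrix(d[, -1, drop = FALSE])
  rownames(v) <- as.character(d$sample_id)
  meta$sample_id <- as.character(meta$sample_id)
  metabolite_matrix(v, meta, state = state[1])
}

#' Write genotype dosages as TSV
#'
#' @param genotypes dogs x SNPs dosage matrix.
#' @param path output file; first column `dog_id`.
#' @export
write_genotypes <- function(genotypes, path) {
  d <- data.frame(dog_id = rownames(genotypes), genotypes,
                  check.names = FALSE)
  .write_tsv(d, path)
}

#' Read genotype dosages written by [write_genotypes()]
#'
#' @param path dosage TSV.
#' @return dogs x SNPs matrix.
#' @export
read_genotypes <- function(path) {
  d <- .read_tsv(path)
  g <- as.matrix(d[, -1, drop = FALSE])
  rownames(g) <- as.character(d$dog_id)
  g
}

#' Write a simulation/pipeline configuration as JSON
#'
#' @param config a `sim_config` (or any nestable list).
#' @param path output path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a configuration written by [write_config()]
#'
#' @param path JSON config path.
#' @return a `sim_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$effect_table <- if (!is.null(raw$effect_table))
    as.data.frame(raw$effect_table)
  do.call(sim_config, raw[setdiff(names(raw), character())])
}
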