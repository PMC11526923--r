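## Container for a samples x metabolites intensity table moving through the
## normalization state machine. States advance only in this order.
.MM_STATES <- c("raw", "filtered", "logged", "batch_corrected",
                "scaled", "imputed", "tech_adjusted")

#' Construct a metabolite matrix
#'
#' Bundles a samples-by-metabolites intensity matrix with per-sample
#' technical metadata and a normalization state. Downstream normalization
#' operations enforce that states advance only in the order
#' raw, filtered, logged, batch_corrected, scaled, imputed, tech_adjusted.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   metabolites in columns (colnames = metabolite names).
#' @param sample_meta data.frame with one row per sample; must contain
#'   columns `sample_id`, `batch`, `run`, `run_order`, `hemolysis`,
#'   `travel_time`, `arrival_temp`. `run_order` is the within-batch
#'   processing index (1-based).
#' @param state normalization state, one of the values listed above.
#' @return an object of class `metab_matrix`.
#' @export
metabolite_matrix <- function(values, sample_meta, state = "raw") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) .stopf("values must have sample-id rownames")
  if (is.null(colnames(values))) .stopf("values must have metabolite colnames")
  state <- match.arg(state, .MM_STATES)
  req <- c("sample_id", "batch", "run", "run_order", "hemolysis",
           "travel_time", "arrival_temp")
  miss <- setdiff(req, names(sample_meta))
  if (length(miss)) .stopf("sample_meta lacks column(s): %s",
                           paste(miss, collapse = ", "))
  if (!identical(as.character(sample_meta$sample_id), rownames(values)))
    .stopf("sample_meta$sample_id must match rownames(values) in order")
  structure(list(values = values, sample_meta = sample_meta, state = state),
            class = "metab_matrix")
}

.state_index <- function(state) match(state, .MM_STATES)

## assert that `mm` is at `need` (or later, when `at_least`)
.check_state <- function(mm, need, at_least = FALSE) {
  i <- .state_index(mm$state); j <- .state_index(need)
  ok <- if (at_least) i >= j else i == j
  if (!ok) .stopf("operation requires state '%s' but matrix is '%s'",
                  need, mm$state)
  invisible(mm)
}

.set_state <- function(mm, state) {
  if (.state_index(state) < .state_index(mm$state))
    .stopf("state cannot move backwards (%s -> %s)", mm$state, state)
  mm$state <- state
  mm
}

#' @export
print.metab_matrix <- function(x, ...) {
  cat(sprintf("<metab_matrix> %d samples x %d metabolites, state = %s\n",
              nrow(x$values), ncol(x$values), x$state))
  cat(sprintf("  missing cells: %d (%.2f%%)\n", sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.metab_matrix <- function(x) dim(x$values)

## subset samples, keeping metadata aligned
.mm_subset_samples <- function(mm, keep) {
  mm$values <- mm$values[keep, , drop = FALSE]
  mm$sample_meta <- mm$sample_meta[keep, , drop = FALSE]
  rownames(mm$sample_meta) <- NULL
  mm
}
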