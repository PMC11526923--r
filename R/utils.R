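#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values.
#' `NA` entries propagate as `NA` and are excluded from the ranking
#' (the effective number of tests is the number of non-missing p-values).
#'
#' @param p numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return numeric vector of q-values, monotone in `p`, capped at 1.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03))
#' @export
fdr_adjust <- function(p) {
  if (!is.numeric(p)) .stopf("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) .stopf("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  if (any(ok)) q[ok] <- stats::p.adjust(p[ok], method = "BH")
  names(q) <- names(p)
  q
}

## deterministic column-wise sd with n-1 denominator, NA-aware
.col_sds <- function(x) {
  apply(x, 2L, stats::sd, na.rm = TRUE)
}

## draw from a symmetric-Dirichlet-like distribution via gammas
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

## matrix square root via eigendecomposition, flooring tiny negative
## eigenvalues at zero (count reported through attribute "n_floored")
.psd_sqrt <- function(K) {
  e <- eigen(K, symmetric = TRUE)
  lam <- e$values
  neg <- lam < 0
  lam[neg] <- 0
  out <- e$vectors %*% (sqrt(lam) * t(e$vectors))
  attr(out, "n_floored") <- sum(neg)
  out
}
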