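#' Median-of-ratios size factors
#'
#' For each sample j, the factor is the median over reference genes of
#' `count[g, j] / geomean(count[g, ])`, where reference genes are those
#' with a positive geometric mean (i.e. nonzero in every sample). This is
#' the standard count normalization for comparing libraries of different
#' depth.
#'
#' @param raw A raw-count [expression_matrix()].
#' @param pseudo_reference If no gene is expressed in every sample, set
#'   `TRUE` to compute the reference on counts + 0.5 instead of erroring.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(raw, pseudo_reference = FALSE) {
  if (inherits(raw, "expr_matrix") && expr_kind(raw) != "raw")
    abort("`size_factors` expects raw counts, got kind '%s'", expr_kind(raw))
  m <- unclass(raw)
  work <- m
  if (pseudo_reference) work <- m + 0.5
  loggeo <- rowMeans(log(work))
  ok <- is.finite(loggeo)
  if (!any(ok))
    abort(paste0("no gene has nonzero counts in every sample; ",
                 "rerun with pseudo_reference = TRUE to use a 0.5-pseudocount reference"))
  ratios <- work[ok, , drop = FALSE] / exp(loggeo[ok])
  factors <- apply(ratios, 2L, stats::median)
  if (any(factors <= 0)) abort("computed non-positive size factor")
  factors
}

#' Normalize counts by size factors
#'
#' Divides each sample column by its size factor and returns a
#' `normalized`-kind matrix.
#'
#' @param raw A raw-count [expression_matrix()].
#' @param factors Per-sample positive factors; computed with
#'   [size_factors()] when omitted.
#' @return A normalized [expression_matrix()].
#' @export
normalize_counts <- function(raw, factors = NULL) {
  if (is.null(factors)) factors <- size_factors(raw)
  if (length(factors) != ncol(raw))
    abort("need one size factor per sample")
  if (any(!is.finite(factors)) || any(factors <= 0))
    abort("size factors must be positive and finite")
  vals <- sweep(unclass(raw), 2L, factors, `/`)
  expression_matrix(vals, "normalized")
}
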