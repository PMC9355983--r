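#' Single-sample gene-set enrichment (ssGSEA) score
#'
#' Rank-weighted running-sum enrichment of a gene set within one sample's
#' expression profile. Genes are ordered by decreasing expression (ties
#' broken lexicographically by gene id for bit-reproducibility) and
#' assigned rank scores `r = N - position + 1`. Walking down the ranking,
#' the score accumulates the gap between the weighted fraction of in-set
#' genes seen so far (weights `r^tau`) and the unweighted fraction of
#' out-of-set genes seen so far:
#' `score = sum_i [P_in(i) - P_out(i)]`. Positive scores mean the set
#' concentrates at the top of the profile.
#'
#' Set genes absent from the profile are dropped with a warning (hard
#' error if none remain). The degenerate case where every profiled gene
#' is in the set has no outside reference; the score is defined as 0,
#' with a warning.
#'
#' @param x Named numeric vector: one sample's expression profile.
#' @param genes Character vector, the gene set.
#' @param tau Rank weight exponent, >= 0 (default 0.25; 0 gives the
#'   unweighted running sum).
#' @return A single enrichment score.
#' @export
ssgsea_score <- function(x, genes, tau = 0.25) {
  if (is.null(names(x)) || length(x) < 2L)
    abort("`x` must be a named vector with >= 2 genes")
  if (!is.numeric(tau) || tau < 0) abort("`tau` must be >= 0")
  present <- intersect(genes, names(x))
  if (!length(present))
    abort("gene set entirely absent from the profile; missing: %s",
          paste(genes, collapse = ", "))
  if (length(present) < length(genes))
    warn("%d/%d set gene(s) absent from the profile; proceeding with the intersection",
         length(genes) - length(present), length(genes))
  if (length(present) == length(x)) {
    warn("every profiled gene is in the set; score defined as 0")
    return(0)
  }
  ord <- order(-x, names(x))
  N <- length(x)
  in_set <- names(x)[ord] %in% present
  r <- N - seq_len(N) + 1
  w <- r^tau * in_set
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_set) / (N - length(present))
  sum(p_in - p_out)
}

#' ssGSEA scores for every sample of a matrix
#'
#' @param expr [expression_matrix()] or named numeric matrix (genes x
#'   samples).
#' @param genes Gene set.
#' @param tau Rank weight exponent.
#' @param normalize Min-max rescale the scores across the cohort to
#'   `[0, 1]` (a constant cohort maps to 0.5).
#' @return Named numeric vector, one score per sample.
#' @export
ssgsea_matrix <- function(expr, genes, tau = 0.25, normalize = FALSE) {
  m <- unclass(expr)
  present <- intersect(genes, rownames(m))
  if (!length(present))
    abort("gene set entirely absent from the matrix; missing: %s",
          paste(genes, collapse = ", "))
  if (length(present) < length(genes))
    warn("%d/%d set gene(s) absent from the matrix; proceeding with the intersection",
         length(genes) - length(present), length(genes))
  scores <- vapply(seq_len(ncol(m)),
                   function(j) ssgsea_score(m[, j], present, tau), numeric(1))
  names(scores) <- colnames(m)
  if (normalize) {
    rng <- range(scores)
    scores <- if (rng[2L] > rng[1L]) (scores - rng[1L]) / diff(rng) else
      rep(0.5, length(scores))
    names(scores) <- colnames(m)
  }
  scores
}
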