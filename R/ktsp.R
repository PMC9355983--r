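#' k-Top-Scoring-Pairs (kTSP) score of one sample
#'
#' Fraction of (down, up) signature gene pairs that comply with the
#' expected within-sample ordering `down < up`. The comparison is strict,
#' so tied pairs count as non-compliant, and the score depends only on the
#' ranks of the expression values: any strictly increasing transform of
#' the profile leaves it unchanged.
#'
#' @param x Named numeric vector: one sample's expression profile.
#' @param signature A [gene_signature()]; genes absent from the profile
#'   are ignored, but at least one up and one down gene must be present.
#' @return Score in `[0, 1]`.
#' @export
ktsp_score <- function(x, signature) {
  stopifnot(inherits(signature, "gene_signature"))
  if (is.null(names(x))) abort("`x` must be a named vector")
  up <- intersect(signature$up_genes, names(x))
  down <- intersect(signature$down_genes, names(x))
  if (!length(up) || !length(down))
    abort("signature '%s': no %s gene present in the profile",
          signature$name,
          if (!length(up)) "up-regulated" else "down-regulated")
  mean(outer(x[down], x[up], `<`))
}

#' kTSP scores for every sample of a matrix
#'
#' @param expr [expression_matrix()] or named numeric matrix.
#' @param signature A [gene_signature()].
#' @return Named numeric vector of per-sample scores in `[0, 1]`.
#' @export
ktsp_matrix <- function(expr, signature) {
  m <- unclass(expr)
  scores <- vapply(seq_len(ncol(m)),
                   function(j) ktsp_score(m[, j], signature), numeric(1))
  stats::setNames(scores, colnames(m))
}
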