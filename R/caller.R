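#' Configuration of the NOTCH activation caller
#'
#' @param tau ssGSEA rank-weight exponent (>= 0, default 0.25).
#' @param normalize_scores Min-max rescale ssGSEA scores across the cohort
#'   before thresholding (default `TRUE`).
#' @param ktsp_threshold kTSP decision threshold in `[0, 1]` (default 0.5).
#' @param ssgsea_threshold Absolute ssGSEA decision threshold, or `NULL`
#'   (default) to use the cohort median.
#' @return An object of class `caller_config`.
#' @export
caller_config <- function(tau = 0.25, normalize_scores = TRUE,
                          ktsp_threshold = 0.5, ssgsea_threshold = NULL) {
  if (!is.numeric(tau) || tau < 0) abort("`tau` must be >= 0")
  if (!is.numeric(ktsp_threshold) || ktsp_threshold < 0 || ktsp_threshold > 1)
    abort("`ktsp_threshold` must be in [0, 1]")
  structure(list(tau = tau, normalize_scores = isTRUE(normalize_scores),
                 ktsp_threshold = ktsp_threshold,
                 ssgsea_threshold = ssgsea_threshold),
            class = "caller_config")
}

#' Call NOTCH pathway activation per sample
#'
#' The caller scores every sample twice: a ssGSEA running-sum enrichment
#' of the signature's up-regulated genes (higher = more NOTCH target
#' expression) and a kTSP rank score (fraction of down < up gene pairs).
#' A sample is called `activated` when both scores reach their
#' thresholds: kTSP >= `ktsp_threshold` and ssGSEA >= `ssgsea_threshold`
#' (cohort median when no absolute threshold is supplied).
#'
#' @param expr Raw or normalized [expression_matrix()]; the unit is
#'   recorded in the result but not changed.
#' @param signature A [gene_signature()] (default: the packaged 21-gene
#'   NOTCH signature, [notch_signature()]).
#' @param config A [caller_config()].
#' @return An object of class `notch_call`: a list with `scores` (data
#'   frame `sample_id`, `ssgsea_score`, `ktsp_score`, `call`),
#'   `thresholds`, `config`, `signature` and the input `kind`. Methods:
#'   `print`, `summary`, `plot`, `as.data.frame`.
#' @examples
#' sig <- notch_signature()
#' cohort <- simulate_expression_cohort(cohort_spec(6, 6, 200, seed = 3), sig)
#' fit <- notch_call(cohort$counts, sig)
#' fit
#' table(called = as.data.frame(fit)$call, truth = cohort$truth)
#' @export
notch_call <- function(expr, signature = notch_signature(),
                       config = caller_config()) {
  stopifnot(inherits(signature, "gene_signature"),
            inherits(config, "caller_config"))
  ss <- ssgsea_matrix(expr, signature$up_genes, tau = config$tau,
                      normalize = config$normalize_scores)
  kt <- ktsp_matrix(expr, signature)
  scores <- data.frame(sample_id = colnames(expr),
                       ssgsea_score = unname(ss),
                       ktsp_score = unname(kt),
                       stringsAsFactors = FALSE)
  out <- call_activation(scores, config)
  structure(list(scores = out$scores, thresholds = out$thresholds,
                 config = config, signature = signature,
                 kind = expr_kind(expr)),
            class = "notch_call")
}

#' Apply the activation decision rule to a score table
#'
#' @param scores Data frame with columns `sample_id`, `ssgsea_score`,
#'   `ktsp_score` (no missing values).
#' @param config A [caller_config()]; with `ssgsea_threshold = NULL` the
#'   cohort median of `ssgsea_score` is used.
#' @return List with `scores` (input plus a `call` column, `"activated"` /
#'   `"not_activated"`) and `thresholds` (the numeric thresholds applied).
#' @export
call_activation <- function(scores, config = caller_config()) {
  need <- c("sample_id", "ssgsea_score", "ktsp_score")
  missing <- setdiff(need, names(scores))
  if (length(missing))
    abort("`scores` missing column(s): %s", paste(missing, collapse = ", "))
  if (any(is.na(scores$ssgsea_score)) || any(is.na(scores$ktsp_score)))
    abort("missing score for sample(s): %s",
          paste(scores$sample_id[is.na(scores$ssgsea_score) |
                                   is.na(scores$ktsp_score)], collapse = ", "))
  ss_thr <- config$ssgsea_threshold %||% stats::median(scores$ssgsea_score)
  act <- scores$ktsp_score >= config$ktsp_threshold &
    scores$ssgsea_score >= ss_thr
  scores$call <- ifelse(act, "activated", "not_activated")
  list(scores = scores,
       thresholds = c(ktsp = config$ktsp_threshold, ssgsea = ss_thr))
}

#' @export
print.notch_call <- function(x, ...) {
  cat(sprintf("NOTCH activation call (%d samples, %s input)\n",
              nrow(x$scores), x$kind))
  cat(sprintf("  signature: %s (%d up / %d down genes)\n", x$signature$name,
              length(x$signature$up_genes), length(x$signature$down_genes)))
  cat(sprintf("  thresholds: kTSP >= %.3g, ssGSEA >= %.3g%s\n",
              x$thresholds["ktsp"], x$thresholds["ssgsea"],
              if (is.null(x$config$ssgsea_threshold)) " (cohort median)" else ""))
  cat(sprintf("  activated: %d / %d\n",
              sum(x$scores$call == "activated"), nrow(x$scores)))
  invisible(x)
}

#' @export
summary.notch_call <- function(object, ...) {
  s <- object$scores
  out <- list(n = nrow(s),
              n_activated = sum(s$call == "activated"),
              thresholds = object$thresholds,
              ssgsea_range = range(s$ssgsea_score),
              ktsp_range = range(s$ktsp_score),
              scores = s)
  class(out) <- "summary.notch_call"
  out
}

#' @export
print.summary.notch_call <- function(x, ...) {
  cat(sprintf("%d samples, %d called activated\n", x$n, x$n_activated))
  cat(sprintf("  ssGSEA in [%.3g, %.3g], kTSP in [%.3g, %.3g]\n",
              x$ssgsea_range[1L], x$ssgsea_range[2L],
              x$ktsp_range[1L], x$ktsp_range[2L]))
  print(x$scores)
  invisible(x)
}

#' Two-axis caller plot (kTSP vs ssGSEA)
#'
#' Scatter of the two caller scores, kTSP on x and ssGSEA on y, with the
#' decision thresholds as dashed lines; a shift down and to the left
#' indicates reduced NOTCH signaling activity.
#'
#' @param x A `notch_call` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.notch_call <- function(x, ...) {
  s <- x$scores
  act <- s$call == "activated"
  graphics::plot(s$ktsp_score, s$ssgsea_score,
                 xlab = "kTSP score", ylab = "ssGSEA score",
                 xlim = c(0, 1), pch = ifelse(act, 19, 1),
                 col = ifelse(act, "firebrick", "grey30"), ...)
  graphics::abline(v = x$thresholds["ktsp"], h = x$thresholds["ssgsea"],
                   lty = 2, col = "grey60")
  graphics::legend("topleft", pch = c(19, 1), col = c("firebrick", "grey30"),
                   legend = c("activated", "not activated"), bty = "n")
  invisible(x)
}

#' @export
as.data.frame.notch_call <- function(x, ...) x$scores

#' Hierarchical clustering of samples on signature genes
#'
#' Restricts the matrix to the signature genes present, then clusters the
#' samples with Euclidean distance and Ward.D2 linkage. Deterministic
#' given the input; the flat labels at the `k`-cluster cut are returned
#' alongside the merge tree.
#'
#' @param expr [expression_matrix()] (normalized values recommended).
#' @param signature A [gene_signature()].
#' @param k Number of flat clusters to cut (default 2).
#' @return List of class `signature_clustering`: `hclust` (the merge
#'   tree), `labels` (named integer cluster ids), `genes_used`, `k`.
#' @export
signature_cluster <- function(expr, signature = notch_signature(), k = 2L) {
  if (ncol(expr) < 2L) abort("clustering needs >= 2 samples")
  genes <- intersect(c(signature$up_genes, signature$down_genes),
                     rownames(expr))
  if (!length(genes)) abort("no signature gene present in the matrix")
  sub <- unclass(expr)[genes, , drop = FALSE]
  hc <- stats::hclust(stats::dist(t(sub), method = "euclidean"),
                      method = "ward.D2")
  labels <- stats::cutree(hc, k = min(k, ncol(expr)))
  structure(list(hclust = hc, labels = labels, genes_used = genes,
                 k = as.integer(k)),
            class = "signature_clustering")
}

#' @export
print.signature_clustering <- function(x, ...) {
  cat(sprintf("signature clustering: %d samples on %d genes (Euclidean, Ward.D2), k = %d\n",
              length(x$labels), length(x$genes_used), x$k))
  print(table(cluster = x$labels))
  invisible(x)
}

#' @export
plot.signature_clustering <- function(x, ...) {
  graphics::plot(x$hclust, ...)
  invisible(x)
}
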