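#' Per-gene log2 fold change between two groups
#'
#' `log2((mean_treated + c) / (mean_control + c))` on normalized values,
#' with pseudocount `c` guarding against zero means.
#'
#' @param normalized Normalized [expression_matrix()].
#' @param group_labels Character/factor vector, one label per sample.
#' @param treated,control The two labels to compare (treated over control).
#' @param pseudocount Added to both group means (default 0.5; 0 for exact
#'   ratios of positive means).
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
log2_fold_change <- function(normalized, group_labels, treated, control,
                             pseudocount = 0.5) {
  groups <- split_groups(normalized, group_labels, treated, control)
  mt <- rowMeans(groups$treated); mc <- rowMeans(groups$control)
  log2((mt + pseudocount) / (mc + pseudocount))
}

split_groups <- function(mat, group_labels, treated, control, min_n = 2L) {
  if (length(group_labels) != ncol(mat))
    abort("need one group label per sample")
  it <- which(group_labels == treated); ic <- which(group_labels == control)
  if (length(it) < min_n || length(ic) < min_n)
    abort("both groups need >= %d samples (treated: %d, control: %d)",
          min_n, length(it), length(ic))
  list(treated = unclass(mat)[, it, drop = FALSE],
       control = unclass(mat)[, ic, drop = FALSE])
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' A deliberately simple count-model test: per gene, a common dispersion
#' alpha is moment-estimated from the residual variability pooled within
#' the two groups (variance function m + alpha m^2, floored at
#' `dispersion_floor`), and the Wald statistic is the ln fold change of
#' the group means divided by its delta-method standard error. The
#' reference distribution is Student t with `n1 + n2 - 2` df by default,
#' which keeps the test calibrated at the small per-group sample sizes
#' typical of animal studies; `reference = "normal"` gives the large-sample
#' version. No dispersion shrinkage across genes is performed.
#'
#' Degenerate genes are defined, not errors: a gene with all-zero counts,
#' or constant counts identical across groups, gets statistic 0 and p 1.
#'
#' @param normalized Normalized [expression_matrix()].
#' @param group_labels Character/factor vector, one label per sample.
#' @param treated,control The two labels to compare.
#' @param reference `"t"` (default) or `"normal"`.
#' @param dispersion_floor Lower bound for the moment dispersion estimate.
#' @param pseudocount Stabilizer added to group means inside the statistic.
#' @return Data frame with `gene_id`, `statistic`, `pvalue`.
#' @export
nb_wald_test <- function(normalized, group_labels, treated, control,
                         reference = c("t", "normal"),
                         dispersion_floor = 1e-8, pseudocount = 0.5) {
  reference <- match.arg(reference)
  groups <- split_groups(normalized, group_labels, treated, control)
  g1 <- groups$control; g2 <- groups$treated
  n1 <- ncol(g1); n2 <- ncol(g2)
  if (n1 < 3L || n2 < 3L)
    warn("fewer than 3 samples in a group; the Wald test will be underpowered")
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  s1 <- apply(g1, 1L, stats::var); s2 <- apply(g2, 1L, stats::var)
  num <- (n1 - 1) * (s1 - m1) + (n2 - 1) * (s2 - m2)
  den <- (n1 - 1) * m1^2 + (n2 - 1) * m2^2
  alpha <- ifelse(den > 0, pmax(num / den, dispersion_floor), dispersion_floor)
  a1 <- m1 + pseudocount; a2 <- m2 + pseudocount
  se2 <- (1 / a1 + alpha) / n1 + (1 / a2 + alpha) / n2
  z <- log(a2 / a1) / sqrt(se2)
  p <- if (reference == "t") 2 * stats::pt(-abs(z), df = n1 + n2 - 2) else
    2 * stats::pnorm(-abs(z))
  degenerate <- (m1 == 0 & m2 == 0) | (s1 == 0 & s2 == 0 & m1 == m2)
  z[degenerate] <- 0; p[degenerate] <- 1
  data.frame(gene_id = rownames(normalized), statistic = z, pvalue = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply the three differential-expression filters
#'
#' A gene passes when, simultaneously, (i) its average normalized
#' expression exceeds `mean_min`, (ii) its |log2 fold change| exceeds
#' `lfc_min`, and (iii) its FDR is below `fdr_max`. All three thresholds
#' are strict inequalities: a mean of exactly 50 or a |log2FC| of exactly
#' 1 fails.
#'
#' @param results Data frame with columns `mean_norm`, `log2fc`, `fdr`.
#' @param mean_min,lfc_min,fdr_max Thresholds (defaults 50, 1, 0.05).
#' @return `results` with a logical `passes` column.
#' @export
apply_de_filters <- function(results, mean_min = 50, lfc_min = 1,
                             fdr_max = 0.05) {
  need <- c("mean_norm", "log2fc", "fdr")
  missing <- setdiff(need, names(results))
  if (length(missing))
    abort("`results` missing column(s): %s", paste(missing, collapse = ", "))
  results$passes <- results$mean_norm > mean_min &
    abs(results$log2fc) > lfc_min &
    results$fdr < fdr_max
  results
}

#' Two-group differential-expression analysis
#'
#' End-to-end convenience wrapper: normalizes raw counts (median-of-ratios)
#' when needed, computes per-gene mean normalized expression, log2 fold
#' changes, NB Wald p-values, BH-FDR, and the three-filter pass flag.
#'
#' @param expr Raw or normalized [expression_matrix()].
#' @param group_labels One label per sample.
#' @param treated,control Labels to compare (treated over control).
#' @param mean_min,lfc_min,fdr_max Filter thresholds (see
#'   [apply_de_filters()]).
#' @param ... Passed to [nb_wald_test()].
#' @return A `de_result` data frame: `gene_id`, `mean_norm`, `log2fc`,
#'   `statistic`, `pvalue`, `fdr`, `passes`.
#' @examples
#' sig <- notch_signature()
#' cohort <- simulate_expression_cohort(cohort_spec(5, 5, 300, seed = 7), sig)
#' de <- de_test(cohort$counts, cohort$metadata$group, "activated", "wild_type")
#' head(de[order(de$pvalue), ])
#' @export
de_test <- function(expr, group_labels, treated, control,
                    mean_min = 50, lfc_min = 1, fdr_max = 0.05, ...) {
  normalized <- if (inherits(expr, "expr_matrix") && expr_kind(expr) == "raw")
    normalize_counts(expr) else expr
  wald <- nb_wald_test(normalized, group_labels, treated, control, ...)
  out <- data.frame(gene_id = wald$gene_id,
                    mean_norm = rowMeans(unclass(normalized)),
                    log2fc = log2_fold_change(normalized, group_labels,
                                              treated, control),
                    statistic = wald$statistic,
                    pvalue = wald$pvalue,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$fdr <- bh_fdr(out$pvalue)
  out <- apply_de_filters(out, mean_min, lfc_min, fdr_max)
  attr(out, "thresholds") <- c(mean_min = mean_min, lfc_min = lfc_min,
                               fdr_max = fdr_max)
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, ...) {
  thr <- attr(x, "thresholds")
  cat(sprintf("differential expression: %d genes tested, %d pass (mean > %g, |log2FC| > %g, FDR < %g)\n",
              nrow(x), sum(x$passes), thr["mean_min"], thr["lfc_min"],
              thr["fdr_max"]))
  utils::head(as.data.frame(x)[order(x$pvalue), ], 10L) |> print()
  invisible(x)
}
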