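#' Minimal hypergeometric (mHG) statistic of a ranked membership vector
#'
#' Given a ranked gene list (most significant first) and a 0/1 membership
#' vector for a query set, the mHG statistic is the smallest
#' hypergeometric tail `HGT(b_n, n) = P(X >= b_n)`,
#' `X ~ Hypergeometric(N, B, n)`, over all prefix cutoffs `n = 1..N-1`,
#' where `b_n` counts members in the top `n`. Small values indicate that
#' members concentrate at the top of the ranking. Ties in the minimum are
#' resolved to the smallest cutoff.
#'
#' @param membership Logical (or 0/1) vector in ranked order.
#' @return List with `stat` (the minimal tail, in (0, 1]), `n_star`
#'   (optimizing cutoff) and `b_star` (members above it). With no members
#'   (`B = 0`) the statistic is 1 by definition.
#' @export
mhg_statistic <- function(membership) {
  lam <- as.logical(membership)
  if (any(is.na(lam))) abort("`membership` must be 0/1 or logical without NA")
  N <- length(lam); B <- sum(lam)
  if (B == 0L || N < 2L)
    return(list(stat = 1, n_star = 0L, b_star = 0L))
  n <- seq_len(N - 1L)
  b <- cumsum(lam)[n]
  tails <- stats::phyper(b - 1L, B, N - B, n, lower.tail = FALSE)
  i <- which.min(tails)  # first index attaining the minimum
  list(stat = tails[i], n_star = n[i], b_star = b[i])
}

#' Exact p-value of the mHG statistic
#'
#' Probability, under a uniform random permutation of the membership
#' vector, that the minimal hypergeometric tail is at most `stat`.
#' Computed exactly by a lattice-path dynamic program over the
#' (B+1) x (N-B+1) grid of (members seen, non-members seen): the path
#' probability mass is propagated cutoff by cutoff and mass entering a
#' cell whose tail probability is <= `stat` is removed (those paths
#' already achieved the statistic); the p-value is one minus the
#' surviving mass.
#'
#' @param stat mHG statistic from [mhg_statistic()].
#' @param N Length of the ranked list.
#' @param B Number of members.
#' @return Exact p-value in `[stat, min(1, stat * N)]`.
#' @export
mhg_exact_pvalue <- function(stat, N, B) {
  if (!is.numeric(stat) || stat <= 0 || stat > 1 + 1e-12)
    abort("`stat` must be in (0, 1]")
  if (!is_count(N) || !is_count(B) || B > N)
    abort("need 0 <= B <= N")
  if (B == 0L || N < 2L) return(1)
  tol <- stat * (1 + 1e-9)
  # prob[b + 1] = P(path alive with b members among first n ranks)
  prob <- c(1, rep(0, B))
  bvals <- 0:B
  for (n in seq_len(N)) {
    remaining <- N - n + 1
    p_succ <- (B - bvals) / remaining
    p_succ[p_succ < 0] <- 0; p_succ[p_succ > 1] <- 1
    stay <- prob * (1 - p_succ)
    step <- c(0, (prob * p_succ)[-(B + 1L)])
    prob <- stay + step
    if (n < N) {
      tails <- stats::phyper(bvals - 1L, B, N - B, n, lower.tail = FALSE)
      prob[tails <= tol] <- 0
    }
  }
  p <- 1 - sum(prob)
  min(max(p, 0), 1)
}

#' mHG enrichment of gene sets in a ranked list
#'
#' Runs [mhg_statistic()] and [mhg_exact_pvalue()] for each gene set
#' against a ranked gene list, then adjusts the exact p-values across sets
#' with [bh_fdr()]. The background universe defaults to the ranked list
#' itself (typically: all expressed genes).
#'
#' @param ranked_genes Character vector, most significant gene first.
#' @param gene_sets List of [gene_set()] objects (e.g. from [read_gmt()]).
#' @return Data frame with `set_name`, `n_overlap`, `mhg_stat`, `n_star`,
#'   `b_star`, `exact_p`, `fdr`.
#' @export
mhg_test <- function(ranked_genes, gene_sets) {
  if (anyDuplicated(ranked_genes)) abort("`ranked_genes` must be unique")
  if (inherits(gene_sets, "gene_set")) gene_sets <- list(gene_sets)
  rows <- lapply(gene_sets, function(gs) {
    lam <- ranked_genes %in% gs$genes
    st <- mhg_statistic(lam)
    data.frame(set_name = gs$name, n_overlap = sum(lam),
               mhg_stat = st$stat, n_star = st$n_star, b_star = st$b_star,
               exact_p = mhg_exact_pvalue(st$stat, length(lam), sum(lam)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$exact_p)
  out
}

#' One-sided exact binomial overlap test
#'
#' `P(X >= k)` for `X ~ Binomial(n, p_null)`: the probability of seeing at
#' least `k` hits among `n` trials when each trial hits with probability
#' `p_null` (e.g. testing whether downregulated genes over-represent a
#' pathway of known size within the genome).
#'
#' @param k_hits Observed hits (0..n).
#' @param n_trials Number of trials.
#' @param p_null Null hit probability, in (0, 1).
#' @return One-sided exact p-value.
#' @export
binomial_overlap_test <- function(k_hits, n_trials, p_null) {
  if (!is_count(k_hits) || !is_count(n_trials) || k_hits > n_trials)
    abort("need integer 0 <= k_hits <= n_trials")
  if (!is.numeric(p_null) || p_null <= 0 || p_null >= 1)
    abort("`p_null` must be in (0, 1)")
  if (k_hits == 0L) return(1)
  stats::pbinom(k_hits - 1, n_trials, p_null, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforced (cumulative
#' minimum from the largest rank); a thin validated front end to
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    abort("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
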