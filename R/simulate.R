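#' Specify a synthetic expression cohort
#'
#' Defines the generative model for a two-arm cohort: negative-binomial
#' counts with per-gene baseline means drawn log-uniformly over
#' `base_mean_range`, a multiplicative `up_effect` (>= 1) on signature
#' up-genes and `down_effect` (in (0, 1]) on signature down-genes in
#' activated samples, a single global dispersion, and per-sample library
#' size jitter.
#'
#' @param n_activated,n_wildtype Samples per arm.
#' @param n_genes Total genes, signature genes included.
#' @param up_effect Fold applied to up-set genes in activated samples
#'   (default 4; 1 gives the null model).
#' @param down_effect Fold applied to down-set genes in activated samples
#'   (default 0.25; 1 gives the null model).
#' @param dispersion NB dispersion alpha (> 0) with variance m + alpha m^2.
#' @param base_mean_range Range (low, high) of per-gene baseline means.
#' @param libsize_jitter Half-width of the uniform per-sample size factor
#'   (default 0.2, i.e. factors in 0.8--1.2).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_activated, n_wildtype, n_genes,
                        up_effect = 4, down_effect = 0.25, dispersion = 0.1,
                        base_mean_range = c(20, 2000), libsize_jitter = 0.2,
                        seed = 1L) {
  if (!is_count(n_activated) || !is_count(n_wildtype) || !is_count(n_genes))
    abort("sample and gene numbers must be non-negative integers")
  if (!is.numeric(up_effect) || up_effect < 1)
    abort("`up_effect` must be >= 1")
  if (!is.numeric(down_effect) || down_effect <= 0 || down_effect > 1)
    abort("`down_effect` must be in (0, 1]")
  if (!is.numeric(dispersion) || dispersion <= 0)
    abort("`dispersion` must be > 0")
  if (length(base_mean_range) != 2L || any(base_mean_range <= 0) ||
      base_mean_range[1L] > base_mean_range[2L])
    abort("`base_mean_range` must be positive and increasing")
  if (libsize_jitter < 0 || libsize_jitter >= 1)
    abort("`libsize_jitter` must be in [0, 1)")
  structure(list(n_activated = as.integer(n_activated),
                 n_wildtype = as.integer(n_wildtype),
                 n_genes = as.integer(n_genes),
                 up_effect = up_effect, down_effect = down_effect,
                 dispersion = dispersion,
                 base_mean_range = as.numeric(base_mean_range),
                 libsize_jitter = libsize_jitter,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a NOTCH-activated vs wild-type expression cohort
#'
#' Draws raw NB counts for `spec$n_genes` genes over the two arms.
#' Signature up-genes have their means multiplied by `spec$up_effect` and
#' down-genes by `spec$down_effect` in activated samples only. Truth
#' labels are returned for recovery tests.
#'
#' @param spec A [cohort_spec()].
#' @param signature A [gene_signature()]; its genes are embedded among the
#'   background genes.
#' @return A list of class `notch_cohort` with elements `counts` (raw
#'   [expression_matrix()]), `metadata` (sample_id, group, treatment),
#'   `truth` (named logical: activated?), `mu` (expected count matrix),
#'   `spec`, `signature`.
#' @export
simulate_expression_cohort <- function(spec, signature = notch_signature()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(signature, "gene_signature"))
  sig_genes <- c(signature$up_genes, signature$down_genes)
  if (spec$n_genes < length(sig_genes))
    abort("`n_genes` (%d) smaller than the signature (%d genes)",
          spec$n_genes, length(sig_genes))
  n_bg <- spec$n_genes - length(sig_genes)
  genes <- c(sig_genes,
             if (n_bg) sprintf("BG%05d", seq_len(n_bg)))
  n <- spec$n_activated + spec$n_wildtype
  if (n < 1L) abort("cohort needs at least one sample")
  samples <- c(if (spec$n_activated) sprintf("ACT%02d", seq_len(spec$n_activated)),
               if (spec$n_wildtype) sprintf("WT%02d", seq_len(spec$n_wildtype)))
  activated <- c(rep(TRUE, spec$n_activated), rep(FALSE, spec$n_wildtype))

  with_seed(spec$seed, {
    lo <- log(spec$base_mean_range[1L]); hi <- log(spec$base_mean_range[2L])
    base <- exp(stats::runif(spec$n_genes, lo, hi))
    sf <- stats::runif(n, 1 - spec$libsize_jitter, 1 + spec$libsize_jitter)
    effect <- matrix(1, nrow = spec$n_genes, ncol = n,
                     dimnames = list(genes, samples))
    effect[signature$up_genes, activated] <- spec$up_effect
    effect[signature$down_genes, activated] <- spec$down_effect
    mu <- base * effect
    mu <- sweep(mu, 2L, sf, `*`)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / spec$dispersion),
                     nrow = spec$n_genes, dimnames = dimnames(mu))
    structure(list(
      counts = expression_matrix(counts, "raw"),
      metadata = data.frame(sample_id = samples,
                            group = ifelse(activated, "activated", "wild_type"),
                            treatment = "vehicle",
                            stringsAsFactors = FALSE),
      truth = stats::setNames(activated, samples),
      mu = mu, spec = spec, signature = signature),
      class = "notch_cohort")
  })
}

#' Simulate a drug-treatment expression series for a cohort
#'
#' Redraws counts from the cohort's generative model with the signature
#' up-genes of activated samples multiplied by `drug_effect`, emulating a
#' pathway inhibitor that suppresses target-gene expression only where the
#' pathway is active. Wild-type samples are statistically unchanged.
#'
#' @param cohort Output of [simulate_expression_cohort()].
#' @param drug_effect Fold (in (0, 1]) applied to up-set genes of
#'   activated samples; 1 gives an independent redraw of the untreated
#'   model.
#' @param seed Integer seed.
#' @return A raw [expression_matrix()] with the cohort's genes and samples.
#' @export
simulate_treatment_series <- function(cohort, drug_effect, seed = 1L) {
  stopifnot(inherits(cohort, "notch_cohort"))
  if (!is.numeric(drug_effect) || drug_effect <= 0 || drug_effect > 1)
    abort("`drug_effect` must be in (0, 1]")
  mu <- cohort$mu
  act <- names(cohort$truth)[cohort$truth]
  mu[cohort$signature$up_genes, act] <-
    mu[cohort$signature$up_genes, act] * drug_effect
  with_seed(seed, {
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / cohort$spec$dispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    expression_matrix(counts, "raw")
  })
}

#' Specify a synthetic xenograft growth study
#'
#' Per-group exponential tumor growth with multiplicative lognormal
#' measurement noise. `treatment_multiplier` scales the group's daily
#' growth rate (1 = untreated kinetics, 0 = stasis, < 0 impossible; use a
#' negative `growth_rate` for regression).
#'
#' @param groups Data frame with columns `name`, `n_animals`,
#'   `growth_rate` (per day, on ln(mm^3)) and optionally
#'   `treatment_multiplier` (default 1).
#' @param v0_range Initial tumor volume range in mm^3 (default 150--300,
#'   the usual randomization window).
#' @param noise_sd SD of the lognormal measurement noise on volumes.
#' @param days Measurement days (non-empty, distinct).
#' @param seed Integer seed.
#' @return An object of class `growth_spec`.
#' @export
growth_spec <- function(groups, v0_range = c(150, 300), noise_sd = 0.1,
                        days = c(0, 4, 7, 11, 14, 18, 21, 25, 28),
                        seed = 1L) {
  if (!is.data.frame(groups) ||
      !all(c("name", "n_animals", "growth_rate") %in% names(groups)))
    abort("`groups` needs columns name, n_animals, growth_rate")
  if (is.null(groups$treatment_multiplier)) groups$treatment_multiplier <- 1
  if (any(groups$n_animals < 2L))
    abort("every group needs >= 2 animals")
  if (anyDuplicated(groups$name)) abort("group names must be unique")
  if (length(v0_range) != 2L || any(v0_range <= 0) || v0_range[1L] > v0_range[2L])
    abort("`v0_range` must be positive and increasing")
  if (!length(days)) abort("`days` must be non-empty")
  if (anyDuplicated(days) || any(days < 0) || any(days != round(days)))
    abort("`days` must be distinct non-negative integers")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  structure(list(groups = groups, v0_range = as.numeric(v0_range),
                 noise_sd = noise_sd, days = sort(as.integer(days)),
                 seed = as.integer(seed)),
            class = "growth_spec")
}

#' Simulate caliper growth curves
#'
#' Per animal, `V(day) = V0 * exp(rate * multiplier * day) * noise` with
#' lognormal noise `exp(N(0, noise_sd))`. Width and length are
#' back-derived assuming width = length, so the caliper volume formula
#' `0.52 * width^2 * length` reproduces `V`.
#'
#' @param spec A [growth_spec()].
#' @return A `growth_table` data frame (see [read_growth_table()]) with a
#'   `volume` column.
#' @export
simulate_growth_curves <- function(spec) {
  stopifnot(inherits(spec, "growth_spec"))
  with_seed(spec$seed, {
    rows <- list()
    for (i in seq_len(nrow(spec$groups))) {
      g <- spec$groups[i, ]
      rate <- g$growth_rate * g$treatment_multiplier
      for (a in seq_len(g$n_animals)) {
        id <- sprintf("%s_%02d", g$name, a)
        v0 <- stats::runif(1, spec$v0_range[1L], spec$v0_range[2L])
        noise <- if (spec$noise_sd > 0)
          exp(stats::rnorm(length(spec$days), 0, spec$noise_sd)) else
          rep(1, length(spec$days))
        v <- v0 * exp(rate * spec$days) * noise
        w <- (v / 0.52)^(1 / 3)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = id, group = g$name, day = spec$days,
          width = w, length = w, volume = 0.52 * w^2 * w,
          stringsAsFactors = FALSE)
      }
    }
    as_growth_table(do.call(rbind, rows))
  })
}

#' Simulate a qPCR Ct table
#'
#' For each target gene, treated-condition Ct values are shifted by
#' `-log2(fold)` relative to control so that the downstream
#' 2^-ddCt computation recovers `true_fold_changes`; the reference gene
#' (fold fixed at 1) is included in every (sample, condition).
#'
#' @param n_samples Replicates per condition.
#' @param genes Target gene names.
#' @param true_fold_changes Positive folds, one per target gene.
#' @param noise_sd SD of additive Gaussian Ct noise (cycles).
#' @param seed Integer seed.
#' @param reference_gene Reference gene name (default `"ACTB"`).
#' @return A validated `ct_table`.
#' @export
simulate_ct_table <- function(n_samples, genes, true_fold_changes,
                              noise_sd = 0, seed = 1L,
                              reference_gene = "ACTB") {
  if (length(genes) != length(true_fold_changes))
    abort("`true_fold_changes` must match `genes` in length")
  if (any(true_fold_changes <= 0)) abort("fold changes must be > 0")
  if (!is_count(n_samples) || n_samples < 1L)
    abort("`n_samples` must be a positive integer")
  target_base <- 26; ref_base <- 18
  with_seed(seed, {
    rows <- list()
    for (cond in c("control", "treated")) {
      for (s in seq_len(n_samples)) {
        sid <- sprintf("%s_%02d", cond, s)
        shift <- if (cond == "treated") -log2(true_fold_changes) else
          rep(0, length(genes))
        ct <- target_base + shift +
          if (noise_sd > 0) stats::rnorm(length(genes), 0, noise_sd) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, condition = cond,
          gene = c(genes, reference_gene),
          ct = c(ct, ref_base +
                   if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0),
          is_reference = c(rep(FALSE, length(genes)), TRUE),
          stringsAsFactors = FALSE)
      }
    }
    as_ct_table(do.call(rbind, rows))
  })
}
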