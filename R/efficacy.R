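#' Caliper tumor volume
#'
#' `TV = 0.52 * width^2 * length` (mm^3), the standard ellipsoid
#' approximation for subcutaneous xenografts measured with digital
#' calipers.
#'
#' @param width,length Caliper dimensions in mm (width the shorter axis);
#'   vectorized.
#' @return Volumes in mm^3.
#' @export
tumor_volume <- function(width, length) {
  if (any(!is.finite(width)) || any(width <= 0) ||
      any(!is.finite(length)) || any(length <= 0))
    abort("caliper dimensions must be positive")
  0.52 * width^2 * length
}

ensure_volume <- function(growth) {
  if (is.null(growth$volume))
    growth$volume <- tumor_volume(growth$width, growth$length)
  growth
}

#' Percent tumor growth inhibition (%TGI)
#'
#' `%TGI = 100 * (1 - (T_final - T_baseline) / (C_final - C_baseline))`
#' on group-summarized volumes (arithmetic mean by default). 0% means the
#' treated arm grew like control, 100% means stasis, and values above
#' 100% indicate regression below baseline.
#'
#' Baseline and final days default to the smallest and largest days
#' measured in both groups. Animals lacking either measurement are
#' excluded with a warning (no interpolation); a control volume change of
#' zero leaves the ratio undefined and is a hard error.
#'
#' @param growth A `growth_table` (see [read_growth_table()]).
#' @param treated_group,control_group Group names.
#' @param baseline_day,final_day Measurement days; `NULL` for defaults.
#' @param summary `"mean"` (default) or `"median"` group summary.
#' @return An object of class `tgi_result`: group summaries at both days
#'   and `tgi_percent`.
#' @examples
#' g <- data.frame(
#'   animal_id = rep(c("c1", "c2", "t1", "t2"), each = 2),
#'   group = rep(c("vehicle", "vehicle", "drug", "drug"), each = 2),
#'   day = rep(c(0, 21), 4), width = 1, length = 1,
#'   volume = c(150, 350, 150, 350, 200, 180, 200, 180))
#' percent_tgi(as_growth_table(g), "drug", "vehicle")
#' @export
percent_tgi <- function(growth, treated_group, control_group,
                        baseline_day = NULL, final_day = NULL,
                        summary = c("mean", "median")) {
  summary <- match.arg(summary)
  growth <- ensure_volume(growth)
  sub <- growth[growth$group %in% c(treated_group, control_group), , drop = FALSE]
  if (!any(sub$group == treated_group)) abort("no animals in group '%s'", treated_group)
  if (!any(sub$group == control_group)) abort("no animals in group '%s'", control_group)
  common <- intersect(sub$day[sub$group == treated_group],
                      sub$day[sub$group == control_group])
  if (!length(common)) abort("the two groups share no measurement day")
  baseline_day <- baseline_day %||% min(common)
  final_day <- final_day %||% max(common)
  if (baseline_day == final_day)
    abort("baseline and final day coincide (day %s)", baseline_day)

  summarize <- function(grp) {
    g <- sub[sub$group == grp, , drop = FALSE]
    have_b <- unique(g$animal_id[g$day == baseline_day])
    have_f <- unique(g$animal_id[g$day == final_day])
    keep <- intersect(have_b, have_f)
    dropped <- setdiff(unique(g$animal_id), keep)
    if (length(dropped))
      warn("group '%s': excluding animal(s) without both day-%s and day-%s measurements: %s",
           grp, baseline_day, final_day, paste(dropped, collapse = ", "))
    if (!length(keep))
      abort("group '%s' has no animal measured on both day %s and day %s",
            grp, baseline_day, final_day)
    f <- if (summary == "mean") mean else stats::median
    c(baseline = f(g$volume[g$day == baseline_day & g$animal_id %in% keep]),
      final = f(g$volume[g$day == final_day & g$animal_id %in% keep]),
      n = length(keep))
  }
  st <- summarize(treated_group); sc <- summarize(control_group)
  dC <- sc[["final"]] - sc[["baseline"]]
  if (dC == 0)
    abort("control group volume change is zero; %%TGI undefined")
  dT <- st[["final"]] - st[["baseline"]]
  structure(list(treated_group = treated_group,
                 control_group = control_group,
                 baseline_day = baseline_day, final_day = final_day,
                 summary = summary,
                 baseline_mean_t = st[["baseline"]], final_mean_t = st[["final"]],
                 baseline_mean_c = sc[["baseline"]], final_mean_c = sc[["final"]],
                 n_treated = st[["n"]], n_control = sc[["n"]],
                 tgi_percent = 100 * (1 - dT / dC)),
            class = "tgi_result")
}

#' @export
print.tgi_result <- function(x, ...) {
  cat(sprintf("%%TGI (%s vs %s, day %s -> %s, %s summary): %.1f%%\n",
              x$treated_group, x$control_group, x$baseline_day, x$final_day,
              x$summary, x$tgi_percent))
  cat(sprintf("  treated: %.1f -> %.1f mm^3 (n = %d)\n",
              x$baseline_mean_t, x$final_mean_t, x$n_treated))
  cat(sprintf("  control: %.1f -> %.1f mm^3 (n = %d)\n",
              x$baseline_mean_c, x$final_mean_c, x$n_control))
  invisible(x)
}

#' Per-animal log-linear growth rates
#'
#' Ordinary least-squares regression of `ln(volume)` on study day,
#' separately for each animal. Under exponential growth the slope is the
#' daily growth rate.
#'
#' @param growth A `growth_table`; volumes must be positive.
#' @return A `growth_fits` data frame: `animal_id`, `group`, `slope`,
#'   `intercept`, `r_squared` (`NA` for a perfectly flat trajectory),
#'   `n_points`.
#' @export
growth_slopes <- function(growth) {
  growth <- ensure_volume(growth)
  if (any(growth$volume <= 0))
    abort("non-positive tumor volume; ln transform undefined")
  ids <- unique(growth$animal_id)
  rows <- lapply(ids, function(id) {
    g <- growth[growth$animal_id == id, , drop = FALSE]
    fit <- stats::lm(log(volume) ~ day, data = g)
    cf <- stats::coef(fit)
    y <- log(g$volume)
    tot <- sum((y - mean(y))^2)
    r2 <- if (tot > 0) 1 - sum(stats::residuals(fit)^2) / tot else NA_real_
    data.frame(animal_id = id, group = g$group[1L],
               slope = unname(cf[2L]), intercept = unname(cf[1L]),
               r_squared = r2, n_points = nrow(g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("growth_fits", "data.frame")
  out
}

#' One-way ANOVA with Tukey-Kramer comparisons on growth slopes
#'
#' Runs a one-way analysis of variance of per-animal slopes across
#' treatment groups and compares all group pairs with the Tukey-Kramer
#' procedure (studentized-range reference with the harmonic adjustment
#' for unequal group sizes, via [stats::TukeyHSD()]).
#'
#' @param fits A `growth_fits` data frame from [growth_slopes()] (or any
#'   data frame with `slope` and `group` columns).
#' @return An object of class `group_comparison`: `anova_F`, `anova_p`,
#'   and a `pairwise` data frame (`group_i`, `group_j`, `mean_diff`,
#'   `lwr`, `upr`, `adjusted_p`).
#' @export
anova_tukey <- function(fits) {
  if (!all(c("slope", "group") %in% names(fits)))
    abort("`fits` needs columns slope and group")
  fits$group <- factor(fits$group)
  sizes <- table(fits$group)
  if (length(sizes) < 2L) abort("need >= 2 groups")
  if (any(sizes < 2L))
    abort("group(s) with < 2 animals: %s",
          paste(names(sizes)[sizes < 2L], collapse = ", "))
  fit <- stats::aov(slope ~ group, data = fits)
  tab <- summary(fit)[[1L]]
  tuk <- stats::TukeyHSD(fit)$group
  pairs <- do.call(rbind, strsplit(rownames(tuk), "-", fixed = TRUE))
  pairwise <- data.frame(group_i = pairs[, 1L], group_j = pairs[, 2L],
                         mean_diff = tuk[, "diff"], lwr = tuk[, "lwr"],
                         upr = tuk[, "upr"], adjusted_p = tuk[, "p adj"],
                         stringsAsFactors = FALSE, row.names = NULL)
  structure(list(groups = levels(fits$group),
                 anova_F = tab[1L, "F value"],
                 anova_p = tab[1L, "Pr(>F)"],
                 pairwise = pairwise),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("one-way ANOVA on slopes: F = %.4g, p = %.4g (%d groups)\n",
              x$anova_F, x$anova_p, length(x$groups)))
  print(x$pairwise)
  invisible(x)
}

#' qPCR fold changes by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; per gene,
#' `ddCt = mean dCt(treated) - mean dCt(control)` and the fold change is
#' `2^-ddCt` (treated relative to control, reference-gene normalized).
#'
#' @param ct A validated `ct_table` (see [as_ct_table()]).
#' @return Data frame with `gene`, `ddct`, `fold_change`, `n_treated`,
#'   `n_control`.
#' @export
ddct_fold_change <- function(ct) {
  if (!inherits(ct, "ct_table")) ct <- as_ct_table(ct)
  key <- paste(ct$sample_id, ct$condition, sep = "\r")
  ref <- ct[ct$is_reference, , drop = FALSE]
  ref_ct <- stats::setNames(ref$ct, paste(ref$sample_id, ref$condition, sep = "\r"))
  targets <- ct[!ct$is_reference, , drop = FALSE]
  targets$dct <- targets$ct - ref_ct[paste(targets$sample_id,
                                           targets$condition, sep = "\r")]
  rows <- lapply(unique(targets$gene), function(g) {
    t_ <- targets[targets$gene == g, , drop = FALSE]
    dt <- t_$dct[t_$condition == "treated"]
    dc <- t_$dct[t_$condition == "control"]
    if (!length(dt) || !length(dc))
      abort("gene '%s' missing in one condition", g)
    ddct <- mean(dt) - mean(dc)
    data.frame(gene = g, ddct = ddct, fold_change = 2^(-ddct),
               n_treated = length(dt), n_control = length(dc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
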