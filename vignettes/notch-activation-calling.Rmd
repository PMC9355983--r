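---
title: "Calling NOTCH pathway activation and quantifying preclinical efficacy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling NOTCH pathway activation and quantifying preclinical efficacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notchcaller)
```

## The problem

Roughly a fifth of adenoid cystic carcinomas carry NOTCH-activating
mutations (disrupted negative regulatory region, lost PEST degron, or
juxtamembrane expansions), and these tumors respond differently to
γ-secretase inhibition than their wild-type counterparts. Deciding from a
bulk expression profile whether a tumor's NOTCH pathway is constitutively
active — and quantifying, in xenograft experiments, how much a drug slows
tumor growth — are the two statistical tasks this package addresses. Both
are small-sample problems (a handful of cell models; five to ten animals
per arm), which drives most of the design choices below.

## The activation caller

A sample is scored on a signature with two halves: 21 genes expected to be
*elevated* under NOTCH activation and 4 genes (*LXN*, *RAPGEF3*,
*TMEM154*, *LGR6*) expected to be *suppressed*. Two statistics look at the
same profile from different angles.

**ssGSEA.** Genes are ranked by decreasing expression within the sample
and given rank scores $r_g = N - \mathrm{pos}(g) + 1$. Walking down the
ranking, the score accumulates the gap between the weighted in-set ECDF
and the unweighted out-of-set ECDF:

$$\mathrm{score} = \sum_{i=1}^{N}\left[
  \frac{\sum_{g \in S,\ \mathrm{pos}(g)\le i} r_g^{\tau}}
       {\sum_{g \in S} r_g^{\tau}}
  - \frac{\#\{g \notin S,\ \mathrm{pos}(g)\le i\}}{N - |S|}\right].$$

The weight exponent defaults to $\tau = 0.25$, the conventional default of
the single-sample enrichment family; $\tau = 0$ gives the unweighted
running sum. The score is monotone in any in-set gene's expression and
blind to reshuffling among out-of-set genes. Two numerical conventions
make it bit-reproducible: expression ties are broken lexicographically by
gene identifier, and the degenerate profile in which *every* measured gene
belongs to the set (no outside reference exists) scores 0, with a warning.

**kTSP.** The fraction of $(d, u)$ pairs from down-set × up-set with
$x_d < x_u$ within the sample. The comparison is strict, so ties count
against compliance, and the score depends only on ranks — it is invariant
under any strictly increasing transform of the profile, which makes it
robust to normalization choices.

**The decision rule.** The two scores are combined conjunctively: a sample
is called activated when kTSP ≥ 0.5 *and* ssGSEA ≥ a threshold. The kTSP
cut of 0.5 is the natural "more pairs right than wrong" point. For ssGSEA
no absolute scale exists across cohorts, so by default scores are min–max
rescaled within the cohort and thresholded at the cohort median; an
absolute threshold can be supplied instead (`caller_config()`). This is a
deliberate design decision on a genuinely open point — the method family
is defined by "the combination of the two scores" without a published
numeric rule — and both thresholds are recorded in every output. The
cohort-median default implies that in a cohort with no activated samples
roughly half will still sit above the ssGSEA median; the kTSP conjunct
(which *does* have an absolute scale) is what keeps the false-call rate
down in that situation.

**Signature membership.** The down-set is fixed and published; the exact
21-gene up-set is not enumerated in the literature we model, so the
packaged default assembles the named NOTCH targets (HES/HEY families,
*NRARP*, *MYC*, *CDK6*, *CCND1*, *KIT*) and pads to 21 with canonical
direct NOTCH targets (*DTX1*, *DTX4*, *JAG1*, *LFNG*, *NOTCH3*, *GATA3*,
*SOX9*, *PTCRA*, *CR2*). It ships as a GMT under `inst/extdata` precisely
so users with their own curation can replace it; every function takes the
signature as an argument.

**Clustering.** `signature_cluster()` restricts the matrix to signature
genes and clusters samples with Euclidean distance and Ward.D2 linkage —
the standard choice for expression heatmaps of this kind — returning the
merge tree and the flat labels at a configurable cut (k = 2 by default:
activated-like vs not). Cluster-significance testing is out of scope.

## Normalization and differential expression

Raw counts are normalized by median-of-ratios size factors: for sample
$j$, the median over all-expressed genes of $c_{gj}/\mathrm{geomean}_g$.
Genes with a zero anywhere are excluded from the reference; if no gene
survives, the error suggests the 0.5-pseudocount fallback
(`pseudo_reference = TRUE`) rather than applying it silently.

The differential-expression stage is deliberately minimal: its
reproducible content is the *three-filter rule*, not estimator internals.
A gene is differentially expressed when, simultaneously,

1. mean normalized expression across all samples > 50,
2. |log₂ fold-change| > 1, and
3. BH-FDR < 0.05,

with all three thresholds strict, exactly as printed in the source
protocol (a mean of exactly 50 fails; |log₂FC| of exactly 1 fails). The
mean is taken over all samples by default (the protocol does not say
per-group; a per-group variant can be built from the exported pieces).
Fold changes use a 0.5 pseudocount on group means, which avoids ±∞ on
zero means while preserving ordering.

The test behind filter 3 is a moment-based negative-binomial Wald test:
per gene, a common dispersion $\alpha$ is estimated by method of moments
pooled within the two groups (variance function $m + \alpha m^2$, floored
at $10^{-8}$), and the statistic is the ln fold change of group means over
its delta-method standard error. No shrinkage across genes, no outlier
refitting, no independent filtering — those belong to full DE machinery,
which this package does not reimplement. One small-sample choice matters:
with five animals per arm the large-sample normal reference is visibly
anticonservative (measured type-I error ≈ 0.09 at nominal 0.05 in our
null simulations), because the moment variance estimate carries roughly
$n_1+n_2-2$ degrees of freedom of noise. The default reference is
therefore Student t with $n_1+n_2-2$ df, which our simulations (2000 NB
genes, 5+5 samples, dispersion 0.05–0.3) place at 0.054–0.062 with ~97%
power for 4-fold genes at FDR < 0.05; `reference = "normal"` restores the
asymptotic version. Degenerate genes are defined results, not errors:
all-zero or across-group-constant genes get statistic 0 and p 1.

## Minimal-hypergeometric enrichment

For a ranked gene list with membership vector $\lambda \in \{0,1\}^N$
(B members), the mHG statistic is the best hypergeometric tail over all
prefix cutoffs:

$$\mathrm{mHG} = \min_{1 \le n \le N-1} P(X \ge b_n), \qquad
  X \sim \mathrm{HG}(N, B, n),\ b_n = \textstyle\sum_{i\le n}\lambda_i,$$

with ties in the minimum resolved to the smallest cutoff and the $B = 0$
case defined as 1. Because the cutoff is optimized, the statistic itself
is not a p-value; the exact p-value is the null probability (uniform over
all $\binom{N}{B}$ orderings) that the minimal tail is at most the
observed one. It is computed by the standard lattice-path dynamic program
on the $(B{+}1)\times(N{-}B{+}1)$ grid: path probability mass is
propagated rank by rank via the hypergeometric transition
$P(\text{member at rank } n \mid b) = (B-b)/(N-n+1)$, mass entering a
cell whose tail is ≤ the observed statistic is removed (those orderings
already achieved it), and the p-value is one minus the surviving mass.
This is $O(NB)$, numerically stable in probability space (tails via
`phyper`, which works in log space internally), and exact: the test suite
checks it against exhaustive enumeration of all orderings for every
$N \le 9$. Cell blocking uses a $10^{-9}$ relative tolerance on the tail
comparison so that floating-point jitter cannot split orderings that are
mathematically tied.

Overlap-style questions (are down-regulated genes over-represented in a
pathway of known size?) use the exact binomial tail
`binomial_overlap_test(k, n, p0)` = $P(X \ge k)$, $X\sim\mathrm{Bin}(n,p_0)$.
Multiple gene sets are adjusted with Benjamini–Hochberg FDR (`bh_fdr()`,
a validated front end to `p.adjust`).

## Xenograft efficacy

Caliper measurements become volumes via the ellipsoid approximation
$TV = 0.52\,w^2\,\ell$ (mm³). Percent tumor growth inhibition compares
volume *changes* from baseline:

$$\%TGI = 100\left(1 - \frac{\bar T_{\mathrm{final}} - \bar T_{\mathrm{baseline}}}
  {\bar C_{\mathrm{final}} - \bar C_{\mathrm{baseline}}}\right),$$

so 0 means growth like control, 100 stasis, and values above 100
regression below baseline. Group summaries are arithmetic means by
default (`summary = "median"` is available); the baseline and final days
default to the smallest and largest days measured in both groups —
mirroring randomization-day baselines. Animals missing either endpoint
are excluded with a warning naming them, never interpolated; a flat
control arm makes the ratio undefined and is an error. %TGI is invariant
to rescaling all volumes by a constant.

Longitudinal inference uses the growth-rate route: per animal, ordinary
least squares of $\ln TV$ on study day (under exponential growth the
slope is the daily rate), then one-way ANOVA on the slopes across groups
and all pairwise Tukey–Kramer comparisons (studentized-range reference
with the harmonic mean adjustment for unequal arm sizes, via
`TukeyHSD`). For two groups the Tukey-adjusted p reduces to the pooled
t-test p through $q = \sqrt{2}\,|t|$, which the tests verify; over 1000
simulated null three-arm studies the family-wise error sits at ≈ 0.05.

qPCR validation uses the 2^−ΔΔCt rule: per sample
$\Delta Ct = Ct_{\mathrm{target}} - Ct_{\mathrm{reference}}$, per gene
$\Delta\Delta Ct = \overline{\Delta Ct}_{\mathrm{treated}} -
\overline{\Delta Ct}_{\mathrm{control}}$, fold $= 2^{-\Delta\Delta Ct}$.
Each (sample, condition) must carry exactly one reference-gene Ct
(typically *ACTB*); its absence is an error naming the sample.

## What the synthetic data emulates — and what it does not

The generators produce data with exactly the structure the analysis
assumes, so recovery tests are informative about the code, not about
biology:

- `simulate_expression_cohort()`: NB counts, variance $m + \alpha m^2$,
  a single global dispersion (default 0.1, a typical bulk RNA-seq scale),
  per-gene baseline means drawn log-uniformly over 20–2000 normalized
  reads, per-sample library size factors uniform in ±20%, and clean
  multiplicative effects (default 4× up, 0.25× down) on signature genes
  of activated samples. Defaults of 10 + 10 samples with these effects
  define the reference recovery condition (the caller should label
  ≥ 90% of samples correctly).
- `simulate_treatment_series()`: an independent redraw of the cohort with
  up-set means of activated samples multiplied by the drug effect —
  treatment changes means only, never dispersion.
- `simulate_growth_curves()`: $V = V_0 e^{rt}\cdot e^{\varepsilon}$,
  $\varepsilon \sim N(0, \sigma^2)$, $V_0$ uniform over 150–300 mm³,
  twice-weekly measurement days over four weeks; noise is multiplicative
  lognormal *by construction*, so the ln-regression assumptions hold
  exactly. Width = length is assumed when back-deriving caliper reads.
- `simulate_ct_table()`: fixed baselines with additive Gaussian Ct noise.

Real data violate all of this in known ways: per-gene (not global)
dispersion, correlated genes, batch and depth artifacts, tumors that
deviate from exponential growth at large volumes, asymmetric caliper
axes. Passing the recovery tests therefore demonstrates correctness of
the estimators under their stated model, not robustness to model
misspecification.

## Numerical choices and degenerate inputs

- All simulation functions take explicit integer seeds and restore the
  caller's RNG state; identical spec + seed gives bitwise-identical
  output, which the pipeline turns into byte-identical files (verified by
  rerunning into a second directory).
- Expression files round-trip exactly: values are serialized at `%.17g`.
  Result tables are serialized at 6 significant digits in both TSV and
  JSON so the two formats agree.
- Readers reject rather than impute: missing values, non-numeric cells
  (reported with row/column coordinates), duplicate identifiers and
  fractional "raw" counts are all hard errors.
- Null-effect settings are legal in the generators (`up_effect = 1`,
  `drug_effect = 1`, `growth_rate = 0`) because null calibration tests
  need them; parameters that would invert the design (`drug_effect > 1`)
  are errors.
- Validation problem sizes were chosen to keep the full suite fast while
  leaving no statistical ambiguity: 2000-gene null/power simulations,
  exhaustive mHG enumeration to $N = 9$ (1004 configurations), 1000
  ANOVA null studies, 100-replicate Ct recoveries.

## Limitations

- The caller's ssGSEA threshold is cohort-relative by default; calls are
  therefore *not* comparable across cohorts unless an absolute threshold
  is supplied. This mirrors how such callers are used in practice
  (within-study) but is a real constraint.
- The packaged 21-gene up-set is a reconstruction from named targets plus
  canonical pathway members, not a published list; treat it as a default,
  not a reference standard.
- The DE stage is a filtering tool, not a full DE framework: no shrinkage,
  no multi-factor designs, no batch terms.
- Efficacy models are per-animal regressions + ANOVA; mixed-effects
  longitudinal models and survival endpoints are out of scope.
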