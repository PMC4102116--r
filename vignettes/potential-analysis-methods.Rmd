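---
title: "Detecting bistable taxa by potential analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bistable taxa by potential analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bistab)
```

## The problem and the model

Cross-sectional surveys of the human gut microbiota show that most
genus-level groups vary smoothly across people, but a handful are either
abundant or nearly absent in most individuals, with few subjects in
between.  `bistab` treats each such taxon as a candidate *tipping
element*: a one-dimensional stochastic system

$$dz = -U'(z)\,dt + \sigma\,dW,$$

where $z$ is the log10 abundance signal, $U$ a potential function and
$\sigma$ the noise level.  At stationarity the Fokker–Planck equation
links the density of $z$ to the potential, $p(z) \propto
\exp(-2U(z)/\sigma^2)$, so an empirical density estimate can be inverted
to a noise-scaled pseudo-potential

$$U(z)/\sigma^2 = -\tfrac{1}{2}\log p(z).$$

Minima of $U$ are (candidate) stable states; a local maximum between two
minima is the *tipping point*, the unstable abundance value across which
small fluctuations can trigger a self-propagating shift to the other
state.  Bistability makes two testable predictions beyond marginal
bimodality: abundances near the tipping point should be less stable over
time than abundances inside either state, and states should persist over
follow-up on the timescale set by the barrier.

## Pipeline overview

`tipping_analysis()` is the central fit.  Per taxon:

1. **Prevalence rule.**  A taxon is *rare* unless its log10 signal
   exceeds 3.0 in more than 20% of subjects.  Rare taxa are not scored
   for bimodality: a detection-floor spike plus a thin tail mimics
   extra modes that carry no ecological meaning.
2. **Potential analysis.**  Gaussian KDE with bandwidth
   $h = 0.8 \times 1.06\,s\,n^{-1/5}$ (Scott's rule, n−1 denominator,
   sharpened by the 0.8 factor for mode sensitivity), evaluated on a
   200-point grid spanning the data range ±3h; density floor $10^{-12}$
   before the log; discrete extrema by sign changes of first
   differences, plateaus resolved to their midpoint.
3. **Extrema filtering.**  A mode is kept only if (i) its contrast
   against the closest antimode exceeds 0.005 *on the density normalized
   to unit sum over the grid*, and (ii) its raw peak density is at least
   0.1.  Failing modes are merged iteratively, shallowest first, the
   minimum deleted together with the lower of its adjacent maxima so
   extrema stay interleaved; the last mode is never pruned.
4. **Bootstrap support.**  The mode count is recomputed in 100 bootstrap
   resamples; the support is the fraction of replicates deviating from
   unimodality (counts above 2 also count, matching the evidence
   notion of "deviation from unimodality").  A taxon is called bimodal
   at support ≥ 0.90.
5. **Tipping point.**  Per multimodal replicate, the highest retained
   maximum between the two deepest minima; the final estimate is the
   mean over those replicates.  States: `high` iff the value strictly
   exceeds the tipping point (ties are `low`; the choice is arbitrary
   but fixed and tested).
6. **Prediction strength.**  As an independent check, the
   Tibshirani–Walther index with M = 20 random half-splits, PAM with
   Euclidean distance, test points classified to the nearest training
   medoid; values above 0.9 are strong and above 0.8 moderate evidence
   for two clusters.

### Why the 0.005 threshold lives on the normalized-density scale

The contrast rule is stated in the literature together with a minimum
density of 0.1, but a contrast of 0.005 measured directly on the scaled
potential admits ordinary KDE sampling wiggles (a relative density
fluctuation of only 1%), which would declare most smooth unimodal
samples multimodal.  Measured on the density normalized to unit sum
over the evaluation grid — the convention of the standard potential-
analysis tooling, whose default grid is about a fifth of the sample
size, hence our 200-point default at cohort sizes near 1,000 — the same
number separates genuine secondary modes from noise cleanly: with these
defaults a well-separated mixture reaches support 1.0 while
N(3, 0.5) at n = 1,000 scores support ≈ 0.  The normalized scale also
makes the rule invariant under affine rescaling of the abundance axis;
the 0.1 minimum density is kept on the raw scale (per log10 unit) and is
therefore the one unit-bearing threshold.  Both are exposed as
arguments.

## The synthetic cohort

The generator fixes the study conditions for every test: 130 taxa ×
1,000 subjects, comprising 70 rare, 34 symmetric, 10 left-skewed, 10
right-skewed and 6 bimodal taxa (60 prevalent overall).  Symmetric taxa
are normal in log10 space (means 3.3–5.0, sd 0.4–0.7); skewed taxa are
skew-normal with shape ±8 (|skewness| ≈ 0.93, safely beyond the ±0.5
class boundary); rare taxa are a detection-floor bump (≈1.8–2.0, sd
0.15) plus a thin exponential tail; bimodal taxa are two-component
normal mixtures with wells ≈2 log10 units apart, sds 0.3–0.35 and
component weights 0.35–0.5.  The planted tipping point of a mixture
taxon is the antimode of its generative density, found numerically.
Every taxon draws from a counter-derived substream of the global seed,
so adding taxa never perturbs existing ones.

Longitudinal cohorts integrate the Langevin model by Euler–Maruyama
with a fixed step (default dt = 0.01 months) and an explicit stability
bound (`dt ≤ 1/max|U''|`; larger steps error).  The default bistable
taxon uses wells at log10 signals 2 and 4, barrier height 1 and σ =
0.4: within-well fluctuations are small (sd ≈ 0.1) and spontaneous
barrier crossings essentially absent on follow-up timescales, so state
shifts are driven by transitional subjects.  35% of baselines are drawn
uniformly between the wells; the remainder sit in a well.  The
transitional fraction is the one deliberately elevated ingredient: the
follow-up cohorts this emulates come largely from intervention trials,
which over-represent perturbed, between-state individuals, and the
resulting cohorts reproduce instability correlations (mean Spearman ρ ≈
−0.3) and 3-month state survival (≈0.95) of the magnitude reported for
real bistable taxa.  With `barrier_height = 0` the generator degenerates
to a wide harmonic basin whose relaxation time far exceeds the follow-up
window — near-neutral diffusion, the matched no-structure control.

What this generator does *not* attempt to reproduce:
real HITChip-style signals have taxon-specific detection floors,
heavy-tailed within-state variation, inter-taxon correlation and
extraction-method batch structure.  Passing the recovery tests therefore
demonstrates that the machinery identifies what was planted under the
model's assumptions, not that every real cohort statistic would be
reproduced.

## Temporal stability

`intermediate_stability()` implements the consecutive-pair statistic as
primary: the reference is the 50% quantile of baseline abundances (the
baseline population is configurable); for each within-subject pair of
consecutive visits, the distance of the earlier value from the reference
is Spearman-correlated with the absolute shift to the next visit, with a
one-sided (AS89) p-value for negative correlation.  A documented
`method = "baseline"` variant correlates baseline distance with
deviation from baseline at later visits, matching descriptions phrased
in terms of deviations from baseline; both are reported by the pipeline.

`km_state_survival()` gives each subject one spell starting at baseline;
the event is the first visit in the opposite state, placed at the
midpoint of the bracketing interval (configurable to the right
endpoint), censoring at the last visit otherwise; the product-limit
estimate (via the survival package) is read off at 3 months.
`simulated_state_null()` compares a bimodal taxon's survival with
unimodal taxa given pseudo-tipping points at the same population
quantile, and `bimodality_stability_enrichment()` tests the overlap of
"bimodal" and "unstable" (ρ < −0.3) taxa with an upper-tail
hypergeometric probability.

## Community level and host associations

States of the bimodal groups are cross-tabulated into a combination
census (2^G possible combinations).  The covariation screen flags a
(bimodal group, taxon) pair only when |r| > 0.25 with two-sided p <
0.05 in *both* DNA-extraction subsets and in ≥95% of 100 bootstrap
resamples of the full cohort; both inequalities are strict, and the 95%
resample rule makes the informal "consistently observed in 100
bootstrap data sets" criterion explicit (the knob is exposed).  PCA is
computed on taxa-centered (not standardized) log10 signals, the common
choice for log-scale array data; leading score vectors are passed
through the same bootstrap bimodality machinery.  Community clustering
uses PAM over the Jensen–Shannon dissimilarity (natural log, 0·log 0 =
0) with prediction strength per candidate k.  Diversity is Shannon
entropy (natural log) on relative abundances — the index is a documented
stand-in, since "overall community diversity" names no specific index —
where relative abundance is the per-sample fraction of total linear
signal.

Host-factor models are binomial GLMs (IRLS) predicting the state from
age, BMI, sex, region and extraction method on complete cases, each
predictor tested by the likelihood-ratio χ² between nested fits,
BH-corrected; FDR < 5% is labelled significant and < 20% a trend
(reporting sugar only).  Reference levels are the most frequent
category.  Perfect separation is detected and reported rather than
silently penalized.  Disease models add the taxon's log10 abundance to
the confounders and report the LRT for the abundance term plus
stratified 5-fold cross-validated ROC AUC with and without it.

## Numerical choices and edge cases

* Constant input, fewer than 10 observations, or all-tied shifts raise
  errors rather than returning degenerate statistics; a fully tied
  diversity vector yields p = 1 by convention in the rank-sum test, as
  does a paired test with all-zero differences.
* Benjamini–Hochberg adjustment is the standard step-up (`p.adjust`).
  It is monotone in p-rank and never anti-conservative, but it is *not*
  an idempotent map — BH(0.1, 0.9) = (0.2, 0.9) while BH(0.2, 0.9) =
  (0.4, 0.9) — so re-adjusting adjusted values can only move them
  upward; the tests assert exactly that.
* The Euler–Maruyama stationary check compares a 10^5-step trajectory
  with exp(−2U/σ²)/Z by Kolmogorov–Smirnov distance.  With the
  fast-mixing check configuration (barrier 0.2, σ = 1.5, dt = 0.03) the
  distance is typically ≈0.012; occasional seeds exceed 0.02 because
  autocorrelation leaves only a few thousand effective samples, which is
  the expected magnitude, not a defect.
* Problem sizes in the tests — 130 × 1,000 cross-sections, 80-subject
  follow-up cohorts over 20 seeds, 100 bootstrap replicates — are the
  package's chosen validation scale: large enough that every planted
  signal is comfortably detectable, small enough to re-run routinely.

## Known limitations

One-dimensional potential analysis sees marginal densities only: a
bimodal marginal can arise from population structure as well as from
bistable dynamics, which is exactly why the temporal-stability and
enrichment statistics exist.  The prediction strength index is weakly
discriminative in one dimension (smooth unimodal samples score ≈0.8;
only values near 1 are informative), so it is treated as supporting
evidence, never as the detector.  Probe-level preprocessing,
phylogenetically informed ordination (UniFrac-style) and
compositional count noise are out of scope; inputs are taken as
genus-level summarized log10 signals.
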