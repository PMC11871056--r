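---
title: "Methods: trait matching, pollen transfer and landscape scaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait matching, pollen transfer and landscape scaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenscape)
```

## The scientific problem

When a nectar-feeding bird probes a tubular flower, the fit between its bill
and the corolla determines where the anthers and stigma touch its body, how
much pollen it picks up and deposits, and possibly how quickly it can drain
the nectar. `pollenscape` implements a complete analysis chain for
experiments of this kind, built around a three-species honeyeater system
feeding at the emu bush *Eremophila maculata*:

1. quantify bill–corolla **trait matching** as ratios of linear
   morphometrics, reduced to multivariate matching scores by PCA;
2. convert **high-speed-video measurements** into per-visit pollen-transfer
   and feeding-efficiency metrics;
3. fit **generalized linear mixed models** relating those metrics to species
   identity and to matching scores;
4. **scale up** experimentally measured per-flower deposition to plant-visit
   and landscape totals by resampling deposition values onto camera-trap
   visitation records.

A synthetic-data generator reproduces the statistical structure the analysis
assumes, so every stage is testable without access to the original field
data.

## Trait matching

Each matching metric is a bird measurement divided by a floral measurement
(e.g. bill length / total corolla length). A ratio of 1 means the two
structures are the same size; there is no expectation that 1 is "best",
because matching is an emergent property of the interaction. Donor flowers
(anthers intact) contribute anther-distance ratios (BL/ACO, BL/AN); receiver
flowers (emasculated, stigma only) contribute stigma-distance ratios
(BL/SCO, BL/SN); both share BL/TCL, BL/ECL and BW/CW, and tarsus length
enters as a body-size covariate. Two separate PCAs are run, one per flower
role, on the role's six variables.

`run_pca()` works on the correlation matrix (centre, then scale by the
sample SD), so results are invariant to affine rescaling of any column —
this matters because ratios and tarsus live on different scales. PCA signs
are arbitrary; we fix each component so its largest-magnitude loading is
positive. Downstream models use `abs_scores()` — the absolute value of the
scores — so modelling results are independent of this convention, but
deterministic signs keep plots and tests stable. A score of 0 is the closest
multivariate match; larger magnitudes mean a bill larger *or* smaller than
the flower.

Two analysis choices were genuinely open. Tarsus enters the PCA raw (then
standardized) rather than as a ratio, because it accounts for body size
rather than measuring fit to any floral structure. And the PCA pools all
bird-by-flower interactions (one row per trial visit) rather than averaging
per bird, since each trial presents a different flower with its own
morphometrics.

## Transfer and feeding metrics

Videos are filmed at 800 frames/s; `frames_to_seconds()` divides frame
counts by the rate. Pollen patches are digitized as polygons on scaled
images; `polygon_area()` applies the shoelace formula in pixel coordinates
and divides by the squared pixels-per-mm scale. The area is
orientation-independent and invariant under translation and rotation;
degenerate outlines (< 3 vertices) are area 0, and a self-intersecting
outline triggers a warning and returns the magnitude of the signed area.
Feeding efficiency is the standardized nectar volume (30 µL of 27 % sucrose
in every trial) divided by the feeding-bout duration, and licking rate is
the lick count over the same bout.

The feeding bout used for the trial-level duration defaults to the
receiver-flower visit (`feeding_from = "receiver"`); the donor bout and the
pooled mean are available, and the trait-matching feeding model always uses
both visits, each paired with its own flower's matching scores. Anther
contact is the total of all contact frames in the visit, summed over
discrete contacts. Per-species summaries report SE over trials (the
trial-level replication shown in per-trial plots); per-bird aggregation is
available via `by_bird = TRUE`.

## The mixed models

All models use a log link and are fitted by maximum likelihood with the
random effects integrated out by the Laplace approximation (via
`glmmTMB`). Family choice follows the response type:

* **stigma pollen counts** — negative binomial NB2 (variance
  $\mu + \mu^2/\theta$), for overdispersed counts;
* **anther-contact duration, patch area** — Tweedie compound Poisson–gamma
  with power in (1, 2), for non-negative continuous data with exact zeros,
  plus a per-species zero-inflation component where structural zeros (visits
  with no anther contact at all) exceed what the family absorbs;
* **feeding duration and efficiency** — Gamma, for strictly positive data.

The five species models use a random bird intercept; the three matching
models use bird nested within species. With only three species the
species-level variance is weakly identified; it is retained for fidelity to
the nested design, and fits that end on a variance boundary are flagged
(`convergence = FALSE`) rather than hidden. The |PC| predictors enter raw
(unstandardized), so coefficients read "per unit of PC score".

Inference mirrors standard practice: `type3_test()` gives type-III Wald
chi-square tests (each term tested with all others present; sum-to-zero
contrasts where an interaction is involved), `pairwise_contrasts()` gives
Tukey-adjusted pairwise comparisons of estimated marginal means with
Cohen's d computed on the raw response (pooled SD, $n-1$ weights), and
`r2_nakagawa()` gives trigamma-method marginal and conditional R²:

$$R^2_m = \frac{\sigma^2_f}{\sigma^2_f + \sigma^2_r + \sigma^2_d}, \qquad
  R^2_c = \frac{\sigma^2_f + \sigma^2_r}{\sigma^2_f + \sigma^2_r + \sigma^2_d},$$

with $\sigma^2_f$ the variance of the fixed-effect linear predictor,
$\sigma^2_r$ the summed random-intercept variances, and $\sigma^2_d$ the
observation-level variance on the latent log scale:
$\psi_1\!\big((1/\bar\mu + 1/\theta)^{-1}\big)$ for NB2 and
$\psi_1(\text{shape})$ for Gamma, where $\psi_1$ is the trigamma function.
The Tweedie has no trigamma form; we use the lognormal approximation
$\ln\!\big(1 + \phi\,\bar\mu^{\,p-2}\big)$ with $\bar\mu$ the mean
conditional fitted value — a documented approximation, adequate because the
Tweedie models here are compared on relative, not absolute, R².

Because each bird feeds at five flowers in sequence, pollen could accumulate
across trials. `trial_effect_check()` runs the type-III ANOVA of deposition
on trial number, species and their interaction first; if neither trial term
is significant (the expected outcome under the generator's defaults), trial
number is omitted from all further models.

## Landscape scaling

The estimator propagates per-flower experimental deposition through field
visitation. For each of $R$ runs (default 100), every camera-trap visit is
assigned a deposition value drawn uniformly **with replacement** from the
experimental pool of the visiting species — pools are never mixed across
species, and measured zeros stay in the pool (removing them would bias
totals upward). The visit's plant-level deposition is the assigned value
times the flowers probed; per species and run, the mean over visits is the
per-plant deposition and the sum is the landscape total. Draws are
independent across visits and runs, with no stratification by site.

Under this scheme the moments are available in closed form
(`closed_form_expectation()`): with $m$ and $v$ the pool's mean and
*population* variance and $f_i$ the flowers probed,

$$E[\text{mean/plant}] = m \bar f, \quad
  E[\text{landscape}] = m \textstyle\sum_i f_i, \quad
  \operatorname{Var}[\text{landscape}] = v \textstyle\sum_i f_i^2 .$$

These exact moments are the test oracle for the sampler: enumeration over
all pool-to-visit assignments on tiny instances, Monte-Carlo convergence at
$R = 10^4$, and cross-seed stability are all checked against them.

One ambiguity in the estimator's definition is whether a value is drawn per
visit or per probed flower within a visit. Per-visit assignment is the
primary implementation (the simplest reading of assigning a value to an
observation); `per_flower = TRUE` draws independently for each probed
flower, which leaves expectations unchanged but shrinks run-to-run variance.

`compare_species()` runs the type-III ANOVA across species with Tukey
contrasts and Cohen's d, treating permutation runs as i.i.d. observations —
the same convention as the source analysis. Note this understates
uncertainty: the runs all resample the same finite experimental pools, so
"significance" here describes the permutation distributions, not new
biological replication. For flowers probed per visit, the raw camera-trap
records are the observations instead.

## The synthetic-data generator

The generator's defaults are the study conditions: three species with 3, 8
and 9 individuals, five two-part trials each (100 trials, 200 flower
visits), camera-trap visit totals 1258 (*A. rufogularis*), 146
(*Pu. albifrons*) and 1495 (*Pi. ornata*), and flowers probed per visit
averaging 5.6, 5.2 and 5.4. Per-flower deposition means (4.6, 47 and 22.6
grains, NB dispersions 0.6–0.9) are anchored so that pool mean × flowers
probed reproduces the study-scale per-plant ordering: the white-fronted
honeyeater deposits most per flower but is seen least; the yellow-plumed
honeyeater deposits moderately but dominates visitation; the spiny-cheeked
honeyeater — whose bill is larger than the flower in every dimension —
deposits least. This is the structure that produces the characteristic
cross-scale rank reversal (top per-plant species ≠ top landscape species).

Where the study reports no value, parameters were chosen once on field
realism: morphometric means and SDs typical of the three species (with the
large species' bill, ~28.5 mm, exceeding the ~24 mm corolla and the small
species' ~16.5 mm bill well inside it); corolla width 4.5 mm so width
matching is near 1 for the two small-billed species and above 1 for the
large one; Gamma feeding bouts of ~1.5 s (large species) vs ~3 s (small
species), matching the observed efficiency ordering; licking rates 6.5 vs
10 licks/s; anther-contact structural-zero probabilities 0.25/0.10/0.10
shared between contact duration and patch area (a missed contact zeroes
both, which is why the patch polygon is empty exactly when the area is
zero).

Morphometrics are multivariate normal (the minimal assumption given
means ± SD), truncated at a 0.1 mm floor; flowers probed are
$1 + \text{Poisson}(\bar f - 1)$ since a visit probes at least one flower;
per-bird log-normal random intercepts (SD 0.5 for deposition and patch
area, 0.25 for contact and feeding durations, each mean-corrected so
marginal means equal the configured values) make the conditional R² of the
mixed models meaningful. A single root seed fans out to per-stage child
seeds through a fixed hash, so changing one stage's scale never perturbs
another stage's draws.

What the generator does **not** emulate: correlation between patch area and
subsequent deposition (the coupling the real study detected — synthetic
runs therefore centre that coefficient on zero), pollen carryover between
successive trials, site-level structure in visitation, and any
within-flower wilting or nectar dynamics. Passing tests demonstrate that
the pipeline recovers what the generator encodes at the study's scale; they
do not demonstrate those extra features of real data.

## Numerical choices and problem sizes

* Optimization: glmmTMB defaults (Laplace approximation, nlminb); fits
  reaching a variance or zero-inflation boundary report
  `convergence = FALSE` and a warning, never silence.
* PCA reconstruction and orthonormality are asserted to 1e-8, variance
  fractions to 1e-10; polygon invariances to 1e-9 relative.
* Test problem sizes, chosen to make sampling error negligible relative to
  the asserted tolerances: moment checks at n = 50 000 draws; the
  Monte-Carlo polygon oracle at 10⁶ points (0.5 % tolerance); permutation
  Monte-Carlo at R = 10⁴ against exact moments; GLMM coverage at ten times
  the study design over 200 replicates per family; test size of the
  type-III Wald test over 1000 null replicates; cross-scale rank reversal
  over 200 replicates with R = 20 runs each (the ranking uses the mean over
  runs, so more runs add nothing to a rank check).

## Known limitations

* The species-level random variance in the nested models is weakly
  identified with three species; interpret its estimate qualitatively.
* The Tweedie R² rests on a lognormal approximation of the latent-scale
  variance.
* Treating permutation runs as independent observations (inherited from the
  source analysis) makes cross-species p-values on permutation outputs
  optimistic.
* Zero-inflated Tweedie models can place structural zeros in either the
  zero-inflation component or the family's own point mass when event rates
  are low; the split is only well identified when conditional zeros are
  rare.
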