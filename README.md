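# pollenscape

Trait matching, pollen transfer and landscape-scale pollination in
nectar-feeding birds.

## What this package is for

In bird-pollination systems, the morphological fit between a bird's bill and
a flower's corolla ("trait matching") is expected to shape how much pollen a
visit transfers and how efficiently the bird extracts nectar — and
per-flower differences between bird species need not survive the jump to
landscape scale, because species also differ enormously in how often they
visit plants. `pollenscape` implements the full analysis chain for
experiments that test these ideas, built around a three-honeyeater /
*Eremophila maculata* (emu bush) study system:

* **Trait matching** — bill–corolla ratios (BL/TCL, BL/ECL, BW/CW, and
  anther- or stigma-distance ratios depending on flower role, plus tarsus as
  a body-size covariate), reduced by correlation-matrix PCA to matching
  scores; the absolute score |PC| measures mismatch (0 = closest match).
* **Transfer and feeding metrics** — frame counts to seconds at 800 fps,
  shoelace areas of digitized pollen-patch polygons (px → mm²), feeding
  efficiency as 30 µL / bout duration, licking rate as licks/s.
* **Mixed models** — log-link GLMMs with the family matched to the response
  (NB2 for stigma pollen counts, zero-inflated Tweedie for contact duration
  and patch area, Gamma for feeding duration/efficiency), random bird (or
  bird-within-species) intercepts, type-III Wald tests, Tukey-adjusted
  pairwise contrasts with Cohen's d, and trigamma-method marginal /
  conditional R²:
  R²m = σ²f / (σ²f + σ²r + σ²d), R²c = (σ²f + σ²r) / (σ²f + σ²r + σ²d),
  with σ²d = ψ₁((1/μ̄ + 1/θ)⁻¹) for NB2 and ψ₁(shape) for Gamma.
* **Landscape scaling** — the permutation estimator: per run, each
  camera-trap visit is assigned a deposition value drawn with replacement
  from the visiting species' experimental pool; value × flowers probed gives
  the plant-visit deposition, averaged (per-plant) or summed (landscape
  total) per species; exact closed-form moments of the estimator are
  provided for verification.

A synthetic-data generator (`simulate_dataset()`) reproduces the study's
statistical structure — 3 species × 3/8/9 birds × 5 two-part trials,
overdispersed deposition counts, zero-inflated patch areas, Gamma feeding
bouts, and 1258/146/1495 camera-trap visits — so the whole pipeline runs and
is tested end to end without any field data.

## Worked example

```r
library(pollenscape)

d  <- simulate_dataset(seed = 42)                    # study-shaped synthetic data
an <- assemble_analysis(d$trials, d$birds, d$flowers)

an$donor_pca
#> Matching-ratio PCA: 6 variables, 100 observations
#> Variance explained (%): 78.5, 8.4, 5.8, 3.6, 2.1, 1.6
```

Most matching variation sits on PC1 (length matching plus body size); the
species are separated along it, with the spiny-cheeked honeyeater (bill
larger than the flower in every dimension) at one extreme.

```r
f <- fit_glmm(standard_model_specs()$dep_species, an$trial_data)
type3_test(f, "species")
#> [1] 5.60711e-07
pairwise_contrasts(f)
#>                                            pair estimate_link p_adjusted cohens_d
#>     Acanthagenys rufogularis - Ptilotula ornata        -2.028   9.32e-05   -0.576
#>   Acanthagenys rufogularis - Purnella albifrons        -2.651   2.43e-07   -1.000
#>           Ptilotula ornata - Purnella albifrons        -0.622   1.54e-01   -0.423
r2_nakagawa(f)
#> marginal R2 = 0.2512, conditional R2 = 0.3245
```

Species differ strongly in stigma pollen deposition: the link-scale contrast
of −2.65 says the spiny-cheeked honeyeater deposits exp(−2.65) ≈ 7 % as many
grains per flower as the white-fronted honeyeater, and the two small-billed
species are not distinguishable from each other.

```r
runs <- run_permutations(d$visits, deposition_pools(d$trials), R = 100, seed = 42)
summarize_permutations(runs)
#>                    species   R n_visits mean_per_plant se_mean_per_plant landscape_total se_landscape_total
#> 1 Acanthagenys rufogularis 100     1258          24.26             0.086           30513              108.1
#> 2         Ptilotula ornata 100     1495         162.96             0.746          243622             1115.1
#> 3       Purnella albifrons 100      146         279.59             2.913           40821              425.2
```

The cross-scale reversal: the white-fronted honeyeater deposits the most
pollen per plant visit (280 grains), but at landscape scale the
yellow-plumed honeyeater dominates (≈244 000 grains) because it accounts
for over half of all recorded visits.

`run_pipeline(pipeline_config(seed = 1))` chains every stage (simulation →
matching → metrics → trial-order pre-check → the eight standard models →
landscape scaling) and writes provenance-stamped CSVs plus a JSON run
manifest. Column definitions and units are in
`inst/extdata/data_dictionary.csv`; a YAML config file can override any
study condition via `read_config()`.

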