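---
title: "Methods: quantifying mulch-film biodegradation and its microbial drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying mulch-film biodegradation and its microbial drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mulchdeg)
```

## The measurement chain

Biodegradable poly(butylene succinate-co-adipate) (PBSA) mulch films buried
in soil are degraded mainly by extracellular esterases of soil fungi. The
package implements the full quantitative chain used to study this process in
cultivated soils:

1. **Film degradation from scans.** A residual black film piece is scanned
   (300 dpi, 8-bit gray, black = 0). The mean gray value of a 300 × 300 px
   region of interest containing the film is converted to a degradation
   ratio by linear interpolation between two calibration grays:
   $$\mathrm{ratio}\,(\%) = 100\,
     \frac{g_\mathrm{residual}-g_\mathrm{fresh}}
          {g_\mathrm{background}-g_\mathrm{fresh}}.$$
   The ratio is 0 % for an intact film and 100 % when only background
   remains. It is *never clamped*: small negative values are ordinary
   measurement noise on intact films and carry information about the noise
   floor.
2. **Viable counts.** Dilution-plate colony counts become CFU per gram of
   *dry* soil (colonies / plated volume × dilution × suspension volume /
   dry mass). Clear-zone-forming colonies on emulsified-polymer plates
   define the *isolation rate* of degraders, 100 × clearing / total.
3. **Esterase activity.** p-nitrophenyl valerate hydrolysis read at 405 nm,
   blank- and background-subtracted, converted to nmol g⁻¹ dry soil min⁻¹
   through the assay volumes, soil mass and incubation time. Replicates are
   summarized by geometric means.
4. **Statistics.** Spearman rank correlation (exact permutation p for
   n ≤ 9), Kolmogorov–Smirnov/Lilliefors normality checks, exact two-sided
   Mann–Whitney U, and step-down Williams' and Shirley–Williams' trend
   tests at one-tailed α = 0.025 for monotone change along the weekly time
   axis.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| ROI size | 300 | px | the analysis window of the scanning protocol at 300 dpi (1 inch square) |
| ROI placement | dark-pixel centroid | — | deterministic, robust to the film drifting on the scanner bed; explicit override available |
| dark threshold | midpoint of calibration grays | gray | only used to find the film for ROI centring, never in the ratio itself |
| rate definition | `endpoint` | %/week | week-3 ratio ÷ 3 carries the stated per-week units; `mean3` and `ols0` are exposed and logged |
| suspension | 1 g wet soil in 10 ml | — | standard plating metadata; required input, not assumed |
| water content | water mass / wet mass | fraction | 105 °C overnight convention, so dry mass = wet × (1 − wc) |
| assay volumes | 0.6 ml reaction, 75 µl aliquot, 330 µl read | ml | the published protocol's values |
| calibration slope | 0.0561 | A/nmol | fitted from a pNP standard series; pNP absorptivity is pH- and volume-dependent, so no constant is hard-coded. The packaged series is synthetic (filename says so) and corresponds to ε ≈ 1.85 × 10⁴ M⁻¹ cm⁻¹ in the 330 µl read volume |
| α (trend tests) | 0.025 | one-tailed | the conventional level for these step-down procedures |
| trend direction | increase | — | degrader counts and activities are tested for increase from the week-0 control |

### Rate definitions and their ambiguity

"Average degradation during the first 3 weeks (ratio/week)" admits several
readings. `endpoint` (week-3 ratio ÷ 3) and `ols0` (through-origin
least-squares slope on weeks 0–3) are slope-like and agree exactly on data
linear through the origin. `mean3` is the literal arithmetic mean of the
week-1..3 ratios; on linear data it equals the week-2 value (twice the
slope), so it is *not* a slope estimate, but it is the literal reading of
the phrase and is kept for comparability. All three are computed by
`reproduce_paper()`; the downstream Spearman correlation moves by less than
0.08 among them, which is why the ambiguity is tolerable.

### Isolation-rate basis

`load_fixtures()` recomputes every clearing percentage from its CFU columns
and flags rows where the printed percentage disagrees by more than one
point. In the packaged tables exactly one row (fungal YM2: printed 51.3 vs
recomputed 5.1) is flagged. The cross-soil correlation defaults to the
printed percentages — the published scatter evidently used them — while the
CFU-derived variant is always reported alongside. The cross-soil *range*
summaries use the CFU-derived rates, which are internally consistent.

## Williams' and Shirley–Williams' tests

At stage $k$ the amalgamated (isotonic) mean of the ordered groups still in
play is compared with the control:
$$\bar t_k = \frac{\hat M_k - \bar x_0}
 {\sqrt{s^2\,(1/n_k + 1/n_0)}},$$
where $\hat M_k$ comes from weighted pool-adjacent-violators (PAVA)
amalgamation and $s^2$ is the pooled within-group variance over all groups.
Testing steps down from the highest group and stops at the first
non-rejection, so rejections always form a contiguous suffix of the
ordering — this contract is asserted on every run. The rank analog re-ranks
the remaining observations at each stage (mid-ranks for ties), amalgamates
the dose-group mean ranks, and uses the variance of the ranks in play
(N(N+1)/12 untied, automatically tie-corrected otherwise).

Two design choices were genuinely open:

* **Step-down form.** At stage $k$ the amalgamation uses only the control
  and groups 1..k ("drop the top group and repeat"), the same construction
  Shirley's rank version requires. This keeps every stage's statistic
  distributionally identical to the top-stage statistic of a smaller
  design, which is exactly what the reference values are computed for.
* **Reference values.** Published critical-value tables for $\bar t$ are
  replaced by seeded Monte-Carlo null quantiles (50,000 replicates, cached
  per design, deterministic and independent of the caller's RNG stream).
  Only group means and a pooled variance enter the parametric statistic, so
  the null can be simulated directly from those sufficient statistics and
  fully vectorized; the rank null is simulated from continuous data, for
  which the rank statistic is distribution-free. The machinery is
  cross-checked two ways: the single-dose design reduces analytically to a
  one-sided Student t (returned exactly via `qt`), and the null rejection
  rate of the full step-down pipeline is verified at 0.025 ± 0.006 over
  10,000 simulated null datasets in the test suite. Transcribing published
  tables was rejected because their values could not be independently
  verified here; an unverifiable constant is a worse foundation than a
  reproducible simulation.

Degenerate inputs are decided without the variance machinery: all-constant
groups reject nothing (parametric path compares exact means; rank path sees
zero rank variance).

## Exact small-sample statistics

* **Spearman.** Mid-ranks throughout; ρ is the Pearson correlation of the
  rank vectors. For n ≤ 9 the two-sided p enumerates all n! permutations
  (vectorized as one matrix product), reproducing the classical exact null
  to machine precision on tie-free data and remaining valid under ties,
  where the classical tables do not apply. For larger n the
  t-approximation is used; its deviation from the exact p is below ~0.02 by
  the n = 9/10 crossover but can reach ~0.08 at n = 5, which is why the
  exact path is the default there.
* **Mann–Whitney U.** For n₁+n₂ ≤ 14 the exact two-sided p enumerates all
  $\binom{n_1+n_2}{n_1}$ labelings with mid-ranks inside the enumeration,
  defining the two-sided p as the null probability of a U at least as far
  from n₁n₂/2 as observed. Larger designs use the normal approximation
  with tie and continuity corrections.
* **KS normality.** The statistic is the direct ECDF scan against a normal
  with estimated moments. Because moments are estimated, the default p is
  Lilliefors-corrected; the anticonservative plain-KS p stays available by
  flag, and both are labeled in the result.

## What the synthetic generators emulate — and what they do not

The generators exist so that every pipeline stage has a parameter-recovery
test with known ground truth; their defaults are the study conditions.

* **Film scans** (`simulate_film_image`): black film filling the frame,
  random disk holes plus thin tears, background showing through, Gaussian
  scanner noise (SD 2 gray levels). The degraded-area fraction is adjusted
  to the target *exactly* (to one pixel) both inside the central 300 px
  control window and outside it; without that, hole-placement clustering
  alone makes the ROI fraction fluctuate by several points around the
  global target, conflating generator variance with pipeline error. For
  fractions above ½ the complement is generated (islands of remaining
  film) and inverted, since random shapes cannot tile a frame. Real scans
  additionally show partial transparency gradients, soil staining and
  non-uniform illumination, none of which are modeled — recovery tests
  therefore bound segmentation-free gray-value arithmetic, not scanner
  artefact handling.
* **Plate counts** (`simulate_plates`): Poisson colonies with binomial
  clear-zone thinning — the minimal model consistent with dilution plating.
  Overcrowding, colony merging and counting error are not modeled.
* **Time courses** (`simulate_timecourse`): logistic degrader growth
  against buried film (default 1.2 week⁻¹ toward 10× baseline, matching
  an order-of-magnitude rise over 4 weeks), stationary baseline without
  film; esterase activity = baseline + increment × excess degrader density,
  inverted through the assay equation into absorbances with multiplicative
  lognormal noise (sdlog 0.1); film degradation accumulating with
  integrated degrader exposure, near-linear over weeks 0–3. Baseline
  activity 60 nmol g⁻¹ min⁻¹ sits centrally in the observed cross-soil span
  (roughly 20–160).
* **Multi-soil surveys** (`simulate_multisoil`): a Gaussian copula couples
  isolation rate and degradation rate. The latent correlation is
  calibrated so the *expected sample Spearman at the simulated n* equals
  the target, by inverting
  $E[r_s] = \frac{6}{\pi(n+1)}\left[(n-2)\sin^{-1}(r/2)+\sin^{-1} r\right]$;
  the usual large-n mapping $2\sin(\pi\rho/6)$ undershoots noticeably at
  n = 11 (expected sample ρ ≈ 0.585 for a 0.63 target).

Every generator is byte-reproducible from its seed and emits its ground
truth alongside the data.

## Numerical choices and degenerate inputs

* Ratios, corrected absorbances and activities pass through negative values
  unclamped; only logarithmic summaries (geometric means, log10 counts)
  exclude non-positives, each exclusion warned and counted.
* PAVA is the classical block-merging sweep; it preserves the weighted
  grand mean to 1e-9 and is tested against an exhaustive monotone-partition
  search.
* Zero plated-volume, dry mass or denominator gray contrast are errors;
  zero total CFU makes the isolation rate missing rather than zero.
* A 16-bit or RGB scan is rescaled/averaged to one 0–255 channel before any
  arithmetic (unweighted channel mean by default — carbon-black film scans
  are near-achromatic — with luminance weights available).
* Noisy-recovery checks are formulated as bias checks over replicate
  simulated assays: a one-standard-error band on a single seeded experiment
  would fail about a third of the time by construction, independent of
  correctness.

## Problem sizes used in the checks

The test suite simulates 10,000 null datasets (4 groups + control, n = 6)
for the Williams calibration, 50,000-replicate reference-value estimates,
20 film scans per degraded fraction at 420² px, 2,000 eleven-soil survey
replicates per correlation target, and 100 small-sample Mann–Whitney
designs against full enumeration. The acceptance script uses 5,000 null
datasets and 500 survey replicates per target. These sizes put Monte-Carlo
error well inside each check's tolerance (e.g. ±0.005 on a 0.025 rejection
rate at 10,000 replicates).

## Known limitations

* The gray-value ratio measures opacity loss; films that thin without
  perforating degrade optically less than gravimetrically, and colored or
  translucent films violate the black-on-light contrast assumption.
* The esterase conversion is only as good as the user's calibration slope;
  the packaged standard series is synthetic and meant to document the
  expected shape, not to calibrate a real spectrophotometer.
* Reference values for the trend tests are simulation-based; with the
  default 50,000 replicates the quantile error is ≈0.01 in $\bar t$, far
  below the spacing of decisions at realistic effect sizes, but exact-table
  reproducibility to the third decimal is not a goal.
* The copula generator controls the rank dependence of two marginals only;
  it does not model the mechanistic coupling (shared degrader populations)
  that presumably generates the field correlation.
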