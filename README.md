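# mulchdeg

Biodegradable poly(butylene succinate-co-adipate) (PBSA) mulch films break
down in farmland soil at wildly different speeds, and the difference is
driven by the soil's native population of polyester-degrading fungi and the
esterases they secrete. `mulchdeg` is the quantitative toolkit for studying
that link: it turns film scans, dilution-plate counts and chromogenic
esterase assays into comparable numbers, and supplies the ordered-trend
statistics needed to test whether degrader populations and enzyme
activities rise while a buried film disappears.

For soil microbiologists, polymer scientists and agronomists running burial
assays, the package covers:

* **Image-based film quantification** — the degradation ratio
  `100 (g_residual − g_fresh) / (g_background − g_fresh)` from mean gray
  values of a 300 × 300 px region of interest, with deterministic
  centroid-based ROI placement and no clamping (negative ratios are data);
  weekly series summarized into a degradation rate (%/week) under three
  selectable definitions.
* **Viable counts** — CFU per gram of dry soil from plate counts with full
  plating metadata, clear-zone isolation rates of polymer degraders, and
  cross-soil range summaries.
* **Esterase activities** — p-nitrophenyl valerate absorbances,
  blank/background-corrected and converted to nmol g⁻¹ dry soil min⁻¹
  through the assay volumes, mass, time and a fitted calibration slope;
  geometric-mean summaries.
* **Trend statistics** — weighted PAVA isotonic amalgamation; step-down
  Williams' and Shirley–Williams' tests (one-tailed α = 0.025) with
  seeded Monte-Carlo reference values; Spearman correlation with exact
  permutation p for n ≤ 9; exact Mann–Whitney U; KS/Lilliefors normality.
* **Synthetic data with ground truth** — film scans with known degraded
  fraction, Poisson plate counts, logistic burial time courses, and
  multi-soil surveys whose Spearman correlation is controlled by a
  calibrated Gaussian copula — so every stage has a parameter-recovery
  test.
* **Packaged study tables** — an 11-soil field dataset (soil properties,
  weekly degradation ratios, viable counts) and `reproduce_paper()`, which
  recomputes its headline aggregations and correlations.

## Worked example

Recompute the field study's headline numbers from the packaged tables:

```r
library(mulchdeg)
reproduce_paper()
```

```
Fungal viable-count ranges across soils:
             column          min min_soil          max max_soil n_missing
          cfu_total 28800.000000      MIY 210000.00000      MJO         0
       cfu_clearing  2630.000000      HIO  81200.00000      MJO         0
 isolation_rate_cfu     4.102964      HIO     42.15686      OKA         0

Week-4 degradation ratio: max 95.9% (OKA), min 1.4% (TKB)

Spearman correlation, isolation rate vs degradation rate:
 rate_method isolation_basis       rho    p_value  n default
    endpoint         printed 0.6514823 0.02988378 11    TRUE
       mean3         printed 0.7243755 0.01169657 11    TRUE
        ols0         printed 0.6970405 0.01713303 11    TRUE
    endpoint             cfu 0.4909091 0.12520441 11   FALSE
       mean3             cfu 0.3909091 0.23454007 11   FALSE
        ols0             cfu 0.4545455 0.16014544 11   FALSE

Internally inconsistent count rows (printed vs CFU-derived %):
 soil_id medium clearing_percent_printed clearing_percent_cfu
     YM2 fungal                     51.3             5.124555
```

Reading this: fungal populations span 2.88 × 10⁴ – 2.10 × 10⁵ CFU g⁻¹ dry
soil, degraders make up 4.1 – 42.2 % of them, and soils with a higher
degrader isolation rate degrade film faster (ρ ≈ 0.65–0.72, p < 0.05,
robust to the rate definition). One table row (YM2) carries a printed
percentage inconsistent with its own CFU columns; the loader flags it
rather than choosing silently.

Trend testing on a simulated burial time course (strong degrader growth,
six replicate plates per week):

```r
spec <- soil_sim_spec(growth_rate = 1.2, count_replicates = 6L, seed = 101L)
tc   <- simulate_timecourse(spec)
cw   <- tc$counts[tc$counts$treatment == "with_film", ]
cfu  <- cfu_per_g_dry(cw$colonies_total, cw$dilution_factor,
                      cw$volume_plated_ml, cw$wet_mass_g,
                      cw$suspension_volume_ml, cw$water_content_fraction)
lg   <- split(log10_transform(cfu, offset = 1), cw$week)
williams_test(ordered_groups(lg[["0"]], lg[c("1", "2", "3", "4")]))
```

```
Williams test (step-down, one-tailed alpha = 0.025, direction = increase)
 group statistic reference reject
     4  4.168345  2.171489   TRUE
     3  3.874465  2.190552   TRUE
     2  3.498756  2.191762   TRUE
     1  3.357808  2.228139   TRUE
```

Every week's log₁₀ degrader count has risen significantly above the week-0
control; with `growth_rate = 0` the same pipeline rejects nothing.

The numbered scripts under `analysis/` run the full workflow (table
aggregations, correlations, image-recovery sweep, simulated trend tests)
and write their tables under `results/`.

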