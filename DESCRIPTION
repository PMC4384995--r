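Package: mulchdeg
Title: Quantifying Biodegradable Mulch Film Breakdown and the Soil Microbes Behind It
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking soil microbial properties to the
    breakdown of biodegradable polyester (PBSA) mulch films buried in
    cultivated soils. Computes image-based film degradation ratios from
    mean gray values against fresh-film and background calibrations,
    converts dilution-plate colony counts into CFU per gram of dry soil
    and clear-zone (polymer-degrader) isolation rates, converts
    p-nitrophenyl ester absorbance readings into soil esterase activities,
    and provides the ordered-trend statistics used to analyse such data:
    step-down Williams' and Shirley-Williams' tests on an ordered time
    axis, weighted pool-adjacent-violators isotonic amalgamation, Spearman
    rank correlation with mid-rank ties, exact Mann-Whitney U, and
    Kolmogorov-Smirnov/Lilliefors normality checks. A synthetic-data
    module generates film scans, plate counts and absorbance series with
    known ground truth so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    tiff,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
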