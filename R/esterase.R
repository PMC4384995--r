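#' Configuration of the p-nitrophenyl ester hydrolysis assay
#'
#' Defaults follow the protocol: 100 mg moist soil shaken with pNP-valerate in
#' 0.6 ml buffer for 30 min at 30 degC; a 75 ul aliquot of supernatant is
#' mixed with 200 ul ethanol and 55 ul 2 M Tris (330 ul measured mixture) and
#' read at 405 nm. The protocol fixes volumes, mass and time but no molar
#' conversion, so `calibration_slope` (absorbance units per nmol pNP in the
#' measured mixture) must come from a pNP standard series run under the same
#' conditions; pNP absorptivity is pH- and volume-dependent, which is why no
#' constant is hard-coded. The packaged standard series
#' (`extdata/pnp_calibration_synthetic.csv`, a synthetic fixture) yields the
#' default 0.0561 A/nmol, i.e. an effective molar absorptivity of
#' 1.85e4 M^-1 cm^-1 in 330 ul.
#'
#' @param reaction_volume_ml Reaction volume, ml.
#' @param aliquot_volume_ml Supernatant aliquot taken into the stop mix, ml.
#' @param stop_mix_volume_ml Final measured-mixture volume, ml.
#' @param incubation_min Incubation time, minutes.
#' @param soil_wet_mass_g Moist soil mass per tube, g.
#' @param water_content_fraction Water mass / wet mass of the soil.
#' @param calibration_slope Absorbance (405 nm) per nmol pNP in the measured
#'   mixture.
#' @return An object of class `assay_config`.
#' @export
assay_config <- function(reaction_volume_ml = 0.6,
                         aliquot_volume_ml = 0.075,
                         stop_mix_volume_ml = 0.075 + 0.200 + 0.055,
                         incubation_min = 30,
                         soil_wet_mass_g = 0.100,
                         water_content_fraction = 0,
                         calibration_slope = 0.0561) {
  stopifnot(reaction_volume_ml > 0, aliquot_volume_ml > 0,
            aliquot_volume_ml <= reaction_volume_ml,
            stop_mix_volume_ml > 0, incubation_min > 0,
            soil_wet_mass_g > 0,
            water_content_fraction >= 0, water_content_fraction < 1,
            calibration_slope > 0)
  structure(list(reaction_volume_ml = reaction_volume_ml,
                 aliquot_volume_ml = aliquot_volume_ml,
                 stop_mix_volume_ml = stop_mix_volume_ml,
                 incubation_min = incubation_min,
                 soil_wet_mass_g = soil_wet_mass_g,
                 water_content_fraction = water_content_fraction,
                 calibration_slope = calibration_slope),
            class = "assay_config")
}

#' Blank- and background-corrected absorbance
#'
#' Subtracts from the sample reading both the substrate-in-buffer blank
#' (spontaneous hydrolysis) and the soil-extract background (soil colour).
#' Results at or below zero are passed through but flagged, since they carry
#' no activity information and are excluded from geometric means downstream.
#'
#' @param a_sample A405 of the reaction supernatant mixture.
#' @param a_blank A405 of substrate in buffer without soil.
#' @param a_background A405 of the soil-extract mixture without substrate.
#' @return List with `a_corr` and logical `flagged` (TRUE when `a_corr <= 0`).
#' @export
corrected_absorbance <- function(a_sample, a_blank, a_background) {
  lo <- -0.05; hi <- 4.0
  vals <- c(a_sample, a_blank, a_background)
  if (any(vals < lo | vals > hi)) {
    warning("absorbance outside plausible range [-0.05, 4.0]")
  }
  a <- a_sample - a_blank - a_background
  list(a_corr = a, flagged = a <= 0)
}

#' Esterase activity from corrected absorbance
#'
#' Reconstructs nmol of p-nitrophenol released per gram of dry soil per
#' minute from the stated volumes, mass and time:
#' nmol in the measured mixture = `a_corr / calibration_slope`; scaled to the
#' whole reaction by `reaction_volume / aliquot_volume`; divided by the dry
#' soil mass and the incubation time. The dry-mass basis matches the CFU
#' basis and soil-enzymology convention.
#'
#' @param a_corr Corrected absorbance (see [corrected_absorbance()]).
#' @param cfg An [assay_config()].
#' @return Activity in nmol per g dry soil per minute (negative if `a_corr`
#'   is negative; see [geometric_mean_activity()] for summarization policy).
#' @export
activity_from_absorbance <- function(a_corr, cfg) {
  stopifnot(inherits(cfg, "assay_config"))
  dry_mass <- cfg$soil_wet_mass_g * (1 - cfg$water_content_fraction)
  if (dry_mass <= 0) stop("dry soil mass must be > 0", call. = FALSE)
  nmol_mixture <- a_corr / cfg$calibration_slope
  nmol_reaction <- nmol_mixture * cfg$reaction_volume_ml / cfg$aliquot_volume_ml
  nmol_reaction / dry_mass / cfg$incubation_min
}

#' Geometric mean of replicate activities
#'
#' Replicate assays are summarized by the geometric mean, exp(mean(log v)).
#' Non-positive replicates (from negative corrected absorbances) have no
#' logarithm and are excluded with a warning; a warning is also raised when
#' fewer than three replicates remain, since summaries are conventionally
#' based on at least three independent assays.
#'
#' @param values Numeric vector of replicate activities.
#' @param min_n Replicate count below which a warning is raised.
#' @return List with `gmean`, `n_used`, `n_excluded`.
#' @export
geometric_mean_activity <- function(values, min_n = 3L) {
  bad <- is.na(values) | values <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive/missing value(s) excluded from geometric mean")
  }
  v <- values[!bad]
  if (length(v) == 0L) {
    return(list(gmean = NA_real_, n_used = 0L, n_excluded = sum(bad)))
  }
  if (length(v) < min_n) {
    warning("geometric mean based on fewer than ", min_n, " replicates")
  }
  list(gmean = exp(mean(log(v))), n_used = length(v), n_excluded = sum(bad))
}

#' Fit the calibration slope from a pNP standard series
#'
#' Ordinary least squares through the origin of absorbance on nmol pNP in the
#' measured mixture (a blank-corrected standard curve passes through zero).
#'
#' @param nmol_pnp nmol of p-nitrophenol per standard.
#' @param a405 Measured absorbance per standard.
#' @return Slope in absorbance units per nmol.
#' @export
fit_calibration_slope <- function(nmol_pnp, a405) {
  stopifnot(length(nmol_pnp) == length(a405), length(nmol_pnp) >= 2L,
            all(nmol_pnp >= 0))
  sum(nmol_pnp * a405) / sum(nmol_pnp^2)
}

#' Process an absorbance table into activities
#'
#' Applies blank/background correction and the absorbance-to-activity
#' conversion row-wise, then summarizes replicates per soil x week x
#' treatment by geometric mean.
#'
#' @param readings Data frame with columns `soil_id`, `timepoint_week`,
#'   `treatment`, `replicate`, `a_sample`, `a_blank`, `a_background`.
#' @param cfg An [assay_config()] (one configuration for the whole table).
#' @return List with `per_replicate` (input plus `a_corr`, `flagged`,
#'   `activity`) and `summary` (one row per soil x week x treatment with
#'   `gmean_activity`, `n_used`, `n_excluded`).
#' @export
esterase_activities <- function(readings, cfg = assay_config()) {
  need <- c("soil_id", "timepoint_week", "treatment", "replicate",
            "a_sample", "a_blank", "a_background")
  missing <- setdiff(need, names(readings))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  cc <- corrected_absorbance(readings$a_sample, readings$a_blank,
                             readings$a_background)
  per <- readings
  per$a_corr <- cc$a_corr
  per$flagged <- cc$flagged
  per$activity <- activity_from_absorbance(per$a_corr, cfg)
  grp <- interaction(per$soil_id, per$timepoint_week, per$treatment,
                     drop = TRUE)
  summ <- do.call(rbind, lapply(split(per, grp), function(d) {
    g <- suppressWarnings(geometric_mean_activity(d$activity))
    data.frame(soil_id = d$soil_id[1L], timepoint_week = d$timepoint_week[1L],
               treatment = d$treatment[1L], gmean_activity = g$gmean,
               n_used = g$n_used, n_excluded = g$n_excluded)
  }))
  rownames(summ) <- NULL
  list(per_replicate = per, summary = summ)
}
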