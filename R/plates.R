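#' Viable count per gram of dry soil from a dilution plate
#'
#' Converts a colony count into CFU per gram of dry soil:
#' colonies / volume plated x dilution factor x suspension volume /
#' (wet mass x (1 - water content)). Water content is water mass per wet soil
#' mass (105 degC overnight drying), the standard soil-science basis, so the
#' dry mass suspended is `wet_mass_g * (1 - water_content_fraction)`.
#'
#' @param colonies Non-negative colony count on the plate.
#' @param dilution_factor Fold dilution of the original suspension at plating
#'   (>= 1; 1 = undiluted).
#' @param volume_plated_ml Volume spread per plate, in ml (> 0).
#' @param wet_mass_g Wet soil mass suspended, in g (> 0).
#' @param suspension_volume_ml Total suspension volume, in ml.
#' @param water_content_fraction Water mass / wet mass, in \[0, 1).
#' @return CFU per gram of dry soil.
#' @export
cfu_per_g_dry <- function(colonies, dilution_factor, volume_plated_ml,
                          wet_mass_g = 1, suspension_volume_ml = 10,
                          water_content_fraction = 0) {
  if (any(colonies < 0)) stop("colony counts must be >= 0", call. = FALSE)
  if (any(dilution_factor < 1)) stop("dilution_factor must be >= 1", call. = FALSE)
  if (any(volume_plated_ml <= 0)) stop("volume_plated_ml must be > 0", call. = FALSE)
  if (any(wet_mass_g <= 0)) stop("wet_mass_g must be > 0", call. = FALSE)
  if (any(water_content_fraction < 0 | water_content_fraction >= 1)) {
    stop("water_content_fraction must lie in [0, 1)", call. = FALSE)
  }
  colonies / volume_plated_ml * dilution_factor * suspension_volume_ml /
    (wet_mass_g * (1 - water_content_fraction))
}

#' Isolation rate of clear-zone-forming (polymer-degrading) colonies
#'
#' Percentage of the viable population that clears emulsified polymer,
#' 100 x clearing / total. Scale-invariant, so raw colony counts and CFU
#' densities give the same answer when both come from the same plate.
#'
#' @param clearing Clear-zone-positive count or CFU density.
#' @param total Total count or CFU density on the same basis.
#' @return Percent in \[0, 100\]; `NA` when `total` is 0.
#' @export
isolation_rate <- function(clearing, total) {
  if (any(clearing > total, na.rm = TRUE)) {
    stop("clearing count exceeds total count", call. = FALSE)
  }
  if (any(clearing < 0, na.rm = TRUE)) stop("counts must be >= 0", call. = FALSE)
  ifelse(is.na(total) | total == 0, NA_real_, 100 * clearing / total)
}

#' Column-wise range summary across soils
#'
#' Minimum and maximum (with the soil attaining each) for every numeric column
#' of a per-soil table, skipping missing entries, as used to report e.g. the
#' range of fungal populations across soils.
#'
#' @param table Data frame with a `soil_id` column and numeric columns.
#' @return Data frame with one row per numeric column: `column`, `min`,
#'   `min_soil`, `max`, `max_soil`, `n_missing`. All-missing columns report
#'   `NA` throughout.
#' @export
cross_soil_summary <- function(table) {
  stopifnot(is.data.frame(table), "soil_id" %in% names(table),
            nrow(table) >= 1L)
  num <- names(table)[vapply(table, is.numeric, logical(1L))]
  out <- lapply(num, function(cn) {
    v <- table[[cn]]
    ok <- !is.na(v)
    if (!any(ok)) {
      return(data.frame(column = cn, min = NA_real_, min_soil = NA_character_,
                        max = NA_real_, max_soil = NA_character_,
                        n_missing = sum(!ok)))
    }
    data.frame(column = cn,
               min = min(v[ok]), min_soil = table$soil_id[ok][which.min(v[ok])],
               max = max(v[ok]), max_soil = table$soil_id[ok][which.max(v[ok])],
               n_missing = sum(!ok))
  })
  do.call(rbind, out)
}

#' Base-10 logarithm of viable counts
#'
#' Viable counts are approximately lognormal, so they are normalized by
#' log10 before normality testing and parametric trend tests. Zeros are
#' excluded with a warning by default; supply a positive `offset` to use
#' log10(count + offset) instead.
#'
#' @param counts Vector of CFU densities (>= 0; negatives are an error).
#' @param offset Either `NULL` (drop zeros, warn) or a positive number added
#'   to every count before the log.
#' @return Numeric vector of base-10 logs (shorter than the input if zeros
#'   were dropped).
#' @export
log10_transform <- function(counts, offset = NULL) {
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be >= 0", call. = FALSE)
  if (!is.null(offset)) {
    stopifnot(offset > 0)
    return(log10(counts + offset))
  }
  zero <- !is.na(counts) & counts == 0
  if (any(zero)) {
    warning(sum(zero), " zero count(s) excluded from log transformation")
    counts <- counts[!zero]
  }
  log10(counts)
}

#' Build a per-soil viable-count table from plate observations
#'
#' Converts a long table of plate observations (one row per plate) into the
#' per-soil summary used for cross-soil analyses: total CFU/g dry, clear-zone
#' CFU/g dry and isolation rate per soil and medium. The isolation rate is
#' computed from the raw colony counts of each plate (the preferred path,
#' since both counts share all plating factors); `rate_basis` records this.
#'
#' @param obs Data frame with columns `soil_id`, `medium`, `dilution_factor`,
#'   `volume_plated_ml`, `colonies_total`, `colonies_clearing`, `wet_mass_g`,
#'   `suspension_volume_ml`, `water_content_fraction`. Replicate plates of the
#'   same soil x medium are averaged on the CFU scale.
#' @return Data frame with one row per soil x medium: `soil_id`, `medium`,
#'   `cfu_total_per_g_dry`, `cfu_clearing_per_g_dry`,
#'   `isolation_rate_percent`, `rate_basis`.
#' @export
viable_count_table <- function(obs) {
  need <- c("soil_id", "medium", "dilution_factor", "volume_plated_ml",
            "colonies_total", "colonies_clearing", "wet_mass_g",
            "suspension_volume_ml", "water_content_fraction")
  missing <- setdiff(need, names(obs))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(obs$colonies_clearing > obs$colonies_total, na.rm = TRUE)) {
    stop("colonies_clearing exceeds colonies_total", call. = FALSE)
  }
  grp <- interaction(obs$soil_id, obs$medium, drop = TRUE)
  rows <- lapply(split(obs, grp), function(d) {
    tot <- cfu_per_g_dry(d$colonies_total, d$dilution_factor,
                         d$volume_plated_ml, d$wet_mass_g,
                         d$suspension_volume_ml, d$water_content_fraction)
    clr <- cfu_per_g_dry(d$colonies_clearing, d$dilution_factor,
                         d$volume_plated_ml, d$wet_mass_g,
                         d$suspension_volume_ml, d$water_content_fraction)
    data.frame(soil_id = d$soil_id[1L], medium = d$medium[1L],
               cfu_total_per_g_dry = mean(tot),
               cfu_clearing_per_g_dry = mean(clr),
               isolation_rate_percent = isolation_rate(
                 sum(d$colonies_clearing), sum(d$colonies_total)),
               rate_basis = "raw_counts")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
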