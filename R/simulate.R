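#' Specification for a synthetic film scan
#'
#' Describes a scanned piece of black film whose degraded area (holes, tears,
#' thinned spots resolved as background showing through) covers a known
#' fraction of the image, plus Gaussian scanner noise. Defaults emulate a
#' 300-dpi scan of carbon-black film on a light scanner bed: film gray 20,
#' background gray 220, noise SD 2 gray levels.
#'
#' @param width,height Image size in pixels.
#' @param gray_film,gray_background Gray levels (0--255) of intact film and
#'   of the background visible through degraded area.
#' @param degraded_fraction Target hole-area fraction f in \[0, 1\].
#' @param hole_radius_range Radii (px) of the random disk holes.
#' @param tear_prob Probability that a placed hole is a thin rectangular tear
#'   instead of a disk.
#' @param control_window Side of the central square window (matching the
#'   analysis ROI) inside which the degraded-area fraction is adjusted to the
#'   target exactly; the complement is adjusted to the same fraction.
#' @param noise_sd SD of the additive Gaussian scanner noise (gray levels).
#' @param seed Integer RNG seed; every generator here is deterministic given
#'   its seed.
#' @return Object of class `film_sim_spec`.
#' @export
film_sim_spec <- function(width = 420L, height = 420L,
                          gray_film = 20, gray_background = 220,
                          degraded_fraction = 0.4,
                          hole_radius_range = c(3, 12),
                          tear_prob = 0.3, control_window = 300L,
                          noise_sd = 2, seed = 1L) {
  stopifnot(width >= 10L, height >= 10L,
            gray_film != gray_background,
            degraded_fraction >= 0, degraded_fraction <= 1,
            noise_sd >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 gray_film = gray_film, gray_background = gray_background,
                 degraded_fraction = degraded_fraction,
                 hole_radius_range = hole_radius_range,
                 tear_prob = tear_prob,
                 control_window = as.integer(control_window),
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "film_sim_spec")
}

#' Simulate a scanned film image with known degraded fraction
#'
#' Places random disk holes and thin rectangular tears on a film-filling
#' image until the degraded area reaches the target fraction, then adjusts
#' individual mask pixels so the hole-area fraction equals
#' `round(f * npixels) / npixels` exactly (one pixel-quantization unit).
#' Degraded pixels take the background gray, intact pixels the film gray;
#' Gaussian noise is added and clamped to \[0, 255\].
#'
#' @param spec A [film_sim_spec()].
#' @param id Label passed to the resulting [film_image()].
#' @return List with `image` (a [film_image()]), `mask` (logical matrix,
#'   TRUE = degraded) and `achieved_fraction`.
#' @export
simulate_film_image <- function(spec, id = "synthetic") {
  stopifnot(inherits(spec, "film_sim_spec"))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  npix <- h * w
  target <- round(spec$degraded_fraction * npix)
  # Random shapes cannot tile the image, so for fractions above 1/2 the
  # complement is generated instead (islands of remaining film on an
  # otherwise degraded piece) and inverted.
  invert <- target > npix / 2
  shape_target <- if (invert) npix - target else target
  mask <- matrix(FALSE, h, w)
  rr <- matrix(row(mask), h, w); cc <- matrix(col(mask), h, w)
  max_iter <- 10000L
  it <- 0L
  while (sum(mask) < shape_target) {
    it <- it + 1L
    if (it > max_iter) {
      stop("placement error: could not reach target degraded fraction in ",
           max_iter, " attempts", call. = FALSE)
    }
    cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
    if (stats::runif(1) < spec$tear_prob) {
      len <- stats::runif(1, 10, max(20, min(h, w) / 4))
      wid <- stats::runif(1, 1, 3)
      if (stats::runif(1) < 0.5) {
        hit <- abs(rr - cy) <= len / 2 & abs(cc - cx) <= wid / 2
      } else {
        hit <- abs(rr - cy) <= wid / 2 & abs(cc - cx) <= len / 2
      }
    } else {
      r <- stats::runif(1, spec$hole_radius_range[1L],
                        spec$hole_radius_range[2L])
      hit <- (rr - cy)^2 + (cc - cx)^2 <= r^2
    }
    mask <- mask | hit
  }
  excess <- sum(mask) - shape_target
  if (excess > 0L) { # trim random pixels back to the exact target
    on_idx <- which(mask)
    mask[sample(on_idx, excess)] <- FALSE
  }
  if (invert) mask <- !mask
  # Exact area-fraction control inside the central analysis window and in
  # its complement separately: the ROI of the downstream pipeline samples a
  # subregion, and without this the ROI hole fraction would fluctuate by
  # several points around f from hole-placement clustering alone. Single
  # flipped pixels read as pin-holes / thinned spots.
  win <- min(spec$control_window, h, w)
  r0 <- floor((h - win) / 2) + 1L; c0 <- floor((w - win) / 2) + 1L
  in_win <- rr >= r0 & rr < r0 + win & cc >= c0 & cc < c0 + win
  for (region in list(which(in_win), which(!in_win))) {
    if (length(region) == 0L) next
    tgt <- round(spec$degraded_fraction * length(region))
    cur <- sum(mask[region])
    if (cur > tgt) {
      mask[sample(region[mask[region]], cur - tgt)] <- FALSE
    } else if (cur < tgt) {
      mask[sample(region[!mask[region]], tgt - cur)] <- TRUE
    }
  }
  px <- ifelse(mask, spec$gray_background, spec$gray_film)
  if (spec$noise_sd > 0) {
    px <- px + stats::rnorm(npix, 0, spec$noise_sd)
  }
  px <- matrix(pmin(pmax(px, 0), 255), h, w)
  list(image = film_image(px, id = id),
       mask = mask,
       achieved_fraction = target / npix)
}

#' Simulate calibration scans (fresh film and background)
#'
#' @param spec A [film_sim_spec()]; `degraded_fraction` is ignored (0 for the
#'   fresh scan, 1 for the background scan).
#' @return List with [film_image()]s `fresh` and `background` and the
#'   corresponding [gray_calibration()] estimated from their mean grays.
#' @export
simulate_calibration_images <- function(spec) {
  stopifnot(inherits(spec, "film_sim_spec"))
  fresh_spec <- spec; fresh_spec$degraded_fraction <- 0
  bg_spec <- spec; bg_spec$degraded_fraction <- 1
  bg_spec$seed <- spec$seed + 1L
  fresh <- simulate_film_image(fresh_spec, id = "fresh")$image
  bg <- simulate_film_image(bg_spec, id = "background")$image
  list(fresh = fresh, background = bg,
       calibration = gray_calibration(mean(fresh$pixels), mean(bg$pixels)))
}

#' Specification of a simulated soil (or set of soils)
#'
#' Parameters emulating the structure of the study system: per-soil fungal
#' densities of order 1e4--1e5 CFU/g dry soil with degrader fractions of a
#' few to ~40 %, logistic degrader growth against buried film over 4 weeks,
#' and esterase activities of order 20--160 nmol/g/min tied to the degrader
#' population.
#'
#' @param n_soils Number of soils.
#' @param total_density_meanlog,total_density_sdlog Lognormal parameters of
#'   the per-soil total fungal density (CFU/g dry); defaults give a median
#'   near 7e4 spanning roughly 3e4--2e5.
#' @param degrader_fraction_range Range of the per-soil degrader fraction.
#' @param growth_rate Logistic growth rate (per week) of the degrader
#'   population against buried film; 0 means no film effect.
#' @param carrying_capacity_fold Carrying capacity as a multiple of the
#'   initial degrader density.
#' @param baseline_activity Basal esterase activity (nmol/g dry/min) at week
#'   0; the observed cross-soil span is roughly 20--160.
#' @param activity_per_degrader Activity increment per CFU/g of degraders
#'   grown beyond the baseline population.
#' @param absorbance_noise_sdlog SD (log scale) of the multiplicative
#'   lognormal noise on simulated absorbances.
#' @param count_replicates Plates per sampling (triplicate by convention).
#' @param target_rho Target Spearman correlation between isolation rate and
#'   degradation rate for [simulate_multisoil()].
#' @param seed Integer RNG seed.
#' @return Object of class `soil_sim_spec`.
#' @export
soil_sim_spec <- function(n_soils = 11L,
                          total_density_meanlog = log(7e4),
                          total_density_sdlog = 0.55,
                          degrader_fraction_range = c(0.04, 0.42),
                          growth_rate = 1.2,
                          carrying_capacity_fold = 10,
                          baseline_activity = 60,
                          activity_per_degrader = 5e-4,
                          absorbance_noise_sdlog = 0.1,
                          count_replicates = 3L,
                          target_rho = 0.63,
                          seed = 1L) {
  stopifnot(n_soils >= 1L, growth_rate >= 0, carrying_capacity_fold >= 1,
            baseline_activity > 0, target_rho >= -1, target_rho <= 1)
  structure(list(n_soils = as.integer(n_soils),
                 total_density_meanlog = total_density_meanlog,
                 total_density_sdlog = total_density_sdlog,
                 degrader_fraction_range = degrader_fraction_range,
                 growth_rate = growth_rate,
                 carrying_capacity_fold = carrying_capacity_fold,
                 baseline_activity = baseline_activity,
                 activity_per_degrader = activity_per_degrader,
                 absorbance_noise_sdlog = absorbance_noise_sdlog,
                 count_replicates = as.integer(count_replicates),
                 target_rho = target_rho,
                 seed = as.integer(seed)),
            class = "soil_sim_spec")
}

#' Simulate dilution plates for a known population density
#'
#' Colony counts are Poisson with mean equal to the expected CFU deposited
#' per plate (density x dry mass / suspension volume x plated volume /
#' dilution); clear-zone-positive colonies are binomial given the true
#' degrader fraction.
#'
#' @param true_density_per_g_dry True total density, CFU/g dry soil.
#' @param degrader_fraction True fraction of clear-zone formers.
#' @param dilutions Vector of fold dilutions plated.
#' @param n_plates Replicate plates per dilution.
#' @param volume_plated_ml,wet_mass_g,suspension_volume_ml,water_content_fraction
#'   Plating metadata (defaults: 0.1 ml of a 1 g / 10 ml suspension, water
#'   content 0.2).
#' @param medium Medium label carried into the table.
#' @param soil_id Soil label.
#' @param seed Integer RNG seed.
#' @return Data frame in the plate-observation schema consumed by
#'   [viable_count_table()].
#' @export
simulate_plates <- function(true_density_per_g_dry, degrader_fraction = 0.2,
                            dilutions = 1000, n_plates = 3L,
                            volume_plated_ml = 0.1, wet_mass_g = 1,
                            suspension_volume_ml = 10,
                            water_content_fraction = 0.2,
                            medium = "fungal", soil_id = "SIM",
                            seed = 1L) {
  stopifnot(true_density_per_g_dry >= 0, all(dilutions >= 1),
            degrader_fraction >= 0, degrader_fraction <= 1)
  set.seed(seed)
  dry_mass <- wet_mass_g * (1 - water_content_fraction)
  rows <- list()
  for (d in dilutions) {
    lambda <- true_density_per_g_dry * dry_mass / suspension_volume_ml *
      volume_plated_ml / d
    tot <- stats::rpois(n_plates, lambda)
    clr <- stats::rbinom(n_plates, tot, degrader_fraction)
    rows[[length(rows) + 1L]] <- data.frame(
      soil_id = soil_id, medium = medium, dilution_factor = d,
      volume_plated_ml = volume_plated_ml, colonies_total = tot,
      colonies_clearing = clr, wet_mass_g = wet_mass_g,
      suspension_volume_ml = suspension_volume_ml,
      water_content_fraction = water_content_fraction)
  }
  do.call(rbind, rows)
}

# Logistic growth from D0 toward K at rate r (per week).
.logistic <- function(D0, K, r, t) {
  K * D0 * exp(r * t) / (K + D0 * (exp(r * t) - 1))
}

#' Simulate a 4-week burial time course for one soil
#'
#' With buried film, the degrader population grows logistically from its
#' baseline; without film it stays at baseline. Weekly triplicate plate
#' counts are Poisson ([simulate_plates()]). Esterase activity is baseline +
#' increment x degrader density, converted to absorbance triples by
#' inverting the assay formula and degraded by multiplicative lognormal
#' noise. The weekly degradation ratio accumulates proportionally to the
#' integrated degrader activity, which is near-linear over weeks 0--3 for
#' moderate growth.
#'
#' @param spec A [soil_sim_spec()].
#' @param weeks Integer vector of sampling weeks (0 = pre-burial control).
#' @param cfg An [assay_config()] used to invert activities into
#'   absorbances.
#' @param soil_id Label.
#' @return List with `counts` (plate-observation schema plus `week` and
#'   `treatment`), `absorbances` (assay schema), `degradation` (week / true
#'   ratio), and `truth` (per-week true densities and activities).
#' @export
simulate_timecourse <- function(spec, weeks = 0:4, cfg = assay_config(),
                                soil_id = "SIM") {
  stopifnot(inherits(spec, "soil_sim_spec"))
  set.seed(spec$seed)
  D_total <- exp(spec$total_density_meanlog)
  frac0 <- mean(spec$degrader_fraction_range)
  D0 <- D_total * frac0
  K <- D0 * spec$carrying_capacity_fold
  D_film <- .logistic(D0, K, spec$growth_rate, weeks)
  D_nofilm <- rep(D0, length(weeks))

  counts <- list(); absorb <- list()
  act <- function(D) {
    spec$baseline_activity + spec$activity_per_degrader * (D - D0)
  }
  dry_mass <- cfg$soil_wet_mass_g * (1 - cfg$water_content_fraction)
  a_blank <- 0.05; a_background <- 0.10
  for (i in seq_along(weeks)) {
    for (trt in c("with_film", "without_film")) {
      D <- if (trt == "with_film") D_film[i] else D_nofilm[i]
      pl <- simulate_plates(D, degrader_fraction = 1,
                            dilutions = 100, n_plates = spec$count_replicates,
                            soil_id = soil_id,
                            seed = spec$seed + 37L * i +
                              (trt == "with_film") * 7919L)
      pl$week <- weeks[i]; pl$treatment <- trt
      counts[[length(counts) + 1L]] <- pl

      a_true <- act(D)
      a_corr <- a_true * dry_mass * cfg$incubation_min /
        (cfg$reaction_volume_ml / cfg$aliquot_volume_ml) *
        cfg$calibration_slope
      noise <- if (spec$absorbance_noise_sdlog > 0) {
        stats::rlnorm(spec$count_replicates, 0, spec$absorbance_noise_sdlog)
      } else {
        rep(1, spec$count_replicates)
      }
      absorb[[length(absorb) + 1L]] <- data.frame(
        soil_id = soil_id, timepoint_week = weeks[i], treatment = trt,
        replicate = seq_len(spec$count_replicates),
        a_sample = a_corr * noise + a_blank + a_background,
        a_blank = a_blank, a_background = a_background)
    }
  }
  # degradation ratio from cumulative degrader exposure, scaled so the
  # week-max ratio approaches but does not exceed 100
  expo <- cumsum(D_film) - D_film[1L]
  ratio <- if (max(expo) > 0) 100 * expo / (max(expo) * 1.05) else expo
  list(counts = do.call(rbind, counts),
       absorbances = do.call(rbind, absorb),
       degradation = data.frame(week = weeks, true_ratio = ratio),
       truth = data.frame(week = weeks, density_with_film = D_film,
                          density_without_film = D_nofilm,
                          activity_with_film = act(D_film),
                          activity_without_film = act(D_nofilm)))
}

# Latent Gaussian correlation giving expected *sample* Spearman rho at size n:
# E[r_s] = 6/(pi (n+1)) [ (n-2) asin(r/2) + asin(r) ]  (bivariate normal).
# Inverted so the generator hits the target on average at finite n.
.latent_r_for_spearman <- function(rho, n) {
  if (abs(rho) >= 1) return(sign(rho))
  if (rho == 0) return(0)
  f <- function(r) {
    6 / (pi * (n + 1)) * ((n - 2) * asin(r / 2) + asin(r)) - rho
  }
  stats::uniroot(f, c(-1, 1), tol = 1e-10)$root
}

#' Simulate a multi-soil survey with controlled rank correlation
#'
#' Draws per-soil isolation rates and film degradation rates from a Gaussian
#' copula whose latent correlation is calibrated so that the expected sample
#' Spearman correlation at the requested number of soils equals
#' `spec$target_rho` (the naive large-n mapping `2 sin(pi rho / 6)`
#' undershoots at small n). Marginals: isolation rate uniform on the spec's
#' degrader-fraction range (as percent); degradation rate lognormal spanning
#' roughly 0--20 %/week.
#'
#' @param spec A [soil_sim_spec()].
#' @return Data frame with `soil_id`, `isolation_rate_percent`,
#'   `degradation_rate_percent_per_week`, plus the latent uniforms
#'   `u_isolation`, `u_rate` for oracle checks.
#' @export
simulate_multisoil <- function(spec) {
  stopifnot(inherits(spec, "soil_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_soils
  if (n < 5L) warning("rank correlation targets are unreliable for n < 5")
  r <- .latent_r_for_spearman(spec$target_rho, n)
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  u1 <- stats::pnorm(z1); u2 <- stats::pnorm(z2)
  iso <- 100 * (spec$degrader_fraction_range[1L] +
                  diff(spec$degrader_fraction_range) * u1)
  rate <- stats::qlnorm(u2, meanlog = log(5), sdlog = 1)
  data.frame(soil_id = sprintf("S%02d", seq_len(n)),
             isolation_rate_percent = iso,
             degradation_rate_percent_per_week = rate,
             u_isolation = u1, u_rate = u2)
}
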