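#' Construct a film image object
#'
#' A `film_image` is a 2-D matrix of gray values on the 0--255 scale (black
#' film = 0, white background = 255) with a resolution and an identifying
#' label, as produced by scanning a residual film piece at typically 300 dpi.
#'
#' @param pixels Numeric matrix of gray values in \[0, 255\]. A 3-D array
#'   (RGB) is collapsed to one gray channel first, see `rgb_weights`.
#' @param dpi Scan resolution in dots per inch (metadata only).
#' @param id Label identifying soil/week/replicate.
#' @param rgb_weights Channel weights used to collapse an RGB array. The
#'   default is the unweighted channel mean, appropriate for near-achromatic
#'   scans of carbon-black film; pass `c(0.299, 0.587, 0.114)` for luminance
#'   weighting.
#' @return An object of class `film_image`.
#' @export
film_image <- function(pixels, dpi = 300, id = NA_character_,
                       rgb_weights = c(1, 1, 1) / 3) {
  if (is.array(pixels) && length(dim(pixels)) == 3L) {
    w <- rgb_weights / sum(rgb_weights)
    nch <- min(dim(pixels)[3L], 3L)
    gray <- matrix(0, nrow = dim(pixels)[1L], ncol = dim(pixels)[2L])
    for (ch in seq_len(nch)) gray <- gray + w[ch] * pixels[, , ch]
    pixels <- gray
  }
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    stop("'pixels' must be a non-empty matrix (or RGB array)", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("gray values must lie in [0, 255] and contain no NA", call. = FALSE)
  }
  structure(list(pixels = pixels, dpi = dpi, id = id), class = "film_image")
}

#' @export
print.film_image <- function(x, ...) {
  cat(sprintf("<film_image '%s': %d x %d px, %g dpi, gray %.1f-%.1f>\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$dpi,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a scanned film image from TIFF or PNG
#'
#' 8-bit and 16-bit grayscale or RGB images are accepted; values are rescaled
#' to the 0--255 gray scale used throughout (readers return \[0, 1\]).
#'
#' @inheritParams film_image
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return A [film_image()].
#' @export
read_film_image <- function(path, dpi = 300, id = basename(path),
                            rgb_weights = c(1, 1, 1) / 3) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(img)) == 3L && dim(img)[3L] == 4L) img <- img[, , 1:3] # drop alpha
  film_image(img * 255, dpi = dpi, id = id, rgb_weights = rgb_weights)
}

#' Write a film image to PNG or TIFF
#'
#' @param image A [film_image()].
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_film_image <- function(image, path) {
  stopifnot(inherits(image, "film_image"))
  norm <- image$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(norm, path),
    png = png::writePNG(norm, path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Gray-value calibration for the degradation-ratio equation
#'
#' Holds the two reference gray values of the equation: the mean gray of a
#' fresh (undegraded) film scan and the mean gray of the background scanned
#' without film.
#'
#' @param gray_fresh Mean gray value of the fresh film (0--255).
#' @param gray_background Mean gray value of the film-free background (0--255).
#' @return An object of class `gray_calibration`.
#' @export
gray_calibration <- function(gray_fresh, gray_background) {
  stopifnot(is.numeric(gray_fresh), is.numeric(gray_background),
            length(gray_fresh) == 1L, length(gray_background) == 1L)
  if (gray_fresh < 0 || gray_fresh > 255 ||
      gray_background < 0 || gray_background > 255) {
    stop("calibration gray values must lie in [0, 255]", call. = FALSE)
  }
  if (gray_background == gray_fresh) {
    stop("calibration error: background and fresh-film gray values are equal",
         call. = FALSE)
  }
  structure(list(gray_fresh = gray_fresh, gray_background = gray_background),
            class = "gray_calibration")
}

#' Locate the region of interest on a film scan
#'
#' The ROI is a square window (default 300 x 300 px at 300 dpi) that must
#' contain the residual film. By default it is centred on the centroid of
#' below-threshold (dark, i.e. film) pixels, which is deterministic and robust
#' to the film piece drifting on the scanner bed; explicit centre coordinates
#' override this. If no pixel falls below the threshold (a fully degraded
#' film), the image centre is used. The window is clipped to stay inside the
#' image.
#'
#' @param image A [film_image()].
#' @param roi_size Side length of the square ROI, in pixels.
#' @param threshold Gray value below which a pixel counts as film; the usual
#'   choice is the midpoint between the calibration grays.
#' @param center Optional `c(row, col)` centre overriding centroid detection.
#' @return Integer vector `c(row0, row1, col0, col1)` of the ROI bounds.
#' @export
locate_roi <- function(image, roi_size = 300L, threshold = 127.5,
                       center = NULL) {
  stopifnot(inherits(image, "film_image"))
  px <- image$pixels
  if (roi_size > nrow(px) || roi_size > ncol(px)) {
    stop("ROI (", roi_size, " px) larger than image (",
         nrow(px), " x ", ncol(px), ")", call. = FALSE)
  }
  if (is.null(center)) {
    dark <- which(px < threshold, arr.ind = TRUE)
    center <- if (nrow(dark) == 0L) {
      c((nrow(px) + 1) / 2, (ncol(px) + 1) / 2)
    } else {
      colMeans(dark)
    }
  }
  half <- (roi_size - 1) / 2
  r0 <- round(center[1L] - half)
  c0 <- round(center[2L] - half)
  r0 <- min(max(r0, 1L), nrow(px) - roi_size + 1L)
  c0 <- min(max(c0, 1L), ncol(px) - roi_size + 1L)
  as.integer(c(r0, r0 + roi_size - 1L, c0, c0 + roi_size - 1L))
}

#' Mean gray value over the region of interest
#'
#' Arithmetic mean of gray values over a square ROI containing the residual
#' film, the quantity entering the degradation-ratio equation.
#'
#' @inheritParams locate_roi
#' @return Mean gray value in \[0, 255\].
#' @export
mean_gray <- function(image, roi_size = 300L, threshold = 127.5,
                      center = NULL) {
  b <- locate_roi(image, roi_size = roi_size, threshold = threshold,
                  center = center)
  mean(image$pixels[b[1L]:b[2L], b[3L]:b[4L]])
}

#' Film degradation ratio from gray values
#'
#' The degradation ratio expresses the loss of film opacity as the position of
#' the residual-film mean gray between the fresh-film gray (0 %) and the
#' film-free background gray (100 %):
#' \deqn{100 (g_{res} - g_{fresh}) / (g_{bg} - g_{fresh}).}
#' Values below 0 or above 100 are legitimate data (measurement noise on
#' nearly intact films routinely produces small negatives) and are never
#' clamped.
#'
#' @param gray_residual Mean gray value of the ROI containing residual film.
#' @param cal A [gray_calibration()].
#' @return Degradation ratio in percent.
#' @export
degradation_ratio <- function(gray_residual, cal) {
  stopifnot(inherits(cal, "gray_calibration"))
  100 * (gray_residual - cal$gray_fresh) /
    (cal$gray_background - cal$gray_fresh)
}

#' Summarize replicate degradation ratios
#'
#' @param ratios Numeric vector of replicate ratios (percent), length >= 1.
#' @return List with `mean`, `se` (sample SD / sqrt(n), `NA` for n = 1) and
#'   `n`.
#' @export
summarize_replicates <- function(ratios) {
  if (length(ratios) == 0L || anyNA(ratios)) {
    stop("'ratios' must be a non-empty numeric vector without NA",
         call. = FALSE)
  }
  n <- length(ratios)
  list(mean = mean(ratios),
       se = if (n >= 2L) stats::sd(ratios) / sqrt(n) else NA_real_,
       n = n)
}

#' Degradation rate over the first three weeks
#'
#' Summarizes a weekly degradation-ratio series into a single speed in percent
#' per week over weeks 1--3, the near-linear phase. Three definitions are
#' available:
#' \describe{
#'   \item{`endpoint`}{week-3 mean ratio divided by 3 (default; carries the
#'     per-week units directly).}
#'   \item{`mean3`}{arithmetic mean of the week-1..3 ratios.}
#'   \item{`ols0`}{least-squares slope through the origin on weeks 0--3, with
#'     the week-0 ratio fixed at 0.}
#' }
#' All three coincide on data that is exactly linear through the origin;
#' rank-based downstream statistics are largely insensitive to the choice.
#'
#' @param weekly Data frame with columns `week` and `mean` (percent) covering
#'   at least weeks 1, 2 and 3.
#' @param method One of `"endpoint"`, `"mean3"`, `"ols0"`.
#' @return List with `rate` (percent/week) and `method`.
#' @export
degradation_rate <- function(weekly, method = c("endpoint", "mean3", "ols0")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(weekly), all(c("week", "mean") %in% names(weekly)))
  y <- weekly$mean[match(1:3, weekly$week)]
  if (anyNA(y)) stop("weeks 1-3 are required to compute a rate", call. = FALSE)
  rate <- switch(method,
    endpoint = y[3L] / 3,
    mean3 = mean(y),
    ols0 = sum((1:3) * y) / sum((1:3)^2)
  )
  list(rate = rate, method = method)
}

#' Quantify a set of replicate film scans into a degradation series
#'
#' Runs the full image pipeline (ROI location, mean gray, ratio) on replicate
#' scans per week and assembles the weekly summary plus derived rate.
#'
#' @param images Named list: for each week (names coercible to integer), a
#'   list of [film_image()] replicates.
#' @param cal A [gray_calibration()].
#' @param soil_id Label for the series.
#' @param roi_size,rate_method Passed to [mean_gray()] / [degradation_rate()].
#' @return List of class `degradation_series` with `soil_id`, `weekly`
#'   (data frame week/mean/se/n), `per_replicate` (data frame) and
#'   `rate_percent_per_week`.
#' @export
quantify_films <- function(images, cal, soil_id = NA_character_,
                           roi_size = 300L, rate_method = "endpoint") {
  stopifnot(inherits(cal, "gray_calibration"))
  thr <- (cal$gray_fresh + cal$gray_background) / 2
  rows <- list()
  for (wk in names(images)) {
    for (i in seq_along(images[[wk]])) {
      g <- mean_gray(images[[wk]][[i]], roi_size = roi_size, threshold = thr)
      rows[[length(rows) + 1L]] <- data.frame(
        soil_id = soil_id, week = as.integer(wk), replicate = i,
        gray_residual = g, ratio_percent = degradation_ratio(g, cal))
    }
  }
  per_rep <- do.call(rbind, rows)
  weekly <- do.call(rbind, lapply(split(per_rep, per_rep$week), function(d) {
    s <- summarize_replicates(d$ratio_percent)
    data.frame(week = d$week[1L], mean = s$mean, se = s$se, n = s$n)
  }))
  weekly <- weekly[order(weekly$week), , drop = FALSE]
  rownames(weekly) <- NULL
  rate <- if (all(1:3 %in% weekly$week)) {
    degradation_rate(weekly, rate_method)$rate
  } else {
    NA_real_
  }
  structure(list(soil_id = soil_id, weekly = weekly, per_replicate = per_rep,
                 rate_percent_per_week = rate, rate_method = rate_method),
            class = "degradation_series")
}
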