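#' Parse scientific notation in either typeset or E dialect
#'
#' Accepts plain numbers, `"6.28e4"`, and typeset forms like
#' `"2.10 x 10^5"` / `"2.10 × 10^5"` (optionally with trailing `^`).
#' `"NA"` and empty strings become missing.
#'
#' @param x Character (or numeric) vector.
#' @return Numeric vector; malformed entries raise an error naming them.
#' @export
parse_scientific <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    s <- x[i]
    if (is.na(s) || s == "" || toupper(s) == "NA") next
    m <- regmatches(s, regexec(
      "^([-+]?[0-9]*\\.?[0-9]+)\\s*[x×]\\s*10\\^?([-+]?[0-9]+)\\^?$", s))[[1L]]
    if (length(m) == 3L) {
      out[i] <- as.numeric(m[2L]) * 10^as.numeric(m[3L])
      next
    }
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) {
      stop("cannot parse numeric value '", s, "' (entry ", i, ")",
           call. = FALSE)
    }
    out[i] <- v
  }
  out
}

#' Load the packaged study tables
#'
#' Reads the three transcribed study tables shipped with the package: soil
#' properties (11 soils; type, texture, pH, total C/N, region), weekly film
#' degradation ratios (mean +/- SE of triplicates, weeks 1--4), and viable
#' counts per medium (total and clear-zone CFU/g dry soil plus the printed
#' clearing percentage). Missing entries stay `NA`. For every viable-count
#' row the clearing percentage is also recomputed from the CFU columns; rows
#' where the printed and recomputed values disagree by more than one
#' percentage point are flagged in `count_conflicts` (the fungal YM2 row is
#' the known internally inconsistent one: printed 51.3 vs 5.1 recomputed).
#'
#' @param path Directory containing the fixture CSVs; defaults to the
#'   package's `extdata`.
#' @return List of class `paper_fixtures` with data frames `soils`,
#'   `degradation`, `counts` and `count_conflicts`.
#' @export
load_fixtures <- function(path = system.file("extdata", package = "mulchdeg")) {
  soils <- utils::read.csv(file.path(path, "soil_properties.csv"))
  degr <- utils::read.csv(file.path(path, "degradation_ratios.csv"))
  counts <- utils::read.csv(file.path(path, "viable_counts.csv"),
                            colClasses = "character")
  counts$cfu_total <- parse_scientific(counts$cfu_total)
  counts$cfu_clearing <- parse_scientific(counts$cfu_clearing)
  counts$clearing_percent_printed <-
    parse_scientific(counts$clearing_percent_printed)

  n_soils <- length(unique(soils$soil_id))
  stopifnot(n_soils == 11L,
            setequal(unique(degr$soil_id), soils$soil_id),
            setequal(unique(counts$soil_id), soils$soil_id),
            all(1:4 %in% degr$week))

  counts$clearing_percent_cfu <- isolation_rate(counts$cfu_clearing,
                                                counts$cfu_total)
  disagree <- !is.na(counts$clearing_percent_printed) &
    !is.na(counts$clearing_percent_cfu) &
    abs(counts$clearing_percent_printed - counts$clearing_percent_cfu) > 1
  structure(list(soils = soils, degradation = degr, counts = counts,
                 count_conflicts = counts[disagree, , drop = FALSE]),
            class = "paper_fixtures")
}

#' Recompute the study's headline quantities from the packaged tables
#'
#' Chains the pipeline over the transcribed tables: per-soil degradation
#' rates from the weekly ratios (all three rate definitions), cross-soil
#' ranges of the fungal viable counts and CFU-derived isolation rates, the
#' week-4 degradation extremes, and the Spearman correlation between
#' isolation rate and degradation rate for every rate definition.
#'
#' The correlation uses the printed clearing percentages by default: the
#' published scatter evidently plotted the printed column, and the one
#' internally inconsistent row (fungal YM2) makes the CFU-derived variant
#' diverge. Both variants are reported.
#'
#' @param fixtures A [load_fixtures()] result.
#' @param isolation_basis `"printed"` or `"cfu"`; which clearing percentage
#'   enters the correlation by default.
#' @return List of class `paper_report` with elements `rates` (soil x
#'   method data frame), `fungal_ranges`, `week4`, `correlations` (one row
#'   per rate method x isolation basis), and `conflicts`.
#' @export
reproduce_paper <- function(fixtures = load_fixtures(),
                            isolation_basis = c("printed", "cfu")) {
  isolation_basis <- match.arg(isolation_basis)
  stopifnot(inherits(fixtures, "paper_fixtures"))
  methods <- c("endpoint", "mean3", "ols0")

  degr <- fixtures$degradation
  soils <- unique(degr$soil_id)
  rates <- data.frame(soil_id = soils)
  for (m in methods) {
    rates[[m]] <- vapply(soils, function(s) {
      degradation_rate(degr[degr$soil_id == s, , drop = FALSE], m)$rate
    }, numeric(1L))
  }

  fungal <- fixtures$counts[fixtures$counts$medium == "fungal", , drop = FALSE]
  fungal <- fungal[match(soils, fungal$soil_id), , drop = FALSE]
  ranges <- cross_soil_summary(data.frame(
    soil_id = fungal$soil_id,
    cfu_total = fungal$cfu_total,
    cfu_clearing = fungal$cfu_clearing,
    isolation_rate_cfu = fungal$clearing_percent_cfu))

  w4 <- degr[degr$week == 4, , drop = FALSE]
  week4 <- list(max = max(w4$mean), max_soil = w4$soil_id[which.max(w4$mean)],
                min = min(w4$mean), min_soil = w4$soil_id[which.min(w4$mean)])

  cors <- list()
  for (basis in c("printed", "cfu")) {
    iso <- if (basis == "printed") {
      fungal$clearing_percent_printed
    } else {
      fungal$clearing_percent_cfu
    }
    for (m in methods) {
      sp <- spearman(rates[[m]], iso)
      cors[[length(cors) + 1L]] <- data.frame(
        rate_method = m, isolation_basis = basis,
        rho = sp$rho, p_value = sp$p_value, n = sp$n,
        default = basis == isolation_basis)
    }
  }
  structure(list(rates = rates, fungal_ranges = ranges, week4 = week4,
                 correlations = do.call(rbind, cors),
                 conflicts = fixtures$count_conflicts),
            class = "paper_report")
}

#' @export
print.paper_report <- function(x, ...) {
  cat("Fungal viable-count ranges across soils:\n")
  print(x$fungal_ranges, row.names = FALSE)
  cat(sprintf("\nWeek-4 degradation ratio: max %.1f%% (%s), min %.1f%% (%s)\n",
              x$week4$max, x$week4$max_soil, x$week4$min, x$week4$min_soil))
  cat("\nSpearman correlation, isolation rate vs degradation rate:\n")
  print(x$correlations, row.names = FALSE)
  if (nrow(x$conflicts)) {
    cat("\nInternally inconsistent count rows (printed vs CFU-derived %):\n")
    print(x$conflicts[, c("soil_id", "medium", "clearing_percent_printed",
                          "clearing_percent_cfu")], row.names = FALSE)
  }
  invisible(x)
}
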