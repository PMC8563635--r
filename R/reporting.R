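#' WHO world standard population weights for the four age bands
#'
#' The WHO world standard population 2000-2025 is published as proportions
#' for eighteen 5-year age groups. Age standardisation here works at the
#' model's four-band resolution, so the published proportions are aggregated
#' once into the bands 0-14, 15-39, 40-64 and 65+ and normalised (the
#' published column itself sums to 100.03 because of rounding in the source).
#'
#' @param five_year Return the underlying 18-group table instead of the
#'   four-band weights.
#'
#' @return Named length-4 numeric summing to 1 (or the 5-year tibble).
#' @export
#' @examples
#' who_standard_weights()
who_standard_weights <- function(five_year = FALSE) {
  tbl <- tibble::tibble(
    age_group = c("0-4", "5-9", "10-14", "15-19", "20-24", "25-29", "30-34",
                  "35-39", "40-44", "45-49", "50-54", "55-59", "60-64",
                  "65-69", "70-74", "75-79", "80-84", "85+"),
    percent = c(8.86, 8.69, 8.60, 8.47, 8.22, 7.93, 7.61, 7.15, 6.59, 6.04,
                5.37, 4.55, 3.72, 2.96, 2.21, 1.52, 0.91, 0.63)
  )
  if (five_year) return(tbl)
  band <- rep(BAND_LABELS, times = c(3, 5, 5, 5))
  w <- tapply(tbl$percent, factor(band, levels = BAND_LABELS), sum)
  w <- as.numeric(w) / sum(tbl$percent)
  stats::setNames(w, BAND_LABELS)
}

#' Aggregate per-country estimates
#'
#' Component-wise sums of populations, incident and prevalent cases over the
#' member countries of each group. Crude prevalence (per 1000, total
#' prevalent over total population) and WHO-standardised prevalence (weighted
#' average of band-specific attained-age rates) are attached per group.
#'
#' @param est Per-country estimates from [estimate_burden()].
#' @param key `"world"`, `"income_group"` or `"region"`.
#' @param std Standard-population weights for standardisation.
#'
#' @return A tibble, one row per group, with summed band columns, totals,
#'   `crude_per1000` and `std_per1000`.
#' @export
aggregate_estimates <- function(est, key = c("world", "income_group", "region"),
                                std = who_standard_weights()) {
  key <- match.arg(key)
  if (nrow(est) == 0) stop("no countries to aggregate", call. = FALSE)
  grp <- switch(key,
    world = rep("World", nrow(est)),
    income_group = est$income_group,
    region = est$region
  )
  num_cols <- grep("^(pop|inc|prev)_", names(est), value = TRUE)
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(group = grp, est[num_cols]), group),
    dplyr::across(dplyr::everything(), sum), .groups = "drop"
  )
  lvls <- switch(key, world = "World", income_group = INCOME_GROUPS,
                 region = REGIONS)
  agg <- agg[order(match(agg$group, lvls)), ]

  att <- as.matrix(agg[paste0("prev_att_", c("0_14", "15_39", "40_64", "65p"))])
  pop <- as.matrix(agg[POP_COLUMNS])
  agg$crude_per1000 <- 1000 * agg$prev_total / agg$pop_total
  agg$std_per1000 <- as.numeric((1000 * att / pop) %*% std)
  agg
}

#' Crude prevalence per 1000
#'
#' @param prevalent Prevalent cases (persons).
#' @param population Population (persons), must be positive.
#' @return `1000 * prevalent / population`.
#' @export
crude_prevalence <- function(prevalent, population) {
  if (any(population <= 0)) stop("population must be positive", call. = FALSE)
  if (any(prevalent < 0)) stop("prevalent cases must be non-negative", call. = FALSE)
  1000 * prevalent / population
}

#' Age-standardised prevalence per 1000
#'
#' Weighted average of band-specific rates under a standard population.
#'
#' @param band_rates Per-1000 prevalence per attained band (length-4).
#' @param std Standard weights summing to 1, see [who_standard_weights()].
#' @return Standardised rate per 1000.
#' @export
standardised_prevalence <- function(band_rates, std = who_standard_weights()) {
  check_band_vector(band_rates, "band_rates")
  check_band_vector(std, "std")
  if (abs(sum(std) - 1) > 1e-9 || any(std < 0)) {
    stop("standard weights must be non-negative and sum to 1", call. = FALSE)
  }
  sum(as.numeric(band_rates) * as.numeric(std))
}

#' Round half away from zero
#'
#' Spreadsheet-style rounding, used for all printed outputs (base `round()`
#' rounds half to even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage shares of a total
#'
#' Shares of incident or prevalent cases across one dimension (onset age
#' bands, attained age bands, income groups or regions), as percentages of
#' the world total, reported unrounded and rounded to the nearest integer
#' (half away from zero).
#'
#' @param est Per-country estimates from [estimate_burden()].
#' @param dimension `"onset_age"`, `"attained_age"`, `"income"` or
#'   `"region"`.
#' @param measure `"incident"` or `"prevalent"`.
#'
#' @return A tibble with `group`, `value`, `share_pct`, `share_pct_rounded`.
#' @export
share_table <- function(est,
                        dimension = c("onset_age", "attained_age", "income",
                                      "region"),
                        measure = c("incident", "prevalent")) {
  dimension <- match.arg(dimension)
  measure <- match.arg(measure)
  suffixes <- c("0_14", "15_39", "40_64", "65p")
  if (dimension %in% c("onset_age", "attained_age")) {
    prefix <- if (measure == "incident") "inc_" else
      if (dimension == "onset_age") "prev_onset_" else "prev_att_"
    if (measure == "incident" && dimension == "attained_age") {
      stop("incident cases are indexed by onset age only", call. = FALSE)
    }
    vals <- colSums(est[paste0(prefix, suffixes)])
    grp <- BAND_LABELS
  } else {
    key <- if (dimension == "income") "income_group" else "region"
    col <- if (measure == "incident") "inc_total" else "prev_total"
    lvls <- if (dimension == "income") INCOME_GROUPS else REGIONS
    vals <- tapply(est[[col]], factor(est[[key]], levels = lvls), sum,
                   default = 0)
    grp <- lvls
  }
  total <- sum(vals)
  if (total <= 0) stop("world total is zero; shares undefined", call. = FALSE)
  tibble::tibble(
    group = grp,
    value = as.numeric(vals),
    share_pct = 100 * as.numeric(vals) / total,
    share_pct_rounded = round_half_up(100 * as.numeric(vals) / total)
  )
}

#' Headline summary table
#'
#' One row for the world, each income level and each region; columns are
#' incident cases per onset band plus total and prevalent cases per attained
#' band plus total (all in thousands, two decimals, rounded half away from
#' zero), then crude and WHO-standardised prevalence per 1000 (two decimals).
#' Totals are computed from unrounded sums before rounding, so a printed
#' total may differ from the sum of its printed band cells by up to 0.01
#' thousand.
#'
#' @param est Per-country estimates from [estimate_burden()].
#' @param std Standard-population weights.
#' @return A tibble with 11 rows and 13 columns.
#' @export
summarise_table1 <- function(est, std = who_standard_weights()) {
  agg <- dplyr::bind_rows(
    aggregate_estimates(est, "world", std),
    aggregate_estimates(est, "income_group", std),
    aggregate_estimates(est, "region", std)
  )
  # fixed 11-row layout: groups with no member countries appear with zero
  # cases and undefined (NA) prevalence rates
  expected <- c("World", INCOME_GROUPS, REGIONS)
  if (!identical(agg$group, expected)) {
    pad <- agg[rep(NA_integer_, length(setdiff(expected, agg$group))), ]
    pad$group <- setdiff(expected, agg$group)
    num <- setdiff(names(pad), c("group", "crude_per1000", "std_per1000"))
    pad[num] <- 0
    agg <- dplyr::bind_rows(agg, pad)
    agg <- agg[match(expected, agg$group), ]
  }
  suffixes <- c("0_14", "15_39", "40_64", "65p")
  out <- tibble::tibble(group = agg$group)
  for (s in suffixes) {
    out[[paste0("incident_", s, "_k")]] <-
      round_half_up(agg[[paste0("inc_", s)]] / 1000, 2)
  }
  out$incident_total_k <- round_half_up(agg$inc_total / 1000, 2)
  for (s in suffixes) {
    out[[paste0("prevalent_", s, "_k")]] <-
      round_half_up(agg[[paste0("prev_att_", s)]] / 1000, 2)
  }
  out$prevalent_total_k <- round_half_up(agg$prev_total / 1000, 2)
  out$crude_per1000 <- round_half_up(agg$crude_per1000, 2)
  out$std_per1000 <- round_half_up(agg$std_per1000, 2)
  out
}

#' Write the headline summary table to CSV
#'
#' @param est Per-country estimates from [estimate_burden()].
#' @param path Output CSV path.
#' @param std Standard-population weights.
#' @return `path`, invisibly.
#' @export
emit_table1 <- function(est, path, std = who_standard_weights()) {
  readr::write_csv(summarise_table1(est, std), path, progress = FALSE)
  invisible(path)
}
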