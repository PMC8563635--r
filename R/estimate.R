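#' Per-country burden estimates
#'
#' Runs the full estimation chain for every country in a table: childhood
#' incidence is scaled to all four age bands, applied to band populations to
#' give incident case counts by onset age; the child-mortality penalty scales
#' band-specific maximum durations down to country durations; steady-state
#' prevalence by onset band is the product of incidence and duration; and
#' prevalent cases are reallocated to attained-age bands through the survival
#' schedule. All counts are carried unrounded.
#'
#' @param tbl A validated country table with no missing incidence (run
#'   [assign_missing_incidence()] first if needed).
#' @param schedule A [survival_schedule()].
#' @param params A [duration_params()].
#' @param ratios Incidence scaling ratios, see [scaling_ratios()].
#' @param penalty_override If non-`NULL`, a single penalty value applied to
#'   every country in place of `cm / penalty_constant` (the 'ignoring
#'   penalty' sensitivity scenario uses 0).
#' @param tail_truncate Passed to [allocate_attained_age()].
#'
#' @return A tibble, one row per country: identifiers, band populations,
#'   `pen`, incident cases per onset band (`inc_*`), prevalent cases per
#'   onset band (`prev_onset_*`) and per attained band (`prev_att_*`), and
#'   the corresponding totals.
#' @export
estimate_burden <- function(tbl, schedule,
                            params = duration_params(),
                            ratios = scaling_ratios(),
                            penalty_override = NULL,
                            tail_truncate = FALSE) {
  tbl <- validate_country_table(tbl, strict = TRUE)
  if (anyNA(tbl$inc_0_14_per100k)) {
    stop("countries without incidence remain: ",
         paste(tbl$iso3[is.na(tbl$inc_0_14_per100k)], collapse = ", "),
         "; run assign_missing_incidence() first", call. = FALSE)
  }
  n <- nrow(tbl)
  pops <- as.matrix(tbl[POP_COLUMNS])
  rates <- scale_incidence_rates(tbl$inc_0_14_per100k, ratios)
  if (n == 1) rates <- matrix(rates, nrow = 1)
  incident <- compute_incident_cases(rates, pops)

  pen <- if (is.null(penalty_override)) {
    penalty(tbl$cm_per1000, params)
  } else {
    rep(penalty_override, n)
  }
  durations <- mean_duration(pen, params)
  if (n == 1) durations <- matrix(durations, nrow = 1)
  p_onset <- incident * durations

  if (tail_truncate) {
    p_att <- t(vapply(seq_len(n), function(i) {
      allocate_attained_age(p_onset[i, ], schedule,
                            tail_truncate = TRUE, durations = durations[i, ])
    }, numeric(4)))
  } else {
    w <- t(vapply(1:4, person_year_weights, numeric(4), schedule = schedule))
    p_att <- p_onset %*% w
  }

  out <- tibble::tibble(
    iso3 = tbl$iso3, name = tbl$name,
    income_group = tbl$income_group, region = tbl$region,
    pen = pen
  )
  band_cols <- function(m, prefix) {
    colnames(m) <- paste0(prefix, c("0_14", "15_39", "40_64", "65p"))
    tibble::as_tibble(m)
  }
  dplyr::bind_cols(
    out,
    band_cols(pops, "pop_"),
    band_cols(incident, "inc_"),
    band_cols(p_onset, "prev_onset_"),
    band_cols(p_att, "prev_att_"),
    tibble::tibble(
      pop_total = rowSums(pops),
      inc_total = rowSums(incident),
      prev_total = rowSums(p_att)
    )
  )
}
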