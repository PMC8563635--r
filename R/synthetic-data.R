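#' Configuration for the synthetic country-table generator
#'
#' The generator emulates the statistical structure of the real 2017 inputs:
#' roughly 200 countries; childhood type 1 diabetes incidence spanning about
#' two orders of magnitude (a handful of Nordic-style registries above
#' 40 per 100,000 down to East Asian rates below 1), modelled log-normally;
#' under-5 child mortality drawn within income-group-specific intervals (low
#' in high-income countries, approaching the 130 per 1000 penalty ceiling in
#' low-income ones); national populations log-normally sized and rescaled to
#' a plausible world total, with younger age structures in high-mortality
#' countries; and about half the countries lacking an observed incidence
#' study, each paired with a same-region observed donor.
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param n_countries Number of countries.
#' @param incidence_log_mean,incidence_log_sd Log-scale mean and sd of the
#'   cross-country childhood incidence distribution (per 100,000/yr).
#' @param cm_range_by_income Named list of `c(low, high)` child-mortality
#'   intervals (per 1000) for HIC, UMIC, LMIC, LIC; all within \[0, 130).
#' @param population_scale Target world population (persons).
#' @param income_mix,region_mix Proportions over income groups / regions;
#'   each must sum to 1.
#' @param frac_missing_incidence Fraction of countries generated without an
#'   observed incidence study.
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             n_countries = 200,
                             incidence_log_mean = log(2.5),
                             incidence_log_sd = 1.15,
                             cm_range_by_income = list(
                               HIC = c(2, 10), UMIC = c(5, 25),
                               LMIC = c(15, 70), LIC = c(40, 125)
                             ),
                             population_scale = 7.5e9,
                             income_mix = c(HIC = 0.30, UMIC = 0.28,
                                            LMIC = 0.27, LIC = 0.15),
                             region_mix = c(Africa = 0.27, Asia = 0.24,
                                            Europe = 0.22, LAC = 0.17,
                                            "NA" = 0.03, Oceania = 0.07),
                             frac_missing_incidence = 0.5) {
  stopifnot(length(seed) == 1, is.finite(seed))
  if (n_countries < 1) stop("`n_countries` must be >= 1", call. = FALSE)
  if (abs(sum(income_mix) - 1) > 1e-9 || any(income_mix < 0)) {
    stop("`income_mix` must be non-negative and sum to 1", call. = FALSE)
  }
  if (abs(sum(region_mix) - 1) > 1e-9 || any(region_mix < 0)) {
    stop("`region_mix` must be non-negative and sum to 1", call. = FALSE)
  }
  if (!setequal(names(income_mix), INCOME_GROUPS) ||
      !setequal(names(region_mix), REGIONS)) {
    stop("`income_mix`/`region_mix` must be named over the income groups and regions",
         call. = FALSE)
  }
  for (grp in INCOME_GROUPS) {
    rng <- cm_range_by_income[[grp]]
    if (is.null(rng) || length(rng) != 2 || rng[1] < 0 || rng[2] >= 130 ||
        rng[1] > rng[2]) {
      stop("child-mortality interval for ", grp,
           " must lie within [0, 130) with low <= high", call. = FALSE)
    }
  }
  if (frac_missing_incidence < 0 || frac_missing_incidence >= 1) {
    stop("`frac_missing_incidence` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_countries = as.integer(n_countries),
         incidence_log_mean = incidence_log_mean,
         incidence_log_sd = incidence_log_sd,
         cm_range_by_income = cm_range_by_income,
         population_scale = population_scale,
         income_mix = income_mix[INCOME_GROUPS],
         region_mix = region_mix[REGIONS],
         frac_missing_incidence = frac_missing_incidence),
    class = "synthetic_config"
  )
}

#' Generate a synthetic country table
#'
#' Draws a full country table under the configured world (see
#' [synthetic_config()]) together with a donor map pairing every country
#' lacking an observed incidence study with a same-region observed country.
#' Age structure covaries with child mortality: the childhood population
#' share interpolates from about 18% in the lowest-mortality countries to
#' about 42% near the penalty ceiling, mirroring the demographic transition.
#'
#' @param config A [synthetic_config()].
#'
#' @return A list with elements `table` (a country table, strict-valid, with
#'   incidence gaps still open) and `donor_map` (named character vector,
#'   recipient ISO3 -> donor ISO3; empty if `frac_missing_incidence` is 0).
#' @export
generate_country_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_countries
  withr::local_seed(config$seed)

  iso3 <- synth_iso3(n)
  income <- sample(INCOME_GROUPS, n, replace = TRUE, prob = config$income_mix)
  region <- sample(REGIONS, n, replace = TRUE, prob = config$region_mix)

  cm <- vapply(income, function(grp) {
    rng <- config$cm_range_by_income[[grp]]
    stats::runif(1, rng[1], rng[2])
  }, numeric(1))

  inc <- stats::rlnorm(n, config$incidence_log_mean, config$incidence_log_sd)

  # national totals: heavy-tailed sizes rescaled to the world total
  pop_total <- stats::rlnorm(n, log(8e6), 1.5)
  pop_total <- pop_total * config$population_scale / sum(pop_total)

  # band shares interpolate between an aged and a youthful structure with cm
  young <- cm / 130
  base_old <- c(0.18, 0.36, 0.30, 0.16)
  base_young <- c(0.42, 0.38, 0.16, 0.04)
  shares <- outer(1 - young, base_old) + outer(young, base_young)
  noise <- matrix(stats::rgamma(4 * n, shape = 60, rate = 60), nrow = n)
  shares <- shares * noise
  shares <- shares / rowSums(shares)
  pops <- round(shares * pop_total)

  # which countries lack an observed study, and their same-region donors;
  # one country per region is kept observed so a donor always exists
  n_missing <- round(config$frac_missing_incidence * n)
  anchors <- vapply(split(seq_len(n), region), function(ix) {
    ix[sample.int(length(ix), 1)]
  }, integer(1))
  pool <- setdiff(seq_len(n), anchors)
  if (n_missing > length(pool)) {
    stop("no observed donor country can be guaranteed in every region: ",
         "frac_missing_incidence is too high for ", n, " countries",
         call. = FALSE)
  }
  missing_idx <- if (n_missing > 0) {
    pool[sample.int(length(pool), n_missing)]
  } else integer(0)
  donor_map <- character(0)
  if (n_missing > 0) {
    observed_idx <- setdiff(seq_len(n), missing_idx)
    donor_map <- vapply(missing_idx, function(i) {
      pool <- observed_idx[region[observed_idx] == region[i]]
      if (length(pool) == 0) {
        stop("no observed donor available in region ", region[i], call. = FALSE)
      }
      iso3[pool[sample.int(length(pool), 1)]]
    }, character(1))
    names(donor_map) <- iso3[missing_idx]
    inc[missing_idx] <- NA_real_
  }

  tbl <- tibble::tibble(
    iso3 = iso3,
    name = paste("Country", iso3),
    income_group = income,
    region = region,
    pop_0_14 = pops[, 1], pop_15_39 = pops[, 2],
    pop_40_64 = pops[, 3], pop_65p = pops[, 4],
    inc_0_14_per100k = inc,
    inc_source = ifelse(is.na(inc), "missing", "observed"),
    inc_donor = NA_character_,
    cm_per1000 = unname(cm)
  )
  list(table = validate_country_table(tbl, strict = TRUE), donor_map = donor_map)
}

# deterministic distinct fake ISO3 codes: AAA, AAB, ...
synth_iso3 <- function(n) {
  stopifnot(n <= 26^3)
  i <- seq_len(n) - 1
  paste0(LETTERS[i %/% 676 + 1], LETTERS[(i %/% 26) %% 26 + 1],
         LETTERS[i %% 26 + 1])
}

#' Generate a calibrated synthetic survival schedule
#'
#' Stands in for registry-derived cumulative-survival tables: for each onset
#' band a Weibull survival curve (shape drawn per band from \[1.5, 3\]) is
#' evaluated at the band-end knot ages, and its scale is calibrated by root
#' finding so that the schedule's implied penalty-free remaining life
#' expectancy — the person-year total produced by the same trapezoidal
#' integration the allocation step uses — matches that band's maximum mean
#' duration. For the 65+ onset band the schedule carries no interior knots
#' (survival runs linearly to zero at `cap_age`), so the mean onset age is
#' the calibrated quantity: `cap_age - 2 * target`.
#'
#' @param seed Integer seed for the band shapes.
#' @param params A [duration_params()]; its `max_duration` entries are the
#'   calibration targets.
#' @param cap_age Closing age of the 65+ band.
#' @param mean_onset_age Mean onset ages for bands 1-3 (the 65+ entry is
#'   recalibrated).
#'
#' @return A [survival_schedule()] whose implied expectancies match the
#'   targets to well within 2%.
#' @export
generate_survival_schedule <- function(seed, params = duration_params(),
                                       cap_age = 99,
                                       mean_onset_age = c(7.5, 27, 52, 72)) {
  withr::local_seed(seed)
  bands <- age_bands(cap_age)
  shapes <- stats::runif(4, 1.5, 3)
  targets <- params$max_duration
  onset <- mean_onset_age
  cum_survival <- vector("list", 4)
  cum_survival[[4]] <- numeric(0)

  # 65+ band: no knots, expectancy is (cap - onset)/2 under the linear tail
  onset[4] <- cap_age - 2 * targets[4]
  if (onset[4] < bands$start[4] || onset[4] >= cap_age) {
    stop("infeasible 65+ target duration ", targets[4],
         " for cap_age ", cap_age, call. = FALSE)
  }

  for (g in 1:3) {
    knot_t <- c(bands$end[g:3], cap_age) - onset[g]
    max_e <- implied_expectancy(knot_t, rep(1, 3 - g + 1))
    if (targets[g] >= max_e) {
      stop(sprintf(
        "infeasible target duration %.1f y for onset band %s: the maximum representable expectancy is %.1f y",
        targets[g], BAND_LABELS[g], max_e), call. = FALSE)
    }
    shape <- shapes[g]
    f <- function(log_scale) {
      s <- exp(-(utils::head(knot_t, -1) / exp(log_scale))^shape)
      implied_expectancy(knot_t, s) - targets[g]
    }
    root <- stats::uniroot(f, lower = log(0.1), upper = log(1e4),
                           tol = 1e-10)$root
    cum_survival[[g]] <- exp(-(utils::head(knot_t, -1) / exp(root))^shape)
  }
  survival_schedule(onset, cum_survival, cap_age = cap_age)
}

# expectancy implied by trapezoid integration over knots (t from onset,
# survival 1 at onset, s at interior knots, 0 at the final knot)
implied_expectancy <- function(knot_t, s_interior) {
  t_all <- c(0, knot_t)
  s_all <- c(1, s_interior, 0)
  sum(diff(t_all) * (utils::head(s_all, -1) + s_all[-1]) / 2)
}

#' Read / write survival schedules as YAML
#'
#' Serialises a schedule as, per onset band, the mean onset age and a list of
#' `(band_end_age, cum_survival)` pairs.
#'
#' @param schedule A [survival_schedule()].
#' @param path YAML file path.
#' @return `write_survival_schedule()` returns `path` invisibly;
#'   `read_survival_schedule()` returns the schedule.
#' @export
write_survival_schedule <- function(schedule, path) {
  bands <- age_bands(schedule$cap_age)
  out <- list(cap_age = schedule$cap_age, onset_bands = list())
  for (g in 1:4) {
    ends <- if (g < 4) bands$end[g:3] else numeric(0)
    out$onset_bands[[BAND_LABELS[g]]] <- list(
      mean_onset_age = unname(schedule$mean_onset_age[g]),
      cum_survival = if (g < 4) {
        lapply(seq_along(ends), function(i) {
          list(band_end_age = ends[i],
               cum_survival = schedule$cum_survival[[g]][i])
        })
      } else list()
    )
  }
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_survival_schedule
#' @export
read_survival_schedule <- function(path) {
  raw <- yaml::read_yaml(path)
  onset <- vapply(BAND_LABELS, function(b) raw$onset_bands[[b]]$mean_onset_age,
                  numeric(1))
  cum_survival <- lapply(BAND_LABELS, function(b) {
    vapply(raw$onset_bands[[b]]$cum_survival, `[[`, numeric(1), "cum_survival")
  })
  survival_schedule(onset, cum_survival, cap_age = raw$cap_age)
}
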