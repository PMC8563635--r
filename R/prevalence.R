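#' Survival schedules for attained-age allocation
#'
#' Prevalent cases are first computed by onset band (the steady-state product
#' of incidence and mean duration) and then redistributed to attained-age
#' bands. The redistribution needs, for each onset band, the mean age at
#' onset within the band and the cumulative survival from onset to the end of
#' each subsequent age band. One schedule is applied globally.
#'
#' `cum_survival` holds, per onset band, the survival probabilities at the
#' ends of that band and all later closed bands (ages 15, 40, 65 as
#' applicable); survival at onset is 1 by definition and no knot exists for
#' the open 65+ band, where survival is taken linearly to zero at `cap_age`.
#'
#' @param mean_onset_age Length-4 numeric, mean onset age inside each band.
#' @param cum_survival List of 4 numeric vectors with lengths 3, 2, 1, 0:
#'   cumulative survival at band-end ages for each onset band.
#' @param cap_age Closing age of the 65+ band (years).
#'
#' @return An object of class `survival_schedule`.
#' @export
survival_schedule <- function(mean_onset_age, cum_survival, cap_age = 99) {
  bands <- age_bands(cap_age)
  check_band_vector(mean_onset_age, "mean_onset_age")
  if (!is.list(cum_survival) || length(cum_survival) != 4 ||
      !identical(lengths(cum_survival), c(3L, 2L, 1L, 0L))) {
    stop("`cum_survival` must be a list of 4 vectors with lengths 3, 2, 1, 0",
         call. = FALSE)
  }
  for (g in 1:4) {
    a <- mean_onset_age[g]
    if (a < bands$start[g] || a >= bands$end[g]) {
      stop(sprintf("mean onset age %.1f lies outside band %s", a,
                   BAND_LABELS[g]), call. = FALSE)
    }
    s <- cum_survival[[g]]
    if (length(s) > 0) {
      if (any(is.na(s)) || any(s < 0) || any(s > 1)) {
        stop("cumulative survival must lie in [0, 1]", call. = FALSE)
      }
      if (is.unsorted(rev(c(1, s)))) {
        stop("cumulative survival must be non-increasing from onset",
             call. = FALSE)
      }
    }
  }
  structure(
    list(mean_onset_age = stats::setNames(as.numeric(mean_onset_age), BAND_LABELS),
         cum_survival = cum_survival,
         cap_age = cap_age),
    class = "survival_schedule"
  )
}

# Piecewise-linear survival curve (in years since onset) implied by the
# schedule for onset band g: S = 1 at onset, the schedule's knots at band
# ends, and a linear tail reaching 0 at cap_age.
schedule_knots <- function(schedule, g) {
  bands <- age_bands(schedule$cap_age)
  a <- schedule$mean_onset_age[g]
  knot_ages <- if (g == 4) c(a, schedule$cap_age) else
    c(a, bands$end[g:3], schedule$cap_age)
  knot_s <- c(1, schedule$cum_survival[[g]], 0)
  list(t = knot_ages - a, s = knot_s, onset_age = a)
}

#' Person-year weights over attained-age bands
#'
#' For one incident case with onset in band `g`, computes the expected
#' person-years lived inside each attained-age band by trapezoidal
#' integration of the schedule's piecewise-linear survival curve: within the
#' onset band from the mean onset age (survival 1) to the band end; across
#' later closed bands between the schedule's endpoint survival values; and in
#' the open 65+ band with survival taken linearly to zero at `cap_age`.
#' Weights are the person-years normalised to sum to one.
#'
#' @param g Onset band index (1-4).
#' @param schedule A [survival_schedule()].
#' @param normalise Return weights summing to 1 (default) or raw person-years
#'   (whose total is the schedule's implied remaining life expectancy).
#'
#' @return Length-4 numeric vector over attained bands (zero below band `g`).
#' @export
person_year_weights <- function(g, schedule, normalise = TRUE) {
  stopifnot(g %in% 1:4)
  bands <- age_bands(schedule$cap_age)
  k <- schedule_knots(schedule, g)
  ages <- k$t + k$onset_age
  py <- numeric(4)
  for (b in g:4) {
    lo <- max(bands$start[b], k$onset_age)
    hi <- bands$end[b]
    py[b] <- integrate_linear(ages, k$s, lo, hi)
  }
  if (!normalise) return(stats::setNames(py, BAND_LABELS))
  total <- sum(py)
  if (total <= 0) stop("degenerate schedule: no person-years past onset",
                       call. = FALSE)
  stats::setNames(py / total, BAND_LABELS)
}

# exact integral of a piecewise-linear function (x, y) over [lo, hi]
integrate_linear <- function(x, y, lo, hi) {
  if (hi <= lo) return(0)
  f <- stats::approxfun(x, y, rule = 2)
  xs <- sort(unique(c(lo, hi, x[x > lo & x < hi])))
  sum(diff(xs) * (f(utils::head(xs, -1)) + f(xs[-1])) / 2)
}

#' Steady-state prevalent cases by onset band
#'
#' The epidemiological steady-state identity: annual new cases equal annual
#' deaths among cases, so `prevalence = incidence x mean duration`, applied
#' per onset band.
#'
#' @param incident_cases Cases per year per onset band (length-4).
#' @param durations Mean duration in years per onset band (length-4).
#'
#' @return Prevalent cases per onset band (real-valued, unrounded).
#' @export
#' @examples
#' prevalence_by_onset(c(100, 100, 60, 12.5), c(60.4, 43.4, 21.1, 8.5))
prevalence_by_onset <- function(incident_cases, durations) {
  check_band_vector(incident_cases, "incident_cases")
  check_band_vector(durations, "durations")
  if (any(incident_cases < 0) || any(durations < 0)) {
    stop("incident cases and durations must be non-negative", call. = FALSE)
  }
  stats::setNames(as.numeric(incident_cases) * as.numeric(durations), BAND_LABELS)
}

#' Allocate prevalent cases from onset bands to attained-age bands
#'
#' Each onset band's prevalent cases are spread over attained bands in
#' proportion to the person-years an incident case is expected to live in
#' each band. By default the weights come from the penalty-free schedule and
#' person-years are rescaled proportionally, so band shares are
#' penalty-invariant and the total is conserved exactly (the penalty already
#' acts on totals through the duration factor). With
#' `tail_truncate = TRUE`, shortened duration instead removes person-years
#' from the oldest attained bands first, reading reduced survival as
#' curtailing old age; `durations` must then be supplied.
#'
#' @param p_onset Prevalent cases per onset band.
#' @param schedule A [survival_schedule()].
#' @param tail_truncate Curtail old-age person-years instead of proportional
#'   rescaling.
#' @param durations Mean durations per onset band (years); required when
#'   `tail_truncate = TRUE`.
#'
#' @return Prevalent cases per attained band; total equals `sum(p_onset)`.
#' @export
allocate_attained_age <- function(p_onset, schedule, tail_truncate = FALSE,
                                  durations = NULL) {
  check_band_vector(p_onset, "p_onset")
  if (any(p_onset < 0)) stop("`p_onset` must be non-negative", call. = FALSE)
  out <- numeric(4)
  for (g in 1:4) {
    if (p_onset[g] == 0) next
    if (tail_truncate) {
      if (is.null(durations)) {
        stop("`durations` is required when `tail_truncate = TRUE`", call. = FALSE)
      }
      py <- person_year_weights(g, schedule, normalise = FALSE)
      w <- truncate_tail(py, durations[g])
    } else {
      w <- person_year_weights(g, schedule)
    }
    out <- out + p_onset[g] * w
  }
  stats::setNames(out, BAND_LABELS)
}

# keep person-years from the youngest attained band upwards until `target`
# years are filled; normalise to weights
truncate_tail <- function(py, target) {
  total <- sum(py)
  if (target >= total || target <= 0) return(py / total)
  kept <- pmin(py, pmax(target - cumsum(c(0, utils::head(py, -1))), 0))
  kept / sum(kept)
}

#' Cohort-simulation oracle for the steady-state model
#'
#' Independent check on `prevalence_by_onset()` + `allocate_attained_age()`:
#' discrete-time (1-year step) cohort bookkeeping. Each year, incident cases
#' enter at their band's mean onset age; existing cases age one year and die
#' according to the schedule's survival curve, time-rescaled so that
#' remaining life expectancy from onset matches the supplied mean durations.
#' After `horizon` years the age distribution of survivors is stationary and
#' is reported per attained band. Survivors are counted at mid-year.
#'
#' @param incident_cases Cases per year per onset band.
#' @param schedule A [survival_schedule()].
#' @param durations Target mean durations (years) per onset band.
#' @param horizon Years to iterate; must be at least `cap_age` so every
#'   cohort present at the start has washed through.
#'
#' @return Prevalent cases per attained band at equilibrium.
#' @export
simulate_steady_state <- function(incident_cases, schedule, durations,
                                  horizon = 2 * schedule$cap_age) {
  check_band_vector(incident_cases, "incident_cases")
  check_band_vector(durations, "durations")
  if (horizon < schedule$cap_age) {
    stop("`horizon` must be at least cap_age for the population to equilibrate",
         call. = FALSE)
  }
  bands <- age_bands(schedule$cap_age)
  out <- numeric(4)
  for (g in 1:4) {
    if (incident_cases[g] == 0) next
    k <- schedule_knots(schedule, g)
    e0 <- integrate_linear(k$t, k$s, 0, max(k$t))
    scale <- durations[g] / e0
    s_fun <- stats::approxfun(k$t * scale, k$s, yleft = 1, yright = 0)
    t_max <- ceiling(max(k$t) * scale)

    # alive[j]: survivors at mid-year of their j-th year since onset
    alive <- numeric(t_max + 1)
    mid <- seq_len(t_max + 1) - 0.5
    s_mid <- s_fun(mid)
    cond <- c(s_mid[1], ifelse(s_mid[-length(s_mid)] > 0,
                               s_mid[-1] / s_mid[-length(s_mid)], 0))
    for (yr in seq_len(horizon)) {
      alive <- c(incident_cases[g], utils::head(alive, -1)) * cond
    }
    attained <- pmin(k$onset_age + mid, schedule$cap_age - 1e-9)
    b_idx <- findInterval(attained, bands$start)
    for (b in unique(b_idx)) out[b] <- out[b] + sum(alive[b_idx == b])
  }
  stats::setNames(out, BAND_LABELS)
}
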