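# Shared fixtures, all built in code.

# A small hand-written country table: two observed HICs, one observed LIC,
# one extrapolated LMIC, one country still missing its rate.
make_test_table <- function() {
  tibble::tibble(
    iso3 = c("FIN", "DNK", "MWI", "IND", "NPL"),
    name = c("Finland", "Denmark", "Malawi", "India", "Nepal"),
    income_group = c("HIC", "HIC", "LIC", "LMIC", "LMIC"),
    region = c("Europe", "Europe", "Africa", "Asia", "Asia"),
    pop_0_14 = c(9e5, 9.5e5, 8e6, 3.6e8, 8e6),
    pop_15_39 = c(1.7e6, 1.8e6, 7e6, 5.5e8, 1.1e7),
    pop_40_64 = c(1.8e6, 1.9e6, 3e6, 3.3e8, 6e6),
    pop_65p = c(1.2e6, 1.1e6, 1e6, 8.5e7, 1.5e6),
    inc_0_14_per100k = c(60, 25, 2.0, 4.9, NA),
    inc_source = c("observed", "observed", "observed", "observed", "missing"),
    inc_donor = rep(NA_character_, 5),
    cm_per1000 = c(2.3, 4.3, 50, 39, 33)
  )
}

# Schedule whose knots are all 1: survival stays at 1 through age 65 and then
# falls linearly to 0 at cap. Person-year overlaps are hand-computable.
all_ones_schedule <- function(cap_age = 99) {
  survival_schedule(
    mean_onset_age = c(7.5, 27, 52, 72),
    cum_survival = list(c(1, 1, 1), c(1, 1), 1, numeric(0)),
    cap_age = cap_age
  )
}

# Independent oracle: expected person-years per attained band for one
# incident case, by brute-force numerical integration of the piecewise-linear
# survival curve on a fine grid (no trapezoid shortcut shared with the
# implementation).
oracle_person_years <- function(onset_age, knot_ages, knot_s, cap_age,
                                step = 1e-3) {
  ages <- c(onset_age, knot_ages, cap_age)
  s <- c(1, knot_s, 0)
  f <- stats::approxfun(ages, s)
  grid <- seq(onset_age, cap_age - step, by = step) + step / 2
  starts <- c(0, 15, 40, 65)
  band <- findInterval(grid, starts)
  py <- tapply(f(grid) * step, factor(band, levels = 1:4), sum, default = 0)
  as.numeric(py)
}
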