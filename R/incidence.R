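#' Incidence-rate scaling ratios
#'
#' Adult incidence of type 1 diabetes is rarely observed directly; the model
#' extrapolates it from childhood (0-14) rates using fixed ratios per age
#' band, with childhood as the reference (ratio 1). Two named presets ship
#' with the package:
#'
#' * `"core"` — Danish registry-derived ratios 1.00 / 0.50 / 0.30 / 0.25,
#'   the default model.
#' * `"china"` — ratios 1.00 / 0.57 / 0.28 / 0.19 observed in a study
#'   covering 10% of the Chinese population; used as an alternative set in
#'   sensitivity analyses.
#'
#' @param preset `"core"`, `"china"`, or a numeric vector of four ratios
#'   (childhood first, which must equal 1).
#'
#' @return Named numeric vector of four ratios, one per age band.
#' @export
#' @examples
#' scaling_ratios("core")
#' scaling_ratios(c(1, 0.5, 0.5, 0.5))
scaling_ratios <- function(preset = "core") {
  if (is.character(preset) && length(preset) == 1) {
    ratios <- switch(preset,
      core  = c(1.00, 0.50, 0.30, 0.25),
      china = c(1.00, 0.57, 0.28, 0.19),
      stop("unknown ratio preset '", preset, "'", call. = FALSE)
    )
  } else {
    check_band_vector(preset, "ratios")
    ratios <- as.numeric(preset)
  }
  if (ratios[1] != 1) {
    stop("the childhood (0-14) ratio is the reference and must equal 1",
         call. = FALSE)
  }
  if (any(ratios < 0)) stop("ratios must be non-negative", call. = FALSE)
  stats::setNames(ratios, BAND_LABELS)
}

#' Scale childhood incidence to all age bands
#'
#' @param childhood_rate Childhood (0-14) incidence, cases per 100,000
#'   person-years. Non-negative scalar or vector (one per country).
#' @param ratios Ratios from [scaling_ratios()].
#'
#' @return If `childhood_rate` is scalar, a named vector of four band rates;
#'   otherwise a matrix with one row per input rate and one column per band.
#' @export
#' @examples
#' scale_incidence_rates(10, scaling_ratios("core"))
scale_incidence_rates <- function(childhood_rate, ratios = scaling_ratios()) {
  if (any(is.na(childhood_rate)) || any(childhood_rate < 0)) {
    stop("`childhood_rate` must be non-negative and non-missing", call. = FALSE)
  }
  check_band_vector(ratios, "ratios")
  out <- outer(as.numeric(childhood_rate), as.numeric(ratios))
  colnames(out) <- BAND_LABELS
  if (length(childhood_rate) == 1) out[1, ] else out
}

#' Incident case counts from rates and population
#'
#' Applies band-specific incidence rates to band populations:
#' `cases = rate * population / 100000`. Counts stay real-valued
#' (unrounded) throughout the pipeline; rounding happens only in reporting.
#'
#' @param rates Cases per 100,000 person-years per band (length-4 vector or
#'   a matrix with 4 columns, one row per country).
#' @param population Persons per band, same shape as `rates`.
#'
#' @return Incident cases per year per band, same shape as the inputs.
#' @export
#' @examples
#' compute_incident_cases(c(10, 5, 3, 2.5), c(1e6, 2e6, 2e6, 0.5e6))
compute_incident_cases <- function(rates, population) {
  if (is.matrix(rates) || is.matrix(population)) {
    if (!is.matrix(rates) || !is.matrix(population) ||
        !identical(dim(rates), dim(population)) || ncol(rates) != 4) {
      stop("`rates` and `population` must have matching 4-column shapes",
           call. = FALSE)
    }
  } else {
    check_band_vector(rates, "rates")
    check_band_vector(population, "population")
  }
  if (any(rates < 0) || any(population < 0)) {
    stop("rates and populations must be non-negative", call. = FALSE)
  }
  rates * population / 1e5
}
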