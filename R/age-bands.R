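#' Age bands used throughout the model
#'
#' The model works at the resolution of four fixed age bands: childhood
#' (0-14), younger adulthood (15-39), middle age (40-64) and older age (65+).
#' Band boundaries are integer years and half-open: a band `[start, end)`
#' contains attained ages `start, ..., end - 1`. The open-ended 65+ band is
#' closed at `cap_age` for person-year arithmetic.
#'
#' @param cap_age Upper age (years) closing the 65+ band. Default 99.
#'
#' @return A tibble with columns `band` (ordered factor), `start` and `end`
#'   (integer years, half-open).
#' @export
#' @examples
#' age_bands()
age_bands <- function(cap_age = 99) {
  if (!is.numeric(cap_age) || length(cap_age) != 1 || cap_age <= 65) {
    stop("`cap_age` must be a single number greater than 65", call. = FALSE)
  }
  tibble::tibble(
    band  = band_factor(BAND_LABELS),
    start = c(0L, 15L, 40L, 65L),
    end   = c(15, 40, 65, cap_age)
  )
}

BAND_LABELS <- c("0-14", "15-39", "40-64", "65+")

band_factor <- function(x) factor(x, levels = BAND_LABELS, ordered = TRUE)

#' @keywords internal
check_band_vector <- function(x, what) {
  if (!is.numeric(x) || length(x) != 4) {
    stop(sprintf("`%s` must be a numeric vector of length 4 (one per age band)",
                 what), call. = FALSE)
  }
  if (anyNA(x)) stop(sprintf("`%s` contains missing values", what), call. = FALSE)
  invisible(x)
}
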