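#' Country-level input tables
#'
#' The pipeline's input is one row per country: ISO3 code, World Bank income
#' group, UN region, population by age band, childhood (0-14) type 1 diabetes
#' incidence per 100,000 person-years, the provenance of that incidence
#' (observed in a registry study, or extrapolated from a donor country), and
#' the under-5 child mortality rate per 1000 live births. Tables travel as
#' UTF-8 CSV with a fixed column set.
#'
#' @name country_table
NULL

COUNTRY_COLUMNS <- c(
  "iso3", "name", "income_group", "region",
  "pop_0_14", "pop_15_39", "pop_40_64", "pop_65p",
  "inc_0_14_per100k", "inc_source", "inc_donor", "cm_per1000"
)

INCOME_GROUPS <- c("HIC", "UMIC", "LMIC", "LIC")
REGIONS <- c("Africa", "Asia", "Europe", "LAC", "NA", "Oceania")
POP_COLUMNS <- c("pop_0_14", "pop_15_39", "pop_40_64", "pop_65p")

#' Read a country-level input table
#'
#' Reads and validates a country table CSV. In strict mode any invariant
#' violation (duplicate ISO3 code, negative population, incidence or child
#' mortality, unknown income group or region, extrapolated row whose donor is
#' absent or itself extrapolated) aborts with an informative error. In
#' lenient mode offending rows are dropped and each drop is reported via a
#' message.
#'
#' @param path Path to a CSV with the fixed column set (`iso3`, `name`,
#'   `income_group`, `region`, `pop_0_14`, `pop_15_39`, `pop_40_64`,
#'   `pop_65p`, `inc_0_14_per100k`, `inc_source`, `inc_donor`, `cm_per1000`).
#' @param strict If `TRUE` (default) reject any invalid row; if `FALSE` drop
#'   invalid rows with a logged reason.
#'
#' @return A validated country table (tibble), row order preserved.
#' @export
read_country_table <- function(path, strict = TRUE) {
  tbl <- readr::read_csv(
    path,
    col_types = readr::cols(
      iso3 = readr::col_character(),
      name = readr::col_character(),
      income_group = readr::col_character(),
      region = readr::col_character(),
      pop_0_14 = readr::col_double(),
      pop_15_39 = readr::col_double(),
      pop_40_64 = readr::col_double(),
      pop_65p = readr::col_double(),
      inc_0_14_per100k = readr::col_double(),
      inc_source = readr::col_character(),
      inc_donor = readr::col_character(),
      cm_per1000 = readr::col_double()
    ),
    # na = "": the region code "NA" (North America) is a real value, so
    # missing fields are serialised as empty strings instead
    na = "", progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(COUNTRY_COLUMNS, names(tbl))
  if (length(missing_cols) > 0) {
    stop("country table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_country_table(tbl[COUNTRY_COLUMNS], strict = strict)
}

#' Validate a country table
#'
#' @param tbl A tibble with the country-table columns.
#' @param strict Abort on the first problem (`TRUE`) or drop bad rows with a
#'   message (`FALSE`).
#' @return The validated (possibly row-filtered) tibble.
#' @export
validate_country_table <- function(tbl, strict = TRUE) {
  missing_cols <- setdiff(COUNTRY_COLUMNS, names(tbl))
  if (length(missing_cols) > 0) {
    stop("country table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl <- tibble::as_tibble(tbl)[COUNTRY_COLUMNS]
  problems <- character(nrow(tbl))

  dup <- duplicated(tbl$iso3)
  if (any(dup)) {
    msg <- sprintf("duplicate country_id '%s'", tbl$iso3[dup])
    problems[dup] <- msg
  }
  for (col in c(POP_COLUMNS, "cm_per1000")) {
    bad <- !is.na(tbl[[col]]) & tbl[[col]] < 0
    bad <- bad | is.na(tbl[[col]])
    problems[bad & problems == ""] <-
      sprintf("field '%s' is missing or negative", col)
  }
  bad_inc <- !is.na(tbl$inc_0_14_per100k) & tbl$inc_0_14_per100k < 0
  problems[bad_inc & problems == ""] <- "field 'inc_0_14_per100k' is negative"
  no_inc <- tbl$inc_source %in% c("observed", "extrapolated") &
    is.na(tbl$inc_0_14_per100k)
  problems[no_inc & problems == ""] <-
    "inc_source claims a rate but 'inc_0_14_per100k' is missing"

  bad_ig <- !tbl$income_group %in% INCOME_GROUPS
  problems[bad_ig & problems == ""] <-
    sprintf("unknown income_group '%s'", tbl$income_group[bad_ig])
  bad_rg <- !tbl$region %in% REGIONS
  problems[bad_rg & problems == ""] <-
    sprintf("unknown region '%s'", tbl$region[bad_rg])

  bad_src <- !tbl$inc_source %in% c("observed", "extrapolated", "missing")
  problems[bad_src & problems == ""] <-
    sprintf("unknown inc_source '%s'", tbl$inc_source[bad_src])

  # an extrapolated row must name a donor present in the table with an
  # observed rate; chained extrapolation has no rule and is rejected
  extr <- tbl$inc_source == "extrapolated" & problems == ""
  if (any(extr)) {
    donor_idx <- match(tbl$inc_donor[extr], tbl$iso3)
    no_donor <- is.na(tbl$inc_donor[extr]) | is.na(donor_idx)
    chained <- !no_donor & tbl$inc_source[donor_idx] != "observed"
    problems[which(extr)[no_donor]] <- "extrapolated row with donor absent from table"
    problems[which(extr)[chained]] <- "donor is itself extrapolated"
  }

  bad <- problems != ""
  if (any(bad)) {
    detail <- sprintf("row %d (%s): %s", which(bad), tbl$iso3[bad], problems[bad])
    if (strict) {
      stop("invalid country table:\n  ", paste(detail, collapse = "\n  "),
           call. = FALSE)
    }
    for (d in detail) message("dropping ", d)
    tbl <- tbl[!bad, ]
  }
  tbl
}

#' Write a country table to CSV
#'
#' Numeric fields are serialised at full precision so that
#' `read_country_table(write_country_table(tbl))` is the identity.
#'
#' @param tbl A valid country table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_country_table <- function(tbl, path) {
  missing_cols <- setdiff(COUNTRY_COLUMNS, names(tbl))
  if (length(missing_cols) > 0) {
    stop("country table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(tbl[COUNTRY_COLUMNS], path, na = "", progress = FALSE)
  invisible(path)
}

#' Fill incidence gaps by donor-country assignment
#'
#' Countries without an observed childhood incidence rate receive the rate of
#' an expert-chosen donor country. The choice of donor (geographical
#' proximity, per capita income, study quality, ethnic background) is input
#' data, not computed: it arrives as a map from recipient ISO3 to donor ISO3.
#' Rates are copied directly, and `inc_source` / `inc_donor` record the
#' provenance. Donors must themselves be observed; chaining through an
#' extrapolated donor is refused.
#'
#' @param tbl A country table.
#' @param donor_map Named character vector: `names()` are recipient ISO3
#'   codes, values are donor ISO3 codes. May be empty.
#' @return The table with incidences filled in; unmapped rows untouched.
#' @export
assign_missing_incidence <- function(tbl, donor_map) {
  if (length(donor_map) == 0) return(tbl)
  if (is.null(names(donor_map)) || any(names(donor_map) == "")) {
    stop("`donor_map` must be a named character vector (recipient -> donor)",
         call. = FALSE)
  }
  rec_idx <- match(names(donor_map), tbl$iso3)
  if (anyNA(rec_idx)) {
    stop("recipient(s) not in table: ",
         paste(names(donor_map)[is.na(rec_idx)], collapse = ", "),
         call. = FALSE)
  }
  don_idx <- match(unname(donor_map), tbl$iso3)
  if (anyNA(don_idx)) {
    stop("donor(s) not in table: ",
         paste(donor_map[is.na(don_idx)], collapse = ", "), call. = FALSE)
  }
  not_observed <- tbl$inc_source[don_idx] != "observed"
  if (any(not_observed)) {
    stop("donor(s) are not observed (chained extrapolation is not allowed): ",
         paste(unique(donor_map[not_observed]), collapse = ", "),
         call. = FALSE)
  }
  tbl$inc_0_14_per100k[rec_idx] <- tbl$inc_0_14_per100k[don_idx]
  tbl$inc_source[rec_idx] <- "extrapolated"
  tbl$inc_donor[rec_idx] <- unname(donor_map)
  tbl
}
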