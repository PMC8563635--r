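test_that("WHO four-band weights sum to one and match the 5-year aggregation", {
  w <- who_standard_weights()
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_true(all(w >= 0))
  five <- who_standard_weights(five_year = TRUE)
  expect_equal(nrow(five), 18)
  # independent aggregation of the published proportions
  idx <- list(1:3, 4:8, 9:13, 14:18)
  by_hand <- vapply(idx, function(i) sum(five$percent[i]), numeric(1))
  expect_equal(unname(w), by_hand / sum(five$percent))
})

test_that("crude and standardised prevalence follow their definitions", {
  expect_equal(crude_prevalence(9000, 3e6), 3)
  expect_equal(crude_prevalence(0, 1e6), 0)
  expect_error(crude_prevalence(10, 0), "positive")

  # equal band rates reproduce the crude rate
  expect_equal(standardised_prevalence(rep(2.5, 4)), 2.5)
  # single-band rate scales by its weight
  w <- who_standard_weights()
  expect_equal(standardised_prevalence(c(4, 0, 0, 0)), 4 * w[[1]])
  expect_error(standardised_prevalence(rep(1, 4), std = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
})

test_that("standardising a population with the standard's structure is the identity", {
  w <- who_standard_weights()
  pop <- 1e6 * w
  prev <- c(800, 2500, 3100, 900)
  rates <- 1000 * prev / pop
  expect_equal(standardised_prevalence(rates, w),
               crude_prevalence(sum(prev), sum(pop)))
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(2.345, 2), 2.35)
  expect_equal(round_half_up(234.715, 2), 234.72)
})

test_that("aggregates are component-wise sums that partition the world", {
  gen <- generate_country_table(synthetic_config(seed = 17, n_countries = 60))
  tbl <- assign_missing_incidence(gen$table, gen$donor_map)
  est <- estimate_burden(tbl, generate_survival_schedule(17))

  world <- aggregate_estimates(est, "world")
  income <- aggregate_estimates(est, "income_group")
  region <- aggregate_estimates(est, "region")
  expect_equal(sum(income$prev_total), world$prev_total)
  expect_equal(sum(region$prev_total), world$prev_total)
  expect_equal(sum(income$inc_total), world$inc_total)
  expect_equal(sum(region$inc_0_14), world$inc_0_14)

  # single-country group equals that country (an observed one, so the
  # one-row slice is a self-contained valid table)
  obs1 <- tbl[tbl$inc_source == "observed", ][1, ]
  one <- estimate_burden(obs1, generate_survival_schedule(17))
  agg1 <- aggregate_estimates(one, "world")
  expect_equal(agg1$prev_total, one$prev_total)
  expect_equal(agg1$inc_65p, one$inc_65p)
})

test_that("share tables report unrounded and rounded percentages of the world total", {
  gen <- generate_country_table(synthetic_config(seed = 17, n_countries = 60))
  tbl <- assign_missing_incidence(gen$table, gen$donor_map)
  est <- estimate_burden(tbl, generate_survival_schedule(17))
  for (dim in c("onset_age", "attained_age", "income", "region")) {
    meas <- if (dim == "attained_age") "prevalent" else "incident"
    st <- share_table(est, dim, meas)
    expect_equal(sum(st$share_pct), 100)
    expect_lte(abs(sum(st$share_pct_rounded) - 100), 1)
  }
  expect_error(share_table(est, "attained_age", "incident"), "onset age")
})

test_that("the headline table has the fixed layout and re-reads within rounding", {
  gen <- generate_country_table(synthetic_config(seed = 8, n_countries = 80))
  tbl <- assign_missing_incidence(gen$table, gen$donor_map)
  est <- estimate_burden(tbl, generate_survival_schedule(23))
  path <- withr::local_tempfile(fileext = ".csv")
  emit_table1(est, path)
  # na = character(): the North America region is literally "NA"
  tab <- readr::read_csv(path, show_col_types = FALSE, na = character())
  expect_equal(dim(tab), c(11, 13))
  expect_equal(tab$group, c("World", "HIC", "UMIC", "LMIC", "LIC", "Africa",
                            "Asia", "Europe", "LAC", "NA", "Oceania"))
  # re-read values match the unrounded aggregates within half a rounding unit
  world <- aggregate_estimates(est, "world")
  expect_lte(abs(tab$prevalent_total_k[1] - world$prev_total / 1000), 0.005)
  expect_lte(abs(tab$incident_total_k[1] - world$inc_total / 1000), 0.005)
  # world row dominates every sub-row component-wise
  num <- as.matrix(tab[-1, -1])
  expect_true(all(sweep(num, 2, as.numeric(tab[1, -1]), "<=")
                  [, 1:10]))
})
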