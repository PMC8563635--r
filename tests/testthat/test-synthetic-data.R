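test_that("generation is deterministic for a fixed seed", {
  a <- generate_country_table(synthetic_config(seed = 11))
  b <- generate_country_table(synthetic_config(seed = 11))
  expect_identical(a, b)
  c <- generate_country_table(synthetic_config(seed = 12))
  expect_false(identical(a$table, c$table))
})

test_that("generated tables pass strict validation with sane magnitudes", {
  gen <- generate_country_table(synthetic_config(seed = 3))
  tbl <- gen$table
  expect_silent(validate_country_table(tbl, strict = TRUE))
  expect_equal(nrow(tbl), 200)
  expect_true(all(tbl$cm_per1000 >= 0 & tbl$cm_per1000 < 130))
  # world total near the configured scale (rounding of band counts aside)
  expect_equal(sum(tbl[c("pop_0_14", "pop_15_39", "pop_40_64", "pop_65p")]),
               7.5e9, tolerance = 1e-3)
  # incidence spans roughly two orders of magnitude
  obs <- tbl$inc_0_14_per100k[tbl$inc_source == "observed"]
  expect_gt(max(obs) / min(obs), 50)
})

test_that("donor maps pair every missing country with a same-region observed donor", {
  gen <- generate_country_table(synthetic_config(seed = 5))
  tbl <- gen$table
  expect_equal(sum(tbl$inc_source == "missing"), 100)
  expect_setequal(names(gen$donor_map), tbl$iso3[tbl$inc_source == "missing"])
  donors <- match(gen$donor_map, tbl$iso3)
  recips <- match(names(gen$donor_map), tbl$iso3)
  expect_true(all(tbl$inc_source[donors] == "observed"))
  expect_true(all(tbl$region[donors] == tbl$region[recips]))
  # after assignment with the total map, no record lacks a rate
  filled <- assign_missing_incidence(tbl, gen$donor_map)
  expect_false(anyNA(filled$inc_0_14_per100k))

  none <- generate_country_table(
    synthetic_config(seed = 5, frac_missing_incidence = 0))
  expect_length(none$donor_map, 0)
})

test_that("group counts fall within binomial 99% bounds of the configured mixes", {
  cfg <- synthetic_config(seed = 8, n_countries = 200)
  tbl <- generate_country_table(cfg)$table
  for (grp in names(cfg$income_mix)) {
    n <- sum(tbl$income_group == grp)
    bounds <- qbinom(c(0.005, 0.995), 200, cfg$income_mix[[grp]])
    expect_gte(n, bounds[1])
    expect_lte(n, bounds[2])
  }
  for (rg in names(cfg$region_mix)) {
    n <- sum(tbl$region == rg)
    bounds <- qbinom(c(0.005, 0.995), 200, cfg$region_mix[[rg]])
    expect_gte(n, bounds[1])
    expect_lte(n, bounds[2])
  }
})

test_that("high-mortality countries have younger age structures", {
  tbl <- generate_country_table(synthetic_config(seed = 21))$table
  young_share <- tbl$pop_0_14 / (tbl$pop_0_14 + tbl$pop_15_39 +
                                   tbl$pop_40_64 + tbl$pop_65p)
  hi <- young_share[tbl$cm_per1000 > 60]
  lo <- young_share[tbl$cm_per1000 < 15]
  expect_gt(mean(hi), mean(lo) + 0.05)
})

test_that("incidence distribution shape is stable across seeds", {
  cfg1 <- synthetic_config(seed = 31, n_countries = 400,
                           frac_missing_incidence = 0)
  cfg2 <- synthetic_config(seed = 32, n_countries = 400,
                           frac_missing_incidence = 0)
  x <- generate_country_table(cfg1)$table$inc_0_14_per100k
  y <- generate_country_table(cfg2)$table$inc_0_14_per100k
  ks <- suppressWarnings(stats::ks.test(log(x), log(y)))
  expect_gt(ks$p.value, 0.001)
})

test_that("generated schedules hit the target expectancies within 2%", {
  params <- duration_params()
  for (seed in c(1, 9, 77)) {
    sch <- generate_survival_schedule(seed, params)
    implied <- vapply(1:4, function(g) {
      sum(person_year_weights(g, sch, normalise = FALSE))
    }, numeric(1))
    expect_equal(implied, unname(params$max_duration), tolerance = 0.02)
    # cumulative survival non-increasing for every onset band
    for (g in 1:3) {
      expect_false(is.unsorted(rev(c(1, sch$cum_survival[[g]]))))
    }
  }
})

test_that("infeasible duration targets raise a calibration error", {
  params <- duration_params(max_duration = c(90, 43.4, 21.1, 8.5))
  expect_error(generate_survival_schedule(1, params), "infeasible")
})

test_that("schedules round-trip through YAML", {
  sch <- generate_survival_schedule(13)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_survival_schedule(sch, path)
  back <- read_survival_schedule(path)
  expect_equal(back$mean_onset_age, sch$mean_onset_age)
  expect_equal(back$cum_survival, sch$cum_survival, tolerance = 1e-12)
  expect_equal(back$cap_age, sch$cap_age)
})

test_that("invalid synthetic configurations are rejected", {
  expect_error(synthetic_config(1, income_mix = c(HIC = 1, UMIC = 0.1,
                                                  LMIC = 0, LIC = 0)),
               "sum to 1")
  expect_error(synthetic_config(1, cm_range_by_income = list(
    HIC = c(2, 10), UMIC = c(5, 25), LMIC = c(15, 70), LIC = c(40, 140))),
    "130")
  expect_error(synthetic_config(1, frac_missing_incidence = 1), "frac_missing")
})

test_that("every region keeps at least one observed country, any seed", {
  for (seed in 101:115) {
    gen <- generate_country_table(synthetic_config(seed = seed))
    tbl <- gen$table
    obs_by_region <- tapply(tbl$inc_source == "observed", tbl$region, any)
    expect_true(all(obs_by_region))
  }
  expect_error(
    generate_country_table(synthetic_config(1, n_countries = 8,
                                            frac_missing_incidence = 0.9)),
    "donor")
})
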