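test_that("steady-state prevalence is incidence times duration per onset band", {
  p <- prevalence_by_onset(c(100, 100, 60, 12.5), c(60.4, 43.4, 21.1, 8.5))
  expect_equal(unname(p), c(6040, 4340, 1266, 106.25))
  expect_equal(sum(p), 11752.25)
  expect_equal(unname(prevalence_by_onset(c(100, 0, 3, 1), c(30, 20, 10, 5))[2]), 0)
  expect_error(prevalence_by_onset(c(-1, 0, 0, 0), rep(1, 4)), "non-negative")
})

test_that("person-year weights match a brute-force life-table oracle", {
  # all-ones knots: survival 1 to age 65, then linear to 0 at 99
  sch <- all_ones_schedule()
  for (g in 1:4) {
    onset <- sch$mean_onset_age[g]
    knots <- if (g < 4) c(15, 40, 65)[g:3] else numeric(0)
    oracle <- oracle_person_years(onset, knots, rep(1, length(knots)), 99)
    got <- person_year_weights(g, sch, normalise = FALSE)
    expect_equal(unname(got), oracle, tolerance = 1e-4)
  }
  # frozen hand value for onset band 0-14: overlaps 7.5, 25, 25 and the
  # closing triangle 34/2 = 17, total 74.5
  w <- person_year_weights(1, all_ones_schedule())
  expect_equal(unname(w), c(7.5, 25, 25, 17) / 74.5)
})

test_that("person-year weights agree with the oracle on generated schedules", {
  for (seed in c(2, 14)) {
    sch <- generate_survival_schedule(seed)
    for (g in 1:4) {
      onset <- sch$mean_onset_age[g]
      knots <- if (g < 4) c(15, 40, 65)[g:3] else numeric(0)
      oracle <- oracle_person_years(onset, knots, sch$cum_survival[[g]], 99)
      got <- person_year_weights(g, sch, normalise = FALSE)
      expect_equal(unname(got), oracle, tolerance = 1e-4)
    }
  }
})

test_that("weights are non-negative and sum to one; 65+ onset is a point mass", {
  sch <- generate_survival_schedule(4)
  for (g in 1:4) {
    w <- person_year_weights(g, sch)
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1)
    expect_true(all(w[seq_len(g - 1)] == 0))
  }
  expect_equal(unname(person_year_weights(4, sch)), c(0, 0, 0, 1))
})

test_that("attained-age allocation conserves totals on random inputs", {
  sch <- generate_survival_schedule(6)
  set.seed(99)
  for (i in 1:50) {
    p <- runif(4, 0, 1e5)
    att <- allocate_attained_age(p, sch)
    expect_equal(sum(att), sum(p), tolerance = 1e-12)
    expect_true(all(att >= 0))
  }
  # all prevalence in the 65+ onset band stays there
  expect_equal(unname(allocate_attained_age(c(0, 0, 0, 500), sch)),
               c(0, 0, 0, 500))
})

test_that("tail truncation removes old-age person-years first and conserves mass", {
  sch <- all_ones_schedule()
  p <- c(1000, 0, 0, 0)
  # duration 40: fills 7.5 + 25 + 7.5 from the youngest bands, nothing in 65+
  att <- allocate_attained_age(p, sch, tail_truncate = TRUE,
                               durations = c(40, 30, 15, 5))
  expect_equal(unname(att), 1000 * c(7.5, 25, 7.5, 0) / 40)
  expect_equal(sum(att), 1000)
  # durations at the penalty-free maximum reduce to proportional weights
  att2 <- allocate_attained_age(p, sch, tail_truncate = TRUE,
                                durations = c(74.5, 48, 23.5, 13.5))
  expect_equal(att2, allocate_attained_age(p, sch))
})

test_that("cohort simulation matches the analytic model in closed form", {
  sch <- all_ones_schedule()
  # onset band 2 (onset age 27): no mortality until 65, linear tail to 99,
  # so penalty-free expectancy is 13 + 25 + 34/2 = 55 years; at constant
  # incidence 100/yr the equilibrium total is the analytic product 100 x 55
  i <- c(0, 100, 0, 0)
  d <- c(60.4, 55, 21.1, 8.5)
  sim <- simulate_steady_state(i, sch, d)
  expect_equal(sum(sim), 100 * 55, tolerance = 0.005)
  # doubling incidence doubles equilibrium prevalence (linearity)
  sim2 <- simulate_steady_state(2 * i, sch, d)
  expect_equal(sim2, 2 * sim)
  expect_error(simulate_steady_state(i, sch, d, horizon = 50), "horizon")
})

test_that("analytic totals agree with the simulation oracle across seeds", {
  params <- duration_params()
  for (seed in 1:6) {
    sch <- generate_survival_schedule(seed, params)
    set.seed(seed)
    i <- runif(4, 10, 200)
    pen <- runif(1, 0, 0.6)
    d <- mean_duration(pen, params)
    analytic <- allocate_attained_age(prevalence_by_onset(i, d), sch)
    sim <- simulate_steady_state(i, sch, d)
    expect_equal(sum(sim), sum(analytic), tolerance = 0.02)
  }
})

test_that("schedule constructor rejects malformed inputs", {
  expect_error(survival_schedule(c(20, 27, 52, 72),
                                 list(c(1, 1, 1), c(1, 1), 1, numeric(0))),
               "outside band")
  expect_error(survival_schedule(c(7.5, 27, 52, 72),
                                 list(c(0.5, 0.8, 0.3), c(1, 1), 1,
                                      numeric(0))),
               "non-increasing")
  expect_error(survival_schedule(c(7.5, 27, 52, 72),
                                 list(c(1, 1), c(1, 1), 1, numeric(0))),
               "lengths")
})
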