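# CA19-9 trajectory classification, HbA1c and enzyme rules.

yr <- function(x) -x * DPY  # "x years before diagnosis" on a day scale, dx = 0

test_that("cumulative average is the mean of the strict prefix", {
  expect_equal(cumulative_average(c(10, 20, 30), c(0, 1, 2), at = 2), 15)
  expect_equal(cumulative_average(rep(7, 5), 1:5, at = 3.5), 7)
  expect_true(is.na(cumulative_average(c(10, 20), c(0, 1), at = 0)))
})

test_that("CA19-9 patterns follow the published rule set", {
  # first documentation above the ULN inside the window
  r <- classify_ca19_9(yr(c(3, 1.5, 0.3)), c(10, 12, 50), 0)
  expect_equal(r$pattern, "aberrant_elevation")
  expect_equal(r$trigger, "above_uln_first_time")
  expect_equal(r$first_elevation_years, 0.3)

  # normal throughout, including in-window points
  r <- classify_ca19_9(yr(c(3, 1.5, 0.3)), c(10, 30, 35), 0)
  expect_equal(r$pattern, "low_to_low")

  # elevated at baseline, oscillating without doubling
  r <- classify_ca19_9(yr(c(4, 3, 2, 1, 0.4)), c(80, 70, 90, 75, 85), 0)
  expect_equal(r$pattern, "high_to_high")

  # doubling of the cumulative average (prior mean 55), value above ULN
  r <- classify_ca19_9(yr(c(2, 1.5, 0.3)), c(50, 60, 120), 0)
  expect_equal(r$pattern, "aberrant_elevation")
  expect_equal(r$trigger, "doubling_of_cumavg")

  # no measurement in the final year
  r <- classify_ca19_9(yr(c(3, 1.5)), c(10, 50), 0)
  expect_equal(r$pattern, "insufficient_data")
})

test_that("HbA1c elevation uses the 4 mmol/mol rule with unit conversion", {
  days <- yr(c(3, 2, 1.5, 0.4))
  r <- detect_hba1c_elevation(days, c(42, 42, 42, 47), "mmol/mol", 0)
  expect_true(r$elevated)
  expect_equal(r$first_elevation_years, 0.4)

  r <- detect_hba1c_elevation(days, c(6.0, 6.0, 6.0, 6.0), "%", 0)
  expect_false(r$elevated)

  # 6.0 % -> 42.08, 6.4 % -> 46.45 mmol/mol: rise of 4.37
  r <- detect_hba1c_elevation(days, c(6.0, 6.0, 6.0, 6.4), "%", 0)
  expect_true(r$elevated)

  expect_error(
    detect_hba1c_elevation(days, c(6, 6, 42, 43),
                           c("%", "%", "mmol/mol", "mmol/mol"), 0),
    "mixed")
})

test_that("enzyme elevation needs 3x the ULN and doubling together", {
  days <- yr(c(3, 2, 1.5, 0.4))
  lip <- list(days = days, values = c(40, 40, 40, 500))
  r <- detect_enzyme_elevation(lipase = lip, dx_day = 0)
  expect_true(r$elevated)
  expect_equal(r$analyte, "lipase")
  expect_equal(r$first_elevation_years, 0.4)

  r <- detect_enzyme_elevation(
    lipase = list(days = days, values = c(40, 40, 40, 150)), dx_day = 0)
  expect_false(r$elevated)  # 150 <= 3 x 60

  # 3.5 x ULN but only 1.8 x the cumulative average
  pam <- list(days = days, values = c(95, 100, 97, 175))
  r <- detect_enzyme_elevation(p_amylase = pam, dx_day = 0)
  expect_false(r$elevated)
})

test_that("lead times convert days to years at 0.1 resolution", {
  r <- classify_ca19_9(c(-2000, -146), c(10, 80), 0)
  expect_equal(round(r$first_elevation_years, 1), 0.4)
  r <- classify_ca19_9(c(-2000, 0), c(10, 80), 0)
  expect_equal(r$first_elevation_years, 0)
})

test_that("Lewis-negative flag requires all values at or below detection", {
  expect_true(flag_lewis_negative(c(1, 1, 1), 2))
  expect_false(flag_lewis_negative(c(1, 15, 1), 2))
  expect_true(is.na(flag_lewis_negative(c(1, 2), NA_real_)))
})

test_that("patterns partition every diagnosed series and scale-invariance holds", {
  withr::local_seed(42)
  classes <- c("aberrant_elevation", "high_to_high", "low_to_low",
               "residual_unclassified", "insufficient_data")
  for (i in 1:200) {
    n <- sample(1:8, 1)
    s <- random_series(c(5, 20, 36, 40, 80, 160),
                       round(-runif(20, 0, 4) * DPY), n)
    r <- classify_ca19_9(s$days, s$values, 0)
    expect_true(r$pattern %in% classes)
    # scale invariance: multiply values and ULN by the same constant
    k <- runif(1, 0.1, 10)
    r2 <- classify_ca19_9(s$days, s$values * k, 0,
                          marker_rules(ca19_9_uln = 37 * k))
    expect_identical(r2$pattern, r$pattern)
    expect_identical(r2$trigger, r$trigger)
  }
})

test_that("raising an in-window value keeps a first-documentation aberrant case aberrant", {
  withr::local_seed(7)
  checked <- 0
  while (checked < 50) {
    s <- random_series(c(5, 20, 40, 80), round(-runif(20, 0, 3) * DPY),
                       sample(2:6, 1))
    r <- classify_ca19_9(s$days, s$values, 0)
    if (r$pattern != "aberrant_elevation" ||
        r$trigger != "above_uln_first_time") next
    in_win <- which(s$days > -DPY)
    i <- in_win[sample.int(length(in_win), 1)]
    v2 <- s$values
    v2[i] <- v2[i] + runif(1, 1, 200)
    r2 <- classify_ca19_9(s$days, v2, 0)
    expect_equal(r2$pattern, "aberrant_elevation")
    checked <- checked + 1
  }
})

test_that("classifier agrees with the brute-force oracle on a coarse grid", {
  # exhaustive sweep: every value combination of a 4-point series
  grid <- c(10, 50, 120)
  days <- yr(c(1.5, 0.9, 0.5, 0.2))
  combos <- expand.grid(grid, grid, grid, grid)
  for (j in seq_len(nrow(combos))) {
    v <- as.numeric(combos[j, ])
    got <- classify_ca19_9(days, v, 0)
    want <- oracle_classify_ca199(days, v, 0)
    expect_identical(got$pattern, want$pattern)
    if (got$pattern == "aberrant_elevation") {
      expect_equal(-got$first_elevation_years * DPY, want$first_day)
    }
  }
  # randomised longer series on a finer grid
  withr::local_seed(99)
  for (i in 1:300) {
    s <- random_series(c(5, 18, 36, 37, 38, 74, 80, 200),
                       round(-runif(30, 0, 5) * DPY), sample(1:6, 1))
    got <- classify_ca19_9(s$days, s$values, 0)
    want <- oracle_classify_ca199(s$days, s$values, 0)
    expect_identical(got$pattern, want$pattern)
  }
})

test_that("low-to-low series never exceed the ULN", {
  withr::local_seed(1)
  for (i in 1:100) {
    s <- random_series(c(5, 20, 36, 40, 80), round(-runif(20, 0, 4) * DPY),
                       sample(1:6, 1))
    r <- classify_ca19_9(s$days, s$values, 0)
    if (r$pattern == "low_to_low") expect_lte(max(s$values), 37)
  }
})

test_that("cohort-level classification returns one row per diagnosed patient", {
  co <- tiny_cohort()
  tr <- classify_trajectories(co)
  expect_equal(nrow(tr), 1)  # P2 has no diagnosis
  expect_equal(tr$pattern, "aberrant_elevation")
  expect_false(tr$hba1c_elevated)
  g <- glance(tr)
  expect_equal(g$n_aberrant, 1)
})

test_that("removing Lewis-negative patients changes no retained classification", {
  gen <- generate_cohort(cohort_config(n_carcinoma = 60), seed = 11)
  tr <- classify_trajectories(gen$cohort)
  keep <- tr$patient_id[!tr$lewis_negative]
  co2 <- gen$cohort
  co2$patients <- co2$patients[co2$patients$patient_id %in% keep, ]
  co2$labs <- co2$labs[co2$labs$patient_id %in% keep, ]
  tr2 <- classify_trajectories(co2)
  m <- dplyr::inner_join(tr, tr2, by = "patient_id", suffix = c("", ".2"))
  expect_true(sum(tr$lewis_negative) > 0)
  expect_identical(m$pattern, m$pattern.2)
})
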