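# Synthetic cohort generator: determinism, validity, calibration.

test_that("the same seed reproduces the cohort exactly", {
  g1 <- generate_cohort(cohort_config(n_carcinoma = 30, n_noncancer = 5),
                        seed = 7)
  g2 <- generate_cohort(cohort_config(n_carcinoma = 30, n_noncancer = 5),
                        seed = 7)
  expect_identical(g1$cohort$patients, g2$cohort$patients)
  expect_identical(g1$cohort$labs, g2$cohort$labs)
  expect_identical(g1$cohort$imaging, g2$cohort$imaging)
  expect_identical(g1$cohort$events, g2$cohort$events)
  expect_identical(g1$truth, g2$truth)
})

test_that("generated cohorts satisfy the record invariants", {
  for (s in c(2, 13)) {
    gen <- generate_cohort(cohort_config(n_carcinoma = 50, n_noncancer = 10),
                           seed = s)
    expect_equal(nrow(validate_cohort(gen$cohort)), 0)
    pt <- gen$cohort$patients
    dx <- pt$dx_date[!is.na(pt$dx_date)]
    bl <- pt$baseline_date[!is.na(pt$dx_date)]
    expect_true(all(as.numeric(dx - bl) >= 182))
    expect_true(all(as.numeric(pt$last_date - pt$baseline_date) >= 182))
  }
})

test_that("a no-elevation configuration yields (almost) no positives", {
  cfg <- cohort_config(
    n_carcinoma = 60,
    p_aberrant = list(ipmn_derived = c(early = 0, late = 0),
                      concomitant_pdac = c(early = 0, late = 0)),
    p_high_to_high = c(ipmn_derived = 0, concomitant_pdac = 0),
    p_hba1c = 0, p_enzyme = c(ipmn_derived = 0, concomitant_pdac = 0))
  gen <- generate_cohort(cfg, seed = 17)
  tr <- classify_trajectories(gen$cohort)
  # false-positive rate of the rules on null series stays below ~5%
  expect_lte(sum(tr$pattern == "aberrant_elevation"), 3)
  expect_lte(sum(tr$enzyme_elevated), 3)
  expect_lte(sum(tr$hba1c_elevated), 2)
})

test_that("classifier recovers intended labels at default noise", {
  gen <- generate_cohort(cohort_config(), seed = 23)
  tr <- classify_trajectories(gen$cohort)
  m <- merge(tr, gen$truth, by = "patient_id")
  expect_gte(mean(m$pattern == m$pattern_intended), 0.95)
  expect_gte(mean(m$enzyme_elevated == m$enzyme_intended), 0.95)
  expect_gte(mean(m$hba1c_elevated == m$hba1c_intended), 0.95)
  expect_equal(sum(m$lewis_negative.x), sum(m$lewis_negative.y))
})

test_that("elevation is documented at the intended lead time", {
  gen <- generate_cohort(cohort_config(), seed = 29)
  tr <- classify_trajectories(gen$cohort)
  m <- merge(tr, gen$truth, by = "patient_id")
  ab <- m[m$pattern_intended == "aberrant_elevation" &
            m$pattern == "aberrant_elevation", ]
  expect_gt(nrow(ab), 20)
  # within one visit interval (and in practice at the documented onset)
  expect_true(all(abs(ab$first_elevation_years - ab$ca19_9_lead_years) <=
                    0.5 + 1e-6))
  expect_lt(median(abs(ab$first_elevation_years - ab$ca19_9_lead_years)),
            0.02)
})

test_that("prevalences recover the configured defaults within binomial error", {
  gen <- generate_cohort(cohort_config(n_carcinoma = 200), seed = 41)
  tr <- classify_trajectories(gen$cohort)
  ft <- evaluate_features(gen$cohort)
  fr <- first_feature_times(ft, gen$cohort)
  m <- merge(merge(tr, fr, by = "patient_id"), gen$truth, by = "patient_id")

  binom_bounds <- function(n, p) {
    c(stats::qbinom(0.025, n, p), stats::qbinom(0.975, n, p))
  }
  # expected aberrant fraction implied by the configuration
  cfg <- cohort_config()
  p_exp <- mean(vapply(c("ipmn_derived", "concomitant_pdac"), function(ty) {
    early <- sum(cfg$stage_probs[[ty]][c("0", "I", "II")])
    cfg$p_ca19_9_available[[ty]] *
      (early * cfg$p_aberrant[[ty]][["early"]] +
         (1 - early) * cfg$p_aberrant[[ty]][["late"]])
  }, 1))
  n_ab <- sum(m$pattern == "aberrant_elevation")
  b <- binom_bounds(200, p_exp)
  expect_gte(n_ab, b[1]); expect_lte(n_ab, b[2])

  n_enz <- sum(m$enzyme_elevated)
  expect_gte(n_enz, binom_bounds(200, 0.18)[1])
  expect_lte(n_enz, binom_bounds(200, 0.18)[2])

  for (ty in c("ipmn_derived", "concomitant_pdac")) {
    sub <- m[m$carcinoma_type == ty, ]
    p <- c(ipmn_derived = 0.86, concomitant_pdac = 0.16)[[ty]]
    n_hrs <- sum(!is.na(sub$t_first_hrs_years))
    b <- binom_bounds(nrow(sub), p)
    expect_gte(n_hrs, b[1]); expect_lte(n_hrs, b[2])
  }
  # lead-time distribution anchors (derived aberrant cases)
  lead <- m$first_elevation_years[m$carcinoma_type == "ipmn_derived" &
                                    m$pattern == "aberrant_elevation"]
  expect_gt(length(lead), 10)
  expect_lt(abs(median(lead) - 0.4), 0.25)
})

test_that("different seeds give statistically indistinguishable marker noise", {
  cfg <- cohort_config(n_carcinoma = 40)
  rejections <- 0
  # per-patient mean log values are the independent units (values within a
  # patient share a set-point, so a raw-value KS test would be invalid)
  patient_means <- function(g) {
    lb <- g$cohort$labs
    lip <- lb[lb$analyte == "lipase", ]
    tapply(log(lip$value), lip$patient_id, mean)
  }
  for (k in 1:6) {
    a <- generate_cohort(cfg, seed = 100 + k)
    b <- generate_cohort(cfg, seed = 200 + k)
    p <- suppressWarnings(
      stats::ks.test(patient_means(a), patient_means(b))$p.value)
    if (p < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 1)
})

test_that("the one feature-free concomitant case is honoured", {
  gen <- generate_cohort(cohort_config(), seed = 47)
  ft <- evaluate_features(gen$cohort)
  fr <- first_feature_times(ft, gen$cohort)
  m <- merge(fr, gen$truth, by = "patient_id")
  neg <- m[!m$any_wf_or_hrs_intended, ]
  expect_equal(nrow(neg), 1)
  expect_equal(neg$carcinoma_type, "concomitant_pdac")
  expect_true(is.na(neg$t_first_any_years))
})
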