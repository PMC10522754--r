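# Worrisome-feature / high-risk-stigmata rules engine.

wf_at <- function(features, day) {
  row <- features[features$day == day, ]
  if (!nrow(row) || row$wf == "") character(0) else
    strsplit(row$wf, ";")[[1]]
}
hrs_at <- function(features, day) {
  row <- features[features$day == day, ]
  if (!nrow(row) || row$hrs == "") character(0) else
    strsplit(row$hrs, ";")[[1]]
}

one_visit_cohort <- function(cyst = 15, mpd = 3, nodule = "absent",
                             ca19_9 = NULL, events = NULL,
                             location = NA_character_) {
  pt <- make_patient("P1", dx_days = 1000, carcinoma_type = "ipmn_derived",
                     clinical_stage = "II", location = location,
                     last_days = 1200, status = "dead")
  labs <- if (is.null(ca19_9)) empty_tbl() else
    make_labs("P1", 400, ca19_9)
  surveillance_cohort(
    pt, labs, make_imaging("P1", 500, cyst = cyst, mpd = mpd,
                           nodule = nodule),
    if (is.null(events)) ipmntraj:::empty_events() else events)
}
empty_tbl <- function() make_labs("P1", numeric(0), numeric(0))

test_that("worrisome-feature predicates fire on the guideline cutoffs", {
  ft <- evaluate_features(one_visit_cohort(cyst = 32, ca19_9 = 20))
  expect_setequal(wf_at(ft, 500), "size_ge_30mm")

  ft <- evaluate_features(one_visit_cohort(mpd = 7, ca19_9 = 45))
  expect_setequal(wf_at(ft, 500), c("mpd_5_to_9.9mm", "ca19_9_gt_37"))

  ft <- evaluate_features(one_visit_cohort())
  expect_length(wf_at(ft, 500), 0)
  expect_length(hrs_at(ft, 500), 0)
})

test_that("high-risk stigmata require their full conjunctions", {
  ft <- evaluate_features(one_visit_cohort(mpd = 11))
  expect_setequal(hrs_at(ft, 500), "mpd_ge_10mm")

  # jaundice without a head lesion is not a stigma
  ev <- make_events("P1", 300, "obstructive_jaundice")
  ft <- evaluate_features(one_visit_cohort(events = ev,
                                           location = "body_tail"))
  expect_length(hrs_at(ft, 500), 0)
  ft <- evaluate_features(one_visit_cohort(events = ev, location = "head"))
  expect_setequal(hrs_at(ft, 500), "obstructive_jaundice_head_lesion")

  ft <- evaluate_features(one_visit_cohort(
    mpd = 12, nodule = "present_ge5mm_enhancing"))
  expect_setequal(hrs_at(ft, 500), c("enhancing_nodule_ge_5mm",
                                     "mpd_ge_10mm"))

  # a non-enhancing nodule triggers neither nodule item
  ft <- evaluate_features(one_visit_cohort(nodule = "present_nonenhancing"))
  expect_length(hrs_at(ft, 500), 0)
  expect_length(wf_at(ft, 500), 0)
})

test_that("growth rule compares against any measurement in a 2-year window", {
  expect_true(growth_exceeds_threshold(c(-1.5 * DPY, 0), c(20, 26), 0))
  # no comparator inside the window
  expect_false(growth_exceeds_threshold(c(-3 * DPY, 0), c(20, 27), 0))
  # 2 mm per 6-month visit: first positive at the third visit after baseline
  days <- round(c(0, 0.5, 1, 1.5, 2) * DPY)
  sizes <- c(20, 22, 24, 26, 28)
  hits <- vapply(days, function(d)
    growth_exceeds_threshold(days, sizes, d), TRUE)
  expect_equal(hits, c(FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("first occurrences and lead times match direct arithmetic", {
  pt <- make_patient("P1", dx_days = 1000, carcinoma_type = "ipmn_derived",
                     clinical_stage = "II", last_days = 1200,
                     status = "dead")
  im <- make_imaging("P1", c(100, 416, 700), cyst = c(15, 32, 33))
  co <- surveillance_cohort(pt, empty_tbl(), im)
  ft <- evaluate_features(co)
  fr <- first_feature_times(ft, co)
  # WF first at dx - 584 days
  expect_equal(round(fr$wf_lead_years, 1), 1.6)
  expect_true(is.na(fr$hrs_lead_years))

  co_none <- surveillance_cohort(pt, empty_tbl(), make_imaging("P1", 500))
  fr <- first_feature_times(evaluate_features(co_none), co_none)
  expect_true(is.na(fr$t_first_wf_years))
  expect_true(is.na(fr$t_first_hrs_years))
})

test_that("event-based items accumulate monotonically", {
  ev <- make_events("P1", 300, "acute_pancreatitis")
  pt <- make_patient("P1", dx_days = 1000, carcinoma_type = "ipmn_derived",
                     clinical_stage = "II", last_days = 1200,
                     status = "dead")
  co <- surveillance_cohort(pt, empty_tbl(),
                            make_imaging("P1", c(100, 400, 700)), ev)
  ft <- evaluate_features(co)
  has_ap <- grepl("acute_pancreatitis", ft$wf)
  expect_equal(has_ap, c(FALSE, TRUE, TRUE))
})

test_that("feature sets use no look-ahead (truncation equivalence)", {
  gen <- generate_cohort(cohort_config(n_carcinoma = 20), seed = 5)
  co <- gen$cohort
  ft <- evaluate_features(co)
  cut <- 600  # days
  co2 <- co
  co2$labs <- co$labs[ave_day(co$labs, co$patients) <= cut, ]
  co2$imaging <- co$imaging[ave_day(co$imaging, co$patients) <= cut, ]
  co2$events <- co$events[ave_day(co$events, co$patients) <= cut, ]
  ft2 <- evaluate_features(co2)
  joint <- merge(ft[ft$day <= cut, ], ft2, by = c("patient_id", "day"))
  expect_gt(nrow(joint), 0)
  expect_identical(joint$wf.x, joint$wf.y)
  expect_identical(joint$hrs.x, joint$hrs.y)
})

test_that("all 12 predicates agree with the independent oracle", {
  withr::local_seed(31)
  for (rep in 1:40) {
    n_im <- sample(2:5, 1)
    im_days <- sort(sample(seq(0, 900, by = 30), n_im))
    imaging <- tibble::tibble(
      day = im_days,
      cyst_size_mm = sample(c(12, 28, 31, 40), n_im, TRUE),
      mpd_diameter_mm = sample(c(3, 6, 9.9, 10, 12), n_im, TRUE),
      mural_nodule = sample(c("absent", "present_lt5mm_enhancing",
                              "present_ge5mm_enhancing",
                              "present_nonenhancing"), n_im, TRUE),
      thickened_enhanced_wall = sample(c(TRUE, FALSE), n_im, TRUE),
      abrupt_caliber_change_with_atrophy = sample(c(TRUE, FALSE), n_im, TRUE),
      lymphadenopathy = sample(c(TRUE, FALSE), n_im, TRUE))
    ca <- tibble::tibble(day = sort(sample(seq(10, 900, 10), 3)),
                         value = sample(c(10, 36, 38, 80), 3, TRUE))
    events <- tibble::tibble(
      day = sample(seq(0, 900, 10), 2),
      kind = sample(c("acute_pancreatitis", "obstructive_jaundice"), 2))
    location <- sample(c("head", "body_tail"), 1)

    pt <- make_patient("P1", dx_days = 1000,
                       carcinoma_type = "ipmn_derived",
                       clinical_stage = "II", location = location,
                       last_days = 1200, status = "dead")
    co <- surveillance_cohort(
      pt,
      make_labs("P1", ca$day, ca$value),
      make_imaging("P1", imaging$day, cyst = imaging$cyst_size_mm,
                   mpd = imaging$mpd_diameter_mm,
                   nodule = imaging$mural_nodule,
                   wall = imaging$thickened_enhanced_wall,
                   abrupt = imaging$abrupt_caliber_change_with_atrophy,
                   lymph = imaging$lymphadenopathy),
      make_events("P1", events$day, events$kind))
    ft <- evaluate_features(co)
    for (d in ft$day) {
      want <- oracle_features_at(d, imaging, ca, events, location)
      expect_setequal(wf_at(ft, d), want$wf)
      expect_setequal(hrs_at(ft, d), want$hrs)
    }
  }
})
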