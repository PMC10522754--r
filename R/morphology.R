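# Rules engine for the 2017 international consensus guideline's worrisome
# features (WF) and high-risk stigmata (HRS), evaluated per visit with
# first-occurrence timing and lead times to carcinoma diagnosis.

WF_ITEMS <- c("size_ge_30mm", "nodule_lt5mm_enhancing", "thickened_wall",
              "mpd_5_to_9.9mm", "abrupt_caliber_change_atrophy",
              "lymphadenopathy", "ca19_9_gt_37", "growth_gt_5mm_per_2y",
              "acute_pancreatitis")
HRS_ITEMS <- c("obstructive_jaundice_head_lesion", "enhancing_nodule_ge_5mm",
               "mpd_ge_10mm")

#' Has the cyst grown by more than 5 mm within 2 years?
#'
#' The guideline growth criterion, read literally: true iff the current size
#' exceeds some earlier measurement taken within the preceding 2 years
#' (730.5 days) by more than 5 mm. No slope is fitted; a measurement older
#' than the window is never a comparator.
#'
#' @param days Measurement times, days.
#' @param sizes_mm Cyst sizes, mm.
#' @param at_day Evaluation time; the current size is the most recent
#'   measurement at or before `at_day`.
#' @return Logical scalar (`FALSE` when no comparator lies in the window).
#' @export
growth_exceeds_threshold <- function(days, sizes_mm, at_day) {
  stopifnot(length(days) == length(sizes_mm))
  days <- as.numeric(days); at_day <- as.numeric(at_day)
  keep <- !is.na(sizes_mm) & days <= at_day
  days <- days[keep]; sizes_mm <- sizes_mm[keep]
  if (!length(days)) return(FALSE)
  o <- order(days); days <- days[o]; sizes_mm <- sizes_mm[o]
  cur_day <- days[length(days)]; cur <- sizes_mm[length(sizes_mm)]
  prior <- days < cur_day & (cur_day - days) <= 2 * DAYS_PER_YEAR
  any(cur - sizes_mm[prior] > 5)
}

eval_patient_features <- function(pid, baseline, dx_date, location,
                                  imaging, labs, events, rules) {
  day_of <- function(d) as.numeric(d - baseline)
  im <- imaging[order(imaging$date), , drop = FALSE]
  ca <- labs[labs$analyte == "ca19_9", , drop = FALSE]
  ca <- ca[order(ca$date), , drop = FALSE]

  # evaluation dates: all imaging dates plus lab dates (CA19-9 can first
  # document a worrisome feature at an interim blood test)
  eval_days <- sort(unique(c(day_of(im$date), day_of(ca$date))))
  if (!length(eval_days)) {
    return(tibble(patient_id = character(), day = double(),
                  wf = character(), hrs = character(),
                  n_wf = integer(), n_hrs = integer()))
  }
  im_days <- day_of(im$date)
  idx <- findInterval(eval_days, im_days)  # last imaging at or before date
  pick_im <- function(col) {
    v <- im[[col]]
    v[ifelse(idx == 0, NA, idx)]
  }
  size  <- pick_im("cyst_size_mm")
  mpd   <- pick_im("mpd_diameter_mm")
  nod   <- pick_im("mural_nodule")
  wall  <- pick_im("thickened_enhanced_wall")
  abrupt <- pick_im("abrupt_caliber_change_with_atrophy")
  lymph <- pick_im("lymphadenopathy")

  ca_days <- day_of(ca$date)
  ca_idx <- findInterval(eval_days, ca_days)
  ca_val <- ca$value[ifelse(ca_idx == 0, NA, ca_idx)]

  ap_day <- suppressWarnings(
    min(day_of(events$date[events$kind == "acute_pancreatitis"])))
  oj_day <- suppressWarnings(
    min(day_of(events$date[events$kind == "obstructive_jaundice"])))

  growth <- vapply(eval_days, function(d)
    growth_exceeds_threshold(im_days, im$cyst_size_mm, d), TRUE)

  wf <- cbind(
    size_ge_30mm = !is.na(size) & size >= 30,
    nodule_lt5mm_enhancing = !is.na(nod) & nod == "present_lt5mm_enhancing",
    thickened_wall = !is.na(wall) & wall,
    `mpd_5_to_9.9mm` = !is.na(mpd) & mpd >= 5 & mpd < 10,
    abrupt_caliber_change_atrophy = !is.na(abrupt) & abrupt,
    lymphadenopathy = !is.na(lymph) & lymph,
    ca19_9_gt_37 = !is.na(ca_val) & ca_val > rules$ca19_9_uln,
    growth_gt_5mm_per_2y = growth,
    acute_pancreatitis = eval_days >= ap_day
  )
  hrs <- cbind(
    obstructive_jaundice_head_lesion =
      eval_days >= oj_day & !is.na(location) & location == "head",
    enhancing_nodule_ge_5mm = !is.na(nod) & nod == "present_ge5mm_enhancing",
    mpd_ge_10mm = !is.na(mpd) & mpd >= 10
  )
  collapse <- function(m) {
    apply(m, 1, function(r) paste(colnames(m)[r], collapse = ";"))
  }
  n_wf <- as.integer(rowSums(wf)); n_hrs <- as.integer(rowSums(hrs))
  tibble(patient_id = pid, day = eval_days,
         wf = collapse(wf), hrs = collapse(hrs),
         n_wf = n_wf, n_hrs = n_hrs)
}

#' Evaluate worrisome features and high-risk stigmata at every visit
#'
#' Applies the guideline's 9 worrisome-feature and 3 high-risk-stigmata
#' predicates at every imaging and laboratory date of every patient, with no
#' look-ahead: each evaluation uses only data dated at or before the visit.
#' Imaging items use the most recent assessment at or before the visit;
#' the CA19-9 item uses the most recent value at or before the visit;
#' event-based items (acute pancreatitis, obstructive jaundice) persist once
#' observed. The jaundice stigma additionally requires a pancreatic-head
#' lesion (taken from the diagnosis location).
#'
#' @param cohort A [surveillance_cohort()].
#' @param rules A [marker_rules()] object (supplies the CA19-9 ULN).
#' @return A tibble of class `feature_timeline`: `patient_id`, `day` (days
#'   since baseline), `years` (since baseline), `wf` and `hrs`
#'   (semicolon-separated item lists), `n_wf`, `n_hrs`.
#' @export
evaluate_features <- function(cohort, rules = marker_rules()) {
  stopifnot(inherits(cohort, "surveillance_cohort"))
  pt <- cohort$patients
  im_by <- split(cohort$imaging, cohort$imaging$patient_id)
  lab_by <- split(cohort$labs, cohort$labs$patient_id)
  ev_by <- split(cohort$events, cohort$events$patient_id)
  out <- purrr::pmap(
    list(pt$patient_id, pt$baseline_date, pt$dx_date, pt$location),
    function(pid, baseline, dx_date, location) {
      eval_patient_features(
        pid, baseline, dx_date, location,
        im_by[[pid]] %||% empty_imaging(),
        lab_by[[pid]] %||% empty_labs(),
        ev_by[[pid]] %||% empty_events(),
        rules)
    })
  out <- bind_rows(out)
  out$years <- out$day / DAYS_PER_YEAR
  out <- out[c("patient_id", "day", "years", "wf", "hrs", "n_wf", "n_hrs")]
  class(out) <- c("feature_timeline", class(out))
  out
}

#' First-occurrence times and lead times of WF / HRS
#'
#' For each patient, the earliest visit at which the worrisome-feature set,
#' the high-risk-stigmata set, or their union is nonempty, plus lead times to
#' carcinoma diagnosis. A patient who never becomes positive has `NA` times
#' (one concomitant carcinoma in the motivating study never did).
#'
#' @param features Output of [evaluate_features()].
#' @param cohort The same [surveillance_cohort()] (supplies diagnosis dates).
#' @return A tibble, one row per patient: `patient_id`, `t_first_wf_years`,
#'   `t_first_hrs_years`, `t_first_any_years` (years since baseline),
#'   `wf_lead_years`, `hrs_lead_years`, `any_lead_years` (years before
#'   diagnosis; `NA` without diagnosis or occurrence).
#' @export
first_feature_times <- function(features, cohort) {
  stopifnot(inherits(cohort, "surveillance_cohort"))
  pt <- cohort$patients
  firsts <- features |>
    group_by(.data$patient_id) |>
    summarise(
      t_first_wf_years = suppressWarnings(min(.data$years[.data$n_wf > 0])),
      t_first_hrs_years = suppressWarnings(min(.data$years[.data$n_hrs > 0])),
      t_first_any_years = suppressWarnings(
        min(.data$years[.data$n_wf + .data$n_hrs > 0])),
      .groups = "drop") |>
    mutate(across(starts_with("t_first"),
                  \(x) ifelse(is.finite(x), x, NA_real_)))
  out <- pt |>
    transmute(.data$patient_id,
              dx_years = as.numeric(.data$dx_date - .data$baseline_date) /
                DAYS_PER_YEAR) |>
    left_join(firsts, by = "patient_id") |>
    mutate(wf_lead_years = .data$dx_years - .data$t_first_wf_years,
           hrs_lead_years = .data$dx_years - .data$t_first_hrs_years,
           any_lead_years = .data$dx_years - .data$t_first_any_years) |>
    select(-"dx_years")
  out
}
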