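# Hand-built cohort fixtures, constructed in code.

d0 <- as.Date("2015-01-01")

make_patient <- function(patient_id = "P1", baseline = d0,
                         dx_days = NA, carcinoma_type = NA_character_,
                         clinical_stage = NA_character_,
                         location = NA_character_,
                         last_days = 3000, status = "alive_censored") {
  tibble::tibble(
    patient_id = patient_id, baseline_date = baseline,
    age_at_baseline = 70, sex = "female", ipmn_type = "branch_duct",
    smoking = "never", bmi = 22, diabetes = "absent",
    family_history_pc = FALSE,
    dx_date = if (is.na(dx_days)) as.Date(NA) else baseline + dx_days,
    carcinoma_type = carcinoma_type, clinical_stage = clinical_stage,
    pathological_stage = NA_character_, location = location,
    last_date = baseline + last_days, status = status)
}

make_labs <- function(patient_id, days, values, analyte = "ca19_9",
                      unit = "U/mL", detection_limit = NA_real_,
                      baseline = d0) {
  tibble::tibble(patient_id = patient_id, date = baseline + days,
                 analyte = analyte, value = values, unit = unit,
                 detection_limit = detection_limit)
}

make_imaging <- function(patient_id, days, cyst = 15, mpd = 3,
                         nodule = "absent", wall = FALSE, abrupt = FALSE,
                         lymph = FALSE, solid = FALSE, baseline = d0) {
  n <- length(days)
  tibble::tibble(
    patient_id = patient_id, date = baseline + days, modality = "MRI_MRCP",
    cyst_size_mm = rep_len(cyst, n), mpd_diameter_mm = rep_len(mpd, n),
    mural_nodule = rep_len(nodule, n),
    thickened_enhanced_wall = rep_len(wall, n),
    abrupt_caliber_change_with_atrophy = rep_len(abrupt, n),
    lymphadenopathy = rep_len(lymph, n),
    solid_mass_detected = rep_len(solid, n))
}

make_events <- function(patient_id, days, kind, baseline = d0) {
  tibble::tibble(patient_id = patient_id, date = baseline + days, kind = kind)
}

# a small fully consistent cohort: one diagnosed and one surveilled patient
tiny_cohort <- function() {
  patients <- dplyr::bind_rows(
    make_patient("P1", dx_days = 1000, carcinoma_type = "ipmn_derived",
                 clinical_stage = "II", location = "head",
                 last_days = 1400, status = "dead"),
    make_patient("P2", last_days = 900))
  labs <- dplyr::bind_rows(
    make_labs("P1", c(0, 400, 800, 950, 1000), c(10, 12, 11, 80, 120)),
    make_labs("P1", c(0, 400, 800, 1000), c(6.0, 6.1, 6.0, 6.1),
              analyte = "hba1c", unit = "%"),
    make_labs("P2", c(0, 300, 600), c(8, 9, 8)))
  imaging <- dplyr::bind_rows(
    make_imaging("P1", c(0, 400, 800), cyst = c(18, 19, 32),
                 mpd = c(3, 6, 11)),
    make_imaging("P2", c(0, 400, 800)))
  events <- make_events("P1", 900, "acute_pancreatitis")
  surveillance_cohort(patients, labs, imaging, events)
}

# days since each row's patient baseline
ave_day <- function(df, patients) {
  bl <- stats::setNames(patients$baseline_date, patients$patient_id)
  as.numeric(df$date - bl[df$patient_id])
}

# random lab series on a coarse grid for oracle-equivalence sweeps
random_series <- function(rng_values, rng_days, n) {
  days <- sort(sample(rng_days, n))
  values <- sample(rng_values, n, replace = TRUE)
  list(days = days, values = values)
}
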