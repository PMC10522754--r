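# Surveillance cohort data model: four tidy tables (patients, labs, imaging,
# events) bundled into a `surveillance_cohort` object, plus CSV readers/writers
# and study-eligibility validation.

ANALYTES   <- c("ca19_9", "cea", "hba1c", "amylase", "p_amylase", "lipase")
MODALITIES <- c("MRI_MRCP", "CT", "AUS", "EUS")
NODULE_LEVELS <- c("absent", "present_lt5mm_enhancing", "present_ge5mm_enhancing",
                   "present_nonenhancing")
EVENT_KINDS <- c("acute_pancreatitis", "obstructive_jaundice", "diabetes_onset",
                 "symptom_onset")
SEX_LEVELS      <- c("male", "female")
IPMN_TYPES      <- c("branch_duct", "main_duct", "mixed")
SMOKING_LEVELS  <- c("never", "past_current")
DIABETES_LEVELS <- c("absent", "recent_onset_lt2y", "unknown_onset",
                     "long_standing_ge2y")
CARCINOMA_TYPES <- c("ipmn_derived", "concomitant_pdac")
STAGE_LEVELS    <- c("0", "I", "II", "III", "IV")
LOCATION_LEVELS <- c("head", "body_tail")
STATUS_LEVELS   <- c("dead", "alive_censored")

PATIENT_COLS <- c("patient_id", "baseline_date", "age_at_baseline", "sex",
                  "ipmn_type", "smoking", "bmi", "diabetes", "family_history_pc",
                  "dx_date", "carcinoma_type", "clinical_stage",
                  "pathological_stage", "location", "last_date", "status")
LAB_COLS     <- c("patient_id", "date", "analyte", "value", "unit",
                  "detection_limit")
IMAGING_COLS <- c("patient_id", "date", "modality", "cyst_size_mm",
                  "mpd_diameter_mm", "mural_nodule", "thickened_enhanced_wall",
                  "abrupt_caliber_change_with_atrophy", "lymphadenopathy",
                  "solid_mass_detected")
EVENT_COLS   <- c("patient_id", "date", "kind")

check_codes <- function(x, allowed, what, allow_na = FALSE) {
  bad <- if (allow_na) which(!is.na(x) & !x %in% allowed) else
    which(is.na(x) | !x %in% allowed)
  if (length(bad)) {
    stop(sprintf("unknown %s code(s) at row(s) %s: %s", what,
                 paste(head(bad, 5), collapse = ", "),
                 paste(unique(x[head(bad, 5)]), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

#' Bundle the four surveillance tables into a cohort object
#'
#' A surveillance cohort is a list of four tibbles (`patients`, `labs`,
#' `imaging`, `events`) sharing a `patient_id` key. The constructor checks
#' coded values against their closed sets, rejects duplicate same-day
#' measurements of one analyte (the trajectory rules depend on "first
#' documentation", so ambiguity is surfaced rather than averaged), and sorts
#' all time-stamped tables by patient and date.
#'
#' @param patients,labs,imaging,events Data frames with the columns described
#'   in [read_cohort()]. `labs`, `imaging`, `events` may be empty.
#' @return An object of class `surveillance_cohort`.
#' @seealso [read_cohort()], [write_cohort()], [validate_cohort()]
#' @export
surveillance_cohort <- function(patients,
                                labs = empty_labs(),
                                imaging = empty_imaging(),
                                events = empty_events()) {
  patients <- as_tibble(patients)
  labs     <- as_tibble(labs)
  imaging  <- as_tibble(imaging)
  events   <- as_tibble(events)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(sprintf("%s table is missing column(s): %s",
                                   what, paste(miss, collapse = ", ")),
                           call. = FALSE)
    df[cols]
  }
  patients <- need(patients, PATIENT_COLS, "patients")
  labs     <- need(labs, LAB_COLS, "labs")
  imaging  <- need(imaging, IMAGING_COLS, "imaging")
  events   <- need(events, EVENT_COLS, "events")

  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id in patients table: ",
         paste(unique(patients$patient_id[duplicated(patients$patient_id)]),
               collapse = ", "), call. = FALSE)
  }
  check_codes(patients$sex, SEX_LEVELS, "sex")
  check_codes(patients$ipmn_type, IPMN_TYPES, "ipmn_type")
  check_codes(patients$smoking, SMOKING_LEVELS, "smoking")
  check_codes(patients$diabetes, DIABETES_LEVELS, "diabetes")
  check_codes(patients$carcinoma_type, CARCINOMA_TYPES, "carcinoma_type",
              allow_na = TRUE)
  check_codes(as.character(patients$clinical_stage), STAGE_LEVELS,
              "clinical_stage", allow_na = TRUE)
  check_codes(as.character(patients$pathological_stage), STAGE_LEVELS,
              "pathological_stage", allow_na = TRUE)
  check_codes(patients$location, LOCATION_LEVELS, "location", allow_na = TRUE)
  check_codes(patients$status, STATUS_LEVELS, "status")
  check_codes(labs$analyte, ANALYTES, "analyte")
  check_codes(imaging$modality, MODALITIES, "modality")
  check_codes(imaging$mural_nodule, NODULE_LEVELS, "mural_nodule",
              allow_na = TRUE)
  check_codes(events$kind, EVENT_KINDS, "event kind")

  dup <- duplicated(labs[c("patient_id", "date", "analyte")])
  if (any(dup)) {
    stop("duplicate (patient_id, date, analyte) lab measurement(s) at row(s) ",
         paste(head(which(dup), 5), collapse = ", "), call. = FALSE)
  }

  labs    <- arrange(labs, .data$patient_id, .data$analyte, .data$date)
  imaging <- arrange(imaging, .data$patient_id, .data$date)
  events  <- arrange(events, .data$patient_id, .data$date)
  patients <- arrange(patients, .data$patient_id)

  structure(list(patients = patients, labs = labs, imaging = imaging,
                 events = events),
            class = "surveillance_cohort")
}

empty_labs <- function() {
  tibble(patient_id = character(), date = as.Date(character()),
         analyte = character(), value = double(), unit = character(),
         detection_limit = double())
}
empty_imaging <- function() {
  tibble(patient_id = character(), date = as.Date(character()),
         modality = character(), cyst_size_mm = double(),
         mpd_diameter_mm = double(), mural_nodule = character(),
         thickened_enhanced_wall = logical(),
         abrupt_caliber_change_with_atrophy = logical(),
         lymphadenopathy = logical(), solid_mass_detected = logical())
}
empty_events <- function() {
  tibble(patient_id = character(), date = as.Date(character()),
         kind = character())
}

#' @export
print.surveillance_cohort <- function(x, ...) {
  n_dx <- sum(!is.na(x$patients$dx_date))
  cat(sprintf(
    "<surveillance_cohort> %d patients (%d with carcinoma diagnosis)\n",
    nrow(x$patients), n_dx))
  cat(sprintf("  labs: %d rows | imaging: %d rows | events: %d rows\n",
              nrow(x$labs), nrow(x$imaging), nrow(x$events)))
  invisible(x)
}

#' Read a surveillance cohort from tidy CSV tables
#'
#' Reads the four-table interchange format (UTF-8, header row, ISO-8601
#' dates, empty cells for missing values) and returns a validated
#' [surveillance_cohort()]. Unknown analyte/modality codes and duplicate
#' `(patient, date, analyte)` lab rows are rejected with the offending row
#' numbers.
#'
#' @param dir Directory containing `patients.csv`, `labs.csv`, `imaging.csv`,
#'   `events.csv`; alternatively give the four paths explicitly.
#' @param patients,labs,imaging,events Paths to the individual CSV files.
#' @return A `surveillance_cohort`.
#' @export
read_cohort <- function(dir = NULL,
                        patients = file.path(dir, "patients.csv"),
                        labs = file.path(dir, "labs.csv"),
                        imaging = file.path(dir, "imaging.csv"),
                        events = file.path(dir, "events.csv")) {
  pt <- readr::read_csv(patients, col_types = readr::cols(
    patient_id = "c", baseline_date = "D", age_at_baseline = "d", sex = "c",
    ipmn_type = "c", smoking = "c", bmi = "d", diabetes = "c",
    family_history_pc = "l", dx_date = "D", carcinoma_type = "c",
    clinical_stage = "c", pathological_stage = "c", location = "c",
    last_date = "D", status = "c"), progress = FALSE)
  lb <- readr::read_csv(labs, col_types = readr::cols(
    patient_id = "c", date = "D", analyte = "c", value = "d", unit = "c",
    detection_limit = "d"), progress = FALSE)
  im <- readr::read_csv(imaging, col_types = readr::cols(
    patient_id = "c", date = "D", modality = "c", cyst_size_mm = "d",
    mpd_diameter_mm = "d", mural_nodule = "c", thickened_enhanced_wall = "l",
    abrupt_caliber_change_with_atrophy = "l", lymphadenopathy = "l",
    solid_mass_detected = "l"), progress = FALSE)
  ev <- readr::read_csv(events, col_types = readr::cols(
    patient_id = "c", date = "D", kind = "c"), progress = FALSE)
  surveillance_cohort(pt, lb, im, ev)
}

#' Write a surveillance cohort to tidy CSV tables
#'
#' Inverse of [read_cohort()]: writes `patients.csv`, `labs.csv`,
#' `imaging.csv`, `events.csv` with ISO-8601 dates and empty cells for
#' missing values, so that `read_cohort(write_cohort(x, d))` round-trips up
#' to row order and float formatting.
#'
#' @param cohort A `surveillance_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "surveillance_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$patients, file.path(dir, "patients.csv"), na = "")
  readr::write_csv(cohort$labs, file.path(dir, "labs.csv"), na = "")
  readr::write_csv(cohort$imaging, file.path(dir, "imaging.csv"), na = "")
  readr::write_csv(cohort$events, file.path(dir, "events.csv"), na = "")
  invisible(dir)
}

violation <- function(patient_id, rule, detail) {
  tibble(patient_id = patient_id, rule = rule, detail = detail)
}

#' Validate study-eligibility rules and record invariants
#'
#' Checks every patient record against the type invariants and the study's
#' eligibility rules: follow-up of at least 6 months, no carcinoma diagnosis
#' within 6 months of the baseline IPMN diagnosis, all time-stamped entries
#' inside the follow-up interval, non-negative lab values, plausible imaging
#' sizes (\eqn{\le} 300 mm), unit consistency within one analyte series, and
#' follow-up end on or after diagnosis. Violations are returned as data, not
#' raised as errors.
#'
#' @param cohort A `surveillance_cohort`.
#' @return A tibble with columns `patient_id`, `rule`, `detail`; zero rows
#'   when the cohort is fully consistent. Idempotent and insensitive to input
#'   row order.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "surveillance_cohort"))
  pt <- cohort$patients
  out <- list()

  fu_days <- as.numeric(pt$last_date - pt$baseline_date)
  short <- which(fu_days < DAYS_PER_YEAR / 2)
  if (length(short)) out <- c(out, list(violation(
    pt$patient_id[short], "followup_lt_6_months",
    sprintf("follow-up %.0f days < 182.6", fu_days[short]))))

  has_dx <- !is.na(pt$dx_date)
  dx_days <- as.numeric(pt$dx_date - pt$baseline_date)
  early <- which(has_dx & dx_days < DAYS_PER_YEAR / 2)
  if (length(early)) out <- c(out, list(violation(
    pt$patient_id[early], "diagnosis_within_6_months",
    sprintf("diagnosis %.0f days after baseline", dx_days[early]))))

  after <- which(has_dx & pt$last_date < pt$dx_date)
  if (length(after)) out <- c(out, list(violation(
    pt$patient_id[after], "followup_ends_before_diagnosis",
    format(pt$last_date[after]))))

  dx_no_type <- which(has_dx & is.na(pt$carcinoma_type))
  if (length(dx_no_type)) out <- c(out, list(violation(
    pt$patient_id[dx_no_type], "diagnosis_missing_type",
    "dx_date present but carcinoma_type missing")))

  bounds <- pt[c("patient_id", "baseline_date", "last_date")]
  check_window <- function(df, what) {
    j <- left_join(df, bounds, by = "patient_id")
    res <- list()
    bad <- which(is.na(j$baseline_date))
    if (length(bad)) res <- c(res, list(violation(
      j$patient_id[bad], "unknown_patient", paste(what, "row for unlisted patient"))))
    pre <- which(!is.na(j$baseline_date) & j$date < j$baseline_date)
    if (length(pre)) res <- c(res, list(violation(
      j$patient_id[pre], "entry_before_baseline",
      paste(what, format(j$date[pre])))))
    post <- which(!is.na(j$baseline_date) & j$date > j$last_date)
    if (length(post)) res <- c(res, list(violation(
      j$patient_id[post], "entry_after_followup_end",
      paste(what, format(j$date[post])))))
    res
  }
  out <- c(out, check_window(cohort$labs, "lab"),
           check_window(cohort$imaging, "imaging"),
           check_window(cohort$events, "event"))

  neg <- which(!is.na(cohort$labs$value) & cohort$labs$value < 0)
  if (length(neg)) out <- c(out, list(violation(
    cohort$labs$patient_id[neg], "negative_lab_value",
    sprintf("%s = %g", cohort$labs$analyte[neg], cohort$labs$value[neg]))))

  mixed <- cohort$labs |>
    group_by(.data$patient_id, .data$analyte) |>
    summarise(n_units = n_distinct(.data$unit), .groups = "drop") |>
    filter(.data$n_units > 1)
  if (nrow(mixed)) out <- c(out, list(violation(
    mixed$patient_id, "mixed_units_in_series", mixed$analyte)))

  im <- cohort$imaging
  for (col in c("cyst_size_mm", "mpd_diameter_mm")) {
    bad <- which(!is.na(im[[col]]) & (im[[col]] < 0 | im[[col]] > 300))
    if (length(bad)) out <- c(out, list(violation(
      im$patient_id[bad], "implausible_size",
      sprintf("%s = %g mm", col, im[[col]][bad]))))
  }

  if (!length(out)) return(violation(character(), character(), character()))
  arrange(bind_rows(out), .data$patient_id, .data$rule)
}
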