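# Prediagnostic blood-marker rules: cumulative-average reference, CA19-9
# trajectory patterns, HbA1c and pancreatic-enzyme elevation detection, lead
# times, and the Lewis-antigen-negative flag.

PATTERN_LEVELS <- c("aberrant_elevation", "high_to_high", "low_to_low",
                    "residual_unclassified", "insufficient_data")

#' Marker rule thresholds
#'
#' Container for the thresholds used by the trajectory and elevation rules.
#' Defaults follow the study conventions: CA19-9 upper limit of normal (ULN)
#' 37 U/mL; a 1-year prediagnostic window, read as the half-open interval
#' `(dx - 365.25 d, dx]`; HbA1c elevation at a 4 mmol/mol rise over the
#' cumulative average; enzyme elevation at more than 3 times the ULN together
#' with at least doubling of the cumulative average. The enzyme ULNs
#' (pancreatic amylase 50 U/L, lipase 60 U/L) are common laboratory limits
#' and can be overridden to match a local assay.
#'
#' `doubling_inclusive = TRUE` reads "doubling" as `>= 2 x` the cumulative
#' average (for both CA19-9 and enzymes); the ULN comparison `> 37` is always
#' strict.
#'
#' @param ca19_9_uln CA19-9 upper limit of normal, U/mL.
#' @param window_years Length of the prediagnostic window, years.
#' @param hba1c_delta_mmol_mol HbA1c rise over the cumulative average that
#'   counts as elevation, mmol/mol (IFCC).
#' @param enzyme_uln_multiple Enzyme values must exceed this multiple of the
#'   analyte ULN.
#' @param enzyme_doubling_factor Enzyme values must reach this multiple of
#'   the cumulative average.
#' @param p_amylase_uln,lipase_uln Enzyme upper limits of normal, U/L.
#' @param ca19_9_doubling_factor Multiple of the cumulative average that
#'   counts as CA19-9 doubling.
#' @param doubling_inclusive Whether the doubling comparisons are inclusive
#'   (`>=`) rather than strict.
#' @return A list of class `marker_rules`.
#' @export
marker_rules <- function(ca19_9_uln = 37,
                         window_years = 1,
                         hba1c_delta_mmol_mol = 4,
                         enzyme_uln_multiple = 3,
                         enzyme_doubling_factor = 2,
                         p_amylase_uln = 50,
                         lipase_uln = 60,
                         ca19_9_doubling_factor = 2,
                         doubling_inclusive = TRUE) {
  rules <- list(ca19_9_uln = ca19_9_uln, window_years = window_years,
                hba1c_delta_mmol_mol = hba1c_delta_mmol_mol,
                enzyme_uln_multiple = enzyme_uln_multiple,
                enzyme_doubling_factor = enzyme_doubling_factor,
                p_amylase_uln = p_amylase_uln, lipase_uln = lipase_uln,
                ca19_9_doubling_factor = ca19_9_doubling_factor,
                doubling_inclusive = doubling_inclusive)
  num <- vapply(rules[names(rules) != "doubling_inclusive"], is.numeric, TRUE)
  if (!all(num)) stop("marker rule thresholds must be numeric", call. = FALSE)
  if (any(unlist(rules[names(num)[num]]) <= 0))
    stop("marker rule thresholds must be positive", call. = FALSE)
  structure(rules, class = "marker_rules")
}

#' Cumulative average of all prior measurements
#'
#' The individualised reference value: the arithmetic mean of all values
#' measured strictly before time `at`. The index measurement is excluded so
#' that a new value is always compared against prior data only.
#'
#' @param values Numeric measurements.
#' @param times Measurement times (any orderable scale; same length as
#'   `values`).
#' @param at Query time.
#' @return The mean of `values[times < at]`, or `NA` if no prior value
#'   exists.
#' @export
cumulative_average <- function(values, times, at) {
  stopifnot(length(values) == length(times))
  prior <- as.numeric(times) < as.numeric(at)
  if (!any(prior)) return(NA_real_)
  mean(values[prior])
}

# running strict-prefix mean: element i is the mean of values[1..i-1], NA at i=1
prefix_means <- function(values) {
  n <- length(values)
  if (n == 0) return(numeric(0))
  c(NA_real_, cumsum(values)[-n] / seq_len(n - 1))
}

# geq respecting the inclusive/strict doubling convention
dbl_cmp <- function(x, y, inclusive) if (inclusive) x >= y else x > y

#' Classify a prediagnostic CA19-9 trajectory
#'
#' Assigns one of five mutually exclusive patterns to a CA19-9 series
#' relative to a carcinoma diagnosis date:
#'
#' * `insufficient_data` — no measurement inside the 1-year window
#'   `(dx - 365.25 d, dx]`;
#' * `aberrant_elevation` — some in-window value exceeds the ULN (37 U/mL)
#'   either as the first documentation above the ULN (all earlier values at
#'   or below it) or as a doubling of the cumulative average of all prior
#'   values (the doubled value itself also above the ULN);
#' * `low_to_low` — every prediagnostic value at or below the ULN;
#' * `high_to_high` — elevated from the first measurement onwards with no
#'   in-window doubling of the cumulative average;
#' * `residual_unclassified` — anything else (e.g. a first exceedance more
#'   than a year before diagnosis that never doubles in-window).
#'
#' @param days Measurement times in days (any common origin), one per value.
#' @param values CA19-9 values, U/mL.
#' @param dx_day Diagnosis time on the same day scale.
#' @param rules A [marker_rules()] object.
#' @return A one-row tibble: `pattern`, `trigger`
#'   (`above_uln_first_time` / `doubling_of_cumavg`, `NA` unless aberrant),
#'   `first_elevation_years` (years before diagnosis of the earliest
#'   qualifying value, `NA` unless aberrant), and `n_in_window`.
#' @export
classify_ca19_9 <- function(days, values, dx_day, rules = marker_rules()) {
  stopifnot(length(days) == length(values), length(dx_day) == 1,
            !is.na(dx_day))
  days <- as.numeric(days); dx_day <- as.numeric(dx_day)
  keep <- !is.na(values) & days <= dx_day
  days <- days[keep]; values <- values[keep]
  o <- order(days); days <- days[o]; values <- values[o]

  uln <- rules$ca19_9_uln
  win_lo <- dx_day - rules$window_years * DAYS_PER_YEAR
  in_win <- days > win_lo
  res <- function(pattern, trigger = NA_character_, first_day = NA_real_) {
    tibble(pattern = pattern, trigger = trigger,
           first_elevation_years = (dx_day - first_day) / DAYS_PER_YEAR,
           n_in_window = sum(in_win))
  }
  if (!any(in_win)) return(res("insufficient_data"))

  above <- values > uln
  # index i qualifies as "first documentation above ULN" iff above[i] and no
  # earlier value is above
  first_doc <- above & (cumsum(above) == 1)
  cavg <- prefix_means(values)
  doubles <- above & !is.na(cavg) &
    dbl_cmp(values, rules$ca19_9_doubling_factor * cavg,
            rules$doubling_inclusive)

  qual <- in_win & (first_doc | doubles)
  if (any(qual)) {
    i <- which(qual)[1]
    trigger <- if (first_doc[i]) "above_uln_first_time" else "doubling_of_cumavg"
    return(res("aberrant_elevation", trigger, days[i]))
  }
  if (!any(above)) return(res("low_to_low"))
  # in-window doubling of the cumulative average, regardless of level
  any_dbl_in_win <- any(in_win & !is.na(cavg) &
                          dbl_cmp(values, rules$ca19_9_doubling_factor * cavg,
                                  rules$doubling_inclusive))
  if (above[1] && !any_dbl_in_win) return(res("high_to_high"))
  res("residual_unclassified")
}

#' Convert HbA1c between NGSP percent and IFCC mmol/mol
#'
#' Uses the IFCC master-equation linear map
#' \eqn{\mathrm{IFCC} = 10.93 \times \mathrm{NGSP} - 23.50}.
#'
#' @param x HbA1c values.
#' @param from Unit of `x`: `"%"` (NGSP) or `"mmol/mol"` (IFCC).
#' @return Values in the other unit.
#' @export
convert_hba1c <- function(x, from = c("%", "mmol/mol")) {
  from <- match.arg(from)
  if (from == "%") 10.93 * x - 23.50 else (x + 23.50) / 10.93
}

hba1c_to_ifcc <- function(values, unit) {
  unit <- unique(unit[!is.na(unit)])
  if (length(unit) > 1)
    stop("mixed HbA1c units within one series: ",
         paste(unit, collapse = ", "), call. = FALSE)
  if (!length(unit)) return(values)
  if (!unit %in% c("%", "mmol/mol"))
    stop("unsupported HbA1c unit: ", unit, call. = FALSE)
  if (unit == "%") convert_hba1c(values, "%") else values
}

#' Detect prediagnostic HbA1c elevation
#'
#' HbA1c elevation is a rise of at least 4 mmol/mol over the cumulative
#' average of all prior measurements, occurring inside the 1-year window
#' before diagnosis. Values in NGSP percent are converted to IFCC mmol/mol
#' via [convert_hba1c()] before comparison.
#'
#' @param days,values Measurement times (days) and HbA1c values.
#' @param unit Unit of `values`: `"%"` or `"mmol/mol"` (scalar or per-value;
#'   mixed units are rejected).
#' @param dx_day Diagnosis time, days.
#' @param rules A [marker_rules()] object.
#' @return One-row tibble: `elevated` (logical), `first_elevation_years`.
#' @export
detect_hba1c_elevation <- function(days, values, unit, dx_day,
                                   rules = marker_rules()) {
  stopifnot(length(days) == length(values))
  days <- as.numeric(days); dx_day <- as.numeric(dx_day)
  keep <- !is.na(values) & days <= dx_day
  days <- days[keep]
  values <- hba1c_to_ifcc(values, rep_len(unit, length(keep))[keep])
  o <- order(days); days <- days[o]; values <- values[o]
  win_lo <- dx_day - rules$window_years * DAYS_PER_YEAR
  cavg <- prefix_means(values)
  hit <- days > win_lo & !is.na(cavg) &
    values - cavg >= rules$hba1c_delta_mmol_mol
  if (!any(hit)) {
    return(tibble(elevated = FALSE, first_elevation_years = NA_real_))
  }
  tibble(elevated = TRUE,
         first_elevation_years = (dx_day - days[which(hit)[1]]) / DAYS_PER_YEAR)
}

#' Detect aberrant pancreatic-enzyme elevation
#'
#' An enzyme elevation is a pancreatic-amylase or lipase value inside the
#' 1-year prediagnostic window that exceeds 3 times the analyte's upper limit
#' of normal *and* reaches twice the cumulative average of all prior values
#' of that analyte. Total amylase carries no rule. Returns the earliest
#' qualifying point across the two analytes.
#'
#' @param p_amylase,lipase Lists with elements `days` and `values`, or `NULL`
#'   when the analyte was not measured.
#' @param dx_day Diagnosis time, days.
#' @param rules A [marker_rules()] object.
#' @return One-row tibble: `elevated`, `analyte`, `first_elevation_years`.
#' @export
detect_enzyme_elevation <- function(p_amylase = NULL, lipase = NULL, dx_day,
                                    rules = marker_rules()) {
  dx_day <- as.numeric(dx_day)
  win_lo <- dx_day - rules$window_years * DAYS_PER_YEAR
  scan <- function(ser, uln) {
    if (is.null(ser) || !length(ser$values)) return(NULL)
    days <- as.numeric(ser$days); values <- ser$values
    keep <- !is.na(values) & days <= dx_day
    days <- days[keep]; values <- values[keep]
    o <- order(days); days <- days[o]; values <- values[o]
    cavg <- prefix_means(values)
    hit <- days > win_lo &
      values > rules$enzyme_uln_multiple * uln &
      !is.na(cavg) &
      dbl_cmp(values, rules$enzyme_doubling_factor * cavg,
              rules$doubling_inclusive)
    if (!any(hit)) return(NULL)
    days[which(hit)[1]]
  }
  hits <- list(p_amylase = scan(p_amylase, rules$p_amylase_uln),
               lipase = scan(lipase, rules$lipase_uln))
  hits <- hits[!vapply(hits, is.null, TRUE)]
  if (!length(hits)) {
    return(tibble(elevated = FALSE, analyte = NA_character_,
                  first_elevation_years = NA_real_))
  }
  first <- which.min(unlist(hits))
  tibble(elevated = TRUE, analyte = names(hits)[first],
         first_elevation_years = (dx_day - hits[[first]]) / DAYS_PER_YEAR)
}

#' Flag plausible Lewis-antigen-negative patients
#'
#' Lewis-antigen-negative individuals produce no CA19-9 regardless of tumour
#' burden; their measured values stay below the assay detection limit. The
#' flag is true iff every measured value is at or below the detection limit.
#'
#' @param values CA19-9 values, U/mL.
#' @param detection_limit Assay detection limit, U/mL.
#' @return Logical scalar; `NA` if the detection limit is missing or no
#'   values exist.
#' @export
flag_lewis_negative <- function(values, detection_limit) {
  values <- values[!is.na(values)]
  limit <- unique(detection_limit[!is.na(detection_limit)])
  if (!length(values) || !length(limit)) return(NA)
  all(values <= max(limit))
}

#' Classify prediagnostic marker trajectories for a whole cohort
#'
#' Runs the CA19-9 trajectory classifier, the HbA1c elevation rule, the
#' pancreatic-enzyme elevation rule and the Lewis-negative flag on every
#' patient with a carcinoma diagnosis.
#'
#' @param cohort A [surveillance_cohort()].
#' @param rules A [marker_rules()] object.
#' @return A tibble of class `trajectory_classification`, one row per
#'   diagnosed patient: `patient_id`, `pattern`, `trigger`,
#'   `first_elevation_years`, `hba1c_elevated`, `hba1c_lead_years`,
#'   `enzyme_elevated`, `enzyme_analyte`, `enzyme_lead_years`,
#'   `lewis_negative`.
#' @export
classify_trajectories <- function(cohort, rules = marker_rules()) {
  stopifnot(inherits(cohort, "surveillance_cohort"))
  pt <- filter(cohort$patients, !is.na(.data$dx_date))
  labs <- semi_join(cohort$labs, pt, by = "patient_id")
  labs_by <- split(labs, labs$patient_id)

  one <- function(pid, baseline, dx_date) {
    lb <- labs_by[[pid]]
    dx_day <- as.numeric(dx_date - baseline)
    day_of <- function(df) as.numeric(df$date - baseline)
    pick <- function(a) {
      if (is.null(lb)) return(NULL)
      s <- lb[lb$analyte == a, ]
      if (!nrow(s)) return(NULL)
      list(days = day_of(s), values = s$value, unit = s$unit,
           detection_limit = s$detection_limit)
    }
    ca <- pick("ca19_9")
    cls <- classify_ca19_9(ca$days %||% numeric(0), ca$values %||% numeric(0),
                           dx_day, rules)
    hb <- pick("hba1c")
    hb_res <- if (is.null(hb)) {
      tibble(elevated = FALSE, first_elevation_years = NA_real_)
    } else {
      detect_hba1c_elevation(hb$days, hb$values, hb$unit, dx_day, rules)
    }
    enz <- detect_enzyme_elevation(pick("p_amylase"), pick("lipase"),
                                   dx_day, rules)
    lewis <- if (is.null(ca)) NA else
      flag_lewis_negative(ca$values, ca$detection_limit)
    tibble(patient_id = pid, pattern = cls$pattern, trigger = cls$trigger,
           first_elevation_years = cls$first_elevation_years,
           hba1c_elevated = hb_res$elevated,
           hba1c_lead_years = hb_res$first_elevation_years,
           enzyme_elevated = enz$elevated, enzyme_analyte = enz$analyte,
           enzyme_lead_years = enz$first_elevation_years,
           lewis_negative = isTRUE(lewis))
  }
  out <- purrr::pmap(list(pt$patient_id, pt$baseline_date, pt$dx_date), one)
  out <- bind_rows(out)
  if (!nrow(out)) {
    out <- tibble(patient_id = character(), pattern = character(),
                  trigger = character(), first_elevation_years = double(),
                  hba1c_elevated = logical(), hba1c_lead_years = double(),
                  enzyme_elevated = logical(), enzyme_analyte = character(),
                  enzyme_lead_years = double(), lewis_negative = logical())
  }
  class(out) <- c("trajectory_classification", class(out))
  out
}

#' @method glance trajectory_classification
#' @export
glance.trajectory_classification <- function(x, ...) {
  tibble(n = nrow(x),
         n_aberrant = sum(x$pattern == "aberrant_elevation"),
         n_high_to_high = sum(x$pattern == "high_to_high"),
         n_low_to_low = sum(x$pattern == "low_to_low"),
         n_residual = sum(x$pattern == "residual_unclassified"),
         n_insufficient = sum(x$pattern == "insufficient_data"),
         n_hba1c = sum(x$hba1c_elevated),
         n_enzyme = sum(x$enzyme_elevated),
         n_lewis_negative = sum(x$lewis_negative, na.rm = TRUE),
         median_ca19_9_lead = median(x$first_elevation_years, na.rm = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
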