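# Cohort-level report: baseline characteristics by carcinoma type,
# lab-by-imaging cross-classification, trajectory-pattern tables with
# printed-style percentages, lead-time summaries, and the survival
# comparison by CA19-9 pattern.

characteristics_table <- function(pt) {
  cont_row <- function(var, label) {
    split_by <- split(pt[[var]], pt$carcinoma_type)
    p <- if (length(split_by) == 2 &&
             all(lengths(split_by) > 0)) {
      rank_sum_test(split_by[[1]], split_by[[2]])$p.value
    } else NA_real_
    tibble(variable = label, level = "median (IQR)",
           overall = sprintf("%.1f (%.1f-%.1f)",
                             median(pt[[var]], na.rm = TRUE),
                             quantile(pt[[var]], 0.25, na.rm = TRUE),
                             quantile(pt[[var]], 0.75, na.rm = TRUE)),
           ipmn_derived = summ_cont(pt[[var]][pt$carcinoma_type == "ipmn_derived"]),
           concomitant_pdac = summ_cont(
             pt[[var]][pt$carcinoma_type == "concomitant_pdac"]),
           p.value = p)
  }
  summ_cont <- function(x) sprintf("%.1f (%.1f-%.1f)",
                                   median(x, na.rm = TRUE),
                                   quantile(x, 0.25, na.rm = TRUE),
                                   quantile(x, 0.75, na.rm = TRUE))
  cat_rows <- function(var, label) {
    ct <- crosstab(pt, !!rlang::sym(var), carcinoma_type)
    test <- crosstab_test(ct)
    m <- ct$counts
    lv <- rownames(m)
    totals <- rowSums(m)
    cols <- colnames(m)
    get <- function(ty, i) if (ty %in% cols) m[i, ty] else 0L
    bind_rows(lapply(seq_along(lv), function(i) {
      tibble(variable = label, level = lv[i],
             overall = sprintf("%d (%s%%)", totals[i],
                               format(pct_label(totals[i], sum(m)))),
             ipmn_derived = sprintf("%d", get("ipmn_derived", i)),
             concomitant_pdac = sprintf("%d", get("concomitant_pdac", i)),
             p.value = if (i == 1) test$p.value else NA_real_)
    }))
  }
  bind_rows(
    cont_row("age_at_baseline", "age_at_baseline_years"),
    cat_rows("sex", "sex"),
    cat_rows("smoking", "smoking"),
    cont_row("bmi", "bmi_kg_m2"),
    cat_rows("diabetes", "diabetes"),
    cat_rows("family_history_pc", "family_history_pc"),
    cat_rows("location", "carcinoma_location"),
    cat_rows("clinical_stage", "clinical_stage"))
}

pattern_table <- function(df, by) {
  ct <- crosstab(df, !!rlang::sym(by), pattern)
  test <- crosstab_test(ct)
  td <- tidy(ct)
  list(counts = ct, tidy = td, test = test, excluded = ct$excluded)
}

#' Assemble the cohort-level report
#'
#' Combines the upstream analyses into the report tables of a surveillance
#' study: baseline characteristics by carcinoma type, marker-elevation
#' prevalences, trajectory-pattern-by-type and -by-stage contingency tables
#' with printed-style row percentages and association tests (patients
#' without in-window CA19-9 data are excluded from the pattern tables and
#' counted), lead-time medians with IQRs, and a log-rank comparison of
#' postdiagnosis survival between aberrant and non-aberrant patterns.
#'
#' @param cohort A [surveillance_cohort()].
#' @param trajectories Output of [classify_trajectories()] (computed if
#'   omitted).
#' @param features Output of [evaluate_features()] (computed if omitted).
#' @param rules A [marker_rules()] object.
#' @return A list of class `cohort_report` with elements `characteristics`,
#'   `marker_prevalence`, `pattern_by_type`, `pattern_by_stage`,
#'   `lead_times`, `survival` (or `NULL` where a component is not
#'   estimable, e.g. in an empty cohort).
#' @export
cohort_report <- function(cohort, trajectories = NULL, features = NULL,
                          rules = marker_rules()) {
  stopifnot(inherits(cohort, "surveillance_cohort"))
  if (is.null(trajectories)) trajectories <- classify_trajectories(cohort, rules)
  if (is.null(features)) features <- evaluate_features(cohort, rules)
  pt <- filter(cohort$patients, !is.na(.data$dx_date))
  out <- list(characteristics = NULL, marker_prevalence = NULL,
              pattern_by_type = NULL, pattern_by_stage = NULL,
              lead_times = NULL, survival = NULL)
  class(out) <- "cohort_report"
  if (!nrow(pt)) return(out)

  df <- left_join(pt, trajectories, by = "patient_id")
  firsts <- first_feature_times(features, cohort) |>
    semi_join(pt, by = "patient_id")
  df <- left_join(df, firsts, by = "patient_id")
  # pattern tables exclude patients without in-window data
  df_cls <- df |>
    mutate(pattern = ifelse(.data$pattern == "insufficient_data",
                            NA_character_, .data$pattern),
           pattern = droplevels(factor(.data$pattern, levels = setdiff(
             PATTERN_LEVELS, "insufficient_data"))),
           stage_group = factor(ifelse(.data$clinical_stage %in% c("0", "I"),
                                       "0/I", .data$clinical_stage),
                                levels = c("0/I", "II", "III", "IV")))

  out$characteristics <- characteristics_table(pt)

  prevalence <- df |>
    group_by(.data$carcinoma_type) |>
    summarise(n = n(),
              n_ca19_9_aberrant = sum(.data$pattern == "aberrant_elevation",
                                      na.rm = TRUE),
              n_hba1c = sum(.data$hba1c_elevated, na.rm = TRUE),
              n_enzyme = sum(.data$enzyme_elevated, na.rm = TRUE),
              n_hrs = sum(!is.na(.data$t_first_hrs_years)),
              n_any_wf_or_hrs = sum(!is.na(.data$t_first_any_years)),
              .groups = "drop") |>
    mutate(pct_hrs = pct_label(.data$n_hrs, .data$n),
           pct_any = pct_label(.data$n_any_wf_or_hrs, .data$n))
  out$marker_prevalence <- prevalence

  if (nrow(df_cls) && any(!is.na(df_cls$pattern))) {
    out$pattern_by_type <- pattern_table(df_cls, "carcinoma_type")
    out$pattern_by_stage <- pattern_table(df_cls, "stage_group")
  }

  lead <- function(x) if (any(!is.na(x))) median_iqr(x) else
    tibble(n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_)
  out$lead_times <- df |>
    group_by(.data$carcinoma_type) |>
    summarise(ca19_9 = lead(.data$first_elevation_years),
              wf_or_hrs = lead(.data$any_lead_years), .groups = "drop") |>
    tidyr::unpack(c("ca19_9", "wf_or_hrs"), names_sep = "_")

  surv_df <- df |>
    filter(!is.na(.data$pattern), .data$pattern != "insufficient_data") |>
    mutate(aberrant = ifelse(.data$pattern == "aberrant_elevation",
                             "aberrant", "not_aberrant"),
           os_years = as.numeric(.data$last_date - .data$dx_date) /
             DAYS_PER_YEAR,
           death = .data$status == "dead")
  if (n_distinct(surv_df$aberrant) == 2 && nrow(surv_df) >= 4) {
    out$survival <- compare_survival(surv_df, os_years, death, aberrant)
  }
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("== Cohort report ==\n")
  if (is.null(x$marker_prevalence)) {
    cat("(empty cohort)\n")
    return(invisible(x))
  }
  cat("\n-- Marker and feature prevalence by carcinoma type --\n")
  print(as.data.frame(x$marker_prevalence), row.names = FALSE)
  if (!is.null(x$pattern_by_type)) {
    cat(sprintf("\n-- CA19-9 pattern by carcinoma type (%d excluded, no in-window data) --\n",
                x$pattern_by_type$excluded))
    print(x$pattern_by_type$counts$counts)
    cat(sprintf("   test: %s p = %.4g\n", x$pattern_by_type$test$method,
                x$pattern_by_type$test$p.value))
    cat("\n-- CA19-9 pattern by clinical stage --\n")
    print(x$pattern_by_stage$counts$counts)
    cat(sprintf("   test: %s p = %.4g\n", x$pattern_by_stage$test$method,
                x$pattern_by_stage$test$p.value))
  }
  cat("\n-- Lead times (years before diagnosis, median [IQR]) --\n")
  print(as.data.frame(x$lead_times), row.names = FALSE)
  if (!is.null(x$survival)) {
    cat("\n-- Postdiagnosis survival, aberrant vs not --\n")
    print(x$survival)
  }
  invisible(x)
}
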