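# Cohort-level statistics: contingency tables with the study's test
# conventions (Pearson chi-square without continuity correction, Fisher's
# exact test when expected counts are small), Wilcoxon rank-sum comparisons,
# and Kaplan-Meier / log-rank survival analyses.

#' Cross-tabulate two categorical variables
#'
#' Builds a contingency table of two patient-level variables. Patients with
#' an undefined value in either variable are excluded from the table and
#' counted in the `excluded` field (the motivating analysis excluded 11
#' patients without in-window CA19-9 data this way).
#'
#' @param data A data frame.
#' @param row,col Unquoted column names (factors keep their level order).
#' @return An object of class `crosstab`: integer count matrix plus the
#'   exclusion count.
#' @export
crosstab <- function(data, row, col) {
  r <- rlang::eval_tidy(rlang::enquo(row), data)
  c_ <- rlang::eval_tidy(rlang::enquo(col), data)
  keep <- !is.na(r) & !is.na(c_)
  counts <- unclass(table(row = r[keep], col = c_[keep]))
  structure(list(counts = counts, excluded = sum(!keep),
                 row_var = rlang::as_label(rlang::enquo(row)),
                 col_var = rlang::as_label(rlang::enquo(col))),
            class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  cat(sprintf("<crosstab> %s x %s (%d excluded)\n", x$row_var, x$col_var,
              x$excluded))
  print(x$counts)
  invisible(x)
}

#' Percentage label as printed in clinical tables
#'
#' Percentages at or above 10 are rounded to whole numbers; smaller ones keep
#' one decimal (so 2/42 prints as 4.8, 3/43 as 7.0, 14/47 as 30).
#'
#' @param count,total Numerator and denominator.
#' @return Numeric percentage on the printed scale.
#' @export
pct_label <- function(count, total) {
  p <- 100 * count / total
  ifelse(p < 9.95, round(p, 1), round(p))
}

#' @method tidy crosstab
#' @export
tidy.crosstab <- function(x, ...) {
  m <- x$counts
  rt <- rowSums(m)
  out <- as_tibble(as.data.frame.table(m, responseName = "n",
                                       stringsAsFactors = FALSE))
  out$row_total <- unname(rt[out$row])
  out$row_pct <- unname(pct_label(out$n, out$row_total))
  as_tibble(out)
}

expected_counts <- function(m) outer(rowSums(m), colSums(m)) / sum(m)

#' Test association in a contingency table
#'
#' Applies the study's convention: Pearson's chi-square without continuity
#' correction, or Fisher's exact test for a 2x2 table when any expected cell
#' count falls below 5 (`method = "auto"`). For larger tables with small
#' expected counts the Pearson statistic is reported with
#' `small_expected = TRUE`.
#'
#' @param x A [crosstab()] or a count matrix.
#' @param method `"auto"`, `"chisq"`, or `"fisher"`.
#' @return One-row tibble: `method`, `statistic`, `df`, `p.value`,
#'   `small_expected`.
#' @export
crosstab_test <- function(x, method = c("auto", "chisq", "fisher")) {
  method <- match.arg(method)
  m <- if (inherits(x, "crosstab")) x$counts else as.matrix(x)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(tibble(method = NA_character_, statistic = NA_real_, df = NA_real_,
                  p.value = NA_real_, small_expected = NA))
  }
  exp <- expected_counts(m)
  small <- any(exp < 5)
  if (method == "auto") {
    method <- if (small && all(dim(m) == c(2, 2))) "fisher" else "chisq"
  }
  if (method == "fisher") {
    stopifnot(all(dim(m) == c(2, 2)))
    p <- fisher_exact_2x2(m)
    return(tibble(method = "fisher", statistic = NA_real_, df = NA_real_,
                  p.value = p, small_expected = small))
  }
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble(method = "chisq", statistic = unname(ht$statistic),
         df = unname(ht$parameter), p.value = ht$p.value,
         small_expected = small)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value obtained by summing the hypergeometric probabilities of
#' all tables (with the observed margins) no more probable than the observed
#' one — the probability-mass convention, not doubling of a one-sided tail.
#'
#' @param m A 2x2 count matrix.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(2, 2)))
  stats::fisher.test(m)$p.value
}

#' Wilcoxon rank-sum comparison of two samples
#'
#' Rank-sum test with midranks for ties: exact when the combined sample size
#' is at most 10 and ties are absent, otherwise the normal approximation with
#' the tie-corrected variance (no continuity correction).
#'
#' @param x,y Numeric samples.
#' @return One-row tibble: `statistic` (Mann-Whitney U for `x`), `p.value`,
#'   `exact`.
#' @export
rank_sum_test <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 10 && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = FALSE))
  tibble(statistic = unname(ht$statistic), p.value = ht$p.value,
         exact = exact)
}

#' Kaplan-Meier product-limit curve
#'
#' @param time Follow-up times (>= 0).
#' @param event Event indicator (1/TRUE = death, 0/FALSE = censored);
#'   subjects censored at an event time are counted at risk for that event
#'   (standard convention).
#' @return A tibble: `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_curve <- function(time, event) {
  stopifnot(all(time >= 0), length(time) == length(event))
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         n_censor = fit$n.censor, surv = fit$surv)
}

#' Compare survival between groups (Kaplan-Meier + log-rank)
#'
#' @param data A data frame.
#' @param time,event,group Unquoted column names: follow-up time, event
#'   indicator, grouping variable. Rows with missing group are dropped.
#' @return An object of class `km_comparison` wrapping the `survfit` fit and
#'   the log-rank test; see [tidy.km_comparison()] and
#'   [glance.km_comparison()].
#' @export
compare_survival <- function(data, time, event, group) {
  df <- tibble(
    time = rlang::eval_tidy(rlang::enquo(time), data),
    event = as.integer(rlang::eval_tidy(rlang::enquo(event), data)),
    group = rlang::eval_tidy(rlang::enquo(group), data))
  df <- filter(df, !is.na(.data$group), !is.na(.data$time))
  if (!nrow(df) || n_distinct(df$group) < 2)
    stop("compare_survival() needs at least two non-empty groups",
         call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  structure(list(fit = fit, logrank = lr, data = df),
            class = "km_comparison")
}

#' @export
print.km_comparison <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<km_comparison> %d groups, %d subjects, %d events\n",
              length(x$logrank$n), sum(x$logrank$n), sum(x$logrank$obs)))
  cat(sprintf("  log-rank chi-square = %.3f, df = %d, p = %.4g\n",
              g$statistic, g$df, g$p.value))
  invisible(x)
}

#' Tidy a survival comparison into one row per curve step
#'
#' @param x A [compare_survival()] result.
#' @param ... Unused.
#' @return Tibble: `group`, `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @method tidy km_comparison
#' @export
tidy.km_comparison <- function(x, ...) {
  fit <- x$fit
  strata <- rep(names(fit$strata), fit$strata)
  tibble(group = sub("^group=", "", strata), time = fit$time,
         n_risk = fit$n.risk, n_event = fit$n.event,
         n_censor = fit$n.censor, surv = fit$surv)
}

#' One-row summary of the log-rank comparison
#'
#' @param x A [compare_survival()] result.
#' @param ... Unused.
#' @return Tibble: `statistic`, `df`, `p.value`, `n`, `n_events`.
#' @method glance km_comparison
#' @export
glance.km_comparison <- function(x, ...) {
  lr <- x$logrank
  df <- length(lr$n) - 1
  tibble(statistic = unname(lr$chisq), df = df,
         p.value = stats::pchisq(lr$chisq, df, lower.tail = FALSE),
         n = sum(lr$n), n_events = sum(lr$obs))
}

#' Median and interquartile range, linearly interpolated
#'
#' @param x Numeric vector (`NA`s dropped).
#' @param digits Decimals kept for presentation (default one, matching the
#'   0.1-year resolution used for lead times).
#' @return Tibble: `n`, `median`, `q1`, `q3`.
#' @export
median_iqr <- function(x, digits = 1) {
  x <- x[!is.na(x)]
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble(n = length(x), median = round(q[2], digits),
         q1 = round(q[1], digits), q3 = round(q[3], digits))
}
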