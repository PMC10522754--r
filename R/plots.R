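# ggplot2 graphics for the main result types.

#' Plot prediagnostic marker trajectories
#'
#' Spaghetti plot of one analyte against years before carcinoma diagnosis,
#' optionally coloured by the classified CA19-9 pattern, on a log scale with
#' the upper limit of normal marked.
#'
#' @param cohort A [surveillance_cohort()].
#' @param analyte Analyte to plot (default `"ca19_9"`).
#' @param trajectories Optional [classify_trajectories()] output for
#'   colouring.
#' @param rules A [marker_rules()] object (reference line).
#' @return A ggplot object.
#' @export
plot_marker_trajectories <- function(cohort, analyte = "ca19_9",
                                     trajectories = NULL,
                                     rules = marker_rules()) {
  stopifnot(inherits(cohort, "surveillance_cohort"))
  pt <- filter(cohort$patients, !is.na(.data$dx_date))
  df <- cohort$labs |>
    filter(.data$analyte == .env$analyte) |>
    inner_join(select(pt, "patient_id", "dx_date"), by = "patient_id") |>
    mutate(years_before_dx = as.numeric(.data$dx_date - .data$date) /
             DAYS_PER_YEAR)
  if (!is.null(trajectories)) {
    df <- left_join(df, select(trajectories, "patient_id", "pattern"),
                    by = "patient_id")
  } else {
    df$pattern <- "all"
  }
  uln <- switch(analyte, ca19_9 = rules$ca19_9_uln,
                p_amylase = rules$p_amylase_uln,
                lipase = rules$lipase_uln, NULL)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = -.data$years_before_dx, y = .data$value,
    group = .data$patient_id, colour = .data$pattern)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Years before carcinoma diagnosis",
                  y = sprintf("%s", analyte), colour = "CA19-9 pattern") +
    ggplot2::theme_minimal()
  if (!is.null(uln)) {
    p <- p + ggplot2::geom_hline(yintercept = uln, linetype = "dashed")
  }
  p
}

#' Kaplan-Meier plot of a survival comparison
#'
#' @param object A [compare_survival()] result.
#' @param ... Unused.
#' @return A ggplot step plot of the survival curves with censoring marks.
#' @method autoplot km_comparison
#' @export
autoplot.km_comparison <- function(object, ...) {
  td <- tidy(object)
  start <- td |> distinct(.data$group) |>
    mutate(time = 0, surv = 1, n_censor = 0L)
  df <- bind_rows(start, td) |> arrange(.data$group, .data$time)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = filter(df, .data$n_censor > 0), shape = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Years since carcinoma diagnosis",
                  y = "Survival probability", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of trajectory pattern counts
#'
#' @param object A [classify_trajectories()] result.
#' @param ... Unused.
#' @return A ggplot bar chart of pattern frequencies.
#' @method autoplot trajectory_classification
#' @export
autoplot.trajectory_classification <- function(object, ...) {
  df <- count(as_tibble(object), .data$pattern)
  ggplot2::ggplot(df, ggplot2::aes(.data$pattern, .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Patients") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
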