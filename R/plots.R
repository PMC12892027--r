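## ggplot2 displays for the standard web-RDS diagnostics.

#' @importFrom ggplot2 ggplot aes geom_line geom_hline geom_col geom_step
#'   labs facet_wrap theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a convergence trace
#'
#' Cumulative sample proportion (or mean) by enrollment order, one panel per
#' category, with the final value marked.
#'
#' @param object A `webrds_convergence`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.webrds_convergence <- function(object, ...) {
  finals <- object$trace %>%
    group_by(.data$category) %>%
    summarise(final = .data$value[dplyr::n()], .groups = "drop")
  ggplot(object$trace, aes(x = .data$index, y = .data$value)) +
    geom_line(color = "steelblue") +
    geom_hline(data = finals, aes(yintercept = .data$final),
               linetype = "dashed", color = "grey40") +
    facet_wrap(~category) +
    labs(x = "enrollment order", y = "cumulative proportion / mean",
         title = paste("Convergence:", object$variable)) +
    theme_minimal()
}

#' Plot a reported-degree histogram
#'
#' @param object A `webrds_degree_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.webrds_degree_summary <- function(object, ...) {
  ggplot(object$histogram, aes(x = .data$degree, y = .data$n)) +
    geom_col(fill = "steelblue") +
    labs(x = "reported network size", y = "participants",
         title = "Contact network size") +
    theme_minimal()
}

#' Plot the cleaning funnel
#'
#' @param object A `webrds_funnel_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.webrds_funnel_report <- function(object, ...) {
  df <- tidy(object)
  df$stage <- factor(df$stage, levels = rev(df$stage))
  ggplot(df, aes(x = .data$n, y = .data$stage)) +
    geom_col(fill = "steelblue") +
    labs(x = "attempts", y = NULL, title = "Intake cleaning funnel") +
    theme_minimal()
}

#' Plot daily cumulative enrollment
#'
#' The enrollment time series: flat under a low incentive, rising after the
#' increase.
#'
#' @param forest Recruitment forest with a `day` column.
#' @return A ggplot.
#' @export
plot_enrollment_curve <- function(forest) {
  df <- forest %>%
    count(.data$day, name = "n") %>%
    arrange(.data$day) %>%
    mutate(cumulative = cumsum(.data$n))
  ggplot(df, aes(x = .data$day, y = .data$cumulative)) +
    geom_step(color = "steelblue") +
    labs(x = "day", y = "cumulative enrollments",
         title = "Recruitment over time") +
    theme_minimal()
}
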