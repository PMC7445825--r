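#' Plot a selection trajectory
#'
#' Frequency of each variant (or phenotype-class mean) across selection
#' steps on a log10 axis, the standard sawtooth view of alternating
#' positive/negative selection: constitutively active variants rise on
#' positive steps and crash on negative steps, inactive variants do the
#' opposite, and a true switch climbs through both.
#'
#' @param object A `selection_trajectory` from [simulate_selection()], or
#'   any data frame with columns `step_index`, `step`, `variant_id`,
#'   `frequency` (e.g. [variant_frequencies()] output joined to rounds).
#' @param variants Optional classified variant table (`variant_id`,
#'   `class`); when supplied, class mean frequencies are drawn instead of
#'   individual variants.
#' @param highlight Optional character vector of variant ids to label
#'   individually even when `variants` is given.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.selection_trajectory <- function(object, variants = NULL,
                                          highlight = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(variants)) {
    df <- dplyr::left_join(df,
                           as_tibble(variants)[, c("variant_id", "class")],
                           by = "variant_id")
    cls <- df |>
      dplyr::summarise(frequency = mean(.data$frequency),
                       .by = dplyr::all_of(c("step_index", "step", "class"))) |>
      dplyr::mutate(series = as.character(.data$class))
    if (!is.null(highlight)) {
      hi <- df[df$variant_id %in% highlight, ] |>
        dplyr::mutate(series = .data$variant_id)
      cls <- dplyr::bind_rows(cls, hi[, names(cls)[names(cls) %in% names(hi)]])
    }
    df <- cls
  } else {
    df$series <- df$variant_id
  }
  df <- df[df$frequency > 0, ]
  steps <- dplyr::distinct(as_tibble(object)[, c("step_index", "step")])
  ggplot2::ggplot(df, ggplot2::aes(.data$step_index, .data$frequency,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::scale_y_log10(labels = function(x) sprintf("%g%%", 100 * x)) +
    ggplot2::scale_x_continuous(breaks = steps$step_index,
                                labels = steps$step) +
    ggplot2::labs(x = "Selection step", y = "Frequency",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a condition-optimization fitness scan
#'
#' Cleaved fractions under positive and negative conditions and the
#' resulting fitness as a function of reaction time.
#'
#' @param object A [fitness_scan()] result carrying a `time_min` column.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fitness_scan <- function(object, ...) {
  df <- as_tibble(object)
  if (is.null(df$time_min)) {
    abort("This scan has no `time_min` column to plot against.")
  }
  long <- tidyr::pivot_longer(
    df, dplyr::all_of(c("r_plus", "r_minus", "fitness")),
    names_to = "quantity", values_to = "value")
  long$quantity <- factor(long$quantity,
                          levels = c("r_plus", "r_minus", "fitness"),
                          labels = c("r(+)", "r(-)", "fitness"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$value,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Reaction time (min)", y = NULL, colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
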