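#' Plot an input function
#'
#' Whole-blood and plasma channels against time.
#'
#' @param object An [input_function()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.input_function <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("whole_blood", "plasma"),
                            names_to = "channel", values_to = "activity")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$activity,
                                   colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "activity (kBq/mL)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a parametric map
#'
#' @param object A [parametric_map()].
#' @param slice Axial slice index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot raster of the slice.
#' @export
autoplot.parametric_map <- function(object, slice = NULL, ...) {
  d <- dim(object$data)
  slice <- slice %||% ceiling(d[3] / 2)
  df <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
  df$value <- as.vector(object$data[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = object$quantity) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s, slice %d", object$quantity, slice)) +
    ggplot2::theme_minimal()
}

#' Plot regional group means with error bars
#'
#' @param comparison A `group_comparison` from [group_compare_regions()].
#' @return A ggplot of group means +/- SD per region, faceted by
#'   quantity, with significant regions starred.
#' @export
plot_group_comparison <- function(comparison) {
  stopifnot(inherits(comparison, "group_comparison"))
  df <- comparison$regions |>
    tidyr::pivot_longer(c("mean_ad", "mean_ctl"), names_to = "group",
                        values_to = "mean") |>
    dplyr::mutate(
      sd = ifelse(.data$group == "mean_ad", .data$sd_ad, .data$sd_ctl),
      group = ifelse(.data$group == "mean_ad", "AD", "CTL"),
      region_h = paste(.data$region, dplyr::coalesce(.data$hemisphere, ""))
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$region_h, .data$mean,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(0.9), width = 0.3) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Scatter plot of an uptake measure against MMSE
#'
#' @param subjects Subject tibble (with `mmse`, `group`).
#' @param measures Tibble with `subject` and the measure column.
#' @param measure Column name to plot (default `"suvr_ratio"`).
#' @return A ggplot with a linear fit across all subjects.
#' @export
plot_score_correlation <- function(subjects, measures,
                                   measure = "suvr_ratio") {
  df <- dplyr::left_join(subjects, measures, by = c(id = "subject"))
  ggplot2::ggplot(df, ggplot2::aes(.data$mmse, .data[[measure]])) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$group)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.4) +
    ggplot2::labs(x = "MMSE", y = measure, shape = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
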