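# ggplot2 views of the main result types.

#' @method autoplot exposure_grid
#' @export
autoplot.exposure_grid <- function(object, year = NULL, ...) {
  year <- year %||% iso_year(object$series$timestamp[1])
  stats <- annual_cell_stats(object, year)
  d <- dplyr::left_join(stats, object$cells, by = "cell_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lon, y = .data$lat,
                                  fill = .data$avg_daily)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~pollutant) +
    ggplot2::labs(x = "longitude", y = "latitude",
                  fill = "annual mean\nof daily means") +
    ggplot2::theme_minimal()
}

#' @method autoplot execution_report
#' @export
autoplot.execution_report <- function(object, ...) {
  d <- dplyr::mutate(object, step = factor(.data$step, levels = rev(.data$step)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$status, y = .data$step,
                                  colour = .data$status)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Outcome prevalence across binned exposure levels
#'
#' A bar chart of the share of rows at or above the outcome threshold within
#' each level of a binned exposure variable, the standard view of an
#' exposure-outcome association in an integrated feature table.
#'
#' @param table Integrated feature tibble.
#' @param exposure Name of a binned (range-label) column.
#' @param outcome Name of a numeric outcome column.
#' @param threshold Outcome dichotomization threshold (default 2, the
#'   two-or-more annual ED/inpatient respiratory visits rule).
#' @return A ggplot object.
#' @export
plot_exposure_outcome <- function(table, exposure, outcome, threshold = 2) {
  d <- table |>
    dplyr::filter(!is.na(.data[[exposure]]), !is.na(.data[[outcome]])) |>
    dplyr::summarise(
      pct = 100 * mean(.data[[outcome]] >= threshold),
      n = dplyr::n(),
      .by = dplyr::all_of(exposure)
    ) |>
    dplyr::arrange(parse_bin_lower(.data[[exposure]]))
  d[[exposure]] <- factor(d[[exposure]], levels = d[[exposure]])
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[exposure]], y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = exposure,
                  y = sprintf("%% with %s >= %s", outcome, threshold)) +
    ggplot2::theme_minimal()
}
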