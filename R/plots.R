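#' Plot methods for pipeline results
#'
#' `autoplot()` methods render the main result types with ggplot2:
#' richness maps and binary ranges as cell rasters (row 1 drawn at the
#' top, matching the grid convention), and gap results as the familiar
#' stacked category-proportion bars per climate x protection scenario.
#' `plot_effectiveness()` draws effective / non-effective counts per
#' scenario.
#'
#' @param object the result object.
#' @param ... unused.
#' @return A ggplot.
#' @name rangegap-plots
NULL

#' @rdname rangegap-plots
#' @method autoplot richness_map
#' @export
autoplot.richness_map <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$richness)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "Richness") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0("Taxon richness - ", object$scenario_id),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname rangegap-plots
#' @method autoplot binary_range
#' @export
autoplot.binary_range <- function(object, ...) {
  df <- mutate(grid_tibble(object$cells * 1), value = factor(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey92", `1` = "darkgreen"),
                               name = NULL,
                               labels = c("absent", "suitable")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0(object$taxon_id, " - ", object$scenario_id,
                                 " (", object$area_km2, " km2)"),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname rangegap-plots
#' @method autoplot gap_results
#' @export
autoplot.gap_results <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pa_scenario,
                                       fill = .data$category)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::facet_wrap(~climate_scenario) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::scale_fill_manual(values = c(
      "Protected" = "#1b4f72", "Partial gap" = "#5dade2",
      "Gap" = "#f1948a", "Not protected" = "#c0392b"
    )) +
    ggplot2::labs(x = "Protected-area scenario", y = "Taxa",
                  fill = "Category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname rangegap-plots
#' @param summary tibble from [summarize_effectiveness()].
#' @export
plot_effectiveness <- function(summary, ...) {
  df <- tidyr::pivot_longer(
    summary, c("n_effective", "n_non_effective"),
    names_to = "status", values_to = "n"
  ) |>
    mutate(status = ifelse(.data$status == "n_effective",
                           "Effective", "Non-effective"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario_id, y = .data$n,
                                   fill = .data$status)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c("Effective" = "grey40",
                                          "Non-effective" = "#c0392b")) +
    ggplot2::labs(x = "Scenario", y = "Protected areas", fill = NULL) +
    ggplot2::theme_minimal()
}
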