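#' Map a per-cell layer
#'
#' Tile map of any per-cell value (suitability, richness, turnover,
#' protected land) on the landscape grid; north is up.
#'
#' @param grid A [make_grid()] grid.
#' @param values Tibble with `cell_id` and the value column.
#' @param value Column to map.
#' @return A ggplot object.
#' @export
plot_cell_layer <- function(grid, values, value) {
  df <- dplyr::left_join(tibble::as_tibble(grid), values, by = "cell_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data[[value]])) +
    ggplot2::geom_tile(width = attr(grid, "cell_size"), height = attr(grid, "cell_size")) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (km)", y = "northing (km)", fill = value) +
    ggplot2::theme_minimal()
}

#' Impact histograms over protected areas and protected land
#'
#' The dual reading of an impact distribution: the share of protected areas
#' (sampling unit = protected area) and the share of total protected land
#' area (weighting cells by their protected land) per value class of a
#' metric.
#'
#' @param impact Per-PA impact tibble from [pa_impact()].
#' @param land_distribution Class-share tibble from
#'   [land_area_distribution()] for the same metric.
#' @param metric Metric column of `impact` (`"rG"`, `"rL"` or `"T"`).
#' @return A ggplot object.
#' @export
plot_impact_distribution <- function(impact, land_distribution, metric = "T") {
  breaks_chr <- levels(land_distribution$class)
  pa_share <- impact |>
    dplyr::filter(!is.na(.data[[metric]])) |>
    dplyr::mutate(class = cut(
      .data[[metric]],
      breaks = unique(c(-Inf, 0, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100, Inf)),
      right = FALSE
    ))
  df <- dplyr::bind_rows(
    dplyr::count(pa_share, .data$class) |>
      dplyr::mutate(share = .data$n / sum(.data$n), unit = "protected areas") |>
      dplyr::select("class", "share", "unit") |>
      dplyr::mutate(class = as.character(.data$class)),
    dplyr::transmute(land_distribution,
      class = as.character(.data$class),
      share = .data$share, unit = "protected land area"
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$share, fill = .data$unit)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = sprintf("%s class (%%)", metric), y = "share", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Richness shift between periods
#'
#' Overlaid frequency distributions of per-protected-area modelled species
#' richness in the reference and future periods.
#'
#' @param impact Per-PA impact tibble from [pa_impact()].
#' @param binwidth Histogram bin width (species).
#' @return A ggplot object.
#' @export
plot_richness_shift <- function(impact, binwidth = 2) {
  df <- impact |>
    dplyr::select("pa_id", reference = "refSR", future = "futureSR") |>
    tidyr::pivot_longer(c("reference", "future"), names_to = "period", values_to = "richness")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$richness, fill = .data$period)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity", alpha = 0.55) +
    ggplot2::labs(x = "modelled species richness", y = "protected areas", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Protected-range change per species
#'
#' Bar chart of species counts per class of protected-range change, with
#' decreases and increases distinguished.
#'
#' @param protection Tibble from [protected_range_change()].
#' @param breaks Class edges for `dPR` (%).
#' @return A ggplot object.
#' @export
plot_protection_change <- function(protection,
                                   breaks = c(-100, -50, 0, 50, 100, 200, 500, Inf)) {
  df <- protection |>
    dplyr::filter(!.data$excluded) |>
    dplyr::mutate(
      class = cut(.data$dPR, breaks = breaks, include.lowest = TRUE),
      direction = ifelse(.data$dPR < 0, "decrease", "increase")
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, fill = .data$direction)) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_manual(values = c(decrease = "grey85", increase = "grey35")) +
    ggplot2::labs(x = "change in protected range (%)", y = "species", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_impact_distribution
#' @param object A `refugia_run` from [run_pipeline()].
#' @param ... Unused.
#' @method autoplot refugia_run
#' @export
autoplot.refugia_run <- function(object, metric = "T", ...) {
  plot_impact_distribution(object$impact, object$distributions[[metric]], metric)
}
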