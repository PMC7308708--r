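#' Plot a derived metabolic series
#'
#' Time course of a derived variable with the dark phase shaded, one
#' panel per animal.
#'
#' @param series A [derive_metabolic_series()] tibble.
#' @param var Variable to plot (default `"vo2"`).
#' @param schedule A [photoperiod()] (used to shade the dark phase).
#' @return A ggplot object.
#' @export
plot_metabolic_series <- function(series, var = "vo2",
                                  schedule = photoperiod()) {
  stopifnot(var %in% names(series))
  ggplot2::ggplot(
    series,
    ggplot2::aes(x = .data$time, y = .data[[var]])
  ) +
    ggplot2::geom_point(
      data = dplyr::filter(series, .data$phase == "night"),
      colour = "grey75", size = 0.3
    ) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(
      ggplot2::vars(.data$animal_id),
      scales = "free_x"
    ) +
    ggplot2::labs(x = NULL, y = var) +
    ggplot2::theme_minimal()
}

#' 24 h polar diagram of event clock times
#'
#' Each group sits on its own concentric ring and each individual's event
#' time is a point on the 24 h clock face, the layout used for circadian
#' phase comparisons.
#'
#' @param polar A [polar_coordinates()] tibble (needs `angle_rad`,
#'   `radius_rank`, `group`).
#' @return A ggplot object.
#' @export
plot_polar_times <- function(polar) {
  ggplot2::ggplot(
    polar,
    ggplot2::aes(
      x = .data$angle_rad * 24 / (2 * pi), y = .data$radius_rank,
      colour = .data$group
    )
  ) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::coord_polar(start = 0) +
    ggplot2::scale_x_continuous(
      limits = c(0, 24), breaks = seq(0, 21, 3),
      labels = sprintf("%02d:00", seq(0, 21, 3))
    ) +
    ggplot2::scale_y_continuous(
      limits = c(0, max(polar$radius_rank) + 1), breaks = NULL
    ) +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Basal-to-stressed energy-phenotype plot
#'
#' Displacement of each sample from the basal phenotype (100%, 100%) to
#' the stressed phenotype after uncoupling, on %-of-baseline OCR and
#' ECAR axes; the arrow length is the metabolic potential.
#'
#' @param flux A [flux_metrics()] tibble.
#' @param group_cols Columns to colour by (first found is used).
#' @return A ggplot object.
#' @export
plot_energy_phenotype <- function(flux,
                                  group_cols = c("condition", "sex")) {
  gc <- intersect(group_cols, names(flux))
  df <- flux |>
    dplyr::filter(is.finite(.data$delta_ocr_pct)) |>
    dplyr::mutate(
      ocr_stressed = 100 + .data$delta_ocr_pct,
      ecar_stressed = 100 + .data$delta_ecar_pct
    )
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$ecar_stressed, y = .data$ocr_stressed)
  ) +
    ggplot2::annotate("point", x = 100, y = 100, shape = 3, size = 3) +
    ggplot2::labs(
      x = "stressed ECAR (% baseline)", y = "stressed OCR (% baseline)"
    ) +
    ggplot2::theme_minimal()
  if (length(gc) > 0) {
    p + ggplot2::geom_segment(
      ggplot2::aes(
        x = 100, y = 100,
        xend = .data$ecar_stressed, yend = .data$ocr_stressed,
        colour = .data[[gc[1]]]
      ),
      alpha = 0.5
    ) +
      ggplot2::geom_point(ggplot2::aes(colour = .data[[gc[1]]]), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}
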