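# ggplot2 visualisations of fits, bands and BMC summaries.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted concentration-response curve
#'
#' Data points, the fitted curve on a log-concentration axis and, when a
#' band is supplied, its ribbon plus the BMR line(s).
#'
#' @param object A `cr_fit`.
#' @param band Optional `cr_band`.
#' @param bmr Optional BMR in % to draw the benchmark-response lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cr_fit
#' @export
autoplot.cr_fit <- function(object, band = NULL, bmr = NULL, ...) {
  data <- object$data
  data <- data[data$concentration_uM > 0, ]
  grid <- band_grid(data$concentration_uM)
  curve <- tibble::tibble(
    concentration_uM = grid,
    response = predict(object, grid)
  )
  p <- ggplot2::ggplot(data,
                       ggplot2::aes(x = .data$concentration_uM,
                                    y = .data$response)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration [µM]",
                  y = "response [% of control]",
                  title = object$family_id)
  if (!is.null(band)) {
    p <- p + ggplot2::geom_ribbon(
      data = tidy(band),
      ggplot2::aes(x = .data$concentration_uM, ymin = .data$lower,
                   ymax = .data$upper),
      inherit.aes = FALSE, alpha = 0.2
    )
  }
  if (!is.null(bmr)) {
    p <- p + ggplot2::geom_hline(yintercept = c(100 - bmr, 100 + bmr),
                                 linetype = "dashed", colour = "grey40")
  }
  p +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point(alpha = 0.7)
}

#' Heatmap of BMCs per compound and endpoint
#'
#' Mirrors the screening summary matrix: one tile per (compound, endpoint),
#' filled by log10 BMC, hits outlined; censored strata are blank.
#'
#' @param bmc_table The `bmc_table` of a [run_pipeline()] result.
#' @return A ggplot object.
#' @export
plot_bmc_matrix <- function(bmc_table) {
  tbl <- dplyr::mutate(
    tibble::as_tibble(bmc_table),
    label = ifelse(.data$censored, "", signif(.data$bmc, 2))
  )
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$endpoint, y = .data$compound)) +
    ggplot2::geom_tile(ggplot2::aes(fill = log10(.data$bmc)),
                       colour = "white") +
    ggplot2::geom_tile(
      data = dplyr::filter(tbl, .data$is_hit),
      fill = NA, colour = "black", linewidth = 0.8
    ) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90",
                                  name = "log10 BMC [µM]") +
    ggplot2::labs(x = NULL, y = NULL)
}
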