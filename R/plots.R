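#' Per-stratum score distributions with calling thresholds
#'
#' Histograms of gene-set scores faceted by stratum, with the median + k*MAD
#' calling threshold overlaid, to visualise how the outlier rule separates
#' the senescent tail.
#'
#' @param calls Tibble from [call_senescent()].
#' @param stratum Column to facet by (default `"cell_type"` when present).
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(calls, stratum = NULL) {
  stratum <- stratum %||%
    (if ("cell_type" %in% names(calls)) "cell_type" else NULL)
  p <- ggplot2::ggplot(calls, ggplot2::aes(x = .data$score,
                                           fill = .data$senescent)) +
    ggplot2::geom_histogram(bins = 60, position = "identity") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$threshold_used),
                        linetype = 2, colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Gene-set score", y = "Nuclei",
                  fill = "Senescent") +
    ggplot2::theme_minimal()
  if (!is.null(stratum)) {
    p <- p + ggplot2::facet_wrap(stratum, scales = "free")
  }
  p
}

#' Per-sample senescent proportions by group
#'
#' Box/jitter plot of per-sample senescent proportions split by diagnosis,
#' faceted by stratum — the standard view of a proportion contrast.
#'
#' @param props Tibble from [sample_proportions()].
#' @param stratum Facet column (default `"cell_type"` when present).
#' @return A ggplot object.
#' @export
plot_proportions <- function(props, stratum = NULL) {
  stratum <- stratum %||%
    (if ("cell_type" %in% names(props)) "cell_type" else NULL)
  d <- filter(props, !.data$excluded)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$diagnosis,
                                       y = .data$proportion,
                                       colour = .data$diagnosis)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.8) +
    ggplot2::labs(x = NULL, y = "Senescent proportion") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
  if (!is.null(stratum)) p <- p + ggplot2::facet_wrap(stratum)
  p
}

#' ROI map of cells, plaques and peri-plaque calls
#'
#' Plots one ROI: cell centroids coloured by peri-plaque status, plaque
#' disks drawn to scale (y axis reversed to match the raster convention of
#' the coordinates).
#'
#' @param cells An `imaging_cell_table`.
#' @param plaques A [plaque_set()] with disks.
#' @param proximity Output of [classify_peri_plaque()].
#' @param roi ROI id to draw (default the first).
#' @return A ggplot object.
#' @export
plot_roi <- function(cells, plaques, proximity, roi = NULL) {
  roi <- roi %||% cells$roi_id[1]
  d <- dplyr::inner_join(as_tibble(cells),
                         proximity[, c("cell_id", "roi_id", "peri_plaque")],
                         by = c("cell_id", "roi_id")) %>%
    filter(.data$roi_id == roi)
  dk <- plaques$disks[plaques$disks$roi_id == roi, ]
  ang <- seq(0, 2 * pi, length.out = 60)
  circles <- purrr::map_dfr(seq_len(nrow(dk)), function(p) {
    tibble(plaque_id = dk$plaque_id[p],
           x = dk$cx_um[p] + dk$radius_um[p] * cos(ang),
           y = dk$cy_um[p] + dk$radius_um[p] * sin(ang))
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x_um, y = .data$y_um)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$peri_plaque), size = 1) +
    ggplot2::geom_polygon(data = circles,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       group = .data$plaque_id),
                          fill = "goldenrod", alpha = 0.5, colour = "grey20") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", colour = "Peri-plaque",
                  title = roi) +
    ggplot2::theme_minimal()
}
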