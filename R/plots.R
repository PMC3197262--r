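#' Plot a longitudinal slice of a phantom image
#'
#' @param object A `phantom_image`.
#' @param plane Longitudinal plane, `"xz"` or `"yz"`.
#' @param ... Unused.
#' @return A ggplot raster of the mid-slice with mm axes.
#' @export
autoplot.phantom_image <- function(object, plane = "xz", ...) {
  sl <- extract_mid_slice(object, plane = plane)
  df <- tidyr::expand_grid(x = sl$off_mm, z = sl$z_mm) |>
    dplyr::arrange(.data$z, .data$x)
  df$signal <- as.vector(sl$mat)
  ggplot2::ggplot(df, ggplot2::aes(.data$z, .data$x, fill = .data$signal)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "axial position (mm)", y = "offset from axis (mm)",
                  fill = "signal") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tile plot of the per-category scores
#'
#' One row per stent, one column per grading category, tiles coloured by
#' score — a compact overview of which stents fail on signal, narrowing or
#' homogeneity.
#'
#' @param grades A `stent_grades` table.
#' @return A ggplot object.
#' @export
plot_grade_summary <- function(grades) {
  long <- tidy(grades) |>
    dplyr::select("stent_id", "name", "score_si", "score_vis", "score_hom") |>
    tidyr::pivot_longer(dplyr::starts_with("score_"),
                        names_to = "category", values_to = "score",
                        names_prefix = "score_") |>
    dplyr::mutate(category = factor(.data$category,
                                    levels = c("si", "vis", "hom"),
                                    labels = c("signal intensity",
                                               "lumen narrowing",
                                               "homogeneity")))
  ggplot2::ggplot(long,
                  ggplot2::aes(.data$category,
                               stats::reorder(.data$name, -.data$stent_id),
                               fill = factor(.data$score))) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`1` = "#d73027", `2` = "#fee08b",
                                          `3` = "#1a9850"),
                               name = "score") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
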