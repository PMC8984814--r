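# ggplot2 displays for catalogs and cage geometries.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a catalog of optimized cages
#'
#' Maximum deformation against face edge count, coloured by classification;
#' the dashed lines mark the regular (1e-5) and near-miss (0.1) thresholds.
#'
#' @param object A `pcage_catalog`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcage_catalog
#' @export
autoplot.pcage_catalog <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$delta_l))
  df$max_def <- pmax(df$delta_l, df$delta_a)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$P), y = .data$max_def,
                                   colour = .data$classification)) +
    ggplot2::geom_jitter(width = 0.2, height = 0, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = c(1e-5, 0.1), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "face edge count P", y = "max(delta_l, delta_a)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cage geometry
#'
#' Simple orthographic projection along z: faces drawn as polygons,
#' back-to-front, shaded by depth.
#'
#' @param object A `pcage_geometry` (or `pcage_optimized`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcage_geometry
#' @export
autoplot.pcage_geometry <- function(object, ...) {
  topo <- object$topology
  df <- purrr::map_dfr(seq_len(topo$N), function(f) {
    pts <- object$coords[topo$faces[f, ], , drop = FALSE]
    tibble::tibble(face = f, x = pts[, 1], y = pts[, 2], depth = mean(pts[, 3]))
  })
  df$face <- stats::reorder(factor(df$face), df$depth)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, group = .data$face,
                                   fill = .data$depth)) +
    ggplot2::geom_polygon(colour = "grey20", linewidth = 0.3, alpha = 0.95) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_gradient(low = "#27408B", high = "#A6C8FF", guide = "none") +
    ggplot2::theme_void()
}

#' @method autoplot pcage_optimized
#' @export
autoplot.pcage_optimized <- function(object, ...) {
  autoplot(object$geometry, ...) +
    ggplot2::ggtitle(sprintf("%s (%s)", object$name, object$classification))
}

#' @export
print.pcage_labelings <- function(x, ...) {
  NextMethod()
}
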