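# ggplot2 displays for the main result types.

#' Plot a structured genome scan
#'
#' LOD curves by linkage group with the permutation threshold, in the
#' style of a standard interval-mapping figure.
#'
#' @param object A `scan_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scan_result <- function(object, ...) {
  d <- object$scan
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$lod)) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$group),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "summed LOD",
                  title = object$trait) +
    ggplot2::theme_minimal()
  if (!is.na(object$threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = object$threshold,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a multivariate scan
#'
#' @param object An `mv_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mv_scan <- function(object, ...) {
  p <- ggplot2::ggplot(object$scan,
                       ggplot2::aes(x = .data$pos, y = .data$pillai)) +
    ggplot2::geom_line(colour = "darkorange3") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$group),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "Pillai-Bartlett trace",
                  title = paste(object$traits, collapse = " + ")) +
    ggplot2::theme_minimal()
  if (!is.na(object$threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = object$threshold,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a genetic map
#'
#' Marker positions along each linkage group.
#'
#' @param object A `genetic_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genetic_map <- function(object, ...) {
  ggplot2::ggplot(object$map,
                  ggplot2::aes(x = factor(.data$group), y = .data$pos)) +
    ggplot2::geom_point(shape = 95, size = 6, colour = "grey20") +
    ggplot2::geom_line(ggplot2::aes(group = .data$group),
                       linewidth = 1.5, colour = "grey80") +
    ggplot2::labs(x = "linkage group", y = "position (cM)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
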