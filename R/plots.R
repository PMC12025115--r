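#' @importFrom ggplot2 ggplot aes geom_point geom_segment geom_boxplot
#'   geom_line labs theme_minimal coord_equal autoplot
NULL

#' Plot a cluster dendrogram
#'
#' A minimal segment-based dendrogram of a Ward merge tree, leaves in the
#' tree's plotting order.
#'
#' @param tree An `hclust` object.
#' @param labels Show leaf labels? (default off; trees of 100 leaves are
#'   unreadable with labels).
#' @return A ggplot object.
#' @export
plot_dendrogram <- function(tree, labels = FALSE) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  xpos <- numeric(n + nrow(tree$merge))
  ypos <- numeric(n + nrow(tree$merge))
  leaf_x <- stats::setNames(seq_len(n), tree$order)
  node_x <- function(k) if (k < 0) leaf_x[[as.character(-k)]] else xpos[n + k]
  node_y <- function(k) if (k < 0) 0 else ypos[n + k]
  segs <- vector("list", nrow(tree$merge))
  for (i in seq_len(nrow(tree$merge))) {
    a <- tree$merge[i, 1]; b <- tree$merge[i, 2]
    xa <- node_x(a); xb <- node_x(b)
    h <- tree$height[i]
    xpos[n + i] <- (xa + xb) / 2
    ypos[n + i] <- h
    segs[[i]] <- tibble(
      x = c(xa, xa, xb), xend = c(xa, xb, xb),
      y = c(node_y(a), h, node_y(b)), yend = c(h, h, h))
  }
  df <- dplyr::bind_rows(segs)
  p <- ggplot(df) +
    geom_segment(aes(x = .data$x, xend = .data$xend,
                     y = .data$y, yend = .data$yend)) +
    labs(x = NULL, y = "Height (weighted log-ratio scale)") +
    theme_minimal()
  if (labels && !is.null(tree$labels)) {
    lab <- tibble(x = seq_len(n), label = tree$labels[tree$order])
    p <- p + ggplot2::geom_text(data = lab,
                                aes(x = .data$x, y = 0, label = .data$label),
                                angle = 90, hjust = 1.1, size = 2.5)
  }
  p
}

#' Plot ternary coordinates
#'
#' @param coords Output of [ternary_coordinates()].
#' @param colour Optional column name used for point colour (e.g.
#'   `"cluster"`).
#' @return A ggplot object with the triangle frame and vertex labels.
#' @export
plot_ternary <- function(coords, colour = NULL) {
  v <- attr(coords, "vertices")
  tri <- tibble(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  p <- ggplot(coords, aes(x = .data$x, y = .data$y))
  if (!is.null(colour) && colour %in% names(coords)) {
    p <- ggplot(coords, aes(x = .data$x, y = .data$y,
                            colour = .data[[colour]]))
  }
  p + geom_point(alpha = 0.8) +
    ggplot2::geom_path(data = tri, aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE) +
    ggplot2::annotate("text", x = c(-0.03, 1.03, 0.5),
                      y = c(-0.03, -0.03, sqrt(3) / 2 + 0.04),
                      label = v) +
    coord_equal() +
    ggplot2::theme_void()
}

#' @describeIn logratio_biplot_coords Autoplot method: samples as points,
#'   parts as labelled arrows from the origin, axes annotated with explained
#'   variance.
#' @param object A `coda_biplot`.
#' @param ... Unused.
#' @param scale_loadings Multiplier applied to loadings for display.
#' @method autoplot coda_biplot
#' @export
autoplot.coda_biplot <- function(object, ..., scale_loadings = NULL) {
  sc <- object$scores
  ld <- object$loadings
  if (is.null(scale_loadings)) {
    scale_loadings <- 0.8 * max(abs(c(sc$axis1, sc$axis2))) /
      max(abs(c(ld$axis1, ld$axis2)))
  }
  pe <- round(100 * object$prop_explained[1:2], 1)
  ggplot(sc, aes(x = .data$axis1, y = .data$axis2)) +
    geom_point(alpha = 0.7) +
    geom_segment(data = ld,
                 aes(x = 0, y = 0, xend = .data$axis1 * scale_loadings,
                     yend = .data$axis2 * scale_loadings),
                 arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                 colour = "firebrick") +
    ggplot2::geom_text(data = ld,
                       aes(x = .data$axis1 * scale_loadings * 1.08,
                           y = .data$axis2 * scale_loadings * 1.08,
                           label = .data$part),
                       colour = "firebrick") +
    labs(x = paste0("Axis 1 (", pe[1], "%)"),
         y = paste0("Axis 2 (", pe[2], "%)")) +
    theme_minimal()
}

#' Plot log-ratio boxplot statistics
#'
#' @param stats Output of [logratio_boxstats()].
#' @return A ggplot object, one facet per part pair, boxes per cluster.
#' @export
plot_logratio_boxes <- function(stats) {
  stats$pair <- paste0("ln(", stats$num, "/", stats$den, ")")
  ggplot(stats, aes(x = .data$cluster,
                    ymin = .data$ymin, lower = .data$lower,
                    middle = .data$middle, upper = .data$upper,
                    ymax = .data$ymax)) +
    geom_boxplot(stat = "identity") +
    ggplot2::facet_wrap(~pair, scales = "free_y") +
    labs(x = NULL, y = "log ratio") +
    theme_minimal()
}

#' Plot a Raman spectrum with detected peaks
#'
#' @param s A `raman_spectrum`.
#' @param peaks Optional `peak_set` to mark.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(s, peaks = NULL) {
  p <- ggplot(s, aes(x = .data$shift, y = .data$intensity)) +
    geom_line() +
    labs(x = expression(paste("Raman shift (", cm^-1, ")")),
         y = "Intensity (a.u.)") +
    theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_vline(data = peaks,
                                 aes(xintercept = .data$position),
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}
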