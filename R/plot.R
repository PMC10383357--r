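#' Plot a tracing target
#'
#' Draws the shape in the report colour code: green segments for the shape's
#' path, a red dot at the trace start and a blue dot at the end. The y axis
#' is reversed so the plot matches image coordinates (y grows downward).
#'
#' @param object A [shape].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot swt_shape
#' @export
autoplot.swt_shape <- function(object, ...) {
  seg <- object$segments
  ends <- tibble(x = c(object$start[1], object$end[1]),
                 y = c(object$start[2], object$end[2]),
                 what = c("start", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1),
      colour = "green4", linewidth = 1) +
    ggplot2::geom_point(
      data = ends,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$what), size = 3) +
    ggplot2::scale_colour_manual(values = c(start = "red", end = "blue"),
                                 name = NULL) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = if (is.na(object$name)) NULL else object$name) +
    ggplot2::theme_minimal()
}

#' Plot a traced session over its shape
#'
#' Adds the drawn path (the legal drawing points, in pink) on top of the
#' shape plot.
#'
#' @param object A `swt_session`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot swt_session
#' @export
autoplot.swt_session <- function(object, ...) {
  p <- autoplot.swt_shape(object$shape)
  log <- tidy(object)
  if (nrow(log))
    p <- p + ggplot2::geom_path(
      data = log, ggplot2::aes(x = .data$x, y = .data$y),
      colour = "deeppink", linewidth = 0.8)
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# paint a filled disc onto an RGB array
paint_disc <- function(rgb, cx, cy, r, col) {
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  ys <- max(1, floor(cy - r + 1)):min(h, ceiling(cy + r + 1))
  xs <- max(1, floor(cx - r + 1)):min(w, ceiling(cx + r + 1))
  gy <- rep(ys, times = length(xs)); gx <- rep(xs, each = length(ys))
  hit <- (gx - 1 - cx)^2 + (gy - 1 - cy)^2 <= r^2
  for (ch in 1:3) rgb[cbind(gy[hit], gx[hit], ch)] <- col[ch]
  rgb
}

# paint a segment of given half-width onto an RGB array
paint_segment <- function(rgb, seg, half, col) {
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  xr <- max(1, floor(min(seg$x0, seg$x1) - half)):min(w, ceiling(max(seg$x0, seg$x1) + half + 1))
  yr <- max(1, floor(min(seg$y0, seg$y1) - half)):min(h, ceiling(max(seg$y0, seg$y1) + half + 1))
  gx <- rep(xr, each = length(yr)); gy <- rep(yr, times = length(xr))
  d <- point_segment_distance(seg, gx - 1, gy - 1)
  hit <- d <= half
  for (ch in 1:3) rgb[cbind(gy[hit], gx[hit], ch)] <- col[ch]
  rgb
}

#' Write an annotated overlay PNG
#'
#' Renders the shape (green), the start dot (red), the end dot (blue) and,
#' when a session is given, the drawn path (pink) into a raster image --
#' the audit picture of a session.
#'
#' @param shp A [shape].
#' @param path Output PNG path.
#' @param session Optional `swt_session` whose drawn path to overlay.
#' @param width,height Canvas size, px; defaults to the shape's bounding
#'   frame (1280x720 for display-space shapes, 512x512 for shape space).
#' @param background Background grey level in `[0, 1]`.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(shp, path, session = NULL,
                              width = NULL, height = NULL, background = 1) {
  stopifnot(inherits(shp, "swt_shape"))
  xmax <- max(shp$segments$x0, shp$segments$x1)
  ymax <- max(shp$segments$y0, shp$segments$y1)
  if (is.null(width)) width <- if (xmax <= 512) 512L else 1280L
  if (is.null(height)) height <- if (ymax <= 512) 512L else 720L
  rgb <- array(background, dim = c(height, width, 3))
  for (i in seq_len(nrow(shp$segments)))
    rgb <- paint_segment(rgb, shp$segments[i, , drop = FALSE], 1.5,
                         c(0, 0.6, 0))
  if (!is.null(session)) {
    log <- tidy(session)
    for (i in seq_len(nrow(log)))
      rgb <- paint_disc(rgb, log$x[i], log$y[i], 2, c(1, 0.08, 0.58))
  }
  rgb <- paint_disc(rgb, shp$start[1], shp$start[2], 6, c(1, 0, 0))
  if (shp$topology == "open")
    rgb <- paint_disc(rgb, shp$end[1], shp$end[2], 6, c(0, 0, 1))
  png::writePNG(rgb, path)
  invisible(path)
}
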