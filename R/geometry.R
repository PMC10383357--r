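#' Geometric primitives for straight-line tracing targets
#'
#' Segments live in image coordinates: the origin is the top-left pixel,
#' `x` grows to the right and `y` grows downward. A segment is one row of a
#' data frame with columns `x0`, `y0` (start) and `x1`, `y1` (end); every
#' function here is vectorised over the rows of that table, so a whole shape
#' can be queried against a point in one call.
#'
#' @param segments A data frame with numeric columns `x0`, `y0`, `x1`, `y1`,
#'   one straight segment per row.
#' @param x,y Coordinates of the query point, in pixels.
#' @name geometry
NULL

new_segments <- function(x0, y0, x1, y1) {
  tibble(x0 = as.numeric(x0), y0 = as.numeric(y0),
         x1 = as.numeric(x1), y1 = as.numeric(y1))
}

check_segments <- function(segments, allow_degenerate = FALSE) {
  need <- c("x0", "y0", "x1", "y1")
  if (!is.data.frame(segments) || !all(need %in% names(segments)))
    stop_solwrite("`segments` must be a data frame with columns x0, y0, x1, y1",
                  "solwrite_validation_error")
  if (nrow(segments) == 0L)
    stop_solwrite("`segments` must contain at least one segment",
                  "solwrite_validation_error")
  len <- segment_length(segments)
  if (!allow_degenerate && any(len <= 0))
    stop_solwrite("degenerate (zero-length) segment: angle and distances are undefined",
                  "solwrite_degenerate_segment")
  invisible(len)
}

#' @describeIn geometry Euclidean length of each segment, in pixels.
#' @export
segment_length <- function(segments) {
  sqrt((segments$x1 - segments$x0)^2 + (segments$y1 - segments$y0)^2)
}

#' @describeIn geometry Orientation-free angle of each segment's carrier
#'   line, in radians in `[0, pi)`. A segment and its reverse have the same
#'   angle; vertical segments map to `pi/2` (angle replaces raw slope so that
#'   vertical lines need no special casing).
#' @export
segment_angle <- function(segments) {
  check_segments(segments)
  a <- atan2(segments$y1 - segments$y0, segments$x1 - segments$x0) %% pi
  # atan2 of an exactly-reversed horizontal segment gives pi; fold it to 0
  ifelse(abs(a - pi) < 1e-12, 0, a)
}

#' @describeIn geometry Difference between two carrier-line angles on the
#'   half-circle: `min(|a-b|, pi - |a-b|)`.
#' @param a,b Angles in radians.
#' @export
angle_difference <- function(a, b) {
  d <- abs(a - b) %% pi
  pmin(d, pi - d)
}

#' @describeIn geometry Scalar position `t` of the foot of the perpendicular
#'   from the point onto each segment's carrier line: `t = 0` at the start,
#'   `t = 1` at the end, linear in between (and beyond).
#' @export
projection_parameter <- function(segments, x, y) {
  len <- check_segments(segments)
  dx <- segments$x1 - segments$x0
  dy <- segments$y1 - segments$y0
  ((x - segments$x0) * dx + (y - segments$y0) * dy) / len^2
}

#' @describeIn geometry Euclidean distance from the point to the closest
#'   point of each (clamped) segment, in pixels. Zero iff the point lies on
#'   the segment.
#' @export
point_segment_distance <- function(segments, x, y) {
  check_segments(segments)
  t <- pmin(1, pmax(0, projection_parameter(segments, x, y)))
  fx <- segments$x0 + t * (segments$x1 - segments$x0)
  fy <- segments$y0 + t * (segments$y1 - segments$y0)
  sqrt((x - fx)^2 + (y - fy)^2)
}

#' @describeIn geometry Signed perpendicular distance from the point to each
#'   segment's carrier (infinite) line. The magnitude is the point-to-line
#'   distance; the sign is positive on the left of the start-to-end travel
#'   direction in the y-down image frame, and flips when the point is
#'   mirrored across the line or the segment is reversed. Only relative
#'   consistency of the sign matters for the deviation log.
#' @export
signed_line_distance <- function(segments, x, y) {
  len <- check_segments(segments)
  dx <- segments$x1 - segments$x0
  dy <- segments$y1 - segments$y0
  (dx * (y - segments$y0) - dy * (x - segments$x0)) / len
}

#' @describeIn geometry Index (and distance) of the segment closest to the
#'   point under [point_segment_distance()]; ties resolve to the lowest index
#'   so replays are deterministic.
#' @return `nearest_segment()` returns a list with elements `index` and
#'   `distance`.
#' @export
nearest_segment <- function(segments, x, y) {
  d <- point_segment_distance(segments, x, y)
  i <- which.min(d)   # which.min takes the first minimum: lowest-index tie rule
  list(index = i, distance = d[[i]])
}

#' Is a drawing point inside the shape's tolerance band?
#'
#' A drawing position is legal when the disc of the given radius centred on
#' the point touches the shape, i.e. when the minimum clamped
#' point-to-segment distance over all shape segments is at most `radius`.
#' The matched (nearest) segment and the signed carrier-line deviation are
#' returned for the spasticity log regardless of legality.
#'
#' @param shape A [shape] object (or a bare segment table).
#' @param x,y Drawing-point centre, pixels.
#' @param radius Drawing radius, pixels.
#' @return A list: `legal` (logical), `segment` (index of the matched
#'   segment), `distance` (clamped distance to it, pixels) and `deviation`
#'   (signed carrier-line distance to it, pixels).
#' @export
is_legal_draw_point <- function(shape, x, y, radius) {
  segments <- if (inherits(shape, "swt_shape")) shape$segments else shape
  ns <- nearest_segment(segments, x, y)
  dev <- signed_line_distance(segments[ns$index, , drop = FALSE], x, y)
  list(legal = ns$distance <= radius,
       segment = ns$index,
       distance = ns$distance,
       deviation = dev)
}

# circular mean of carrier-line angles on [0, pi): average on the doubled
# circle so 179 deg and 1 deg average to 0 deg, not 90
mean_carrier_angle <- function(angles, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(angles))
  s <- sum(weights * sin(2 * angles))
  c <- sum(weights * cos(2 * angles))
  (atan2(s, c) / 2) %% pi
}
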