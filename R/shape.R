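#' Digital tracing targets
#'
#' A shape is the interactive digital version of the drawn figure: an ordered
#' table of merged straight segments walked from the trace's start point to
#' its end point, plus the topology (`"open"` for a polyline with two free
#' endpoints, `"closed"` for a polygon whose start and end coincide), the
#' start/end points themselves, and the perimeter (sum of segment lengths)
#' used by the completion check.
#'
#' @param segments Segment table (`x0`, `y0`, `x1`, `y1`), ordered along the
#'   trace path and oriented start-to-end.
#' @param topology `"open"` or `"closed"`.
#' @param start,end Numeric `c(x, y)` trace endpoints; equal for closed
#'   shapes.
#' @param name Optional label carried through to reports.
#' @return An object of class `swt_shape`.
#' @export
shape <- function(segments, topology = c("open", "closed"),
                  start, end, name = NA_character_) {
  topology <- match.arg(topology)
  check_segments(segments)
  segments <- as_tibble(segments[c("x0", "y0", "x1", "y1")])
  segments$length <- segment_length(segments)
  segments$angle <- segment_angle(segments)
  if (topology == "closed" && !isTRUE(all(abs(start - end) < 1e-6)))
    stop_solwrite("closed shape must have start == end", "solwrite_validation_error")
  structure(
    list(segments = segments, topology = topology,
         start = as.numeric(start), end = as.numeric(end),
         perimeter = sum(segments$length), name = name),
    class = "swt_shape")
}

#' @export
print.swt_shape <- function(x, ...) {
  cat(sprintf("<swt_shape%s> %s, %d segment(s), perimeter %.1f px\n",
              if (is.na(x$name)) "" else paste0(" ", x$name),
              x$topology, nrow(x$segments), x$perimeter))
  cat(sprintf("  start (%.1f, %.1f)  end (%.1f, %.1f)\n",
              x$start[1], x$start[2], x$end[1], x$end[2]))
  invisible(x)
}

#' @method tidy swt_shape
#' @export
tidy.swt_shape <- function(x, ...) {
  dplyr::mutate(x$segments, segment = dplyr::row_number(), .before = 1)
}

#' @method glance swt_shape
#' @export
glance.swt_shape <- function(x, ...) {
  tibble(name = x$name, topology = x$topology,
         n_segments = nrow(x$segments), perimeter = x$perimeter,
         start_x = x$start[1], start_y = x$start[2],
         end_x = x$end[1], end_y = x$end[2])
}

#' Map a 512x512 shape into the display frame
#'
#' The tracing target is detected in 512x512 shape space but the session runs
#' in camera/display coordinates. The mapping is a uniform scale that
#' preserves aspect ratio, sized so the shape canvas spans `fill` of the
#' smaller frame dimension, centred in the frame.
#'
#' @param shp An [shape] object in 512x512 space.
#' @param width,height Display frame size in pixels (default 1280x720).
#' @param fill Fraction of the limiting frame dimension the canvas occupies.
#' @param canvas Side length of the source canvas (512).
#' @return The shape with all coordinates and the perimeter rescaled.
#' @export
scale_shape <- function(shp, width = 1280, height = 720, fill = 0.9,
                        canvas = 512) {
  stopifnot(inherits(shp, "swt_shape"))
  s <- fill * min(width, height) / canvas
  ox <- (width - canvas * s) / 2
  oy <- (height - canvas * s) / 2
  tx <- function(x) ox + s * x
  ty <- function(y) oy + s * y
  seg <- new_segments(tx(shp$segments$x0), ty(shp$segments$y0),
                      tx(shp$segments$x1), ty(shp$segments$y1))
  shape(seg, shp$topology,
        start = c(tx(shp$start[1]), ty(shp$start[2])),
        end = c(tx(shp$end[1]), ty(shp$end[2])),
        name = shp$name)
}

#' Read and write shapes as JSON
#'
#' The on-disk form stores segments as `[x0, y0, x1, y1]` endpoint rows plus
#' topology, start, end, perimeter and name, so a detected shape can be
#' reused across sessions without re-running detection.
#'
#' @param shp A [shape] object.
#' @param path File path.
#' @return `write_shape_json()` returns `path` invisibly; `read_shape_json()`
#'   returns the [shape].
#' @export
write_shape_json <- function(shp, path) {
  stopifnot(inherits(shp, "swt_shape"))
  doc <- list(
    name = shp$name, topology = shp$topology,
    start = shp$start, end = shp$end, perimeter = shp$perimeter,
    segments = unname(as.matrix(shp$segments[c("x0", "y0", "x1", "y1")])))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_shape_json
#' @export
read_shape_json <- function(path) {
  if (!file.exists(path))
    stop_solwrite(paste0("shape file not found: ", path), "solwrite_io_error")
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  seg <- doc$segments
  if (is.null(dim(seg))) seg <- matrix(seg, ncol = 4, byrow = TRUE)
  shape(new_segments(seg[, 1], seg[, 2], seg[, 3], seg[, 4]),
        topology = doc$topology, start = doc$start, end = doc$end,
        name = if (is.null(doc$name) || is.na(doc$name)) NA_character_ else doc$name)
}
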