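#' Built-in stroke specifications
#'
#' A stroke spec is the ground truth behind a synthetic fixture: an ordered
#' list of straight strokes (endpoint pairs) in 512x512 shape space, a
#' stroke width, and whether the strokes form a cycle. Four figures are
#' built in, matching the shapes the test is typically run with: the letter
#' `"M"` (four strokes, open), a `"rectangle"` (closed), the Greek capital
#' `"Pi"` (three strokes, open) and a `"triangle"` (closed).
#'
#' @param name One of `builtin_shapes()`.
#' @param stroke_width Rendered stroke width, pixels (3-5 sensible; 4
#'   default).
#' @return A `swt_strokes` object: a tibble of strokes (`x0`, `y0`, `x1`,
#'   `y1`) with attributes `name`, `closed` and `stroke_width`.
#' @export
stroke_spec <- function(name, stroke_width = 4) {
  v <- switch(name,
    M = list(pts = rbind(c(80, 432), c(80, 80), c(256, 300),
                         c(432, 80), c(432, 432)), closed = FALSE),
    rectangle = list(pts = rbind(c(106, 156), c(406, 156),
                                 c(406, 356), c(106, 356)), closed = TRUE),
    Pi = list(pts = rbind(c(112, 416), c(112, 96),
                          c(400, 96), c(400, 416)), closed = FALSE),
    triangle = list(pts = rbind(c(256, 96), c(96, 416), c(416, 416)),
                    closed = TRUE),
    stop_solwrite(paste0("unknown fixture '", name, "'; built-ins: ",
                         paste(builtin_shapes(), collapse = ", ")),
                  "solwrite_validation_error"))
  pts <- v$pts
  if (v$closed) pts <- rbind(pts, pts[1, ])
  strokes <- new_segments(pts[-nrow(pts), 1], pts[-nrow(pts), 2],
                          pts[-1, 1], pts[-1, 2])
  if (any(pts < 0) || any(pts > 511))
    stop_solwrite("stroke endpoints must lie inside the 512x512 canvas",
                  "solwrite_validation_error")
  structure(strokes, name = name, closed = v$closed,
            stroke_width = stroke_width,
            class = c("swt_strokes", class(strokes)))
}

#' @rdname stroke_spec
#' @export
builtin_shapes <- function() c("M", "rectangle", "Pi", "triangle")

#' Analytic ground-truth shape of a stroke spec
#'
#' Builds the [shape] a perfect detector would recover: the spec's own
#' strokes, with topology, start/end points and path ordering derived by the
#' same junction rules the detection pipeline uses (bottom-leftmost free
#' endpoint starts an open trace; closed traces start and end at the
#' bottom-leftmost vertex).
#'
#' @param spec A `swt_strokes` object (or a built-in fixture name).
#' @return A [shape] in 512x512 coordinates.
#' @export
ground_truth_shape <- function(spec) {
  if (is.character(spec)) spec <- stroke_spec(spec)
  g <- shape_graph(spec, j_tol = 0.5)
  topology <- if (all(g$degree == 2L)) "closed" else "open"
  ep <- assign_endpoints(spec, topology, j_tol = 0.5)
  path <- order_path(g, ep$start, topology)
  shape(path, topology, start = ep$start, end = ep$end,
        name = attr(spec, "name") %||% NA_character_)
}

#' Render a stroke spec as a shape image
#'
#' Rasterises the strokes onto a white 512x512 canvas as black bands of the
#' spec's stroke width (butt caps: a pixel belongs to a stroke when its
#' perpendicular foot falls inside the stroke and its distance to it is at
#' most half the width). This is the synthetic stand-in for a physician's
#' scanned or digitally drawn figure.
#'
#' @inheritParams ground_truth_shape
#' @return A 512x512 matrix in {0, 1} (0 = stroke), directly consumable by
#'   [detect_edges()] or [build_shape()].
#' @export
render_shape_image <- function(spec) {
  if (is.character(spec)) spec <- stroke_spec(spec)
  w <- attr(spec, "stroke_width")
  img <- matrix(1, 512L, 512L)
  half <- w / 2
  for (i in seq_len(nrow(spec))) {
    s <- spec[i, , drop = FALSE]
    xr <- floor(min(s$x0, s$x1) - half):ceiling(max(s$x0, s$x1) + half)
    yr <- floor(min(s$y0, s$y1) - half):ceiling(max(s$y0, s$y1) + half)
    xr <- xr[xr >= 0 & xr <= 511]; yr <- yr[yr >= 0 & yr <= 511]
    gx <- rep(xr, each = length(yr))
    gy <- rep(yr, times = length(xr))
    tt <- projection_parameter(s, gx, gy)
    d <- point_segment_distance(s, gx, gy)
    hit <- tt >= 0 & tt <= 1 & d <= half
    img[cbind(gy[hit] + 1L, gx[hit] + 1L)] <- 0
  }
  img
}

# rigid 21-landmark template: offsets (px) of each landmark relative to the
# index fingertip (landmark 8) in display space for a right hand in tripod
# pose, y growing downward. Only landmarks 4, 8, 12 (and the wrist, for
# tracking) matter to the engine; the rest are anatomically plausible
# filler.
hand_template <- function() {
  rbind(
    c(  0, 180),  # 0 wrist
    c(-45, 150), c(-60, 115), c(-58,  80), c(-32,  38),  # thumb, tip = 4
    c(-18, 120), c(-12,  75), c( -6,  38), c(  0,   0),  # index, tip = 8
    c(  8, 118), c( 12,  72), c( 16,  38), c( 18,  30),  # middle, tip = 12
    c( 30, 120), c( 34,  80), c( 36,  50), c( 38,  40),  # ring
    c( 52, 125), c( 55,  92), c( 57,  68), c( 58,  55))  # pinky
}

#' Simulate a tracing trajectory as a landmark stream
#'
#' Generates the stream a hand tracker would emit while a subject traces a
#' fixture: the index fingertip follows the shape path at constant speed
#' with perpendicular Gaussian tremor (noise along the path would change
#' speed, not deviation, so perpendicular-only noise gives the spasticity
#' estimator a closed-form expectation), the thumb and middle fingertips ride
#' in tripod pose, and the remaining landmarks follow a rigid hand template.
#' Coordinates are produced directly in display space (the shape scaled with
#' [scale_shape()] into a 1280x720 frame by default).
#'
#' Failure events inject the scripted mishaps the engine must catch:
#' `release_pinch` opens the grip for 0.2 s, `jump_off_shape` displaces the
#' fingertip by five drawing radii for one frame, and `drop_hand` removes
#' 0.5 s of frames (longer than the tolerated detection gap).
#'
#' @param spec A `swt_strokes` object or built-in fixture name.
#' @param duration Seconds the full path traversal should take; mutually
#'   exclusive with `speed`.
#' @param speed Fingertip speed along the path, px/s in display space.
#' @param tremor_sigma Standard deviation of the perpendicular tremor, px.
#' @param frame_rate Frames per second (default 60, the reference camera).
#' @param events List of `list(time = seconds, type = "release_pinch" |
#'   "jump_off_shape" | "drop_hand")`.
#' @param seed Integer seed; the same seed yields a bit-identical stream.
#' @param radius Drawing radius the session will use (sets the
#'   `jump_off_shape` displacement), px.
#' @param fraction Stop the fingertip after this fraction of the path
#'   (then idle in place); 1 traces the whole path.
#' @param idle_until Keep emitting idle frames until this time, seconds
#'   (used by [half_trace()]); `NULL` ends the stream `post_roll` seconds
#'   after the path is done.
#' @param post_roll Seconds of trailing frames after the path is covered.
#' @param width,height,fill Display mapping, as in [scale_shape()].
#' @param display Set to `FALSE` to simulate in raw 512x512 shape space.
#' @return A landmark stream tibble (`t`, `lm`), with the display-space
#'   ground-truth shape attached as attribute `"shape"`.
#' @export
simulate_trajectory <- function(spec, duration = NULL, speed = NULL,
                                tremor_sigma = 0, frame_rate = 60,
                                events = list(), seed = 1, radius = 20,
                                fraction = 1, idle_until = NULL,
                                post_roll = 0.5, width = 1280, height = 720,
                                fill = 0.9, display = TRUE) {
  if (is.character(spec)) spec <- stroke_spec(spec)
  stopifnot(tremor_sigma >= 0, frame_rate > 0, fraction > 0, fraction <= 1)
  shp <- ground_truth_shape(spec)
  if (display) shp <- scale_shape(shp, width, height, fill)
  seg <- shp$segments
  cum <- c(0, cumsum(seg$length))
  L <- shp$perimeter
  if (is.null(speed)) {
    if (is.null(duration))
      stop_solwrite("give either `duration` or `speed`", "solwrite_validation_error")
    speed <- L / duration
  }
  stopifnot(speed > 0)
  t_path <- fraction * L / speed
  t_end <- if (is.null(idle_until)) t_path + post_roll else idle_until
  nf <- max(2L, ceiling(t_end * frame_rate) + 1L)
  t <- (seq_len(nf) - 1L) / frame_rate
  arc <- pmin(speed * t, fraction * L)
  # segment carrying each arc position (vertices belong to the later segment
  # except at the very end of the path)
  si <- pmin(findInterval(arc, cum, rightmost.closed = TRUE), nrow(seg))
  ux <- (seg$x1 - seg$x0)[si] / seg$length[si]
  uy <- (seg$y1 - seg$y0)[si] / seg$length[si]
  bx <- seg$x0[si] + ux * (arc - cum[si])
  by <- seg$y0[si] + uy * (arc - cum[si])
  noise <- with_local_seed(seed, rnorm(nf, 0, tremor_sigma))
  px <- bx + (-uy) * noise
  py <- by + ux * noise

  tmpl <- hand_template()
  pinch_open <- rep(FALSE, nf)
  drop <- rep(FALSE, nf)
  for (ev in events) {
    type <- ev$type %||% ev[[2]]
    time <- as.numeric(ev$time %||% ev[[1]])
    if (type == "release_pinch") {
      pinch_open <- pinch_open | (t >= time & t < time + 0.2)
    } else if (type == "jump_off_shape") {
      k <- which(t >= time)[1]
      if (!is.na(k)) {
        px[k] <- px[k] + (-uy[k]) * 5 * radius
        py[k] <- py[k] + ux[k] * 5 * radius
      }
    } else if (type == "drop_hand") {
      drop <- drop | (t >= time & t < time + 0.5)
    } else {
      stop_solwrite(paste0("unknown trajectory event type '", type, "'"),
                    "solwrite_validation_error")
    }
  }

  lm <- lapply(seq_len(nf), function(k) {
    m <- tmpl
    m[, 1] <- m[, 1] + px[k]
    m[, 2] <- m[, 2] + py[k]
    if (pinch_open[k]) m[LM_THUMB_TIP + 1L, ] <- m[LM_THUMB_TIP + 1L, ] + c(90, 60)
    m
  })
  frames <- tibble(t = t, lm = lm)[!drop, ]
  attr(frames, "shape") <- shp
  frames
}

#' Simulate a partial trace
#'
#' The fingertip covers the given fraction of the path and then idles in
#' place (still pinched, still on the shape) until just past the 60 s limit,
#' so the session ends `TIMED_OUT` and scores on the partial-performance
#' rule. `fraction = 1` reduces to a full [simulate_trajectory()].
#'
#' @inheritParams simulate_trajectory
#' @param fraction Fraction of the path to cover, in (0, 1].
#' @param total_time Stream duration, seconds (just past the time limit by
#'   default).
#' @return A landmark stream tibble.
#' @export
half_trace <- function(spec, fraction, duration = 30, total_time = 61,
                       tremor_sigma = 0, frame_rate = 60, seed = 1, ...) {
  stopifnot(fraction > 0, fraction <= 1)
  simulate_trajectory(spec, duration = duration, tremor_sigma = tremor_sigma,
                      frame_rate = frame_rate, seed = seed,
                      fraction = fraction, idle_until = total_time, ...)
}

#' Write a shape image as PNG
#'
#' @param img Image matrix in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shape_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}
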