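# shared fixtures, built in code and cached for the session

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# detected shape of a built-in fixture (full pipeline, fixed seed)
detected_shape <- function(name, seed = 0L) {
  cached(paste0("det_", name, "_", seed),
         build_shape(render_shape_image(name), seed = seed, name = name))
}

# analytic ground truth scaled into the default 1280x720 display frame
display_truth <- function(name) {
  cached(paste0("disp_", name), scale_shape(ground_truth_shape(name)))
}

# one horizontal segment as a one-row table
seg1 <- function(x0, y0, x1, y1) {
  tibble::tibble(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
}

# dense-sampling oracle: minimum distance from (x, y) to n points sampled
# uniformly along the segment
sampled_segment_distance <- function(s, x, y, n = 1e4) {
  t <- seq(0, 1, length.out = n)
  px <- s$x0 + t * (s$x1 - s$x0)
  py <- s$y0 + t * (s$y1 - s$y0)
  min(sqrt((px - x)^2 + (py - y)^2))
}

# Hausdorff-style distance between two nearly identical segments: the
# largest distance from either segment's endpoints to the other segment
segment_hausdorff <- function(a, b) {
  max(point_segment_distance(b, c(a$x0, a$x1), c(a$y0, a$y1)),
      point_segment_distance(a, c(b$x0, b$x1), c(b$y0, b$y1)))
}

# a landmark frame in tripod pose with the index tip at (x, y)
pinched_frame <- function(x, y, open_pinch = FALSE) {
  m <- solwrite:::hand_template()
  m[, 1] <- m[, 1] + x
  m[, 2] <- m[, 2] + y
  if (open_pinch) m[5, ] <- m[5, ] + c(90, 60)
  m
}

# build a stream tibble from vectors of times and index-tip positions
stream_of <- function(t, x, y, open_pinch = FALSE) {
  op <- rep_len(open_pinch, length(t))
  tibble::tibble(t = t, lm = lapply(seq_along(t), function(i)
    pinched_frame(x[i], y[i], op[i])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
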