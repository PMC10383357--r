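#' Shape detection: image in, tracing target out
#'
#' The detection pipeline turns a black-on-white drawing of a straight-line
#' figure into a [shape]: preprocessing (512x512, binarised), Canny edge
#' detection (hysteresis thresholds 50/150, Sobel aperture 3), probabilistic
#' Hough line extraction, duplicate-segment merging, topology classification
#' and start/end assignment. [build_shape()] composes the stages.
#'
#' Images are numeric matrices in `[0, 1]`, indexed `[row, col]` with row 1
#' the top of the image, so pixel coordinates are `x = col - 1`,
#' `y = row - 1` (y grows downward).
#'
#' @name shape_detection
NULL

#' Read a shape image file
#'
#' Decodes PNG (and TIFF, if the `tiff` package is available) into a
#' grayscale or colour array with intensities in `[0, 1]`.
#'
#' @param path Image file path.
#' @return Numeric matrix (grayscale) or array (colour).
#' @export
read_shape_image <- function(path) {
  if (!file.exists(path))
    stop_solwrite(paste0("image file not found: ", path), "solwrite_io_error")
  ext <- tolower(tools::file_ext(path))
  out <- tryCatch({
    if (ext %in% c("tif", "tiff")) {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop_solwrite("reading TIFF requires the 'tiff' package", "solwrite_io_error")
      tiff::readTIFF(path)
    } else {
      png::readPNG(path)
    }
  }, error = function(e) {
    stop_solwrite(paste0("could not decode image '", path, "': ",
                         conditionMessage(e)), "solwrite_io_error")
  })
  out
}

#' Preprocess a raw shape image
#'
#' Enforces the input contract for shape detection: the figure must be black
#' strokes on a white background (no colour, no gray-level content) and the
#' working resolution is 512x512. Colour images whose channels disagree, or
#' grayscale images with more than `mid_gray_max` of pixels at intermediate
#' intensities, are rejected. Compliant inputs are resized to 512x512
#' (bilinear) and binarised with Otsu's threshold.
#'
#' @param raw Numeric matrix or array in `[0, 1]` as returned by
#'   [read_shape_image()].
#' @param mid_gray_max Maximum tolerated fraction of mid-gray pixels
#'   (intensity in (0.2, 0.8)) before binarisation; default 5%.
#' @param size Working resolution (512).
#' @return A `size` x `size` numeric matrix with values in {0, 1}
#'   (0 = stroke, 1 = background).
#' @export
preprocess_image <- function(raw, mid_gray_max = 0.05, size = 512L) {
  if (is.array(raw) && length(dim(raw)) == 3L) {
    nch <- dim(raw)[3]
    ch <- if (nch >= 3L) raw[, , 1:3, drop = FALSE] else raw[, , 1, drop = FALSE]
    if (dim(ch)[3] == 3L) {
      spread <- pmax(ch[, , 1], ch[, , 2], ch[, , 3]) -
        pmin(ch[, , 1], ch[, , 2], ch[, , 3])
      if (mean(spread > 0.1) > 0.01)
        stop_solwrite(
          "input image is coloured; the shape image must be black and white",
          "solwrite_validation_error")
      g <- (ch[, , 1] + ch[, , 2] + ch[, , 3]) / 3
    } else g <- ch[, , 1]
  } else if (is.matrix(raw)) {
    g <- raw
  } else {
    stop_solwrite("`raw` must be an image matrix or array", "solwrite_validation_error")
  }
  g <- pmin(pmax(g, 0), 1)
  if (mean(g > 0.2 & g < 0.8) > mid_gray_max)
    stop_solwrite(
      "input image has gray-level content; the shape image must be black and white",
      "solwrite_validation_error")
  if (!all(dim(g) == c(size, size))) {
    img <- EBImage::resize(EBImage::Image(t(g)), w = size, h = size)
    g <- t(EBImage::imageData(img))
    g <- pmin(pmax(g, 0), 1)
  }
  th <- EBImage::otsu(EBImage::Image(t(g)), range = c(0, 1))
  bin <- ifelse(g < th, 0, 1)
  frac_stroke <- mean(bin == 0)
  if (frac_stroke == 0)
    stop_solwrite("no shape content: the image contains no black strokes",
                  "solwrite_validation_error")
  if (frac_stroke > 0.5)
    stop_solwrite("expected black strokes on a white background",
                  "solwrite_validation_error")
  bin
}

# value of the 8-neighbour at offset (dy, dx), replicate border
shift_mat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  m[pmin(pmax(seq_len(nr) + dy, 1L), nr),
    pmin(pmax(seq_len(nc) + dx, 1L), nc)]
}

#' Canny edge detection
#'
#' Classic Canny on a preprocessed binary image: 3x3 Sobel gradients
#' (replicate border), L1 gradient magnitude, non-maximum suppression
#' quantised to four directions, and hysteresis thresholding in which pixels
#' above `high` are sure edges and pixels above `low` are kept only when
#' 8-connected to a sure edge. Defaults follow the tuned values for
#' black-and-white shape images: thresholds 50/150 on the 0-255 intensity
#' scale, Sobel aperture 3.
#'
#' @param img Preprocessed image matrix in `[0, 1]` (see
#'   [preprocess_image()]).
#' @param low,high Hysteresis thresholds on the 0-255 scale.
#' @param aperture Sobel aperture; only the 3x3 operator is implemented.
#' @return Logical matrix of edge pixels.
#' @export
detect_edges <- function(img, low = 50, high = 150, aperture = 3L) {
  if (aperture != 3L)
    stop_solwrite("only the 3x3 Sobel aperture is supported", "solwrite_validation_error")
  m <- img * 255
  E <- function(dy, dx) shift_mat(m, dy, dx)
  gx <- (E(-1, 1) - E(-1, -1)) + 2 * (E(0, 1) - E(0, -1)) + (E(1, 1) - E(1, -1))
  gy <- (E(1, -1) - E(-1, -1)) + 2 * (E(1, 0) - E(-1, 0)) + (E(1, 1) - E(-1, 1))
  mag <- abs(gx) + abs(gy)

  # non-maximum suppression: compare against the two neighbours along the
  # gradient direction, quantised to 0/45/90/135 degrees
  ang <- atan2(gy, gx) %% pi
  sector <- floor(((ang + pi / 8) %% pi) / (pi / 4))  # 0..3
  M <- function(dy, dx) shift_mat(mag, dy, dx)
  na_ <- matrix(0, nrow(m), ncol(m)); nb_ <- na_
  sel <- sector == 0; na_[sel] <- M(0, 1)[sel];  nb_[sel] <- M(0, -1)[sel]
  sel <- sector == 1; na_[sel] <- M(1, 1)[sel];  nb_[sel] <- M(-1, -1)[sel]
  sel <- sector == 2; na_[sel] <- M(1, 0)[sel];  nb_[sel] <- M(-1, 0)[sel]
  sel <- sector == 3; na_[sel] <- M(-1, 1)[sel]; nb_[sel] <- M(1, -1)[sel]
  keep <- mag > na_ & mag >= nb_
  # border pixels have replicated gradients; exclude them so the BFS below
  # never walks off the matrix
  keep[c(1, nrow(keep)), ] <- FALSE
  keep[, c(1, ncol(keep))] <- FALSE

  strong <- keep & mag > high
  weak <- keep & mag > low
  edge <- strong
  stack <- which(strong)
  nr <- nrow(m)
  offs <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  while (length(stack)) {
    nb <- rep(stack, each = 8L) + offs
    nb <- nb[weak[nb] & !edge[nb]]
    nb <- unique(nb)
    edge[nb] <- TRUE
    stack <- nb
  }
  edge
}

#' Extract raw line segments with a probabilistic Hough transform
#'
#' Progressive probabilistic Hough: edge points are visited in a seeded
#' random order, each voting over all line orientations; when a point's best
#' accumulator cell reaches `threshold` votes, the supporting pixels along
#' that line are gathered (within a narrow band around a total-least-squares
#' refit of the candidate), split at gaps longer than `max_gap`, and the run
#' containing the triggering point becomes a segment if it is at least
#' `min_length` long. Extracted pixels are removed and their votes retracted,
#' so each edge pixel supports at most one segment. Over-detection (several
#' raw segments per drawn stroke, e.g. one per stroke boundary) is expected
#' and resolved later by [merge_duplicate_segments()].
#'
#' @param edges Logical edge map from [detect_edges()].
#' @param seed Integer seed controlling the random visiting order; fixed
#'   seed implies bit-identical output.
#' @param threshold Accumulator votes needed to trigger a line.
#' @param min_length Minimum segment length, pixels.
#' @param max_gap Maximum gap between supporting pixels along the line,
#'   pixels.
#' @param theta_step Angular resolution, radians (default 1 degree).
#' @param band Half-width of the pixel-gathering band around the candidate
#'   line, pixels.
#' @return Tibble of raw segments (`x0`, `y0`, `x1`, `y1`, `length`,
#'   `angle`).
#' @export
extract_raw_segments <- function(edges, seed = 0L, threshold = 30L,
                                 min_length = 30, max_gap = 10,
                                 theta_step = pi / 180, band = 2) {
  idx <- which(edges)
  if (!length(idx))
    stop_solwrite("no straight lines detected: edge map is empty",
                  "solwrite_detection_error")
  nr <- nrow(edges)
  X <- ((idx - 1L) %/% nr)      # 0-based x = column - 1
  Y <- ((idx - 1L) %% nr)       # 0-based y = row - 1
  n <- length(idx)
  thetas <- seq(0, pi - theta_step / 2, by = theta_step)
  nth <- length(thetas)
  ct <- cos(thetas); st <- sin(thetas)
  D <- ceiling(sqrt(nrow(edges)^2 + ncol(edges)^2))
  acc <- matrix(0L, nth, 2L * D + 1L)
  th_seq <- seq_len(nth)
  alive <- rep(TRUE, n)
  voted <- rep(FALSE, n)
  ord <- with_local_seed(seed, sample.int(n))
  segs <- list()

  for (i in ord) {
    if (!alive[i]) next
    rho_idx <- as.integer(round(X[i] * ct + Y[i] * st)) + D + 1L
    cells <- cbind(th_seq, rho_idx)
    acc[cells] <- acc[cells] + 1L
    voted[i] <- TRUE
    vals <- acc[cells]
    j <- which.max(vals)
    if (vals[j] < threshold) next

    # candidate carrier line through this point at the winning orientation
    nx <- ct[j]; ny <- st[j]
    d0 <- (X - X[i]) * nx + (Y - Y[i]) * ny
    in_band <- alive & abs(d0) <= band
    if (sum(in_band) < 2L) next
    # refine by total least squares on the banded pixels, then re-gather
    cx <- mean(X[in_band]); cy <- mean(Y[in_band])
    cm <- cbind(X[in_band] - cx, Y[in_band] - cy)
    ev <- eigen(crossprod(cm), symmetric = TRUE)
    u <- ev$vectors[, 1]                       # line direction
    dperp <- (X - cx) * (-u[2]) + (Y - cy) * u[1]
    in_band2 <- alive & abs(dperp) <= max(1.6, band * 0.8)
    pts <- which(in_band2)
    if (!length(pts)) next
    tproj <- (X[pts] - cx) * u[1] + (Y[pts] - cy) * u[2]
    o <- order(tproj)
    pts <- pts[o]; tproj <- tproj[o]
    run_id <- cumsum(c(0L, diff(tproj) > max_gap))
    # the run containing (or nearest to) the triggering point
    t_seed <- (X[i] - cx) * u[1] + (Y[i] - cy) * u[2]
    if (i %in% pts) {
      rid <- run_id[match(i, pts)]
    } else {
      rid <- run_id[which.min(abs(tproj - t_seed))]
    }
    sel <- run_id == rid
    run <- pts[sel]
    tmin <- min(tproj[sel]); tmax <- max(tproj[sel])

    # retract the run's pixels and their votes
    alive[run] <- FALSE
    for (k in run[voted[run]]) {
      ri <- as.integer(round(X[k] * ct + Y[k] * st)) + D + 1L
      ck <- cbind(th_seq, ri)
      acc[ck] <- acc[ck] - 1L
    }
    voted[run] <- FALSE

    if (tmax - tmin >= min_length) {
      segs[[length(segs) + 1L]] <-
        c(cx + u[1] * tmin, cy + u[2] * tmin, cx + u[1] * tmax, cy + u[2] * tmax)
    }
  }

  if (!length(segs))
    stop_solwrite("no straight lines detected", "solwrite_detection_error")
  m <- do.call(rbind, segs)
  out <- new_segments(m[, 1], m[, 2], m[, 3], m[, 4])
  out$length <- segment_length(out)
  out$angle <- segment_angle(out)
  out
}

#' Merge duplicate line segments
#'
#' The Hough stage typically detects several nearly-coincident segments per
#' drawn stroke (one per stroke boundary, plus fragments). Two segments are
#' duplicates when their midpoints are closer than `d_tol` and their
#' carrier-line angles differ by less than `a_tol`. Duplicate pairs are
#' merged repeatedly until a fixpoint: the merged segment lies on the
#' length-weighted mean carrier line of the pair and spans the extreme
#' projections of all four endpoints onto it, so the total extent is
#' preserved. The operation is idempotent and never increases the segment
#' count.
#'
#' @param segments Raw segment table.
#' @param d_tol Midpoint distance tolerance, pixels.
#' @param a_tol Angle difference tolerance, radians (default 5 degrees).
#' @return Tibble of merged segments.
#' @export
merge_duplicate_segments <- function(segments, d_tol = 15, a_tol = 5 * pi / 180) {
  check_segments(segments)
  seg <- as.matrix(segments[c("x0", "y0", "x1", "y1")])
  repeat {
    k <- nrow(seg)
    if (k < 2L) break
    mx <- (seg[, 1] + seg[, 3]) / 2
    my <- (seg[, 2] + seg[, 4]) / 2
    len <- sqrt((seg[, 3] - seg[, 1])^2 + (seg[, 4] - seg[, 2])^2)
    ang <- atan2(seg[, 4] - seg[, 2], seg[, 3] - seg[, 1]) %% pi
    pair <- NULL
    for (i in seq_len(k - 1L)) {
      dmid <- sqrt((mx[-(1:i)] - mx[i])^2 + (my[-(1:i)] - my[i])^2)
      dang <- angle_difference(ang[-(1:i)], ang[i])
      hit <- which(dmid < d_tol & dang < a_tol)
      if (length(hit)) { pair <- c(i, i + hit[1]); break }
    }
    if (is.null(pair)) break
    i <- pair[1]; j <- pair[2]
    w <- len[c(i, j)]
    a <- mean_carrier_angle(ang[c(i, j)], w)
    u <- c(cos(a), sin(a))
    cx <- sum(w * mx[c(i, j)]) / sum(w)
    cy <- sum(w * my[c(i, j)]) / sum(w)
    ex <- c(seg[i, c(1, 3)], seg[j, c(1, 3)])
    ey <- c(seg[i, c(2, 4)], seg[j, c(2, 4)])
    tp <- (ex - cx) * u[1] + (ey - cy) * u[2]
    merged <- c(cx + u[1] * min(tp), cy + u[2] * min(tp),
                cx + u[1] * max(tp), cy + u[2] * max(tp))
    seg[i, ] <- merged
    seg <- seg[-j, , drop = FALSE]
  }
  out <- new_segments(seg[, 1], seg[, 2], seg[, 3], seg[, 4])
  out$length <- segment_length(out)
  out$angle <- segment_angle(out)
  out
}

# Junction graph of a merged segment set: endpoints within j_tol of each
# other snap to a shared vertex (cluster mean). Returns vertices, per-vertex
# degree, the segment->vertex incidence, and the snapped segment table.
shape_graph <- function(segments, j_tol = 12) {
  check_segments(segments)
  k <- nrow(segments)
  ex <- c(segments$x0, segments$x1)
  ey <- c(segments$y0, segments$y1)
  np <- 2L * k
  parent <- seq_len(np)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
    if ((ex[i] - ex[j])^2 + (ey[i] - ey[j])^2 <= j_tol^2) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  root <- vapply(seq_len(np), find, integer(1))
  vid <- match(root, unique(root))
  nv <- max(vid)
  vx <- vapply(seq_len(nv), function(v) mean(ex[vid == v]), numeric(1))
  vy <- vapply(seq_len(nv), function(v) mean(ey[vid == v]), numeric(1))
  v0 <- vid[seq_len(k)]        # vertex of each segment's start endpoint
  v1 <- vid[k + seq_len(k)]    # ... and end endpoint
  if (any(v0 == v1))
    stop_solwrite("a segment collapsed onto a single junction; junction tolerance too large for this shape",
                  "solwrite_detection_error")
  degree <- tabulate(c(v0, v1), nv)
  # connectivity over the vertex graph
  comp <- rep(NA_integer_, nv)
  cur <- 0L
  for (s in seq_len(nv)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nbr <- c(v1[v0 == v], v0[v1 == v])
      nbr <- nbr[is.na(comp[nbr])]
      comp[nbr] <- cur
      queue <- c(queue, nbr)
    }
  }
  if (cur > 1L)
    stop_solwrite("shape is not a single connected trace",
                  "solwrite_detection_error")
  snapped <- new_segments(vx[v0], vy[v0], vx[v1], vy[v1])
  list(vx = vx, vy = vy, degree = degree, v0 = v0, v1 = v1,
       segments = snapped)
}

#' Classify a merged segment set as an open or closed shape
#'
#' A shape is closed when its segments form a single cycle: after snapping
#' endpoints within `j_tol` pixels into shared junction vertices, every
#' vertex must join exactly two segment endpoints. Anything else (a polyline
#' with two free endpoints, a T-junction, ...) is open. Disconnected input
#' is an error.
#'
#' @inheritParams merge_duplicate_segments
#' @param j_tol Junction snap tolerance, pixels.
#' @return `"open"` or `"closed"`.
#' @export
classify_topology <- function(segments, j_tol = 12) {
  g <- shape_graph(segments, j_tol)
  if (all(g$degree == 2L)) "closed" else "open"
}

#' Assign the trace's start and end points
#'
#' For an open shape the trace starts at the bottom-leftmost free endpoint
#' and ends at the bottom-rightmost one ("bottom" meaning larger y in image
#' coordinates); the shape must be a single path, i.e. have exactly two
#' free (degree-1) endpoints. For a closed shape the start and end coincide
#' at the bottom-leftmost junction vertex.
#'
#' @inheritParams classify_topology
#' @param topology Optional precomputed topology; classified from the
#'   segments when omitted.
#' @return List with numeric `start` and `end` points.
#' @export
assign_endpoints <- function(segments, topology = NULL, j_tol = 12) {
  g <- shape_graph(segments, j_tol)
  if (is.null(topology))
    topology <- if (all(g$degree == 2L)) "closed" else "open"
  if (topology == "closed") {
    cand <- order(-g$vy, g$vx)[1]
    p <- c(g$vx[cand], g$vy[cand])
    return(list(start = p, end = p))
  }
  free <- which(g$degree == 1L)
  if (length(free) != 2L || any(g$degree > 2L))
    stop_solwrite("trace is not a single path: an open shape must have exactly two free endpoints",
                  "solwrite_detection_error")
  o <- free[order(-g$vy[free], g$vx[free])]
  list(start = c(g$vx[o[1]], g$vy[o[1]]),
       end = c(g$vx[o[2]], g$vy[o[2]]))
}

# order the snapped segments along the trace path from start to end,
# orienting each segment in walk direction
order_path <- function(g, start, topology) {
  k <- length(g$v0)
  sv <- which.min((g$vx - start[1])^2 + (g$vy - start[2])^2)
  used <- rep(FALSE, k)
  out <- matrix(NA_real_, k, 4)
  cur <- sv
  for (step_i in seq_len(k)) {
    inc <- which(!used & (g$v0 == cur | g$v1 == cur))
    if (!length(inc))
      stop_solwrite("trace walk failed: path is broken", "solwrite_detection_error")
    if (length(inc) > 1L) {
      # only happens at the start vertex of a cycle: deterministic direction,
      # towards the neighbour with the smaller x
      nxt <- vapply(inc, function(s) if (g$v0[s] == cur) g$v1[s] else g$v0[s],
                    integer(1))
      inc <- inc[order(g$vx[nxt], g$vy[nxt])]
    }
    s <- inc[1]
    nxt <- if (g$v0[s] == cur) g$v1[s] else g$v0[s]
    out[step_i, ] <- c(g$vx[cur], g$vy[cur], g$vx[nxt], g$vy[nxt])
    used[s] <- TRUE
    cur <- nxt
  }
  new_segments(out[, 1], out[, 2], out[, 3], out[, 4])
}

#' Detect the tracing target in a shape image
#'
#' Runs the whole detection pipeline: [preprocess_image()] (512x512,
#' binarised), [detect_edges()] (Canny 50/150, aperture 3),
#' [extract_raw_segments()] (probabilistic Hough, seeded),
#' [merge_duplicate_segments()], topology classification and start/end
#' assignment. Stage failures are reported with the failing stage's name.
#'
#' @param raw Raw image matrix/array (see [read_shape_image()]), or a file
#'   path.
#' @param seed Seed for the probabilistic Hough stage; a fixed seed makes
#'   the detected shape bit-identical across runs.
#' @param params Detection parameters; see [detection_params()].
#' @param name Optional shape label.
#' @return A [shape] in 512x512 coordinates, segments ordered along the
#'   trace path.
#' @export
build_shape <- function(raw, seed = 0L, params = detection_params(),
                        name = NA_character_) {
  run_stage <- function(stage, expr) {
    withCallingHandlers(expr, error = function(e) {
      if (is.null(attr(e, "solwrite_stage"))) {
        e$message <- paste0("shape detection [", stage, "]: ", conditionMessage(e))
        attr(e, "solwrite_stage") <- stage
        stop(e)
      }
    })
  }
  if (is.character(raw)) raw <- read_shape_image(raw)
  img <- run_stage("preprocess", preprocess_image(raw, params$mid_gray_max))
  edges <- run_stage("edges", detect_edges(img, params$canny_low,
                                           params$canny_high, params$aperture))
  raw_seg <- run_stage("hough", extract_raw_segments(
    edges, seed = seed, threshold = params$hough_threshold,
    min_length = params$hough_min_length, max_gap = params$hough_max_gap))
  merged <- run_stage("merge", merge_duplicate_segments(
    raw_seg, d_tol = params$merge_d_tol, a_tol = params$merge_a_tol))
  g <- run_stage("topology", shape_graph(merged, params$junction_tol))
  topology <- if (all(g$degree == 2L)) "closed" else "open"
  ep <- run_stage("endpoints", assign_endpoints(merged, topology,
                                                params$junction_tol))
  path <- run_stage("ordering", order_path(g, ep$start, topology))
  shp <- shape(path, topology, start = ep$start, end = ep$end, name = name)
  attr(shp, "n_raw_segments") <- nrow(raw_seg)
  shp
}

#' Detection parameter set
#'
#' Bundles the tunables of the detection pipeline with their defaults:
#' Canny hysteresis thresholds 50/150 with Sobel aperture 3 (the values
#' tuned for black-and-white shape images), Hough accumulator threshold 30
#' with minimum line length 30 px and maximum gap 10 px (a standard starting
#' point for 512x512 binary glyphs), duplicate tolerances of 15 px midpoint
#' distance and 5 degrees angle, and a 12 px junction snap tolerance.
#'
#' @param canny_low,canny_high Canny hysteresis thresholds (0-255 scale).
#' @param aperture Sobel aperture (3).
#' @param hough_threshold,hough_min_length,hough_max_gap Probabilistic
#'   Hough parameters, pixels/votes.
#' @param merge_d_tol,merge_a_tol Duplicate-segment tolerances (pixels,
#'   radians).
#' @param junction_tol Endpoint snap tolerance, pixels.
#' @param mid_gray_max Maximum mid-gray pixel fraction accepted by
#'   preprocessing.
#' @return Named list of parameters.
#' @export
detection_params <- function(canny_low = 50, canny_high = 150, aperture = 3L,
                             hough_threshold = 30L, hough_min_length = 30,
                             hough_max_gap = 10, merge_d_tol = 15,
                             merge_a_tol = 5 * pi / 180, junction_tol = 12,
                             mid_gray_max = 0.05) {
  if (canny_low >= canny_high)
    stop_solwrite("canny_low must be below canny_high", "solwrite_validation_error")
  list(canny_low = canny_low, canny_high = canny_high, aperture = aperture,
       hough_threshold = hough_threshold, hough_min_length = hough_min_length,
       hough_max_gap = hough_max_gap, merge_d_tol = merge_d_tol,
       merge_a_tol = merge_a_tol, junction_tol = junction_tol,
       mid_gray_max = mid_gray_max)
}
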