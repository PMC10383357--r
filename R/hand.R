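#' Hand landmark frames and the tripod-pinch grip
#'
#' A landmark frame is one timestamped observation of the 21 standard hand
#' keypoints in display pixel coordinates, indexed 0-20 in the usual
#' hand-tracking numbering: 0 is the wrist, 4 the thumb tip, 8 the index
#' finger tip, 12 the middle finger tip. A stream is a tibble with a strictly
#' increasing `t` column (seconds) and an `lm` list-column of 21x2 matrices
#' (columns x, y). The landmark *source* is abstract: streams may come from a
#' JSONL replay file, from the built-in trajectory simulator, or from a live
#' tracking adapter; the tracing engine never touches a tracking library.
#'
#' @name hand_model
NULL

LM_WRIST <- 0L
LM_THUMB_TIP <- 4L
LM_INDEX_TIP <- 8L
LM_MIDDLE_TIP <- 12L

check_landmarks <- function(lm) {
  if (!is.matrix(lm) || !identical(dim(lm), c(21L, 2L)) || !is.numeric(lm) ||
      any(!is.finite(lm)))
    stop_solwrite("a landmark frame must be a finite numeric 21x2 matrix",
                  "solwrite_validation_error")
  invisible(lm)
}

#' Euclidean distance between two landmarks of a frame
#'
#' @param lm A 21x2 landmark matrix (or a one-row stream tibble's `lm[[1]]`).
#' @param a,b Landmark indices in 0-20.
#' @return Distance in pixels.
#' @export
fingertip_distance <- function(lm, a, b) {
  check_landmarks(lm)
  if (any(c(a, b) < 0L) || any(c(a, b) > 20L))
    stop_solwrite("landmark indices must lie in 0..20", "solwrite_validation_error")
  d <- lm[a + 1L, ] - lm[b + 1L, ]
  sqrt(sum(d^2))
}

#' Is the hand holding a tripod pinch?
#'
#' The writing grip requires the thumb, index and middle fingertips to be
#' brought together: both the index-to-thumb and the middle-to-thumb
#' distances must be strictly below the threshold. The default threshold of
#' 60 px is tuned for a hand about 50 cm from a 1280x720 camera and is
#' configurable per session.
#'
#' @inheritParams fingertip_distance
#' @param threshold Pinch distance threshold, pixels (strict `<`).
#' @return Logical flag.
#' @export
is_tripod_pinch <- function(lm, threshold = 60) {
  if (threshold <= 0)
    stop_solwrite("pinch threshold must be positive", "solwrite_validation_error")
  fingertip_distance(lm, LM_THUMB_TIP, LM_INDEX_TIP) < threshold &&
    fingertip_distance(lm, LM_THUMB_TIP, LM_MIDDLE_TIP) < threshold
}

#' The drawing point of a frame
#'
#' The drawing point is the disc centred on the index fingertip (landmark 8)
#' whose radius sets the tracing tolerance. The radius is clinically bounded:
#' 20 px (the most challenging setting) to 40 px (the most permissive).
#'
#' @inheritParams fingertip_distance
#' @param radius Drawing radius, pixels, in `[20, 40]`.
#' @return List with `center` (`c(x, y)`) and `radius`.
#' @export
drawing_point <- function(lm, radius) {
  check_radius(radius)
  check_landmarks(lm)
  list(center = lm[LM_INDEX_TIP + 1L, ], radius = radius)
}

check_radius <- function(radius) {
  if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) ||
      radius < 20 || radius > 40)
    stop_solwrite("drawing radius must lie in [20, 40] pixels",
                  "solwrite_validation_error")
  invisible(radius)
}

#' Sticky selection of the tracked hand
#'
#' When several hands are visible, the session works with the hand first
#' seen in the stream and ignores the others. The tracker keeps the last
#' wrist position of the chosen hand and, on each new detection set, selects
#' the candidate whose wrist is nearest to it (within `max_jump` pixels).
#' An empty detection set, or no candidate near the last wrist, signals
#' "hand lost" (`NULL`) rather than switching hands; the hand re-attaches
#' when a detection reappears near the last tracked wrist.
#'
#' @param max_jump Maximum wrist displacement between consecutive
#'   selections, pixels.
#' @return A tracker object with methods `select(candidates)` (candidates
#'   is a list of 21x2 landmark matrices; returns one matrix or `NULL`) and
#'   `reset()`.
#' @export
hand_tracker <- function(max_jump = 150) {
  last_wrist <- NULL
  select <- function(candidates) {
    if (!length(candidates)) return(NULL)
    for (lm in candidates) check_landmarks(lm)
    if (is.null(last_wrist)) {
      # first detection wins and stays the tracked hand
      last_wrist <<- candidates[[1]][LM_WRIST + 1L, ]
      return(candidates[[1]])
    }
    d <- vapply(candidates, function(lm)
      sqrt(sum((lm[LM_WRIST + 1L, ] - last_wrist)^2)), numeric(1))
    i <- which.min(d)
    if (d[i] > max_jump) return(NULL)
    last_wrist <<- candidates[[i]][LM_WRIST + 1L, ]
    candidates[[i]]
  }
  reset <- function() last_wrist <<- NULL
  list(select = select, reset = reset)
}

#' Read and write landmark streams as JSON Lines
#'
#' One frame per line: `{"t": seconds, "lm": [[x, y] x 21]}`, coordinates in
#' display pixels. Timestamps must be strictly increasing.
#'
#' @param frames A stream tibble (`t`, `lm`).
#' @param path File path.
#' @return `write_landmark_stream()` returns `path` invisibly;
#'   `read_landmark_stream()` returns the stream tibble.
#' @export
write_landmark_stream <- function(frames, path) {
  check_stream(frames)
  lines <- vapply(seq_len(nrow(frames)), function(i) {
    jsonlite::toJSON(list(t = frames$t[[i]],
                          lm = unname(frames$lm[[i]])),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_landmark_stream
#' @export
read_landmark_stream <- function(path) {
  if (!file.exists(path))
    stop_solwrite(paste0("stream file not found: ", path), "solwrite_io_error")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rec <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec[[i]] <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e)
      stop_solwrite(sprintf("malformed stream line %d: %s", i,
                            conditionMessage(e)), "solwrite_io_error"))
    if (is.null(rec[[i]]$t) || is.null(rec[[i]]$lm))
      stop_solwrite(sprintf("malformed stream line %d: missing 't' or 'lm'", i),
                    "solwrite_io_error")
  }
  frames <- tibble(
    t = vapply(rec, function(r) as.numeric(r$t), numeric(1)),
    lm = lapply(rec, function(r) {
      m <- r$lm
      if (is.list(m)) m <- do.call(rbind, m)
      storage.mode(m) <- "double"
      m
    }))
  check_stream(frames)
  frames
}

check_stream <- function(frames) {
  if (!is.data.frame(frames) || !all(c("t", "lm") %in% names(frames)))
    stop_solwrite("a landmark stream must have columns `t` and `lm`",
                  "solwrite_validation_error")
  if (nrow(frames) == 0L)
    stop_solwrite("landmark stream is empty", "solwrite_validation_error")
  if (any(diff(frames$t) <= 0))
    stop_solwrite("stream timestamps must be strictly increasing",
                  "solwrite_stream_error")
  for (lm in frames$lm) check_landmarks(lm)
  invisible(frames)
}
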