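#' Session configuration
#'
#' Bundles the per-session tunables of the tracing test. The drawing radius
#' is clinically bounded to `[20, 40]` px (20 = most challenging, 40 = most
#' permissive). The time limit is the 60 s convention of the original
#' sub-test. A trace counts as complete when the accumulated drawn length
#' reaches `length_match_fraction` of the shape perimeter *and* the index
#' fingertip is within `end_vicinity` pixels of the end point; the vicinity
#' defaults to the drawing radius. `max_hand_gap` is the longest tolerated
#' gap between consecutive frames before the hand is declared lost.
#'
#' @param radius Drawing radius, px, in `[20, 40]`.
#' @param pinch_threshold Tripod-pinch distance threshold, px.
#' @param time_limit Session time limit, seconds.
#' @param length_match_fraction Fraction of the perimeter that must be drawn
#'   for completion.
#' @param end_vicinity Completion/arming distance to the start or end dot,
#'   px; defaults to `radius`.
#' @param max_hand_gap Longest tolerated inter-frame gap while tracing,
#'   seconds.
#' @param max_step_factor Per-frame drawn-length advance is capped at
#'   `max_step_factor * radius` so dropped frames cannot teleport length.
#' @return A `swt_config` list.
#' @export
session_config <- function(radius = 20, pinch_threshold = 60, time_limit = 60,
                           length_match_fraction = 0.9, end_vicinity = radius,
                           max_hand_gap = 0.25, max_step_factor = 3) {
  check_radius(radius)
  stopifnot(pinch_threshold > 0, time_limit > 0,
            length_match_fraction > 0, length_match_fraction <= 1,
            end_vicinity > 0, max_hand_gap > 0, max_step_factor > 0)
  structure(list(radius = radius, pinch_threshold = pinch_threshold,
                 time_limit = time_limit,
                 length_match_fraction = length_match_fraction,
                 end_vicinity = end_vicinity, max_hand_gap = max_hand_gap,
                 max_step_factor = max_step_factor),
            class = "swt_config")
}

#' Create a fresh tracing session
#'
#' The session is the test's finite-state record. It starts in `IDLE` and
#' moves through the automaton: `IDLE -> TRACING` on arming (tripod pinch
#' with the index tip on the start dot), then per frame either stays
#' `TRACING`, completes (`COMPLETED`), fails (`FAILED` with a reason:
#' out_of_bounds, grip_lost or hand_lost) or runs out of time (`TIMED_OUT`).
#' Terminal phases are absorbing.
#'
#' @param shp The [shape] to trace, in the same (display) coordinate space
#'   as the landmark stream.
#' @param config A [session_config()].
#' @return A `swt_session` object.
#' @export
new_session <- function(shp, config = session_config()) {
  stopifnot(inherits(shp, "swt_shape"))
  if (shp$perimeter <= 0)
    stop_solwrite("shape has zero perimeter", "solwrite_validation_error")
  structure(list(shape = shp, config = config,
                 phase = "IDLE", fail_reason = "none",
                 start_time = NA_real_, prev_t = NA_real_,
                 elapsed = NA_real_, drawn_length = 0,
                 last_x = NA_real_, last_y = NA_real_,
                 deviations = numeric(0),
                 trace_t = numeric(0), trace_x = numeric(0),
                 trace_y = numeric(0), n_frames = 0L),
            class = "swt_session")
}

terminal_phase <- function(phase) phase %in% c("COMPLETED", "FAILED", "TIMED_OUT")

#' Try to arm an idle session
#'
#' Arming requires the tripod pinch to be held while the index fingertip is
#' inside the start dot's central area (within `end_vicinity` of the start
#' point). On success the session transitions to `TRACING` and the clock
#' starts; otherwise it stays `IDLE`.
#'
#' @param session A `swt_session` in phase `IDLE`.
#' @param t Frame timestamp, seconds.
#' @param lm 21x2 landmark matrix.
#' @return The updated session.
#' @export
try_arm <- function(session, t, lm) {
  if (session$phase != "IDLE")
    stop_solwrite("try_arm requires phase IDLE", "solwrite_state_error")
  check_landmarks(lm)
  session$n_frames <- session$n_frames + 1L
  cfg <- session$config
  p <- lm[LM_INDEX_TIP + 1L, ]
  on_start <- sqrt(sum((p - session$shape$start)^2)) <= cfg$end_vicinity
  if (is_tripod_pinch(lm, cfg$pinch_threshold) && on_start) {
    session$phase <- "TRACING"
    session$start_time <- t
    session$last_x <- p[1]
    session$last_y <- p[2]
  }
  session$prev_t <- t
  session
}

#' Advance a tracing session by one frame
#'
#' Checks run in order: (1) the stream gap — a gap longer than
#' `max_hand_gap` fails the session with reason `hand_lost`; (2) the clock —
#' past the time limit the session ends `TIMED_OUT`; (3) the grip — losing
#' the tripod pinch fails with `grip_lost`; (4) legality — a drawing point
#' farther than the radius from every shape segment fails immediately with
#' `out_of_bounds`. On a legal frame the signed carrier-line deviation of
#' the matched segment is appended to the spasticity log, the drawn length
#' advances by the displacement projected onto the matched segment's
#' direction (capped at `max_step_factor * radius`), and the completion
#' check runs.
#'
#' @inheritParams try_arm
#' @param session A `swt_session` in phase `TRACING`.
#' @return The updated session.
#' @export
session_step <- function(session, t, lm) {
  if (session$phase != "TRACING")
    stop_solwrite("session_step requires phase TRACING", "solwrite_state_error")
  cfg <- session$config
  shp <- session$shape
  if (!is.na(session$prev_t) && t <= session$prev_t)
    stop_solwrite("stream timestamps must be strictly increasing",
                  "solwrite_stream_error")
  session$n_frames <- session$n_frames + 1L

  if (t - session$prev_t > cfg$max_hand_gap) {
    session$phase <- "FAILED"; session$fail_reason <- "hand_lost"
    session$elapsed <- session$prev_t - session$start_time
    session$prev_t <- t
    return(session)
  }
  elapsed <- t - session$start_time
  if (elapsed > cfg$time_limit) {
    session$phase <- "TIMED_OUT"
    session$elapsed <- cfg$time_limit
    session$prev_t <- t
    return(session)
  }
  check_landmarks(lm)
  if (!is_tripod_pinch(lm, cfg$pinch_threshold)) {
    session$phase <- "FAILED"; session$fail_reason <- "grip_lost"
    session$elapsed <- elapsed
    session$prev_t <- t
    return(session)
  }
  p <- lm[LM_INDEX_TIP + 1L, ]
  legal <- is_legal_draw_point(shp, p[1], p[2], cfg$radius)
  if (!legal$legal) {
    session$phase <- "FAILED"; session$fail_reason <- "out_of_bounds"
    session$elapsed <- elapsed
    session$prev_t <- t
    return(session)
  }
  session$deviations <- c(session$deviations, legal$deviation)
  session$trace_t <- c(session$trace_t, t)
  session$trace_x <- c(session$trace_x, p[1])
  session$trace_y <- c(session$trace_y, p[2])
  seg <- shp$segments[legal$segment, ]
  u <- c(seg$x1 - seg$x0, seg$y1 - seg$y0) / seg$length
  adv <- abs((p[1] - session$last_x) * u[1] + (p[2] - session$last_y) * u[2])
  adv <- min(adv, cfg$max_step_factor * cfg$radius)
  session$drawn_length <- session$drawn_length + adv
  session$last_x <- p[1]; session$last_y <- p[2]
  session$prev_t <- t
  if (completion_check(session, p)) {
    session$phase <- "COMPLETED"
    session$elapsed <- elapsed
  }
  session
}

#' Completion check
#'
#' A trace is complete when the drawn length has reached
#' `length_match_fraction` of the shape's perimeter and the index fingertip
#' is within `end_vicinity` of the end point. For closed shapes the end
#' coincides with the start; the length condition is the safety step that
#' prevents instant completion at the shared start/end dot.
#'
#' @param session A `swt_session`.
#' @param p Current drawing-point centre `c(x, y)`.
#' @return Logical flag.
#' @export
completion_check <- function(session, p) {
  cfg <- session$config
  shp <- session$shape
  session$drawn_length >= cfg$length_match_fraction * shp$perimeter &&
    sqrt(sum((p - shp$end)^2)) <= cfg$end_vicinity
}

#' Fraction of the shape's perimeter that was traced
#'
#' @param session A `swt_session`.
#' @return `min(1, drawn_length / perimeter)`.
#' @export
fraction_traced <- function(session) {
  if (session$shape$perimeter <= 0)
    stop_solwrite("shape has zero perimeter", "solwrite_validation_error")
  min(1, session$drawn_length / session$shape$perimeter)
}

#' Replay a landmark stream through a session
#'
#' Feeds the frames of a stream, in order, through [try_arm()] (while idle)
#' and [session_step()] (while tracing), stopping at the first terminal
#' phase. Replay is deterministic: the same stream and configuration always
#' produce the same session.
#'
#' @param shp The [shape] to trace (display coordinates).
#' @param frames A landmark stream tibble (`t`, `lm`).
#' @param config A [session_config()].
#' @return The final `swt_session`.
#' @export
run_session <- function(shp, frames, config = session_config()) {
  check_stream(frames)
  session <- new_session(shp, config)
  for (i in seq_len(nrow(frames))) {
    if (terminal_phase(session$phase)) break
    if (session$phase == "IDLE") {
      session <- try_arm(session, frames$t[[i]], frames$lm[[i]])
    } else {
      session <- session_step(session, frames$t[[i]], frames$lm[[i]])
    }
  }
  session
}

#' Finalise a terminal session into a result
#'
#' Maps the terminal phase to the outcome used by scoring: `COMPLETED` to
#' `"completed"`, `TIMED_OUT` to `"partial"` (the session simply stops at
#' the time limit; partial performance within 60 s is worth 1 point), and
#' `FAILED` to `"failed"`.
#'
#' @param session A `swt_session` in a terminal phase.
#' @return A `swt_result` with `outcome`, `elapsed` (s), `fraction_traced`,
#'   `deviations` (signed px, one per legal tracing frame) and
#'   `fail_reason`.
#' @export
finalize <- function(session) {
  if (!terminal_phase(session$phase))
    stop_solwrite("finalize requires a terminal session phase",
                  "solwrite_state_error")
  outcome <- switch(session$phase, COMPLETED = "completed",
                    TIMED_OUT = "partial", FAILED = "failed")
  structure(list(outcome = outcome, elapsed = session$elapsed,
                 fraction_traced = fraction_traced(session),
                 deviations = session$deviations,
                 fail_reason = session$fail_reason,
                 n_frames = session$n_frames,
                 shape_name = session$shape$name,
                 radius = session$config$radius),
            class = "swt_result")
}

#' @export
print.swt_session <- function(x, ...) {
  cat(sprintf("<swt_session> phase %s, %d frame(s), drawn %.1f px (%.0f%% of perimeter)\n",
              x$phase, x$n_frames, x$drawn_length, 100 * fraction_traced(x)))
  if (x$fail_reason != "none") cat("  fail reason:", x$fail_reason, "\n")
  invisible(x)
}

#' @export
print.swt_result <- function(x, ...) {
  cat(sprintf("<swt_result> %s in %.1f s, fraction traced %.2f, %d deviation(s)\n",
              x$outcome, x$elapsed, x$fraction_traced, length(x$deviations)))
  invisible(x)
}

#' @method tidy swt_session
#' @export
tidy.swt_session <- function(x, ...) {
  s <- unclass(x)
  tibble(t = s$trace_t, x = s$trace_x, y = s$trace_y,
         deviation = s$deviations)
}

#' @method glance swt_session
#' @export
glance.swt_session <- function(x, ...) {
  tibble(phase = x$phase, fail_reason = x$fail_reason,
         elapsed = x$elapsed, drawn_length = x$drawn_length,
         fraction_traced = fraction_traced(x), n_frames = x$n_frames,
         n_legal_frames = length(x$deviations))
}

#' Write a session's per-frame audit log as JSON Lines
#'
#' One line per legal tracing frame: timestamp, drawing-point centre and
#' signed deviation. Replaying the original stream reproduces the log
#' exactly.
#'
#' @param session A `swt_session`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(session, path) {
  log <- tidy(session)
  lines <- vapply(seq_len(nrow(log)), function(i)
    jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE, digits = NA),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
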