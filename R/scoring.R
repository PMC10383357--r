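#' Assign the 0-4 performance score
#'
#' The sub-test grading: any failure (drawing out of bounds, losing the
#' grip, losing the hand) scores 0, as does a partial trace covering no more
#' than 1/3 of the shape. A partial trace beyond 1/3 within the 60 s limit
#' scores 1. A completed trace is graded on completion time alone: under
#' 20 s scores 4, 20 s up to (but not including) 40 s scores 3, and 40 s up
#' to the 60 s limit scores 2.
#'
#' @param result A `swt_result` from [finalize()].
#' @return Integer score in 0-4.
#' @export
assign_score <- function(result) {
  stopifnot(inherits(result, "swt_result"))
  if (result$outcome == "failed") return(0L)
  if (result$outcome == "partial")
    return(if (result$fraction_traced > 1 / 3) 1L else 0L)
  e <- result$elapsed
  if (is.na(e) || e > 60)
    stop_solwrite("internal error: completed session with elapsed > 60 s",
                  "solwrite_internal_error")
  if (e < 20) 4L else if (e < 40) 3L else 2L
}

#' Hand-spasticity estimate from the deviation log
#'
#' Spasticity is operationalised as the mean deviation of the drawing point
#' from the shape's carrier lines over the session. The per-frame deviations
#' are signed, so two means are reported: the mean of absolute deviations
#' (`mean_abs`, the headline wobble figure) and the signed mean
#' (`mean_signed`, which retains systematic drift to one side of the line
#' and cancels for symmetric wobble).
#'
#' @param deviations Numeric vector of signed per-frame deviations, pixels.
#' @return One-row tibble with `mean_signed`, `mean_abs` and `n`. For an
#'   empty log both means are `NA` (with a warning): the spasticity of an
#'   untraced session is undefined.
#' @export
compute_spasticity <- function(deviations) {
  if (!length(deviations)) {
    warn("empty deviation log: spasticity is undefined")
    return(tibble(mean_signed = NA_real_, mean_abs = NA_real_, n = 0L))
  }
  tibble(mean_signed = mean(deviations), mean_abs = mean(abs(deviations)),
         n = length(deviations))
}

#' Build a one-row score report
#'
#' Combines the session result, the score and the spasticity estimate into
#' the row format of the results CSV.
#'
#' @param result A `swt_result`.
#' @param session_id Free-form session identifier.
#' @param shape_name Shape label; defaults to the one carried by the result.
#' @param timestamp Wall-clock time of the report; defaults to now (UTC).
#' @return One-row tibble with columns `session_id`, `timestamp`,
#'   `shape_name`, `score`, `elapsed_s`, `fraction_traced`,
#'   `spasticity_mean_abs_px`, `spasticity_mean_signed_px`, `outcome`,
#'   `radius_px`.
#' @export
score_report <- function(result, session_id = "session-1",
                         shape_name = NULL, timestamp = NULL) {
  stopifnot(inherits(result, "swt_result"))
  sp <- if (length(result$deviations)) compute_spasticity(result$deviations)
        else tibble(mean_signed = NA_real_, mean_abs = NA_real_, n = 0L)
  if (is.null(timestamp))
    timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  tibble(
    session_id = as.character(session_id),
    timestamp = as.character(timestamp),
    shape_name = as.character(shape_name %||% result$shape_name),
    score = assign_score(result),
    elapsed_s = result$elapsed,
    fraction_traced = result$fraction_traced,
    spasticity_mean_abs_px = sp$mean_abs,
    spasticity_mean_signed_px = sp$mean_signed,
    outcome = result$outcome,
    radius_px = result$radius)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Append a score report to the results CSV
#'
#' RFC-4180 comma-separated, UTF-8. The header is written once, when the
#' file does not yet exist (or is empty); subsequent reports are appended as
#' data rows.
#'
#' @param report A one-row tibble from [score_report()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(report, path) {
  fresh <- !file.exists(path) || file.size(path) == 0
  ok <- tryCatch({
    readr::write_csv(report, path, append = !fresh, col_names = fresh)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_solwrite(paste0("could not write results CSV '", path, "': ",
                         conditionMessage(ok)), "solwrite_io_error")
  invisible(path)
}
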