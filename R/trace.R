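#' Per-frame gaze trace
#'
#' The substrate of all detection and measures: per-frame gaze predictions at
#' a nominal constant frame rate, in screen frame units (top-left origin,
#' y down), with a validity flag marking frames where a face was detected and
#' a prediction exists. Invalid frames keep their row (so frame indexing
#' stays aligned with the video) but carry `NA` coordinates.
#'
#' @param frames Strictly increasing integer frame indices (0-based).
#' @param x,y Gaze coordinates in frame units; `NA` allowed where `!valid`.
#' @param valid Logical vector, per-sample prediction validity.
#' @param fps Nominal frames per second.
#' @param t0 Trace start time in seconds (default 0).
#' @param trial_id Optional trial identifier.
#' @param source_model Optional free-text gaze model name.
#' @return An object of class `gaze_trace`.
#' @export
gaze_trace <- function(frames, x, y, valid = NULL, fps = 30, t0 = 0,
                       trial_id = NA_character_, source_model = NA_character_) {
  frames <- as.integer(frames)
  if (is.null(valid)) valid <- is.finite(x) & is.finite(y)
  n <- length(frames)
  stopifnot(length(x) == n, length(y) == n, length(valid) == n, fps > 0)
  if (n > 1L && any(diff(frames) <= 0L))
    stop("gaze_trace: frame indices must be strictly increasing")
  structure(list(frames = frames, x = as.numeric(x), y = as.numeric(y),
                 valid = as.logical(valid), fps = fps, t0 = t0,
                 trial_id = trial_id, source_model = source_model),
            class = "gaze_trace")
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf("Gaze trace '%s': %d samples @ %g fps, %d valid (%.1f%%)\n",
              x$trial_id, length(x$frames), x$fps, sum(x$valid),
              100 * mean(x$valid)))
  invisible(x)
}

#' @export
as.data.frame.gaze_trace <- function(x, ...) {
  data.frame(trial_id = x$trial_id, frame = x$frames,
             t_sec = x$t0 + x$frames / x$fps,
             x_fu = x$x, y_fu = x$y, valid = as.integer(x$valid),
             source_model = x$source_model, stringsAsFactors = FALSE)
}

#' Gaze coordinates of a trace in the centered analysis frame (degrees)
#'
#' @param trace A [gaze_trace()].
#' @param geom A [screen_geometry()].
#' @return A data.frame with columns `frame`, `x_deg`, `y_deg`, `valid`.
#' @export
trace_deg <- function(trace, geom = screen_geometry()) {
  cc <- screen_to_centered(trace$x, trace$y, geom)
  data.frame(frame = trace$frames, x_deg = cc$x, y_deg = cc$y,
             valid = trace$valid)
}

#' Subset a gaze trace to a window of frames
#'
#' @param trace A [gaze_trace()].
#' @param from,to Inclusive frame-index bounds.
#' @return A `gaze_trace` restricted to `from:to`.
#' @export
trace_window <- function(trace, from, to) {
  keep <- trace$frames >= from & trace$frames <= to
  gaze_trace(trace$frames[keep], trace$x[keep], trace$y[keep],
             trace$valid[keep], fps = trace$fps, t0 = trace$t0,
             trial_id = trace$trial_id, source_model = trace$source_model)
}
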