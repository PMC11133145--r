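#' Fixation-task estimate, accuracy and precision
#'
#' For each 2500 ms target presentation the fixation estimate is the
#' coordinate-wise median of the valid raw gaze predictions; accuracy is the
#' Euclidean offset between that estimate and the displayed target, and
#' precision is quantified two ways over the presentation window:
#'
#' * RMS — square root of the mean of squared Euclidean distances between
#'   *consecutive* samples (inter-sample noise);
#' * STD — square root of the mean of squared Euclidean distances of each
#'   sample from the window mean (dispersion; population convention,
#'   divide by n).
#'
#' All three are in degrees and lower is better; for white noise
#' RMS = sqrt(2) * STD in expectation.
#'
#' @param x,y Numeric sample coordinates (degrees) within one presentation
#'   window; `NA`s (invalid frames) are dropped.
#' @return `fixation_estimate`: named numeric `c(x, y)` (or `NA`s if no
#'   valid sample).
#' @export
fixation_estimate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (!any(ok)) return(c(x = NA_real_, y = NA_real_))
  c(x = stats::median(x[ok]), y = stats::median(y[ok]))
}

#' @rdname fixation_estimate
#' @param estimate,target Length-2 points in the same frame (degrees).
#' @return `fixation_accuracy`: Euclidean distance in degrees.
#' @export
fixation_accuracy <- function(estimate, target) {
  sqrt(sum((as.numeric(estimate) - as.numeric(target))^2))
}

#' @rdname fixation_estimate
#' @return `precision_rms`, `precision_std`: degrees (`NA` if fewer than 2
#'   valid samples).
#' @export
precision_rms <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) return(NA_real_)
  sqrt(mean(diff(x)^2 + diff(y)^2))
}

#' @rdname fixation_estimate
#' @export
precision_std <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) return(NA_real_)
  sqrt(mean((x - mean(x))^2 + (y - mean(y))^2))
}

#' Per-location fixation measures for one trial
#'
#' Windows the trace to each target presentation (mapping schedule times to
#' frames at the trace fps) and computes estimate, accuracy, RMS and STD per
#' location.
#'
#' @param trace A [gaze_trace()] of one fixation trial.
#' @param spec The matching `"fixation"` [make_trial()] spec.
#' @param geom A [screen_geometry()].
#' @param settle_ms Initial part of each presentation excluded from the
#'   window (saccade latency allowance; default 400 ms).
#' @return A data.frame with one row per presentation: `presentation`,
#'   `target_x_deg`, `target_y_deg`, `est_x_deg`, `est_y_deg`,
#'   `accuracy_deg`, `rms_deg`, `std_deg`.
#' @export
fixation_task_measures <- function(trace, spec, geom = screen_geometry(),
                                   settle_ms = 400) {
  stopifnot(inherits(spec, "fixation_trial_spec"))
  d <- trace_deg(trace, geom)
  sched <- spec$schedule
  res <- lapply(seq_len(nrow(sched)), function(i) {
    f0 <- timestamps_to_frames(sched$onset_s[i] + settle_ms / 1000, trace$fps)
    f1 <- timestamps_to_frames(sched$offset_s[i], trace$fps) - 1L
    w <- d[d$frame >= f0 & d$frame <= f1 & d$valid, , drop = FALSE]
    est <- fixation_estimate(w$x_deg, w$y_deg)
    data.frame(presentation = i,
               target_x_deg = sched$x_deg[i], target_y_deg = sched$y_deg[i],
               est_x_deg = est[["x"]], est_y_deg = est[["y"]],
               accuracy_deg = if (is.finite(est[["x"]]))
                 fixation_accuracy(est, c(sched$x_deg[i], sched$y_deg[i]))
                 else NA_real_,
               rms_deg = precision_rms(w$x_deg, w$y_deg),
               std_deg = precision_std(w$x_deg, w$y_deg))
  })
  do.call(rbind, res)
}
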