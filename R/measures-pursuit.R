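#' Smooth-pursuit movement-angle estimate
#'
#' Raw gaze during the target-movement window is smoothed coordinate-wise
#' with a Savitzky-Golay filter (order 1, window n/2) and the movement
#' angle is estimated from ordinary least-squares regressions of x and y on
#' time: `theta = atan2(slope_y, slope_x)`, in the centered y-up frame,
#' mapped to [0, 360). Regressing both coordinates on time keeps the
#' estimate well-defined for vertical motion.
#'
#' @param trace A [gaze_trace()] windowed to the target movement, or a
#'   [trace_deg()] data.frame; >= 6 valid samples.
#' @param geom A [screen_geometry()].
#' @param sg_window Smoothing window as a fraction of n (default 1/2).
#' @param fps Frames per second (taken from the trace when available).
#' @return A list: `angle_deg` in [0, 360), `speed_dps` (fitted gaze speed,
#'   deg/s), `quality` (`"ok"` or `"low_displacement"`).
#' @export
pursuit_angle <- function(trace, geom = screen_geometry(), sg_window = 0.5,
                          fps = 30) {
  if (inherits(trace, "gaze_trace")) fps <- trace$fps
  d <- if (inherits(trace, "gaze_trace")) trace_deg(trace, geom) else trace
  d <- d[d$valid & is.finite(d$x_deg), , drop = FALSE]
  if (nrow(d) < 6L) stop("pursuit_angle: fewer than 6 valid samples")
  xs <- savgol_smooth(d$x_deg, order = 1, window = sg_window)
  ys <- savgol_smooth(d$y_deg, order = 1, window = sg_window)
  tt <- d$frame / fps
  bx <- stats::coef(stats::lm(xs ~ tt))[2]
  by <- stats::coef(stats::lm(ys ~ tt))[2]
  ang <- atan2(by, bx) * 180 / pi
  if (ang < 0) ang <- ang + 360
  speed <- sqrt(bx^2 + by^2)
  displacement <- speed * diff(range(tt))
  list(angle_deg = unname(ang), speed_dps = unname(speed),
       quality = if (displacement < 0.5) "low_displacement" else "ok")
}

#' Circular angular deviation
#'
#' Absolute difference between two direction angles on the circle, in
#' [0, 180] degrees; symmetric and wraparound-aware (350 vs 10 is 20).
#'
#' @param a,b Angles in degrees (any real values).
#' @return Deviation in degrees, `[0, 180]`.
#' @export
angular_deviation <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Pursuit onset latency and duration
#'
#' Latency is the time from target movement start to the detected pursuit
#' onset; duration is offset minus onset. A negative latency (onset before
#' the target moved) is returned with an `"anticipatory"` flag, a zero
#' duration with `"degenerate"`.
#'
#' @param onset_frame,offset_frame Detected frames
#'   (from [detect_pursuit_onset_offset()]); `onset_frame <= offset_frame`.
#' @param t_move_start_s Target movement start (seconds from trace start).
#' @param fps Frames per second.
#' @param t0 Trace start time (seconds).
#' @return A list: `latency_ms`, `duration_ms`, `flag` (`"ok"`,
#'   `"anticipatory"` or `"degenerate"`).
#' @export
pursuit_latency_duration <- function(onset_frame, offset_frame,
                                     t_move_start_s, fps = 30, t0 = 0) {
  stopifnot(onset_frame <= offset_frame)
  latency <- (t0 + onset_frame / fps - t_move_start_s) * 1000
  duration <- (offset_frame - onset_frame) / fps * 1000
  flag <- if (duration == 0) "degenerate"
          else if (latency < 0) "anticipatory" else "ok"
  list(latency_ms = latency, duration_ms = duration, flag = flag)
}
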