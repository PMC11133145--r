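#' Smooth-pursuit onset and offset by changepoint detection
#'
#' Works on the critical interval between the self-paced trial start and the
#' stop of the target movement. Each gaze coordinate is smoothed with a
#' Savitzky-Golay filter (order 1, window n/3), first-differenced into a
#' 2-D velocity series, and segmented with [changepoints_exact_k()]
#' (`k = 2`, minimum segment length 3). The two breakpoints mark pursuit
#' onset and offset.
#'
#' A `quality` flag is set to `"low_velocity"` when the derivative variance
#' is negligible (an all-static trace has no meaningful segmentation and the
#' tie-break result is returned).
#'
#' @param trace A [gaze_trace()] covering the interval, >= 12 samples; or a
#'   data.frame from [trace_deg()].
#' @param geom A [screen_geometry()].
#' @param sg_window Savitzky-Golay window as a fraction of n (default 1/3).
#' @param min_size Minimum changepoint segment length (default 3).
#' @return A list: `onset_frame`, `offset_frame` (frame indices of the
#'   trace), `quality` (`"ok"` or `"low_velocity"`).
#' @export
detect_pursuit_onset_offset <- function(trace, geom = screen_geometry(),
                                        sg_window = 1 / 3, min_size = 3) {
  d <- if (inherits(trace, "gaze_trace")) trace_deg(trace, geom) else trace
  # interpolate over dropouts so differencing stays aligned with frames
  ok <- d$valid & is.finite(d$x_deg)
  if (sum(ok) < 12L) stop("detect_pursuit_onset_offset: fewer than 12 valid samples")
  x <- stats::approx(d$frame[ok], d$x_deg[ok], xout = d$frame, rule = 2)$y
  y <- stats::approx(d$frame[ok], d$y_deg[ok], xout = d$frame, rule = 2)$y
  xs <- savgol_smooth(x, order = 1, window = sg_window)
  ys <- savgol_smooth(y, order = 1, window = sg_window)
  deriv <- cbind(diff(xs), diff(ys))
  cp <- changepoints_exact_k(deriv, k = 2, min_size = min_size)
  quality <- if (stats::var(c(deriv)) < 1e-12) "low_velocity" else "ok"
  # derivative element j spans samples j -> j+1; after a breakpoint at b the
  # new regime's first fully-governed sample is b+1 for an onset (movement
  # begins) and b itself marks the last moving step for an offset (sample
  # b+1 is already at rest)
  n <- nrow(d)
  list(onset_frame = d$frame[min(cp$breakpoints[1] + 2L, n)],
       offset_frame = d$frame[min(cp$breakpoints[2] + 1L, n)],
       quality = quality)
}
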