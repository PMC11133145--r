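#' Screen geometry of the stimulus window
#'
#' The stimulus platform presents all tasks in a fixed coordinate system of
#' frame units (FU). The study window is 1600 x 900 FU, corresponding to
#' 29.6 x 16.65 degrees of visual angle at 54.05 FU per degree.
#'
#' Screen coordinates are top-left origin, x rightward, y downward (the FU
#' convention of the stimulus platform). All angle computations happen in the
#' centered analysis frame (see [screen_to_centered()]): origin at the window
#' center, y up, angles counterclockwise from +x in [0, 360).
#'
#' @param fu_per_degree Frame units per degree of visual angle.
#' @param window_fu Numeric length-2, window (width, height) in frame units.
#' @param fps Nominal sampling rate in frames per second.
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' fu_to_deg(1600, geom) # window width, 29.6 degrees
#' @export
screen_geometry <- function(fu_per_degree = 54.05,
                            window_fu = c(1600, 900),
                            fps = 30) {
  stopifnot(is.numeric(fu_per_degree), length(fu_per_degree) == 1L,
            fu_per_degree > 0, length(window_fu) == 2L, all(window_fu > 0),
            fps > 0)
  structure(list(fu_per_degree = fu_per_degree,
                 window_fu = as.numeric(window_fu),
                 window_deg = as.numeric(window_fu) / fu_per_degree,
                 fps = fps),
            class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("Screen geometry: %.0f x %.0f FU (%.2f x %.2f deg), %.4g FU/deg, %g fps\n",
              x$window_fu[1], x$window_fu[2], x$window_deg[1], x$window_deg[2],
              x$fu_per_degree, x$fps))
  invisible(x)
}

#' Convert between frame units and degrees of visual angle
#'
#' @param v Numeric vector of lengths (FU for `fu_to_deg`, degrees for
#'   `deg_to_fu`).
#' @param geom A [screen_geometry()].
#' @return Numeric vector of the same length.
#' @export
fu_to_deg <- function(v, geom = screen_geometry()) v / geom$fu_per_degree

#' @rdname fu_to_deg
#' @export
deg_to_fu <- function(v, geom = screen_geometry()) v * geom$fu_per_degree

#' Convert screen FU coordinates to the centered analysis frame (degrees)
#'
#' The centered frame has its origin at the window center, x rightward and
#' y *upward*, in degrees; angles are measured counterclockwise from +x.
#' The screen frame is top-left origin, y downward, in FU.
#'
#' @param x,y Numeric vectors of coordinates.
#' @param geom A [screen_geometry()].
#' @return A list with components `x` and `y`.
#' @export
screen_to_centered <- function(x, y, geom = screen_geometry()) {
  list(x = (x - geom$window_fu[1] / 2) / geom$fu_per_degree,
       y = (geom$window_fu[2] / 2 - y) / geom$fu_per_degree)
}

#' @rdname screen_to_centered
#' @export
centered_to_screen <- function(x, y, geom = screen_geometry()) {
  list(x = x * geom$fu_per_degree + geom$window_fu[1] / 2,
       y = geom$window_fu[2] / 2 - y * geom$fu_per_degree)
}

#' Map timestamps to video frame numbers at a constant frame rate
#'
#' Recorded event timestamps are aligned to model prediction time series by
#' assuming a constant fps: `frame = round((t - t0) * fps)`, rounding half up
#' so the mapping is deterministic and order preserving.
#'
#' @param times Numeric vector of timestamps (seconds), all `>= t0`.
#' @param fps Frames per second (> 0).
#' @param t0 Trace start time (seconds).
#' @return Integer vector of 0-based frame indices.
#' @export
timestamps_to_frames <- function(times, fps, t0 = 0) {
  stopifnot(fps > 0)
  if (any(times < t0 - 1e-9))
    stop("timestamps before trace start t0: input ordering error")
  as.integer(floor((times - t0) * fps + 0.5))
}
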