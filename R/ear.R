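#' Eye aspect ratio from six eye landmarks
#'
#' The eye aspect ratio (EAR) summarizes eyelid closure from the pixel
#' distances of six eye landmarks: `p1`/`p4` the horizontal eye corners,
#' `p2`/`p3` on the upper lid, `p6`/`p5` on the lower lid (so `p2-p6` and
#' `p3-p5` are the two vertical distances). EAR is near a constant open-eye
#' value while the eye is open and drops towards zero during a blink:
#'
#' `EAR = (|p2 - p6| + |p3 - p5|) / (2 |p1 - p4|)`
#'
#' The ratio is invariant under rigid transforms and uniform scaling of the
#' landmark set.
#'
#' @param p1,p2,p3,p4,p5,p6 Numeric length-2 landmark coordinates (pixels).
#' @return Nonnegative scalar EAR.
#' @examples
#' ear_from_landmarks(c(0, 0), c(0.5, 0.5), c(1.5, 0.5),
#'                    c(2, 0), c(1.5, -0.5), c(0.5, -0.5)) # 0.5
#' @export
ear_from_landmarks <- function(p1, p2, p3, p4, p5, p6) {
  d <- function(a, b) sqrt(sum((a - b)^2))
  h <- d(p1, p4)
  if (h == 0) stop("ear_from_landmarks: degenerate eye (p1 == p4)")
  (d(p2, p6) + d(p3, p5)) / (2 * h)
}
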