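#' Blink detection from a 1-D blink time series
#'
#' The blink pipeline for eye-aspect-ratio (`polarity = "dip"`) or
#' blink-probability (`polarity = "pulse"`) series:
#'
#' 1. [changepoints_penalized()] proposes candidate onsets/offsets.
#' 2. [verify_changepoints()] discards changepoints with no verifying peak
#'    of the right polarity within +-`peak_window` frames (~200 ms at
#'    30 Hz), removing false identifications.
#' 3. [blinks_from_changepoints()] clusters surviving changepoints
#'    agglomeratively (single linkage, distance threshold 25 frames); each
#'    cluster of 2+ changepoints becomes one blink, its earliest member the
#'    onset and its latest the offset.
#'
#' @param series Numeric vector (length >= 30 for `detect_blinks`).
#' @param polarity `"dip"` for series that fall during blinks (EAR),
#'   `"pulse"` for series that rise (blink probability).
#' @param fps Frames per second, for durations.
#' @param penalty,beta Passed to [changepoints_penalized()].
#' @param peak_window Verification half-window in frames (default 6).
#' @param mad_k Peak prominence rule: the extremum must lie beyond the
#'   running median by `mad_k` MADs of the series (default 3).
#' @param agglom_threshold Single-linkage merge threshold in frames
#'   (default 25).
#' @return A data.frame of blink events sorted by onset: `onset_frame`,
#'   `offset_frame`, `duration_ms`.
#' @export
detect_blinks <- function(series, polarity = c("dip", "pulse"), fps = 30,
                          penalty = NULL, beta = 3, peak_window = 6,
                          mad_k = 3, agglom_threshold = 25) {
  polarity <- match.arg(polarity)
  if (length(series) < 30L) stop("detect_blinks: series shorter than 30 samples")
  cp <- changepoints_penalized(series, penalty = penalty, beta = beta)
  kept <- verify_changepoints(cp$breakpoints, series, polarity,
                              window = peak_window, mad_k = mad_k)
  blinks_from_changepoints(kept, fps = fps,
                           agglom_threshold = agglom_threshold)
}

#' @rdname detect_blinks
#' @param cps Sorted integer changepoint indices (1-based).
#' @param window Half-window in frames within which a verifying peak must
#'   lie.
#' @return `verify_changepoints`: the subset of `cps` with a verifying
#'   extremum.
#' @export
verify_changepoints <- function(cps, series, polarity = c("dip", "pulse"),
                                window = 6, mad_k = 3) {
  polarity <- match.arg(polarity)
  if (length(cps) == 0L) return(integer(0))
  n <- length(series)
  s <- if (polarity == "dip") -series else series
  med <- stats::runmed(s, k = min(31L, n - (1 - n %% 2L)), endrule = "median")
  thr <- med + mad_k * stats::mad(s)
  # candidate peaks: local maxima of the oriented series beyond the threshold
  left <- c(-Inf, s[-n]); right <- c(s[-1], -Inf)
  peak <- which(s >= left & s >= right & s > thr)
  cps[vapply(cps, function(cp) any(abs(peak - cp) <= window), TRUE)]
}

#' @rdname detect_blinks
#' @return `blinks_from_changepoints`: the blink event data.frame.
#' @export
blinks_from_changepoints <- function(cps, fps = 30, agglom_threshold = 25) {
  cps <- sort(as.integer(cps))
  empty <- data.frame(onset_frame = integer(0), offset_frame = integer(0),
                      duration_ms = numeric(0))
  if (length(cps) == 0L) return(empty)
  # single-linkage agglomeration of 1-D indices == split at gaps > threshold
  grp <- cumsum(c(1L, as.integer(diff(cps) > agglom_threshold)))
  cl <- split(cps, grp)
  cl <- cl[lengths(cl) >= 2L]          # singletons: no duration definable
  if (length(cl) == 0L) return(empty)
  out <- data.frame(
    onset_frame = vapply(cl, min, 0L),
    offset_frame = vapply(cl, max, 0L))
  out$duration_ms <- (out$offset_frame - out$onset_frame) / fps * 1000
  out <- out[order(out$onset_frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}
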