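#' 20% winsorized mean
#'
#' Robust location estimate used for all hierarchical aggregation of task
#' measures: values below the 10th percentile are set to the 10th percentile
#' and values above the 90th percentile to the 90th percentile before
#' averaging. Percentiles use the linear-interpolation convention
#' (`stats::quantile(type = 7)`).
#'
#' Groups with fewer than 3 values fall back to the plain mean (percentile
#' clipping is inert at such sizes anyway).
#'
#' @param values Nonempty numeric vector of finite values.
#' @return The winsorized mean, a length-1 numeric.
#' @examples
#' winsorized_mean(c(1, 2, 3, 4, 100)) # the outlier is clipped to q90
#' @export
winsorized_mean <- function(values) {
  if (length(values) == 0L) stop("winsorized_mean: empty input")
  if (any(!is.finite(values))) stop("winsorized_mean: non-finite values")
  if (length(values) < 3L) return(mean(values))
  q <- stats::quantile(values, probs = c(0.1, 0.9), names = FALSE, type = 7)
  mean(pmin(pmax(values, q[1]), q[2]))
}

#' Savitzky-Golay smoothing with fractional window lengths
#'
#' Local least-squares polynomial smoothing, as used on 30 Hz gaze traces
#' before angle estimation (order 1, window n/2) and before pursuit
#' onset/offset changepoint detection (order 1, window n/3). A fractional
#' `window` is interpreted as a fraction of the series length; the effective
#' window is the largest odd integer not exceeding the requested length,
#' never below 3 and never above the largest odd integer <= n. Endpoints are
#' handled by `signal::sgolayfilt`'s one-sided polynomial fits.
#'
#' @param series Numeric vector, length >= 3.
#' @param order Polynomial order (default 1).
#' @param window Either a fraction in (0, 1) of the series length, or an
#'   absolute window length >= 1.
#' @return Smoothed numeric vector, same length as `series`.
#' @export
savgol_smooth <- function(series, order = 1, window = 0.5) {
  n <- length(series)
  if (n < 3L) stop("savgol_smooth: series shorter than 3 samples")
  w <- effective_sg_window(n, window, order)
  signal::sgolayfilt(series, p = order, n = w)
}

#' @rdname savgol_smooth
#' @param n Series length.
#' @export
effective_sg_window <- function(n, window, order = 1) {
  req <- as.integer(if (window < 1) floor(n * window) else floor(window))
  w <- req - (1L - req %% 2L)          # largest odd <= requested
  w <- max(w, 3L)
  if (w <= order) w <- order + 2L - (order + 1L) %% 2L  # smallest odd > order
  nmax <- n - (1L - n %% 2L)           # largest odd <= n
  as.integer(min(w, nmax))
}
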