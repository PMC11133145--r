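#' Changepoint segmentation of short time series
#'
#' Offline changepoint detection tailored to 30 Hz gaze and blink series.
#' Two variants are provided, both minimizing the squared deviation of each
#' segment from its own mean (summed over columns for multivariate series):
#'
#' * [changepoints_exact_k()] — globally optimal segmentation with exactly
#'   `k` changepoints, found by dynamic programming with a minimum segment
#'   length (used with `k = 2` to mark smooth-pursuit onset and offset).
#' * [changepoints_penalized()] — optimal partitioning with a linear
#'   penalty per changepoint, for longer series with an unknown number of
#'   events (used on blink time series).
#'
#' Cost ties are broken toward the lexicographically smallest breakpoint
#' tuple. Breakpoints are reported as the 1-based index of the *last*
#' element of each non-final segment.
#'
#' @param series Numeric vector, or a matrix with one column per coordinate.
#' @param k Number of changepoints (exact-k variant).
#' @param min_size Minimum segment length in samples.
#' @return An object of class `changepoint_result`: list with `breakpoints`
#'   (integer vector), `cost` (total within-segment squared deviation,
#'   penalty excluded), `method`.
#' @examples
#' changepoints_exact_k(c(rep(0, 10), rep(5, 10), rep(0, 10)), k = 2)
#' @export
changepoints_exact_k <- function(series, k = 2, min_size = 3) {
  z <- as.matrix(series)
  n <- nrow(z)
  stopifnot(k >= 1, min_size >= 1)
  if (n < (k + 1) * min_size)
    stop(sprintf("changepoints_exact_k: series of length %d is too short; need >= %d",
                 n, (k + 1) * min_size))
  cc <- segcost_tables(z)
  m <- k + 1L  # number of segments
  # H[s, i]: minimal cost of segmenting z[i..n] into s segments
  H <- matrix(Inf, nrow = m, ncol = n + 1L)
  H[1L, 1:(n - min_size + 1L)] <-
    vapply(1:(n - min_size + 1L), function(i) segcost(cc, i, n), 0)
  if (m > 1L) for (s in 2:m) {
    imax <- n - s * min_size + 1L
    for (i in seq_len(max(imax, 0L))) {
      js <- (i + min_size - 1L):(n - (s - 1L) * min_size)
      H[s, i] <- min(segcost(cc, i, js) + H[s - 1L, js + 1L])
    }
  }
  total <- H[m, 1L]
  # greedy front-to-back backtrack: smallest feasible breakpoint at each step
  bps <- integer(0)
  i <- 1L
  rem <- total
  tol <- 1e-9 * (1 + abs(total))
  for (s in m:2) {
    js <- (i + min_size - 1L):(n - (s - 1L) * min_size)
    val <- segcost(cc, i, js) + H[s - 1L, js + 1L]
    j <- js[which(val <= rem + tol)[1L]]
    bps <- c(bps, j)
    rem <- H[s - 1L, j + 1L]
    i <- j + 1L
  }
  structure(list(breakpoints = bps, cost = total, method = "exact_k"),
            class = "changepoint_result")
}

#' @rdname changepoints_exact_k
#' @param penalty Cost added per changepoint; default
#'   `beta * sigma^2 * log(n)` with `sigma` a robust scale estimate of the
#'   differenced series (`mad(diff(series)) / sqrt(2)`).
#' @param beta Penalty multiplier used when `penalty` is `NULL`.
#' @export
changepoints_penalized <- function(series, penalty = NULL, beta = 3,
                                   min_size = 2) {
  z <- as.matrix(series)
  n <- nrow(z)
  stopifnot(n >= min_size)
  if (is.null(penalty)) {
    sig <- stats::mad(diff(z[, 1])) / sqrt(2)
    if (!is.finite(sig) || sig == 0) sig <- stats::sd(diff(z[, 1])) / sqrt(2)
    if (!is.finite(sig) || sig == 0) sig <- 1e-12
    penalty <- beta * sig^2 * log(n)
  }
  stopifnot(penalty > 0)
  cc <- segcost_tables(z)
  # H[i]: minimal penalized cost of segmenting z[i..n]; greedy-smallest ties
  H <- rep(Inf, n + 2L)
  H[n + 1L] <- 0
  for (i in n:1) {
    if (i + min_size - 1L > n) next
    js <- (i + min_size - 1L):n
    js <- js[js == n | js <= n - min_size]
    if (length(js) == 0L) next
    H[i] <- min(segcost(cc, i, js) + ifelse(js == n, 0, penalty) + H[js + 1L])
  }
  total <- H[1L]
  tol <- 1e-9 * (1 + abs(total))
  bps <- integer(0); cost <- 0
  i <- 1L; rem <- total
  repeat {
    js <- (i + min_size - 1L):n
    js <- js[js == n | js <= n - min_size]
    val <- segcost(cc, i, js) + ifelse(js == n, 0, penalty) + H[js + 1L]
    j <- js[which(val <= rem + tol)[1L]]
    cost <- cost + segcost(cc, i, j)
    if (j == n) break
    bps <- c(bps, j)
    rem <- H[j + 1L]
    i <- j + 1L
  }
  structure(list(breakpoints = bps, cost = cost, method = "penalized",
                 penalty = penalty),
            class = "changepoint_result")
}

#' @export
print.changepoint_result <- function(x, ...) {
  cat(sprintf("Changepoints (%s): [%s], cost %.4g\n", x$method,
              paste(x$breakpoints, collapse = ", "), x$cost))
  invisible(x)
}

# cumulative-sum tables for O(1) within-segment squared-deviation cost
segcost_tables <- function(z) {
  list(s1 = rbind(0, apply(z, 2, cumsum)),
       s2 = rbind(0, apply(z^2, 2, cumsum)))
}

# cost of segment z[i..j] (j may be a vector): sum over columns of
# sum((v - mean(v))^2)
segcost <- function(cc, i, j) {
  len <- j - i + 1
  tot <- 0
  for (col in seq_len(ncol(cc$s1))) {
    s <- cc$s1[j + 1L, col] - cc$s1[i, col]
    q <- cc$s2[j + 1L, col] - cc$s2[i, col]
    tot <- tot + (q - s^2 / len)
  }
  pmax(tot, 0)
}
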