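# Brute-force reference implementations, kept independent of the package's
# dynamic-programming / vectorized code paths.

oracle_winsorized_mean <- function(v) {
  if (length(v) < 3) return(mean(v))
  q10 <- unname(quantile(v, 0.1, type = 7))
  q90 <- unname(quantile(v, 0.9, type = 7))
  v[v < q10] <- q10
  v[v > q90] <- q90
  mean(v)
}

oracle_median <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# plain-loop within-segment squared deviation cost, multivariate
oracle_segcost <- function(z, i, j) {
  z <- as.matrix(z)
  sum(apply(z[i:j, , drop = FALSE], 2, function(v) sum((v - mean(v))^2)))
}

# exhaustive search over all k=2 breakpoint pairs, lexicographic tie-break
oracle_exact_2 <- function(z, min_size = 3) {
  z <- as.matrix(z)
  n <- nrow(z)
  best <- Inf; best_bp <- NULL
  for (b1 in min_size:(n - 2 * min_size)) {
    for (b2 in (b1 + min_size):(n - min_size)) {
      cost <- oracle_segcost(z, 1, b1) + oracle_segcost(z, b1 + 1, b2) +
        oracle_segcost(z, b2 + 1, n)
      if (cost < best - 1e-9) { best <- cost; best_bp <- c(b1, b2) }
    }
  }
  list(breakpoints = best_bp, cost = best)
}

# exhaustive search over all segmentations (any number of breakpoints),
# linear penalty, lexicographic tie-break via enumeration order
oracle_penalized <- function(z, penalty, min_size = 2) {
  z <- as.matrix(z)
  n <- nrow(z)
  best <- Inf; best_bp <- NULL
  enumerate <- function(start, bps) {
    # close the final segment at n
    if (n - start + 1 >= min_size) {
      cost <- penalty * length(bps)
      prev <- 1
      for (b in c(bps, n)) { cost <- cost + oracle_segcost(z, prev, b); prev <- b + 1 }
      if (cost < best - 1e-9) { best <<- cost; best_bp <<- bps }
    }
    if (length(bps) > 20) return()
    bmin <- start + min_size - 1
    bmax <- n - min_size
    if (bmin <= bmax) for (b in bmin:bmax) enumerate(b + 1, c(bps, b))
  }
  enumerate(1, integer(0))
  list(breakpoints = best_bp, cost = best)
}

# the canonical step-ramp validation trial: short initiation delay so the
# prescribed n/3 smoothing window stays below the movement duration
canonical_pursuit <- function(angle = 30) {
  make_trial("pursuit", seed = 1, angle = angle, delay = 0.4)
}
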