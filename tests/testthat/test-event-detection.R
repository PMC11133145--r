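test_that("eye aspect ratio follows the landmark formula and its invariances", {
  # closed eye: vertical distances vanish
  expect_equal(ear_from_landmarks(c(0, 0), c(1, 0), c(2, 0),
                                  c(3, 0), c(2, 0), c(1, 0)), 0)
  # (1 + 1) / (2 * 2)
  expect_equal(ear_from_landmarks(c(0, 0), c(0.5, 0.5), c(1.5, 0.5),
                                  c(2, 0), c(1.5, -0.5), c(0.5, -0.5)), 0.5)
  # invariance under rotation, translation and uniform scaling
  set.seed(21)
  pts <- replicate(6, runif(2, -3, 3), simplify = FALSE)
  base <- do.call(ear_from_landmarks, pts)
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rig <- lapply(pts, function(p) 2.5 * as.vector(R %*% p) + c(10, -4))
  expect_equal(do.call(ear_from_landmarks, rig), base)
  expect_error(ear_from_landmarks(c(1, 1), c(0, 1), c(0, 2),
                                  c(1, 1), c(0, 0), c(0, 1)), "degenerate")
})

test_that("fixation clustering finds dense spatio-temporal groups", {
  mk <- function(frames, x, y)
    data.frame(frame = frames, x_deg = x, y_deg = y, valid = TRUE)
  # constant trace: one cluster at the point
  cl <- detect_fixation_clusters(mk(0:99, rep(2, 100), rep(-1, 100)),
                                 eps = 0.26)
  expect_identical(nrow(cl), 1L)
  expect_equal(c(cl$x_deg, cl$y_deg), c(2, -1))
  expect_identical(c(cl$start_frame, cl$end_frame, cl$n), c(0L, 99L, 100L))
  # an isolated sample cannot reach min_size 2
  lone <- mk(c(0:9, 50), c(rep(0, 10), 9), c(rep(0, 10), 9))
  expect_identical(nrow(detect_fixation_clusters(lone, eps = 0.26)), 1L)
  expect_identical(nrow(detect_fixation_clusters(mk(0, 1, 1), eps = 1)), 0L)
  # two stationary segments 10 degrees apart resolve into two clusters
  set.seed(5)
  n <- 60
  seg <- mk(0:(2 * n - 1),
            c(rnorm(n, -5, 0.1), rnorm(n, 5, 0.1)),
            c(rnorm(n, 0, 0.1), rnorm(n, 0, 0.1)))
  cl2 <- detect_fixation_clusters(seg, eps = 0.26)
  expect_identical(nrow(cl2), 2L)
  expect_lt(abs(cl2$x_deg[1] - mean(seg$x_deg[1:n])), 0.1)
  expect_lt(abs(cl2$x_deg[2] - mean(seg$x_deg[(n + 1):(2 * n)])), 0.1)
  # output is a disjoint, temporally ordered partition of a sample subset
  idx_used <- sum(cl2$n)
  expect_lte(idx_used, 2 * n)
  expect_true(all(diff(cl2$start_frame) > 0))
  # empty / all-invalid trace
  inv <- mk(0:9, rnorm(10), rnorm(10)); inv$valid <- FALSE
  expect_identical(nrow(detect_fixation_clusters(inv, eps = 1)), 0L)
})

test_that("exact-K changepoints are globally optimal with lexicographic ties", {
  r <- changepoints_exact_k(c(rep(0, 10), rep(5, 10), rep(0, 10)), k = 2)
  expect_identical(r$breakpoints, c(10L, 20L))
  expect_equal(r$cost, 0)
  # constant series: zero cost at the smallest feasible tuple
  rc <- changepoints_exact_k(rep(1, 12), k = 2, min_size = 3)
  expect_identical(rc$breakpoints, c(3L, 6L))
  expect_equal(rc$cost, 0)
  expect_error(changepoints_exact_k(1:8, k = 2, min_size = 3), ">= 9")
  # equivalence with exhaustive search, 1-D and 2-D random series
  set.seed(31)
  for (rep in 1:60) {
    n <- sample(9:12, 1)
    z <- if (rep %% 2) rnorm(n) else matrix(rnorm(2 * n), ncol = 2)
    got <- changepoints_exact_k(z, k = 2, min_size = 3)
    ref <- oracle_exact_2(z, min_size = 3)
    expect_identical(got$breakpoints, as.integer(ref$breakpoints))
    expect_equal(got$cost, ref$cost, tolerance = 1e-9)
  }
})

test_that("penalized changepoints match exhaustive search and its limits", {
  # one clean step: exactly one breakpoint at the step
  step <- c(rep(0, 15), rep(10, 15))
  r <- changepoints_penalized(step, penalty = 5)
  expect_identical(r$breakpoints, 15L)
  # infinite penalty: no breakpoints
  expect_identical(changepoints_penalized(step, penalty = 1e12)$breakpoints,
                   integer(0))
  set.seed(32)
  for (rep in 1:60) {
    n <- sample(6:12, 1)
    z <- rnorm(n, sd = 1) + rep(c(0, 3), each = ceiling(n / 2))[1:n]
    pen <- runif(1, 0.5, 8)
    got <- changepoints_penalized(z, penalty = pen)
    ref <- oracle_penalized(z, penalty = pen)
    expect_identical(got$breakpoints, as.integer(ref$breakpoints))
  }
})

test_that("changepoint verification keeps only peak-backed points", {
  set.seed(33)
  flat <- rnorm(200, 0.3, 0.005)
  dip <- flat; dip[100:106] <- 0.05
  expect_identical(verify_changepoints(c(99L, 107L), dip, "dip"),
                   c(99L, 107L))
  expect_identical(verify_changepoints(c(50L), flat, "dip"), integer(0))
  expect_identical(verify_changepoints(integer(0), dip, "dip"), integer(0))
  # pulse polarity looks for maxima instead
  pulse <- rnorm(200, 0, 0.005); pulse[100:106] <- 0.9
  expect_identical(verify_changepoints(c(99L, 107L), pulse, "pulse"),
                   c(99L, 107L))
  expect_identical(verify_changepoints(c(99L, 107L), pulse, "dip"), integer(0))
})

test_that("changepoint clusters become blinks via single-linkage gaps", {
  b <- blinks_from_changepoints(c(100L, 108L), fps = 30)
  expect_identical(nrow(b), 1L)
  expect_identical(c(b$onset_frame, b$offset_frame), c(100L, 108L))
  expect_equal(b$duration_ms, 8 / 30 * 1000)
  # a gap over 25 frames splits into two singletons, which are discarded
  expect_identical(nrow(blinks_from_changepoints(c(100L, 140L))), 0L)
  b2 <- blinks_from_changepoints(c(100L, 108L, 150L, 161L))
  expect_identical(b2$onset_frame, c(100L, 150L))
  expect_identical(b2$offset_frame, c(108L, 161L))
  # cross-check the gap rule against hclust single linkage
  set.seed(34)
  cps <- sort(sample(1:500, 25))
  grp_pkg <- cumsum(c(1L, as.integer(diff(cps) > 25)))
  grp_h <- cutree(hclust(dist(cps), method = "single"), h = 25)
  expect_identical(as.integer(unclass(factor(grp_pkg))),
                   as.integer(unclass(factor(grp_h))))
})

test_that("the blink pipeline recovers synthetic cued blinks", {
  # flat noisy baseline: nothing detected
  set.seed(35)
  expect_identical(nrow(detect_blinks(rnorm(300, 0.3, 0.02), "dip")), 0L)
  # one isolated clean dip
  one <- rnorm(300, 0.3, 0.01)
  one[150:158] <- c(0.2, 0.08, 0.05, 0.05, 0.05, 0.08, 0.15, 0.22, 0.27)
  ev1 <- detect_blinks(one, "dip")
  expect_identical(nrow(ev1), 1L)
  expect_true(ev1$onset_frame <= 151 && ev1$offset_frame >= 156)
  # seven-beep trials at default noise: all blinks, onsets within 2 frames
  for (s in c(2, 9)) {
    spec <- make_trial("blink", seed = s)
    bs <- simulate_blink_trace(spec, polarity = "dip", seed = s)
    ev <- detect_blinks(bs$series, "dip")
    expect_identical(nrow(ev), 7L)
    expect_true(all(abs(ev$onset_frame - bs$truth$onset_frame) <= 2))
  }
})

test_that("pursuit onset/offset are recovered on a noiseless step-ramp trial", {
  spec <- canonical_pursuit()
  sim <- simulate_gaze_trace(spec, noise_profile("none", dropout = 0),
                             seed = 1)
  po <- detect_pursuit_onset_offset(sim$trace)
  truth_on <- sim$events$onset_frame[sim$events$event_type == "pursuit_onset"]
  truth_off <- sim$events$onset_frame[sim$events$event_type == "pursuit_offset"]
  expect_lte(abs(po$onset_frame - truth_on), 1)
  expect_lte(abs(po$offset_frame - truth_off), 1)
  expect_identical(po$quality, "ok")
  # an all-static trace is flagged as having no usable velocity structure
  flat <- gaze_trace(0:39, rep(800, 40), rep(450, 40), fps = 30)
  expect_identical(detect_pursuit_onset_offset(flat)$quality, "low_velocity")
  short <- gaze_trace(0:5, rep(800, 6), rep(450, 6), fps = 30)
  expect_error(detect_pursuit_onset_offset(short), "12")
})

test_that("detectors are deterministic for fixed input", {
  spec <- make_trial("blink", seed = 4)
  bs <- simulate_blink_trace(spec, polarity = "dip", seed = 4)
  expect_identical(detect_blinks(bs$series, "dip"),
                   detect_blinks(bs$series, "dip"))
})
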