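test_that("fixation estimate is the coordinate-wise median of valid samples", {
  expect_equal(fixation_estimate(rep(3, 9), rep(4, 9)), c(x = 3, y = 4))
  expect_equal(fixation_estimate(c(rep(0, 5), 10), c(rep(0, 5), 10)),
               c(x = 0, y = 0))
  set.seed(41)
  x <- rnorm(101); y <- rnorm(101)
  expect_equal(fixation_estimate(x, y),
               c(x = oracle_median(x), y = oracle_median(y)))
  expect_true(all(is.na(fixation_estimate(NA_real_, NA_real_))))
})

test_that("fixation accuracy is the Euclidean offset in degrees", {
  expect_equal(fixation_accuracy(c(1, 2), c(1, 2)), 0)
  expect_equal(fixation_accuracy(c(3, 4), c(0, 0)), 5)
  # FU inputs convert through the platform scale first
  geom <- screen_geometry()
  est_fu <- c(854.05, 450); tgt_fu <- c(800, 450)
  expect_equal(fixation_accuracy(fu_to_deg(est_fu, geom),
                                 fu_to_deg(tgt_fu, geom)), 1)
})

test_that("RMS and STD precision follow their definitions and closed forms", {
  expect_equal(precision_rms(rep(1, 20), rep(2, 20)), 0)
  expect_equal(precision_std(rep(1, 20), rep(2, 20)), 0)
  expect_equal(precision_rms(rep(c(0, 1), 10), rep(0, 20)), 1)
  expect_equal(precision_std(c(0, 2), c(0, 0)), 1)
  expect_true(is.na(precision_rms(3, 3)))
  # iid 2-D Gaussian, sigma 1 per axis: STD -> sqrt(2), RMS/STD -> sqrt(2)
  set.seed(42)
  x <- rnorm(10000); y <- rnorm(10000)
  expect_equal(precision_std(x, y), sqrt(2), tolerance = 0.03)
  expect_equal(precision_rms(x, y) / precision_std(x, y), sqrt(2),
               tolerance = 0.03)
})

test_that("zone classification uses half-open cells with edge clamping", {
  geom <- screen_geometry()
  grid <- zone_grid(4, 4)
  ctr <- zone_centers(grid, geom)
  expect_identical(classify_zone(ctr$x_deg, ctr$y_deg, grid, geom), 1:16)
  # top-left corner region is zone 1
  expect_identical(classify_zone(-14, 8, grid, geom), 1L)
  # a point exactly on the first vertical boundary belongs to the right cell
  b1 <- -geom$window_deg[1] / 2 + geom$window_deg[1] / 4
  expect_identical(classify_zone(b1, 8, grid, geom), 2L)
  # out-of-window points clamp to edge zones; 1x1 grid is always zone 1
  expect_identical(classify_zone(-99, 99, grid, geom), 1L)
  expect_identical(classify_zone(99, -99, grid, geom), 16L)
  expect_identical(classify_zone(99, -99, zone_grid(1, 1), geom), 1L)
  expect_error(classify_zone(NaN, 0, grid, geom), "finite")
})

test_that("zero-noise sessions classify every zone correctly", {
  spec <- make_trial("zone", seed = 6)
  sim <- simulate_gaze_trace(spec, noise_profile("none", dropout = 0),
                             seed = 6)
  zc <- zone_classification(list(trace = sim$trace, spec = spec))
  expect_equal(zc$accuracy, 1)
  expect_identical(unname(diag(zc$confusion)), rep(1L, 16))
  expect_identical(sum(zc$confusion), 16L)
  expect_equal(unname(zc$precision), rep(1, 16))
})

test_that("grid coarsening is containment-based and never lowers accuracy", {
  set.seed(43)
  for (rep in 1:20) {
    pairs <- data.frame(presented = sample(16, 200, replace = TRUE),
                        predicted = sample(16, 200, replace = TRUE))
    acc4 <- zone_classification_from_pairs(pairs)$accuracy
    for (to in list(zone_grid(2, 2), zone_grid(2, 1), zone_grid(1, 2))) {
      cz <- coarsen_zone_labels(pairs, to = to)
      expect_gte(cz$accuracy, acc4)
      # originally correct pairs stay correct under any coarsening
      ok4 <- pairs$presented == pairs$predicted
      expect_true(all((cz$pairs$presented == cz$pairs$predicted)[ok4]))
    }
  }
  expect_error(coarsen_zone_labels(
    data.frame(presented = 1L, predicted = 1L), to = zone_grid(3, 1)),
    "nested")
  # a vertical-neighbor confusion within the same screen half is correct
  # under the 2 x 1 (two columns) split
  vert <- data.frame(presented = 1L, predicted = 5L)
  expect_equal(coarsen_zone_labels(vert, to = zone_grid(2, 1))$accuracy, 1)
  expect_equal(coarsen_zone_labels(vert, to = zone_grid(1, 2))$accuracy, 1)
  expect_equal(coarsen_zone_labels(data.frame(presented = 1L, predicted = 13L),
                                   to = zone_grid(1, 2))$accuracy, 0)
})

test_that("vertically dominant noise favors the column split over the row split", {
  set.seed(44)
  geom <- screen_geometry()
  ctr <- zone_centers(zone_grid(4, 4), geom)
  pres <- sample(16, 1000, replace = TRUE)
  px <- ctr$x_deg[pres] + rnorm(1000, 0, 1)
  py <- ctr$y_deg[pres] + rnorm(1000, 0, 3)
  pairs <- data.frame(presented = pres, predicted = classify_zone(px, py))
  a21 <- coarsen_zone_labels(pairs, to = zone_grid(2, 1))$accuracy
  a12 <- coarsen_zone_labels(pairs, to = zone_grid(1, 2))$accuracy
  expect_gte(a21, a12)
})

test_that("pursuit angle respects the centered y-up convention", {
  geom <- screen_geometry()
  mkramp <- function(ux, uy) {
    t <- 0:29
    cc <- centered_to_screen(0.45 * t * ux, 0.45 * t * uy, geom)
    gaze_trace(t, cc$x, cc$y, fps = 30)
  }
  expect_equal(pursuit_angle(mkramp(1, 0))$angle_deg, 0, tolerance = 1e-6)
  expect_equal(pursuit_angle(mkramp(0, 1))$angle_deg, 90, tolerance = 1e-6)
  expect_equal(pursuit_angle(mkramp(-1, 0))$angle_deg, 180, tolerance = 1e-6)
  expect_equal(pursuit_angle(mkramp(1, 1))$angle_deg, 45, tolerance = 1e-6)
  expect_identical(pursuit_angle(mkramp(0, 0))$quality, "low_displacement")
})

test_that("angular deviation is the circular absolute difference", {
  expect_equal(angular_deviation(350, 10), 20)
  expect_equal(angular_deviation(17, 17), 0)
  expect_equal(angular_deviation(0, 180), 180)
  set.seed(45)
  a <- runif(100, -720, 720); b <- runif(100, -720, 720)
  expect_equal(angular_deviation(a, b), angular_deviation(b, a))
  expect_true(all(angular_deviation(a, b) >= 0 & angular_deviation(a, b) <= 180))
})

test_that("pursuit latency and duration derive from detected frames", {
  ld <- pursuit_latency_duration(39, 55, t_move_start_s = 1.0, fps = 30)
  expect_equal(ld$latency_ms, 300)
  expect_equal(ld$duration_ms, 16 / 30 * 1000)
  expect_identical(ld$flag, "ok")
  expect_identical(pursuit_latency_duration(10, 10, 0, 30)$flag, "degenerate")
  ant <- pursuit_latency_duration(5, 20, t_move_start_s = 1.0, fps = 30)
  expect_lt(ant$latency_ms, 0)
  expect_identical(ant$flag, "anticipatory")
  # injected 250 ms onset latency is recovered on a noiseless trial
  spec <- canonical_pursuit()
  sim <- simulate_gaze_trace(spec, noise_profile("none", dropout = 0), seed = 2)
  po <- detect_pursuit_onset_offset(sim$trace)
  ld2 <- pursuit_latency_duration(po$onset_frame, po$offset_frame,
                                  spec$t_move_start_s, 30)
  expect_lt(abs(ld2$latency_ms - 250), 67)
})

test_that("blink measures assign events to the nearest preceding beep", {
  spec <- make_trial("blink", seed = 10)
  ev <- data.frame(
    onset_frame = timestamps_to_frames(spec$beep_onsets_s + 0.3, 30),
    offset_frame = timestamps_to_frames(spec$beep_onsets_s + 0.6, 30))
  ev$duration_ms = (ev$offset_frame - ev$onset_frame) / 30 * 1000
  bm <- blink_measures(ev, spec, fps = 30)
  expect_identical(bm$n_blinks, 7L)
  expect_identical(bm$per_blink$beep, 1:7)
  expect_true(all(abs(bm$per_blink$latency_ms - 300) < 34))
  # an event before the first beep counts but gets no latency
  early <- rbind(data.frame(onset_frame = 2L, offset_frame = 8L,
                            duration_ms = 200), ev)
  bm2 <- blink_measures(early, spec, fps = 30)
  expect_identical(bm2$n_blinks, 8L)
  expect_true(is.na(bm2$per_blink$latency_ms[1]))
  expect_identical(sum(is.na(bm2$per_blink$latency_ms)), 1L)
})

test_that("free-viewing stats discard the first cluster and normalize entropy", {
  geom <- screen_geometry()
  mkcl <- function(x, y) data.frame(cluster = seq_along(x), x_deg = x,
                                    y_deg = y,
                                    start_frame = seq_along(x) * 10L,
                                    end_frame = seq_along(x) * 10L + 5L,
                                    n = 3L)
  cl5 <- mkcl(rnorm(5), rnorm(5))
  expect_identical(freeview_stats(cl5, geom = geom)$n_fixations, 4L)
  # all retained fixations in one bin: entropy 0
  one <- mkcl(rep(0.5, 6), rep(0.5, 6))
  expect_equal(freeview_stats(one, geom = geom)$entropy, 0)
  # fixations exactly uniform over the 16 bins: entropy 1
  ctr <- zone_centers(zone_grid(4, 4), geom)
  uni <- mkcl(ctr$x_deg, ctr$y_deg)
  expect_equal(freeview_stats(uni, geom = geom,
                              discard_first = FALSE)$entropy, 1)
  expect_identical(freeview_stats(mkcl(0, 0), geom = geom)$n_fixations, 0L)
})
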