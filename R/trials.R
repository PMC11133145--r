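#' Generate a stimulus schedule for one trial of the task battery
#'
#' Builds the exact stimulus schedule for one trial of one of the five
#' battery tasks, reproducing the study's parameterization:
#'
#' * `"fixation"` — a bullseye target shown at 13 locations (center plus
#'   three eccentricity rings of four), a subset of a 7 x 7 grid spanning
#'   -11.1..11.1 deg horizontally and -6.2..6.2 deg vertically; 2500 ms per
#'   location, order randomized, starting and ending at the center;
#'   target diameter 0.6 deg.
#' * `"zone"` — a pattern shown for 1500 ms in each cell of a non-visible
#'   4 x 4 grid (7.4 x 4.16 deg cells tiling the window), in randomized
#'   order with a 200 ms gap between presentations.
#' * `"pursuit"` — step-ramp pursuit: after a self-paced start, the target
#'   appears after a random delay (exponential, mean 0.5 s, truncated at
#'   5 s, plus a constant 0.2 s offset) at 3 deg from the center opposite
#'   the movement direction, then moves linearly at 15 deg/s through the
#'   center until 8.3 deg past it. Direction is one of 12 angles spread
#'   evenly over the circle (0, 30, ..., 330 deg); pass `angle` to schedule
#'   without replacement across a session.
#' * `"blink"` — seven auditory beeps (nominal 100 ms), pauses of 1.4 s
#'   between beeps uniformly jittered by +-0.2 s.
#' * `"freeview"` — a 3 s free-viewing display, modeled by a synthetic
#'   ground-truth saliency map (mixture of 2-D Gaussian hotspots), followed
#'   by a 1 s central fixation cross.
#'
#' All coordinates are in the centered analysis frame (degrees, y up); all
#' times are seconds from trial start. Schedules are deterministic given
#' `seed`.
#'
#' @param task One of `"fixation"`, `"zone"`, `"pursuit"`, `"blink"`,
#'   `"freeview"`.
#' @param seed Integer seed controlling all randomized schedule elements.
#' @param geom A [screen_geometry()].
#' @param angle Pursuit only: movement direction in degrees; must be one of
#'   the 12 allowed angles. Default: drawn from them.
#' @param delay Pursuit only: override for the random initiation delay
#'   (seconds, in `[0.2, 5.2]`). Default: drawn from the exponential design.
#' @return An object of classes `c("<task>_trial_spec", "trial_spec")`.
#' @examples
#' make_trial("pursuit", seed = 1)
#' @export
make_trial <- function(task, seed = 1, geom = screen_geometry(),
                       angle = NULL, delay = NULL) {
  task <- match.arg(task, c("fixation", "zone", "pursuit", "blink",
                            "freeview"))
  spec <- withr_seed(seed, switch(task,
    fixation = make_fixation_trial(geom),
    zone     = make_zone_trial(geom),
    pursuit  = make_pursuit_trial(geom, angle, delay),
    blink    = make_blink_trial(),
    freeview = make_freeview_trial(geom)))
  spec$task <- task
  spec$seed <- seed
  spec$schema_version <- 1L
  class(spec) <- c(paste0(task, "_trial_spec"), "trial_spec")
  spec
}

# run expr under a local RNG state seeded with seed
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' The 13 fixation-task target locations (centered degrees)
#' @param geom A [screen_geometry()].
#' @return Data frame with columns `x_deg`, `y_deg`, `ring`.
#' @export
fixation_locations <- function(geom = screen_geometry()) {
  # center plus three concentric rings of 4, on the 7x7 grid lattice
  sx <- 11.1 / 3; sy <- 6.2 / 3
  ring_pts <- function(k) data.frame(
    x_deg = c(-1, 1, 1, -1) * k * sx,
    y_deg = c(-1, -1, 1, 1) * k * sy,
    ring = k)
  rbind(data.frame(x_deg = 0, y_deg = 0, ring = 0),
        ring_pts(1), ring_pts(2), ring_pts(3))
}

make_fixation_trial <- function(geom) {
  loc <- fixation_locations(geom)
  dwell <- 2.5
  periph <- loc[-1L, ]
  order_mid <- sample(nrow(periph))
  # center first and last; all 13 locations presented
  seq_loc <- rbind(loc[1L, ], periph[order_mid, ], loc[1L, ])
  n <- nrow(seq_loc)
  schedule <- data.frame(
    onset_s = (seq_len(n) - 1L) * dwell,
    offset_s = seq_len(n) * dwell,
    x_deg = seq_loc$x_deg, y_deg = seq_loc$y_deg)
  list(schedule = schedule, dwell_ms = 2500, target_diameter_deg = 0.6,
       locations = loc, duration_s = n * dwell)
}

make_zone_trial <- function(geom) {
  grid <- zone_grid(4, 4)
  ord <- sample(16L)
  on_s <- 1.5; gap_s <- 0.2
  ctr <- zone_centers(grid, geom)
  schedule <- data.frame(
    onset_s = (seq_len(16L) - 1L) * (on_s + gap_s),
    offset_s = (seq_len(16L) - 1L) * (on_s + gap_s) + on_s,
    zone = ord,
    x_deg = ctr$x_deg[ord], y_deg = ctr$y_deg[ord])
  list(schedule = schedule, grid = grid, present_ms = 1500, gap_ms = 200,
       duration_s = 16 * (on_s + gap_s))
}

make_pursuit_trial <- function(geom, angle = NULL, delay = NULL) {
  angles <- seq(0, 330, by = 30)
  if (is.null(delay)) delay <- min(stats::rexp(1, rate = 1 / 0.5), 5) + 0.2
  stopifnot(delay >= 0.2, delay <= 5.2)
  theta <- if (is.null(angle)) sample(angles, 1L) else angle
  if (!theta %in% angles)
    stop("pursuit angle must be one of 0, 30, ..., 330 degrees")
  speed <- 15; start_lead_s <- 0.2; end_radius <- 8.3
  u <- c(cos(theta * pi / 180), sin(theta * pi / 180))
  start <- -u * speed * start_lead_s       # 3 deg before center along -theta
  travel_s <- (speed * start_lead_s + end_radius) / speed
  list(angle_deg = theta, speed_dps = speed,
       start_deg = start, end_radius_deg = end_radius,
       t_move_start_s = delay, t_move_end_s = delay + travel_s,
       duration_s = delay + travel_s + 0.3)
}

make_blink_trial <- function() {
  gaps <- 1.4 + stats::runif(6, -0.2, 0.2)
  onsets <- 0.5 + cumsum(c(0, gaps))
  list(beep_onsets_s = onsets, beep_duration_ms = 100,
       duration_s = max(onsets) + 1.2)
}

make_freeview_trial <- function(geom, n_hotspots = 3) {
  w <- geom$window_deg
  mu_x <- stats::runif(n_hotspots, -0.3 * w[1], 0.3 * w[1])
  mu_y <- stats::runif(n_hotspots, -0.3 * w[2], 0.3 * w[2])
  sd_deg <- stats::runif(n_hotspots, 1.5, 2.5)
  wgt <- stats::runif(n_hotspots, 0.5, 1)
  list(hotspots = data.frame(x_deg = mu_x, y_deg = mu_y, sd_deg = sd_deg,
                             weight = wgt / sum(wgt)),
       view_s = 3, post_fix_s = 1, duration_s = 3)
}

#' @export
print.trial_spec <- function(x, ...) {
  cat(sprintf("Trial spec: task '%s', seed %d, duration %.2f s\n",
              x$task, x$seed, x$duration_s))
  invisible(x)
}

#' Serialize / restore a trial spec as JSON
#'
#' @param spec A [make_trial()] spec.
#' @param path Output (input) file path.
#' @return `read_trial_spec` returns the restored `trial_spec`.
#' @export
write_trial_spec <- function(spec, path) {
  x <- unclass(spec)
  if (!is.null(x$grid)) x$grid <- unclass(x$grid)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_trial_spec
#' @export
read_trial_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("schedule", "locations", "hotspots"))
    if (!is.null(x[[f]])) x[[f]] <- as.data.frame(x[[f]])
  if (!is.null(x$grid)) x$grid <- zone_grid(x$grid$w, x$grid$h)
  if (!is.null(x$start_deg)) x$start_deg <- as.numeric(x$start_deg)
  class(x) <- c(paste0(x$task, "_trial_spec"), "trial_spec")
  x
}
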