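#' Synthesize a gaze trace with known ground truth for a trial spec
#'
#' Generates the idealized oculomotor response to a stimulus schedule
#' (fixation hold, saccade after a latency, smooth pursuit after an onset
#' latency at a fixed gain, saliency-driven free viewing), then adds a
#' per-participant systematic bias (magnitude from the noise profile,
#' direction random), AR(1) Gaussian sample noise, and frame dropouts.
#' The true event log (fixation windows and centroids, pursuit onset/offset,
#' target angle) is returned alongside the trace, so detector and measure
#' recovery can be scored against known truth.
#'
#' @param spec A [make_trial()] spec.
#' @param noise A [noise_profile()].
#' @param ocu An [oculomotor_params()].
#' @param fps Sampling rate in frames per second (10-120).
#' @param seed Integer seed; output is bit-for-bit reproducible given
#'   `(spec, seed)`.
#' @param bias_angle Optional bias direction in radians; supply one value per
#'   simulated participant to keep the accuracy offset constant across that
#'   participant's trials. Default: drawn from `seed`.
#' @return A list with components `trace` (a [gaze_trace()] in screen FU),
#'   `events` (data.frame: `event_type`, `onset_frame`, `offset_frame`,
#'   `x_deg`, `y_deg`, `aux`), and `bias_deg` (the applied bias vector,
#'   centered degrees).
#' @export
simulate_gaze_trace <- function(spec, noise = noise_profile("faze"),
                                ocu = oculomotor_params(), fps = 30,
                                seed = 1, bias_angle = NULL) {
  stopifnot(inherits(spec, "trial_spec"), fps >= 10, fps <= 120)
  withr_seed(seed + 1013L, {
    n <- floor(spec$duration_s * fps) + 1L
    t <- (seq_len(n) - 1L) / fps
    ideal <- ideal_gaze_path(spec, t, ocu, fps)
    if (is.null(bias_angle)) bias_angle <- stats::runif(1, 0, 2 * pi)
    bias <- noise$bias_deg * c(cos(bias_angle), sin(bias_angle))
    sd_axis <- noise$std_deg / sqrt(2)
    x <- ideal$x + bias[1] + ar1_noise(n, sd_axis, noise$rho)
    y <- ideal$y + bias[2] + ar1_noise(n, sd_axis, noise$rho)
    valid <- stats::runif(n) >= noise$dropout
    x[!valid] <- NA_real_; y[!valid] <- NA_real_
    geom <- screen_geometry(fps = fps)
    sc <- centered_to_screen(x, y, geom)
    ev <- ideal$events
    # truth centroids are actual mean eye positions, i.e. include the bias
    fix <- ev$event_type == "fixation"
    ev$x_deg[fix] <- ev$x_deg[fix] + bias[1]
    ev$y_deg[fix] <- ev$y_deg[fix] + bias[2]
    list(trace = gaze_trace(0:(n - 1L), sc$x, sc$y, valid, fps = fps,
                            trial_id = sprintf("%s_%d", spec$task, seed),
                            source_model = noise$name),
         events = ev, bias_deg = bias)
  })
}

# first 0-based frame whose timestamp is at or after t
ceil_frame <- function(t, fps) as.integer(ceiling(t * fps - 1e-9))

# stationary AR(1) series with marginal sd `sd` and lag-1 correlation rho
ar1_noise <- function(n, sd, rho) {
  if (sd == 0 || n == 0L) return(numeric(n))
  w <- stats::rnorm(n)
  e <- numeric(n)
  e[1] <- w[1]
  if (n > 1L) {
    a <- sqrt(1 - rho^2)
    for (i in 2:n) e[i] <- rho * e[i - 1] + a * w[i]
  }
  sd * e
}

# noiseless eye path (centered degrees) + truth events for a trial spec
ideal_gaze_path <- function(spec, t, ocu, fps) {
  UseMethod("ideal_gaze_path")
}

#' @export
ideal_gaze_path.fixation_trial_spec <- function(spec, t, ocu, fps) {
  step_path(spec$schedule, t, ocu, fps)
}

#' @export
ideal_gaze_path.zone_trial_spec <- function(spec, t, ocu, fps) {
  step_path(spec$schedule, t, ocu, fps, aux = spec$schedule$zone)
}

# piecewise-constant path: hold previous target until onset + saccade latency
step_path <- function(sched, t, ocu, fps, aux = seq_len(nrow(sched))) {
  lat <- ocu$saccade_latency_ms / 1000
  x <- rep(sched$x_deg[1], length(t)); y <- rep(sched$y_deg[1], length(t))
  k <- nrow(sched)
  for (i in 2:k) {
    mv <- t >= sched$onset_s[i] + lat
    x[mv] <- sched$x_deg[i]; y[mv] <- sched$y_deg[i]
  }
  on_f <- timestamps_to_frames(pmin(sched$onset_s + lat, max(t)), fps)
  off_f <- timestamps_to_frames(pmin(sched$offset_s, max(t)), fps)
  on_f[1] <- 0L
  list(x = x, y = y,
       events = data.frame(event_type = "fixation",
                           onset_frame = on_f, offset_frame = off_f,
                           x_deg = sched$x_deg, y_deg = sched$y_deg,
                           aux = aux))
}

#' @export
ideal_gaze_path.pursuit_trial_spec <- function(spec, t, ocu, fps) {
  t_on <- spec$t_move_start_s + ocu$pursuit_latency_ms / 1000
  t_off <- spec$t_move_end_s
  u <- c(cos(spec$angle_deg * pi / 180), sin(spec$angle_deg * pi / 180))
  v <- ocu$pursuit_gain * spec$speed_dps
  travel <- pmin(pmax(t - t_on, 0), t_off - t_on) * v
  # truth marks the first frame of each new regime: first moving frame,
  # first frame at rest again
  list(x = travel * u[1], y = travel * u[2],
       events = data.frame(
         event_type = c("pursuit_onset", "pursuit_offset"),
         onset_frame = ceil_frame(c(t_on, t_off), fps),
         offset_frame = ceil_frame(c(t_on, t_off), fps),
         x_deg = NA_real_, y_deg = NA_real_,
         aux = spec$angle_deg))
}

#' @export
ideal_gaze_path.blink_trial_spec <- function(spec, t, ocu, fps) {
  list(x = numeric(length(t)), y = numeric(length(t)),
       events = data.frame(event_type = "fixation", onset_frame = 0L,
                           offset_frame = length(t) - 1L,
                           x_deg = 0, y_deg = 0, aux = 1))
}

#' @export
ideal_gaze_path.freeview_trial_spec <- function(spec, t, ocu, fps) {
  hs <- spec$hotspots
  dw <- ocu$freeview_dwell_ms_range / 1000
  fix_x <- 0; fix_y <- 0; t_start <- 0
  xs <- numeric(0); ys <- numeric(0); on_s <- numeric(0); off_s <- numeric(0)
  while (t_start < spec$view_s) {
    dwell <- stats::runif(1, dw[1], dw[2])
    t_end <- min(t_start + dwell, spec$view_s)
    xs <- c(xs, fix_x); ys <- c(ys, fix_y)
    on_s <- c(on_s, t_start); off_s <- c(off_s, t_end)
    t_start <- t_end
    k <- sample.int(nrow(hs), 1L, prob = hs$weight)
    fix_x <- stats::rnorm(1, hs$x_deg[k], hs$sd_deg[k])
    fix_y <- stats::rnorm(1, hs$y_deg[k], hs$sd_deg[k])
  }
  x <- numeric(length(t)); y <- numeric(length(t))
  for (i in seq_along(xs)) {
    inwin <- t >= on_s[i] & t < off_s[i]
    x[inwin] <- xs[i]; y[inwin] <- ys[i]
  }
  x[t >= spec$view_s] <- xs[length(xs)]
  y[t >= spec$view_s] <- ys[length(ys)]
  list(x = x, y = y,
       events = data.frame(event_type = "fixation",
                           onset_frame = timestamps_to_frames(on_s, fps),
                           offset_frame = timestamps_to_frames(off_s, fps),
                           x_deg = xs, y_deg = ys, aux = seq_along(xs)))
}

#' Synthesize a blink time series with known ground truth
#'
#' Produces an eye-aspect-ratio style trace (baseline with one dip per cued
#' blink) or a blink-probability style trace (near-zero baseline with one
#' pulse per blink), with the blink response starting at a random latency
#' after each beep and lasting `ocu$blink_duration_ms`. Lid kinematics are
#' asymmetric, as in real blinks: a fast linear closure over the first third
#' of the blink and a slower linear reopening over the remainder; additive
#' Gaussian noise on top.
#'
#' @param spec A `"blink"` [make_trial()] spec.
#' @param ocu An [oculomotor_params()].
#' @param polarity `"dip"` (eye-aspect-ratio) or `"pulse"`
#'   (blink probability).
#' @param fps Frames per second.
#' @param seed Integer seed.
#' @return A list with `series` (numeric vector), `truth` (data.frame:
#'   `beep`, `beep_onset_s`, `onset_frame`, `offset_frame`), and `fps`.
#' @export
simulate_blink_trace <- function(spec, ocu = oculomotor_params(),
                                 polarity = c("dip", "pulse"), fps = 30,
                                 seed = 1) {
  stopifnot(inherits(spec, "blink_trial_spec"))
  polarity <- match.arg(polarity)
  withr_seed(seed + 2027L, {
    n <- floor(spec$duration_s * fps) + 1L
    t <- (seq_len(n) - 1L) / fps
    base <- if (polarity == "dip") ocu$ear_baseline else 0
    amp <- if (polarity == "dip") ocu$ear_baseline - ocu$ear_floor
           else ocu$pulse_height
    series <- rep(base, n)
    lat <- stats::runif(length(spec$beep_onsets_s),
                        ocu$blink_latency_ms_range[1],
                        ocu$blink_latency_ms_range[2]) / 1000
    dur <- ocu$blink_duration_ms / 1000
    t_on <- spec$beep_onsets_s + lat
    close_frac <- 1 / 3  # fast lid closure, slower reopening
    for (i in seq_along(t_on)) {
      ph <- (t - t_on[i]) / dur
      inb <- ph >= 0 & ph <= 1
      p <- ph[inb]
      exc <- amp * ifelse(p < close_frac, p / close_frac,
                          (1 - p) / (1 - close_frac))
      series[inb] <- series[inb] + if (polarity == "dip") -exc else exc
    }
    if (polarity == "dip") series <- pmax(series, ocu$ear_floor)
    series <- series + stats::rnorm(n, 0, ocu$blink_noise_sd)
    list(series = series,
         truth = data.frame(beep = seq_along(t_on),
                            beep_onset_s = spec$beep_onsets_s,
                            onset_frame = ceil_frame(t_on, fps),
                            offset_frame = ceil_frame(t_on + dur, fps)),
         fps = fps)
  })
}
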