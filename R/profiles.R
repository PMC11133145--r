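#' Spatial noise profile of a gaze prediction model
#'
#' Describes the error structure of a webcam gaze model as measured on the
#' fixation task: a systematic accuracy offset (bias magnitude, direction
#' random per participant), sample noise with a given dispersion (STD,
#' 2-D radial, degrees), temporal autocorrelation rho, and a frame dropout
#' probability (face-detection failures).
#'
#' Noise is AR(1) per axis. With stationary radial dispersion STD, the
#' expected sample-to-sample RMS is `STD * sqrt(2 * (1 - rho))`, so rho is
#' what makes the independently observed RMS and STD mutually consistent
#' (white noise, rho = 0, forces RMS = sqrt(2) * STD and cannot reproduce
#' RMS < STD as observed for the more precise models).
#'
#' Presets reproduce the three benchmarked gaze models' measured accuracy,
#' STD and RMS: `"mpiigaze"` (3.70, 2.96, 2.33 deg), `"ethxgaze"`
#' (3.40, 2.39, 1.80 deg), `"faze"` (2.44, 1.63, 0.47 deg).
#'
#' @param name Profile name, or one of the preset names.
#' @param bias_deg Accuracy offset magnitude in degrees.
#' @param std_deg Radial sample noise STD in degrees.
#' @param rms_deg Target sample-to-sample RMS in degrees; determines `rho`.
#' @param dropout Per-frame probability of an invalid sample.
#' @return An object of class `noise_profile` with fields `name`, `bias_deg`,
#'   `std_deg`, `rms_deg`, `rho`, `dropout`.
#' @examples
#' noise_profile("faze")
#' noise_profile("quiet", bias_deg = 0, std_deg = 0.1, rms_deg = 0.1 * sqrt(2))
#' @export
noise_profile <- function(name = "faze", bias_deg = NULL, std_deg = NULL,
                          rms_deg = NULL, dropout = NULL) {
  presets <- list(
    mpiigaze = list(bias_deg = 3.70, std_deg = 2.96, rms_deg = 2.33),
    ethxgaze = list(bias_deg = 3.40, std_deg = 2.39, rms_deg = 1.80),
    faze     = list(bias_deg = 2.44, std_deg = 1.63, rms_deg = 0.47),
    none     = list(bias_deg = 0,    std_deg = 0,    rms_deg = 0)
  )
  p <- presets[[tolower(name)]]
  if (is.null(p)) p <- list(bias_deg = NA_real_, std_deg = NA_real_,
                            rms_deg = NA_real_)
  if (!is.null(bias_deg)) p$bias_deg <- bias_deg
  if (!is.null(std_deg))  p$std_deg  <- std_deg
  if (!is.null(rms_deg))  p$rms_deg  <- rms_deg
  if (is.null(dropout)) dropout <- if (tolower(name) %in% names(presets)) 0.02 else 0
  if (any(!is.finite(c(p$bias_deg, p$std_deg, p$rms_deg))))
    stop("noise_profile: unknown preset '", name,
         "' and no explicit parameters given")
  stopifnot(p$std_deg >= 0, p$bias_deg >= 0, dropout >= 0, dropout < 1)
  rho <- if (p$std_deg > 0) 1 - (p$rms_deg / p$std_deg)^2 / 2 else 0
  if (rho < -1e-9 || rho >= 1)
    stop("noise_profile: RMS/STD ratio implies rho outside [0, 1)")
  rho <- max(rho, 0)
  structure(c(list(name = name), p, list(rho = rho, dropout = dropout)),
            class = "noise_profile")
}

#' @export
print.noise_profile <- function(x, ...) {
  cat(sprintf(
    "Noise profile '%s': bias %.2f deg, STD %.2f deg, RMS %.2f deg (rho %.3f), dropout %.3f\n",
    x$name, x$bias_deg, x$std_deg, x$rms_deg, x$rho, x$dropout))
  invisible(x)
}

#' Oculomotor response parameters for the simulator
#'
#' Idealized oculomotor dynamics used when synthesizing gaze and blink
#' responses to a trial schedule. Defaults sit near typical human values so
#' that recovery tests run under realistic conditions: 200 ms saccade
#' latency, 250 ms smooth-pursuit onset latency at gain 0.9, blinks with a
#' 300 ms lid closure starting 250-450 ms after the auditory cue.
#'
#' @param saccade_latency_ms Latency from target onset to the orienting
#'   saccade (ms).
#' @param pursuit_latency_ms Latency from target motion onset to pursuit
#'   onset (ms).
#' @param pursuit_gain Eye velocity / target velocity during pursuit.
#' @param blink_latency_ms_range Uniform range of blink response latency
#'   after a beep (ms).
#' @param blink_duration_ms Lid closure duration (ms).
#' @param ear_baseline,ear_floor Eye-aspect-ratio open-eye baseline and
#'   closed-eye floor.
#' @param pulse_height Blink-probability pulse height for probability traces.
#' @param blink_noise_sd Additive Gaussian noise SD on blink series.
#' @param freeview_dwell_ms_range Uniform range of per-fixation dwell during
#'   free viewing (ms).
#' @return An object of class `oculomotor_params`.
#' @export
oculomotor_params <- function(saccade_latency_ms = 200,
                              pursuit_latency_ms = 250,
                              pursuit_gain = 0.9,
                              blink_latency_ms_range = c(250, 450),
                              blink_duration_ms = 300,
                              ear_baseline = 0.3,
                              ear_floor = 0.05,
                              pulse_height = 0.9,
                              blink_noise_sd = 0.02,
                              freeview_dwell_ms_range = c(200, 400)) {
  stopifnot(saccade_latency_ms > 0, pursuit_latency_ms > 0,
            pursuit_gain > 0, pursuit_gain <= 1.2,
            blink_duration_ms > 0, ear_floor < ear_baseline,
            blink_noise_sd >= 0)
  structure(list(saccade_latency_ms = saccade_latency_ms,
                 pursuit_latency_ms = pursuit_latency_ms,
                 pursuit_gain = pursuit_gain,
                 blink_latency_ms_range = blink_latency_ms_range,
                 blink_duration_ms = blink_duration_ms,
                 ear_baseline = ear_baseline, ear_floor = ear_floor,
                 pulse_height = pulse_height,
                 blink_noise_sd = blink_noise_sd,
                 freeview_dwell_ms_range = freeview_dwell_ms_range),
            class = "oculomotor_params")
}
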