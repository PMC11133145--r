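#' Blink measures for a cued-blink trial
#'
#' From detected blink events and the trial's beep schedule: the blink count
#' (seven is expected for a compliant trial), per-blink onset latency
#' relative to its assigned beep, and per-blink duration. Each blink is
#' assigned to the nearest preceding beep; blinks before the first beep stay
#' in the count but get no latency.
#'
#' @param events Blink events from [detect_blinks()] (sorted by onset).
#' @param spec The `"blink"` [make_trial()] spec.
#' @param fps Frames per second of the series the events came from.
#' @return A list: `n_blinks`, and `per_blink` (data.frame `onset_frame`,
#'   `offset_frame`, `beep`, `latency_ms`, `duration_ms`; `beep`/
#'   `latency_ms` are `NA` for unassigned blinks).
#' @export
blink_measures <- function(events, spec, fps = 30) {
  stopifnot(inherits(spec, "blink_trial_spec"))
  beeps <- spec$beep_onsets_s
  n <- nrow(events)
  beep <- rep(NA_integer_, n); lat <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    t_on <- events$onset_frame[i] / fps
    prior <- which(beeps <= t_on + 1e-9)
    if (length(prior) > 0L) {
      beep[i] <- max(prior)
      lat[i] <- (t_on - beeps[beep[i]]) * 1000
    }
  }
  list(n_blinks = n,
       per_blink = data.frame(onset_frame = events$onset_frame,
                              offset_frame = events$offset_frame,
                              beep = beep, latency_ms = lat,
                              duration_ms = events$duration_ms))
}
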