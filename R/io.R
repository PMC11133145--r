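#' Gaze CSV format
#'
#' The exchange format for gaze traces: one row per frame, columns
#' `trial_id`, `frame`, `t_sec`, `x_fu`, `y_fu`, `valid` (0/1),
#' `source_model`. Invalid rows are kept (flagged, not dropped) so frame
#' indexing stays aligned with the video. Writing then reading a set of
#' traces is lossless.
#'
#' @param traces A [gaze_trace()] or list of them.
#' @param path File path.
#' @return `read_gaze_csv`: a named list of `gaze_trace` objects, one per
#'   `trial_id`, in file order.
#' @export
write_gaze_csv <- function(traces, path) {
  if (inherits(traces, "gaze_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_gaze_csv
#' @param fps Frame rate to assume when reconstructing traces whose `t_sec`
#'   column does not determine it (single-sample trials); default 30.
#' @export
read_gaze_csv <- function(path, fps = 30) {
  if (!file.exists(path)) stop("read_gaze_csv: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "frame", "t_sec", "x_fu", "y_fu", "valid",
            "source_model")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("read_gaze_csv: schema error, missing columns: ",
         paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$frame) | df$frame < 0 | df$frame != floor(df$frame))
  if (length(bad) > 0L)
    stop("read_gaze_csv: malformed frame index at line ", bad[1] + 1L)
  out <- lapply(split(df, factor(df$trial_id, levels = unique(df$trial_id))),
                function(g) {
    tr_fps <- if (nrow(g) > 1L) {
      dt <- diff(g$t_sec) / diff(g$frame)
      1 / stats::median(dt)
    } else fps
    gaze_trace(g$frame, g$x_fu, g$y_fu, g$valid == 1, fps = tr_fps,
               t0 = g$t_sec[1] - g$frame[1] / tr_fps,
               trial_id = g$trial_id[1], source_model = g$source_model[1])
  })
  out
}

#' Events CSV
#'
#' Detected events (fixations, pursuit onset/offset, blinks) in a tidy
#' table: `trial_id`, `event_type`, `onset_frame`, `offset_frame`, `x_deg`,
#' `y_deg`, `aux`.
#'
#' @param events Data.frame in the events schema.
#' @param path File path.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run configuration
#'
#' YAML configuration with four blocks — `geometry` (`fu_per_degree`,
#' `window_fu`, `fps`), `detection` (`eps`, `temporal_window`, `min_size`,
#' `k`, `min_segment`, `penalty_beta`, `peak_window`, `peak_mad_k`,
#' `agglom_threshold`), `measures` (`grid`, `entropy_bins`, `settle_ms`),
#' and `simulation` (`noise`, `seed`, `trials`). Unknown keys are rejected;
#' missing keys take the defaults below.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return A named list of the four blocks, with class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad) > 0L)
      stop("read_run_config: unknown config block(s): ",
           paste(bad, collapse = ", "))
    for (blk in names(user)) {
      badk <- setdiff(names(user[[blk]]), names(cfg[[blk]]))
      if (length(badk) > 0L)
        stop("read_run_config: unknown key(s) in '", blk, "': ",
             paste(badk, collapse = ", "))
      cfg[[blk]][names(user[[blk]])] <- user[[blk]]
    }
  }
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @export
default_config <- function() {
  list(
    geometry = list(fu_per_degree = 54.05, window_fu = c(1600, 900),
                    fps = 30),
    detection = list(eps = "faze", temporal_window = 6, min_size = 2,
                     k = 2, min_segment = 3, penalty_beta = 3,
                     peak_window = 6, peak_mad_k = 3, agglom_threshold = 25),
    measures = list(grid = c(4, 4), entropy_bins = c(4, 4), settle_ms = 400),
    simulation = list(noise = "faze", seed = 1, trials = 1)
  )
}

config_geom <- function(cfg) {
  screen_geometry(cfg$geometry$fu_per_degree,
                  unlist(cfg$geometry$window_fu), cfg$geometry$fps)
}
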