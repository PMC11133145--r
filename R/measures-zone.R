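#' Zone grids over the stimulus window
#'
#' A `W x H` zone grid divides the window into `W` equal divisions across
#' its width and `H` across its height. Zone ids are numbered row-major:
#' left to right, top to bottom, 1-based (zone 1 is top-left). The study's
#' main grid is 4 x 4 (cells 7.4 x 4.16 deg); coarser 2 x 2, 2 x 1 and
#' 1 x 2 grids are used to quantify the gain from larger zones.
#'
#' @param w,h Number of divisions across width and height (>= 1).
#' @return An object of class `zone_grid` with fields `w`, `h`.
#' @export
zone_grid <- function(w = 4, h = 4) {
  stopifnot(w >= 1, h >= 1)
  structure(list(w = as.integer(w), h = as.integer(h)), class = "zone_grid")
}

#' @rdname zone_grid
#' @param grid A `zone_grid`.
#' @param geom A [screen_geometry()].
#' @return `zone_centers`: data.frame of zone centers (`zone`, `x_deg`,
#'   `y_deg`, centered frame).
#' @export
zone_centers <- function(grid, geom = screen_geometry()) {
  wd <- geom$window_deg
  cw <- wd[1] / grid$w; ch <- wd[2] / grid$h
  rowcol <- expand.grid(col = seq_len(grid$w), row = seq_len(grid$h))
  data.frame(zone = seq_len(grid$w * grid$h),
             x_deg = -wd[1] / 2 + (rowcol$col - 0.5) * cw,
             y_deg = wd[2] / 2 - (rowcol$row - 0.5) * ch)
}

#' Classify a gaze point to a zone
#'
#' Cells are half-open with left/top edges inclusive, so a point exactly on
#' a vertical boundary belongs to the right cell and one on a horizontal
#' boundary to the lower cell. Points outside the window clamp to the
#' nearest edge cell.
#'
#' @param x,y Point coordinates, centered degrees (y up); vectors allowed.
#' @param grid A [zone_grid()].
#' @param geom A [screen_geometry()].
#' @return Integer zone id(s), row-major 1-based.
#' @export
classify_zone <- function(x, y, grid = zone_grid(4, 4),
                          geom = screen_geometry()) {
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("classify_zone: non-finite point")
  wd <- geom$window_deg
  # column index from left edge; row index from top edge (screen y down)
  col <- floor((x + wd[1] / 2) / (wd[1] / grid$w)) + 1
  row <- floor((wd[2] / 2 - y) / (wd[2] / grid$h)) + 1
  # y exactly on a horizontal boundary: top edge inclusive -> lower cell.
  # floor() on (top - y) already assigns boundary y to the cell below it.
  col <- pmin(pmax(col, 1), grid$w)
  row <- pmin(pmax(row, 1), grid$h)
  as.integer((row - 1) * grid$w + col)
}

#' Zone-classification measures for one or more trials
#'
#' For each 1500 ms zone presentation, the valid gaze samples are reduced to
#' their coordinate-wise median and classified to a zone; accuracy is the
#' fraction of presentations whose predicted zone equals the presented zone,
#' precision per zone is the ratio of correct identifications among all
#' presentations predicted as that zone, and the confusion matrix
#' (presented x predicted) is accumulated over trials.
#'
#' @param trials A list of `list(trace =, spec =)` pairs (one per trial), as
#'   returned by [simulate_gaze_trace()] together with its spec, or a single
#'   such pair.
#' @param grid A [zone_grid()] (default the 4 x 4 study grid).
#' @param geom A [screen_geometry()].
#' @return An object of class `zone_classification`: list with `pairs`
#'   (data.frame `presented`, `predicted`, `x_deg`, `y_deg`), `confusion`
#'   (matrix), `accuracy`, `precision` (per predicted zone), `n_scored`.
#' @export
zone_classification <- function(trials, grid = zone_grid(4, 4),
                                geom = screen_geometry()) {
  if (!is.null(trials$trace)) trials <- list(trials)
  pairs <- do.call(rbind, lapply(trials, function(tr) {
    spec <- tr$spec
    stopifnot(inherits(spec, "zone_trial_spec"))
    d <- trace_deg(tr$trace, geom)
    sched <- spec$schedule
    do.call(rbind, lapply(seq_len(nrow(sched)), function(i) {
      f0 <- timestamps_to_frames(sched$onset_s[i], tr$trace$fps)
      f1 <- timestamps_to_frames(sched$offset_s[i], tr$trace$fps) - 1L
      w <- d[d$frame >= f0 & d$frame <= f1 & d$valid, , drop = FALSE]
      est <- fixation_estimate(w$x_deg, w$y_deg)
      if (!is.finite(est[["x"]])) return(NULL)  # no valid samples: unscored
      data.frame(presented = sched$zone[i],
                 predicted = classify_zone(est[["x"]], est[["y"]], grid, geom),
                 x_deg = est[["x"]], y_deg = est[["y"]])
    }))
  }))
  zone_classification_from_pairs(pairs, grid)
}

#' @rdname zone_classification
#' @param pairs Data.frame with integer columns `presented`, `predicted`.
#' @export
zone_classification_from_pairs <- function(pairs, grid = zone_grid(4, 4)) {
  nz <- grid$w * grid$h
  conf <- matrix(0L, nz, nz,
                 dimnames = list(presented = seq_len(nz),
                                 predicted = seq_len(nz)))
  for (i in seq_len(nrow(pairs)))
    conf[pairs$presented[i], pairs$predicted[i]] <-
      conf[pairs$presented[i], pairs$predicted[i]] + 1L
  correct <- sum(diag(conf))
  pred_tot <- colSums(conf)
  precision <- ifelse(pred_tot > 0, diag(conf) / pred_tot, NA_real_)
  structure(list(pairs = pairs, confusion = conf,
                 accuracy = correct / max(sum(conf), 1L),
                 precision = precision, n_scored = sum(conf)),
            class = "zone_classification")
}

#' @export
print.zone_classification <- function(x, ...) {
  cat(sprintf("Zone classification: %d scored presentations, accuracy %.3f, mean precision %.3f\n",
              x$n_scored, x$accuracy, mean(x$precision, na.rm = TRUE)))
  invisible(x)
}

#' Coarsen 4 x 4 zone labels onto a nested grid
#'
#' Maps presented/predicted zone labels from a source grid onto a coarser
#' target grid whose cells are unions of source cells (e.g. 4 x 4 onto
#' 2 x 2, 2 x 1 or 1 x 2), by spatial containment, and recomputes the
#' classification. Coarsening can only merge errors into correct
#' classifications, so accuracy is monotone nondecreasing.
#'
#' @param pairs Data.frame with columns `presented`, `predicted` labeled on
#'   `from`.
#' @param from,to Source and target [zone_grid()]s; `to` divisions must
#'   divide `from` divisions.
#' @return A `zone_classification` on the target grid.
#' @export
coarsen_zone_labels <- function(pairs, from = zone_grid(4, 4), to) {
  if (from$w %% to$w != 0 || from$h %% to$h != 0)
    stop("coarsen_zone_labels: target grid is not nested in source grid")
  relabel <- function(z) {
    row <- (z - 1L) %/% from$w + 1L
    col <- (z - 1L) %% from$w + 1L
    row2 <- ceiling(row * to$h / from$h)
    col2 <- ceiling(col * to$w / from$w)
    as.integer((row2 - 1L) * to$w + col2)
  }
  zone_classification_from_pairs(
    data.frame(presented = relabel(pairs$presented),
               predicted = relabel(pairs$predicted)), to)
}
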