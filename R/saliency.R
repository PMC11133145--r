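#' Saliency maps over the stimulus window
#'
#' A saliency map is a nonnegative 2-D density sampled on a regular grid
#' over the stimulus window at a fixed cell scale (default 0.25 deg/cell,
#' four cells per 1-deg Gaussian sigma). Rows run top to bottom, columns
#' left to right (screen convention); cell centers carry the density.
#'
#' @param values Numeric matrix (rows x cols), all `>= 0` for raw maps.
#' @param cell_deg Cell edge length in degrees.
#' @param geom A [screen_geometry()].
#' @param normalization One of `"raw"`, `"sum1"`, `"znorm"`.
#' @return An object of class `saliency_map`.
#' @export
saliency_map <- function(values, cell_deg = 0.25, geom = screen_geometry(),
                         normalization = "raw") {
  stopifnot(is.matrix(values))
  if (normalization != "znorm" && any(values < -1e-12))
    stop("saliency_map: negative values in a raw/sum1 map")
  structure(list(values = values, cell_deg = cell_deg, geom = geom,
                 normalization = normalization),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("Saliency map: %d x %d cells @ %.3g deg/cell (%s)\n",
              nrow(x$values), ncol(x$values), x$cell_deg, x$normalization))
  invisible(x)
}

# cell-center coordinate axes of a map grid, centered degrees
map_axes <- function(cell_deg, geom) {
  wd <- geom$window_deg
  nc <- max(1L, round(wd[1] / cell_deg))
  nr <- max(1L, round(wd[2] / cell_deg))
  list(x = -wd[1] / 2 + (seq_len(nc) - 0.5) * wd[1] / nc,
       y = wd[2] / 2 - (seq_len(nr) - 0.5) * wd[2] / nr,
       nr = nr, nc = nc)
}

#' Continuous gaze heatmap from fixation centroids
#'
#' Convolves an isotropic Gaussian across fixations: the map is the sum of
#' Gaussians (unit mass each, in cell units) centered at the fixation
#' centroids, sampled at cell centers. Sigma defaults to 1 degree, the
#' approximate size of the fovea. Mass falling outside the window is
#' truncated, so boundary fixations contribute slightly less than interior
#' ones.
#'
#' @param fixations Data.frame with `x_deg`, `y_deg` (centered degrees),
#'   e.g. from [detect_fixation_clusters()]. Empty input gives a zero map.
#' @param geom A [screen_geometry()].
#' @param sigma Gaussian sigma in degrees (default 1).
#' @param cell_deg Grid resolution in degrees per cell (default 0.25).
#' @return A `"raw"` [saliency_map()].
#' @export
heatmap_from_fixations <- function(fixations, geom = screen_geometry(),
                                   sigma = 1, cell_deg = 0.25) {
  stopifnot(sigma > 0)
  ax <- map_axes(cell_deg, geom)
  m <- matrix(0, ax$nr, ax$nc)
  for (i in seq_len(nrow(fixations))) {
    gx <- stats::dnorm(ax$x, fixations$x_deg[i], sigma)
    gy <- stats::dnorm(ax$y, fixations$y_deg[i], sigma)
    m <- m + outer(gy, gx) * cell_deg^2
  }
  saliency_map(m, cell_deg, geom)
}

#' Ground-truth saliency map of a synthetic free-viewing trial
#'
#' Samples the trial's Gaussian-hotspot mixture density on the map grid and
#' normalizes it to sum 1.
#'
#' @param spec A `"freeview"` [make_trial()] spec.
#' @param geom A [screen_geometry()].
#' @param cell_deg Grid resolution (degrees per cell).
#' @return A `"sum1"` [saliency_map()].
#' @export
mixture_map <- function(spec, geom = screen_geometry(), cell_deg = 0.25) {
  stopifnot(inherits(spec, "freeview_trial_spec"))
  ax <- map_axes(cell_deg, geom)
  m <- matrix(0, ax$nr, ax$nc)
  hs <- spec$hotspots
  for (i in seq_len(nrow(hs))) {
    gx <- stats::dnorm(ax$x, hs$x_deg[i], hs$sd_deg[i])
    gy <- stats::dnorm(ax$y, hs$y_deg[i], hs$sd_deg[i])
    m <- m + hs$weight[i] * outer(gy, gx)
  }
  saliency_map(m / sum(m), cell_deg, geom, normalization = "sum1")
}

#' Saliency comparison indices: AUC, CC, SIM
#'
#' Three standard agreement measures between a saliency map and reference
#' fixations or a reference map:
#'
#' * `auc_score` — fixation-thresholded ROC area (Judd variant): thresholds
#'   sweep the map values at the test fixations; at each, TPR is the
#'   fraction of fixations with map value >= threshold and FPR the fraction
#'   of all cells >= threshold; trapezoidal area, ties averaged. A constant
#'   map scores 0.5.
#' * `cc_score` — Pearson correlation between the two maps over cells.
#' * `sim_score` — histogram intersection: both maps normalized to sum 1,
#'   then the sum of cellwise minima; 1 for identical maps, 0 for disjoint
#'   support.
#'
#' @param map,mapA,mapB [saliency_map()]s (same grid for pairwise scores).
#' @param fixations Data.frame with `x_deg`, `y_deg` of test fixations
#'   (centered degrees), at least one row.
#' @return A scalar score.
#' @export
auc_score <- function(map, fixations) {
  if (nrow(fixations) == 0L) stop("auc_score: no test fixations")
  wd <- map$geom$window_deg
  nr <- nrow(map$values); nc <- ncol(map$values)
  ci <- pmin(pmax(floor((fixations$x_deg + wd[1] / 2) / (wd[1] / nc)) + 1, 1),
             nc)
  ri <- pmin(pmax(floor((wd[2] / 2 - fixations$y_deg) / (wd[2] / nr)) + 1, 1),
             nr)
  fv <- map$values[cbind(ri, ci)]
  allv <- as.vector(map$values)
  thr <- sort(unique(fv))
  tpr <- vapply(thr, function(h) mean(fv >= h), 0)
  fpr <- vapply(thr, function(h) mean(allv >= h), 0)
  tpr <- c(1, tpr, 0); fpr <- c(1, fpr, 0)
  ord <- order(fpr, tpr)
  sum(diff(fpr[ord]) * (utils::head(tpr[ord], -1) + utils::tail(tpr[ord], -1)) / 2)
}

#' @rdname auc_score
#' @export
cc_score <- function(mapA, mapB) {
  a <- as.vector(mapA$values); b <- as.vector(mapB$values)
  stopifnot(length(a) == length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("cc_score: correlation undefined for a constant map")
  stats::cor(a, b)
}

#' @rdname auc_score
#' @export
sim_score <- function(mapA, mapB) {
  a <- as.vector(mapA$values); b <- as.vector(mapB$values)
  stopifnot(length(a) == length(b))
  if (sum(a) <= 0 || sum(b) <= 0) stop("sim_score: zero-mass map")
  sum(pmin(a / sum(a), b / sum(b)))
}

#' Scanpath from ordered fixation clusters
#'
#' @param clusters Temporally ordered clusters from
#'   [detect_fixation_clusters()].
#' @return An object of class `scanpath`: the cluster centroids in order,
#'   with `path_length_deg`, the summed consecutive centroid distance.
#' @export
scanpath <- function(clusters) {
  n <- nrow(clusters)
  len <- if (n >= 2L)
    sum(sqrt(diff(clusters$x_deg)^2 + diff(clusters$y_deg)^2)) else 0
  structure(list(fixations = clusters[, c("x_deg", "y_deg", "start_frame")],
                 path_length_deg = len),
            class = "scanpath")
}

#' @export
print.scanpath <- function(x, ...) {
  cat(sprintf("Scanpath: %d fixations, path length %.2f deg\n",
              nrow(x$fixations), x$path_length_deg))
  invisible(x)
}
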