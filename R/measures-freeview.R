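#' Free-viewing fixation count and gaze entropy
#'
#' The first fixation cluster of each trial is discarded to reduce the
#' effect of the initial center fixation; the fixation count is the number
#' of remaining clusters. Gaze entropy is the Shannon entropy of the
#' retained fixation counts over a spatial bin grid (default the 4 x 4 zone
#' grid), normalized by `log(#bins)` so it lies in [0, 1]: 0 when all
#' fixations share one bin, 1 when they are exactly uniform over bins.
#'
#' @param clusters Fixation clusters from [detect_fixation_clusters()]
#'   (temporally ordered).
#' @param bins A [zone_grid()] used as the entropy binning.
#' @param geom A [screen_geometry()].
#' @param discard_first Discard the initial center fixation (default TRUE).
#' @return A list: `n_fixations`, `entropy` (`NA` if no retained fixation).
#' @export
freeview_stats <- function(clusters, bins = zone_grid(4, 4),
                           geom = screen_geometry(), discard_first = TRUE) {
  if (discard_first && nrow(clusters) > 0L)
    clusters <- clusters[-1L, , drop = FALSE]
  n <- nrow(clusters)
  if (n == 0L) return(list(n_fixations = 0L, entropy = NA_real_))
  z <- classify_zone(clusters$x_deg, clusters$y_deg, bins, geom)
  p <- tabulate(z, nbins = bins$w * bins$h)
  p <- p[p > 0] / n
  h <- -sum(p * log(p)) / log(bins$w * bins$h)
  list(n_fixations = n, entropy = h)
}
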