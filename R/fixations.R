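#' Spatio-temporal density clustering of fixations
#'
#' Fixation detection for low-sample-rate gaze data, where velocity and
#' acceleration thresholds are unreliable: two valid samples are neighbors
#' iff their spatial distance is at most `eps` *and* their frame gap is at
#' most `temporal_window` frames; fixation clusters are the connected
#' components of this neighbor graph with at least `min_size` members, each
#' summarized by its centroid.
#'
#' The spatial threshold defaults to half the measured sample-to-sample RMS
#' precision of the gaze model: 1.13 deg (MPIIGaze), 0.89 deg (ETHXGaze),
#' 0.26 deg (FAZE). The temporal threshold of 6 samples is ~200 ms at 30 Hz.
#'
#' @param trace A [gaze_trace()], or a data.frame with columns `frame`,
#'   `x_deg`, `y_deg`, `valid` (as from [trace_deg()]).
#' @param eps Spatial neighborhood radius in degrees (> 0), or a gaze model
#'   preset name (`"mpiigaze"`, `"ethxgaze"`, `"faze"`).
#' @param temporal_window Maximum frame gap between neighbors (default 6).
#' @param min_size Minimum cluster size in samples (default 2).
#' @param geom A [screen_geometry()] (used only when `trace` is a
#'   `gaze_trace` in FU).
#' @return A data.frame of clusters in temporal order, one row each:
#'   `cluster`, `x_deg`, `y_deg` (centroid), `start_frame`, `end_frame`,
#'   `n`. Zero rows if no cluster qualifies.
#' @export
detect_fixation_clusters <- function(trace, eps = "faze",
                                     temporal_window = 6, min_size = 2,
                                     geom = screen_geometry()) {
  if (is.character(eps)) {
    eps <- c(mpiigaze = 1.13, ethxgaze = 0.89, faze = 0.26)[[tolower(eps)]]
    if (is.null(eps)) stop("unknown eps preset")
  }
  stopifnot(eps > 0, temporal_window >= 1, min_size >= 1)
  d <- if (inherits(trace, "gaze_trace")) trace_deg(trace, geom) else trace
  d <- d[d$valid & is.finite(d$x_deg) & is.finite(d$y_deg), , drop = FALSE]
  n <- nrow(d)
  empty <- data.frame(cluster = integer(0), x_deg = numeric(0),
                      y_deg = numeric(0), start_frame = integer(0),
                      end_frame = integer(0), n = integer(0))
  if (n == 0L) return(empty)
  # union-find over samples; only pairs within the temporal window can link
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  eps2 <- eps^2
  for (i in seq_len(n)) {
    j <- i + 1L
    while (j <= n && d$frame[j] - d$frame[i] <= temporal_window) {
      if ((d$x_deg[i] - d$x_deg[j])^2 + (d$y_deg[i] - d$y_deg[j])^2 <= eps2) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
      j <- j + 1L
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  keep <- split(seq_len(n), comp)
  keep <- keep[lengths(keep) >= min_size]
  if (length(keep) == 0L) return(empty)
  out <- do.call(rbind, lapply(keep, function(idx) {
    data.frame(x_deg = mean(d$x_deg[idx]), y_deg = mean(d$y_deg[idx]),
               start_frame = min(d$frame[idx]), end_frame = max(d$frame[idx]),
               n = length(idx))
  }))
  out <- out[order(out$start_frame), , drop = FALSE]
  out <- cbind(cluster = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
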