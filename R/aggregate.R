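#' Hierarchical winsorized aggregation of task measures
#'
#' Task measures are aggregated with the 20% winsorized mean applied level
#' by level in a stated order — e.g. first over the 13 target locations
#' within a trial, then over the trials within a participant, then over
#' participants. Each step collapses one grouping level; intermediate
#' tables are returned for inspection. Empty groups propagate a missing
#' marker and are excluded at the next level.
#'
#' @param table Data.frame of tidy measures containing `value` plus the
#'   grouping columns.
#' @param levels Character vector of grouping columns in collapse order
#'   (innermost first), e.g. `c("location", "trial", "participant")`.
#' @param value Name of the value column (default `"value"`).
#' @param by Extra grouping columns never collapsed (e.g. `model`, `task`).
#' @return A list: `result` (data.frame keyed by `by`, or a single number
#'   when `by` is empty), `intermediate` (list of the table after each
#'   collapse).
#' @examples
#' tb <- expand.grid(location = 1:3, trial = 1:2, participant = 1:4)
#' tb$value <- rnorm(nrow(tb))
#' aggregate_hierarchical(tb, c("location", "trial", "participant"))$result
#' @export
aggregate_hierarchical <- function(table, levels, value = "value",
                                   by = character(0)) {
  stopifnot(all(c(levels, by, value) %in% names(table)))
  steps <- list()
  cur <- table
  for (i in seq_along(levels)) {
    keys <- c(by, levels[-seq_len(i)])
    cur <- cur[is.finite(cur[[value]]), , drop = FALSE]
    if (length(keys) == 0L) {
      cur <- data.frame(value = winsorized_mean(cur[[value]]))
      names(cur) <- value
    } else {
      cur <- stats::aggregate(cur[[value]], by = cur[keys],
                              FUN = winsorized_mean)
      names(cur)[ncol(cur)] <- value
    }
    steps[[levels[i]]] <- cur
  }
  list(result = if (length(by) == 0L) cur[[value]][1L] else cur,
       intermediate = steps)
}

#' Cross-task score transformation for model comparison
#'
#' Puts the per-participant task scores on a common footing before model
#' comparison: fixation accuracy and pursuit angular deviation are
#' log-transformed (approximate normality), classification accuracy and AUC
#' are inverted as `1 - value` so that, like the other scores, lower is
#' better; every task's column is then z-scored over participants
#' (zero-variance columns z-score to 0).
#'
#' @param scores Data.frame with columns `participant`, `task`, `value`;
#'   one row per participant and task.
#' @param log_tasks Tasks to log-transform (must be strictly positive).
#' @param invert_tasks Tasks in [0, 1] to invert as `1 - value`.
#' @return The input with added columns `transformed` and `z` (mean 0, SD 1
#'   within task).
#' @export
transform_scores <- function(scores,
                             log_tasks = c("fixation_accuracy",
                                           "angular_deviation"),
                             invert_tasks = c("zone_accuracy", "auc")) {
  stopifnot(all(c("participant", "task", "value") %in% names(scores)))
  out <- scores
  out$transformed <- out$value
  for (tk in log_tasks) {
    i <- out$task == tk
    if (any(i & out$value <= 0))
      stop("transform_scores: nonpositive values before log in task '", tk,
           "' (participants: ",
           paste(out$participant[i & out$value <= 0], collapse = ", "), ")")
    out$transformed[i] <- log(out$value[i])
  }
  for (tk in invert_tasks) {
    i <- out$task == tk
    if (any(i & (out$value < 0 | out$value > 1)))
      stop("transform_scores: values outside [0, 1] in inverted task '", tk, "'")
    out$transformed[i] <- 1 - out$value[i]
  }
  out$z <- NA_real_
  for (tk in unique(out$task)) {
    i <- out$task == tk
    v <- out$transformed[i]
    s <- stats::sd(v)
    out$z[i] <- if (!is.finite(s) || s == 0) 0 else (v - mean(v)) / s
  }
  out
}
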