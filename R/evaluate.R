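#' Match detected events to ground-truth movements
#'
#' An event is attributed to a movement when its time falls inside the
#' movement's window `[onset, offset + window_extend]`.  Events outside
#' every window are spurious.
#'
#' @param events events `data.frame` from [hand_count()].
#' @param truth ground-truth `data.frame` from [simulate_protocol()].
#' @param window_extend seconds appended after each movement's offset.
#' @return integer vector, per movement, of the number of attributed
#'   events.
#' @export
match_events <- function(events, truth, window_extend = 0.5) {
  m <- nrow(truth)
  counts <- integer(m)
  if (is.null(events) || nrow(events) == 0 || m == 0) return(counts)
  ord <- order(truth$onset_s)
  onset <- truth$onset_s[ord]
  offset <- truth$offset_s[ord] + window_extend
  idx <- findInterval(events$t, onset)
  ok <- idx >= 1 & events$t <= offset[pmax(idx, 1)]
  tab <- table(idx[ok])
  counts[ord[as.integer(names(tab))]] <- as.integer(tab)
  counts
}

#' Counting probability against ground truth
#'
#' For each group of movements, the probability of counting is the
#' fraction of movements with at least one attributed event; the raw
#' event-to-movement ratio (which can exceed 1 when a long movement is
#' counted more than once after the 2 s reset) is reported alongside.
#'
#' @inheritParams match_events
#' @param by character vector of `truth` columns to group by; `NULL` for a
#'   single overall row.  Groups with no movements are simply absent from
#'   the result (a probability there is undefined, not zero).
#' @return `data.frame` with the grouping columns plus `n_movements`,
#'   `n_detected`, `n_events`, `probability`, `ratio`.
#' @export
#' @examples
#' truth <- data.frame(idx = 1:2, onset_s = c(1, 5), offset_s = c(2, 6),
#'                     kind = "wrist_flexext", amplitude_deg = 45,
#'                     peak_speed_dps = 150, speed_class = "slow")
#' events <- data.frame(t = 1.5)
#' counting_probability(events, truth)$probability   # 0.5
counting_probability <- function(events, truth,
                                 by = c("amplitude_deg", "speed_class"),
                                 window_extend = 0.5) {
  stopifnot(is.data.frame(truth), nrow(truth) > 0)
  matched <- match_events(events, truth, window_extend)
  df <- truth
  df$.matched <- matched
  if (is.null(by) || length(by) == 0) {
    groups <- list(all = rep("all", nrow(df)))
    by <- character(0)
  } else {
    stopifnot(all(by %in% names(truth)))
    groups <- lapply(by, function(col) df[[col]])
    names(groups) <- by
  }
  agg <- stats::aggregate(
    df$.matched,
    by = groups,
    FUN = function(x) c(
      n_movements = length(x),
      n_detected = sum(x >= 1),
      n_events = sum(x)
    )
  )
  stats_mat <- agg$x
  out <- agg[, setdiff(names(agg), "x"), drop = FALSE]
  out$n_movements <- as.integer(stats_mat[, "n_movements"])
  out$n_detected <- as.integer(stats_mat[, "n_detected"])
  out$n_events <- as.integer(stats_mat[, "n_events"])
  out$probability <- out$n_detected / out$n_movements
  out$ratio <- out$n_events / out$n_movements
  if (length(by) > 0) {
    out <- out[do.call(order, out[by]), , drop = FALSE]
  } else {
    out$all <- NULL
  }
  rownames(out) <- NULL
  out
}

#' Overall counting accuracy
#'
#' Total movements detected over total movements known, as a percentage.
#'
#' @inheritParams match_events
#' @return scalar percentage in \[0, 100\].
#' @export
overall_accuracy <- function(events, truth, window_extend = 0.5) {
  matched <- match_events(events, truth, window_extend)
  100 * sum(matched >= 1) / nrow(truth)
}
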