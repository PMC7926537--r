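#' Explore HAND parameter combinations on labelled exercise logs
#'
#' Reproduces the parameter-grid exploration: for every parameter
#' combination the counter is recalibrated (the run-length SD depends on
#' the filter and threshold) on movement-free data and applied to hand
#' exercise logs with a known movement count and to arm-only logs where
#' any count is a false positive.
#'
#' `hand_error` is the absolute counting error as a percentage of the true
#' count, averaged over hand logs; `arm_error` is the number of spurious
#' counts as a percentage of the number of arm movements, averaged over
#' arm logs.
#'
#' @param hand_logs list of `list(d = <differential data.frame>,
#'   expected = <true movement count>)`.
#' @param arm_logs list of `list(d = <differential data.frame>,
#'   n_movements = <arm movements performed>)`; these logs contain no hand
#'   movement and double as the calibration data.
#' @param grid `data.frame` of parameter combinations with columns
#'   `lp_cutoff` (NA for no filtering), `threshold`, and optionally
#'   `sds_two_axes` and `extra_samples_one_axis` (defaults 5 and 2).
#' @param fs sampling rate, Hz.
#' @param min_runs passed to [calibrate()].
#' @return the grid with `sigma`, `hand_error` and `arm_error` columns
#'   appended (percent).
#' @export
parameter_sweep <- function(hand_logs, arm_logs, grid, fs = default_fs,
                            min_runs = 100) {
  if (!is.data.frame(grid) || nrow(grid) == 0) {
    stop("parameter grid must be a non-empty data.frame")
  }
  stopifnot(all(c("lp_cutoff", "threshold") %in% names(grid)),
            length(hand_logs) > 0, length(arm_logs) > 0)
  if (!"sds_two_axes" %in% names(grid)) grid$sds_two_axes <- 5L
  if (!"extra_samples_one_axis" %in% names(grid)) {
    grid$extra_samples_one_axis <- 2L
  }
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    params <- hand_count_params(
      lp_cutoff = if (is.na(g$lp_cutoff)) NULL else g$lp_cutoff,
      threshold = g$threshold,
      sds_two_axes = g$sds_two_axes,
      extra_samples_one_axis = g$extra_samples_one_axis,
      fs = fs
    )
    calib <- tryCatch(
      calibrate(arm_logs[[1]]$d, params, min_runs = min_runs),
      error = function(e) NULL
    )
    if (is.null(calib)) {
      # this filter/threshold combination leaves too few supra-threshold
      # runs at rest to estimate sigma; report it as uncalibratable
      return(c(sigma = NA_real_, hand_error = NA_real_,
               arm_error = NA_real_))
    }
    hand_err <- vapply(hand_logs, function(lg) {
      counted <- hand_count(lg$d, params, calib)$count
      abs(counted - lg$expected) / lg$expected * 100
    }, numeric(1))
    arm_err <- vapply(arm_logs, function(lg) {
      counted <- hand_count(lg$d, params, calib)$count
      counted / lg$n_movements * 100
    }, numeric(1))
    c(sigma = calib$sigma,
      hand_error = mean(hand_err),
      arm_error = mean(arm_err))
  })
  cbind(grid, do.call(rbind, res))
}

#' Hand-use intensity
#'
#' Normalises a movement count by wear time, as counts per hour or per
#' minute.
#'
#' @param events events `data.frame` from [hand_count()] (or an integer
#'   count).
#' @param wear_duration wear time, in hours (for `unit = "hour"`) or
#'   minutes (for `unit = "minute"`).
#' @param unit `"hour"` or `"minute"`.
#' @return counts per unit time.
#' @export
#' @examples
#' intensity(1000L, 1)                 # 1000 counts/hour
#' intensity(50L, 1, unit = "minute")  # 50 counts/minute
intensity <- function(events, wear_duration, unit = c("hour", "minute")) {
  unit <- match.arg(unit)
  if (!is.numeric(wear_duration) || wear_duration <= 0) {
    stop("wear_duration must be positive")
  }
  count <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  count / wear_duration
}
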