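#' Parameters of the wrist-accelerometry activity counter
#'
#' Conventional upper-extremity activity counting used as the comparison
#' metric: the sum of absolute sample-to-sample acceleration changes over a
#' running 0.25 s window (about 13 samples at 52.6 Hz), peak-detected with
#' a 0.33 g threshold and capped at 4 peaks per second.
#'
#' @param window running-window length, seconds.
#' @param peak_threshold peak detection threshold on the running sum, g.
#' @param max_peaks_per_second cap on accepted peaks in any trailing 1 s.
#' @param fs sampling rate, Hz.
#' @param mode `"per_axis"` sums the absolute per-axis differences (the
#'   convention of the activity-counts literature); `"magnitude"` uses the
#'   Euclidean norm of the 3-axis difference vector instead.
#' @return an `activity_params` object.
#' @export
activity_params <- function(window = 0.25, peak_threshold = 0.33,
                            max_peaks_per_second = 4, fs = default_fs,
                            mode = c("per_axis", "magnitude")) {
  mode <- match.arg(mode)
  stopifnot(window > 0, peak_threshold > 0, max_peaks_per_second >= 1,
            fs > 0)
  structure(
    list(
      window = window,
      peak_threshold = peak_threshold,
      max_peaks_per_second = as.integer(max_peaks_per_second),
      fs = fs,
      mode = mode,
      window_samples = as.integer(round(window * fs))
    ),
    class = "activity_params"
  )
}

accel_matrix <- function(accel) {
  stopifnot(all(c("ax", "ay", "az") %in% names(accel)))
  as.matrix(accel[, c("ax", "ay", "az"), drop = FALSE])
}

#' Running activity signal from wrist acceleration
#'
#' `s[k]` is the sum, over the `w = round(window * fs)` most recent
#' sample-to-sample steps, of the absolute acceleration change (summed over
#' the three axes).  The window is trailing (causal).  A constant
#' acceleration offset, such as gravity, cancels because only differences
#' enter.
#'
#' @param accel `data.frame` with columns `t`, `ax`, `ay`, `az` (g), e.g. a
#'   sensor log.
#' @param params an [activity_params()].
#' @return `data.frame` with columns `t` and `activity` (g); one row per
#'   sample from the `w + 1`-th on.  Fewer samples than the window yields
#'   an empty result with a warning.
#' @export
activity_signal <- function(accel, params = activity_params()) {
  stopifnot(inherits(params, "activity_params"))
  a <- accel_matrix(accel)
  w <- params$window_samples
  n <- nrow(a)
  if (n < w + 1) {
    warning(sprintf("log has %d samples, shorter than the %d-sample window",
                    n, w))
    return(data.frame(t = numeric(0), activity = numeric(0)))
  }
  da <- abs(diff(a))
  step <- switch(params$mode,
    per_axis = rowSums(da),
    magnitude = sqrt(rowSums(diff(a)^2))
  )
  cs <- cumsum(c(0, step))
  s <- cs[(w + 1):length(cs)] - cs[seq_len(length(cs) - w)]
  data.frame(t = accel$t[(w + 1):n], activity = s)
}

#' Wrist-accelerometry activity count
#'
#' Detects peaks of the running activity signal above the threshold.  A
#' peak is a strict local maximum (plateaus count once, at their first
#' sample).  Detection is limited to `max_peaks_per_second`: a peak is
#' rejected if that many peaks were already accepted within the trailing
#' second.
#'
#' @inheritParams activity_signal
#' @return list with `count`, `peak_times` (seconds) and the `signal`
#'   `data.frame` from [activity_signal()].
#' @export
activity_count <- function(accel, params = activity_params()) {
  sig <- activity_signal(accel, params)
  s <- sig$activity
  tt <- sig$t
  n <- length(s)
  peak_times <- numeric(0)
  if (n >= 3) {
    thr <- params$peak_threshold
    cap <- params$max_peaks_per_second
    for (k in 2:(n - 1)) {
      if (s[k] > thr && s[k] > s[k - 1] && s[k] >= s[k + 1]) {
        recent <- sum(peak_times > tt[k] - 1)
        if (recent < cap) {
          peak_times <- c(peak_times, tt[k])
        }
      }
    }
  }
  list(count = length(peak_times), peak_times = peak_times, signal = sig)
}
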