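#' Parameters of the HAND counting algorithm
#'
#' The algorithm has four tunable parameters: the low-pass cutoff applied
#' to the differential reading, the minimum absolute per-sample change for
#' a sample to count toward a run (`threshold`, in raw LSB; one LSB is
#' about 0.122 milligauss), the integer scale factor applied to the
#' calibrated run-length standard deviation to obtain the two-axis run
#' requirement (`sds_two_axes`), and the number of additional same-direction
#' samples demanded when only a single axis is moving
#' (`extra_samples_one_axis`).  Defaults are the values selected by the
#' parameter exploration on in-lab exercises: 8 Hz, 8 LSB, 5 and 2.
#'
#' @param lp_cutoff low-pass cutoff, Hz; `NULL` disables filtering.
#' @param threshold minimum absolute per-sample change, LSB.
#' @param sds_two_axes positive integer scale factor on the run-length SD.
#' @param extra_samples_one_axis non-negative integer, extra samples
#'   required for the single-axis trigger.
#' @param reset_timeout seconds after a count at which suppression expires
#'   even without a direction reversal.  Fixed at 2 s on the device.
#' @param fs sampling rate, Hz.
#' @return a `hand_count_params` object (a validated list).
#' @export
#' @examples
#' hand_count_params()                      # device defaults
#' hand_count_params(lp_cutoff = NULL)      # no filtering
hand_count_params <- function(lp_cutoff = 8, threshold = 8,
                              sds_two_axes = 5, extra_samples_one_axis = 2,
                              reset_timeout = 2, fs = default_fs) {
  if (!is.null(lp_cutoff)) {
    stopifnot(is.numeric(lp_cutoff), length(lp_cutoff) == 1, lp_cutoff > 0)
    if (lp_cutoff >= fs / 2) {
      stop(sprintf("lp_cutoff (%g Hz) must be below fs/2 (%g Hz)",
                   lp_cutoff, fs / 2))
    }
  }
  stopifnot(
    is.numeric(threshold), length(threshold) == 1, threshold >= 0,
    is.numeric(sds_two_axes), length(sds_two_axes) == 1,
    sds_two_axes >= 1, sds_two_axes == as.integer(sds_two_axes),
    is.numeric(extra_samples_one_axis), length(extra_samples_one_axis) == 1,
    extra_samples_one_axis >= 0,
    extra_samples_one_axis == as.integer(extra_samples_one_axis),
    is.numeric(reset_timeout), reset_timeout > 0,
    is.numeric(fs), fs > 0
  )
  structure(
    list(
      lp_cutoff = lp_cutoff,
      threshold = threshold,
      sds_two_axes = as.integer(sds_two_axes),
      extra_samples_one_axis = as.integer(extra_samples_one_axis),
      reset_timeout = reset_timeout,
      fs = fs
    ),
    class = "hand_count_params"
  )
}

#' @export
print.hand_count_params <- function(x, ...) {
  cat("HAND algorithm parameters\n")
  cat(sprintf("  low-pass cutoff      : %s\n",
              if (is.null(x$lp_cutoff)) "none" else paste0(x$lp_cutoff, " Hz")))
  cat(sprintf("  change threshold     : %g LSB (~%.3g mG)\n",
              x$threshold, 1000 * lsb_to_gauss(x$threshold)))
  cat(sprintf("  SDs (2 axes)         : %d\n", x$sds_two_axes))
  cat(sprintf("  + samples (1 axis)   : %d\n", x$extra_samples_one_axis))
  cat(sprintf("  reset timeout        : %g s,  fs: %g Hz\n",
              x$reset_timeout, x$fs))
  invisible(x)
}

# "Rounded to the closest integer", halves away from zero (so 4 x 1.5 -> 6,
# 4 x 1.2 = 4.8 -> 5).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive run-length requirements from a measured run-length SD
#'
#' The two-axis requirement is the run-length standard deviation scaled by
#' `sds_two_axes` and rounded to the closest integer (at least 1); the
#' single-axis requirement adds `extra_samples_one_axis` more samples, a
#' deliberately more stringent criterion when only one axis is moving.
#'
#' @param sigma standard deviation (in samples) of the same-direction
#'   run-length distribution measured on movement-free data.
#' @param params a [hand_count_params()].
#' @param n_runs optional number of run observations behind `sigma`
#'   (recorded for provenance).
#' @return a `hand_calibration` object with elements `sigma`,
#'   `n_two_axes`, `n_one_axis`, `n_runs` and the parameter snapshot the
#'   calibration is valid for.
#' @export
#' @examples
#' p <- hand_count_params(sds_two_axes = 4)
#' calibration_from_sigma(1.5, p)$n_two_axes   # 6
calibration_from_sigma <- function(sigma, params = hand_count_params(),
                                   n_runs = NA_integer_) {
  stopifnot(inherits(params, "hand_count_params"),
            is.numeric(sigma), length(sigma) == 1, sigma >= 0)
  n_two <- max(1L, as.integer(round_half_away(params$sds_two_axes * sigma)))
  n_one <- n_two + params$extra_samples_one_axis
  structure(
    list(
      sigma = sigma,
      n_two_axes = n_two,
      n_one_axis = n_one,
      n_runs = n_runs,
      params = list(
        lp_cutoff = params$lp_cutoff,
        threshold = params$threshold,
        sds_two_axes = params$sds_two_axes,
        extra_samples_one_axis = params$extra_samples_one_axis,
        fs = params$fs
      )
    ),
    class = "hand_calibration"
  )
}

#' @export
print.hand_calibration <- function(x, ...) {
  cat("HAND run-length calibration\n")
  cat(sprintf("  sigma      : %.4f samples (from %s runs)\n", x$sigma,
              if (is.na(x$n_runs)) "?" else format(x$n_runs)))
  cat(sprintf("  n_two_axes : %d samples\n", x$n_two_axes))
  cat(sprintf("  n_one_axis : %d samples\n", x$n_one_axis))
  invisible(x)
}

# Signed supra-threshold change signs per axis: +1/-1 when |delta| exceeds
# the threshold, 0 otherwise (ignored samples).
supra_threshold_signs <- function(y, threshold) {
  delta <- diff(y)
  s <- sign(delta)
  s[abs(delta) <= threshold] <- 0
  s
}

# Lengths of maximal same-direction runs in a sign sequence, with
# sub-threshold samples (zeros) transparent: they neither extend nor break
# a run.
run_lengths <- function(signs) {
  s <- signs[signs != 0]
  if (length(s) == 0) return(integer(0))
  r <- rle(s)
  r$lengths
}

#' Calibrate the run-length requirements on movement-free data
#'
#' Filters a movement-free differential log (e.g. recorded while the arm
#' moves but the splinted hand does not, or while the device rests on a
#' table), applies the change threshold, pools the lengths of maximal
#' same-direction runs over the three axes, and takes their standard
#' deviation.  The run-length requirements follow from
#' [calibration_from_sigma()].  This is a device-noise calibration, not a
#' per-user one: it characterises the sensing noise floor at the chosen
#' filter and threshold.
#'
#' @param rest differential reading `data.frame` with no hand movement.
#' @param params a [hand_count_params()].
#' @param min_runs minimum number of pooled run observations required.
#' @return a `hand_calibration` object.
#' @export
calibrate <- function(rest, params = hand_count_params(), min_runs = 100) {
  stopifnot(inherits(params, "hand_count_params"))
  y <- lowpass(diff_matrix(rest), params$lp_cutoff, params$fs)
  runs <- unlist(lapply(seq_len(ncol(y)), function(j) {
    run_lengths(supra_threshold_signs(y[, j], params$threshold))
  }))
  if (length(runs) < min_runs) {
    stop(sprintf(
      paste0("insufficient calibration data: %d usable same-direction runs ",
             "(need >= %d); record a longer movement-free log or lower the ",
             "threshold"),
      length(runs), min_runs
    ))
  }
  calibration_from_sigma(stats::sd(runs), params, n_runs = length(runs))
}
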