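## Minimum-jerk profile constants: peak speed = 1.875 A / T and peak
## acceleration = (10 / sqrt(3)) A / T^2 for a stroke of amplitude A and
## duration T.
min_jerk_speed_coef <- 1.875
min_jerk_accel_coef <- 10 / sqrt(3)

min_jerk_pos <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)
min_jerk_vel <- function(tau) 30 * tau^2 * (1 - tau)^2

#' Anthropometric geometry of an emulated hand
#'
#' `dim1` is the distance from the wrist crease to the MCP (knuckle)
#' centre of rotation of the index finger; `dim2` from the wrist crease to
#' the interdigital fold where the magnetic ring sits.  The three named
#' sizes are anthropometric stand-ins spanning a 5th-percentile female
#' hand to a 95th-percentile male hand.
#'
#' @param size `"small"`, `"medium"` or `"large"`; ignored when both
#'   `dim1` and `dim2` are given.
#' @param dim1,dim2 custom dimensions, cm.
#' @return a `hand_geometry` object (dimensions in cm).
#' @export
hand_geometry <- function(size = c("medium", "small", "large"),
                          dim1 = NULL, dim2 = NULL) {
  defaults <- list(
    small  = c(dim1 = 8.0,  dim2 = 9.0),
    medium = c(dim1 = 9.3,  dim2 = 10.5),
    large  = c(dim1 = 10.5, dim2 = 12.0)
  )
  if (is.null(dim1) || is.null(dim2)) {
    size <- match.arg(size)
    d <- defaults[[size]]
    dim1 <- d[["dim1"]]
    dim2 <- d[["dim2"]]
  } else {
    size <- if (is.character(size) && length(size) == 1) size else "custom"
  }
  stopifnot(dim1 > 0, dim1 < dim2)
  structure(
    list(size_label = size, dim1 = dim1, dim2 = dim2),
    class = "hand_geometry"
  )
}

#' Classify a peak angular speed
#'
#' Slow below 200 degrees/s, medium from 200 to 400, fast above 400.
#'
#' @param peak_speed peak angular speed(s), degrees/s.
#' @return factor with levels slow, medium, fast.
#' @export
speed_class <- function(peak_speed) {
  cls <- ifelse(peak_speed < 200, "slow",
                ifelse(peak_speed <= 400, "medium", "fast"))
  factor(cls, levels = c("slow", "medium", "fast"))
}

#' One movement command for the simulator
#'
#' @param kind `"wrist_flexext"`, `"finger_flexext"`, `"arm_only"` or
#'   `"rest"`.
#' @param amplitude movement amplitude, degrees.  Hand movements must lie
#'   in \[5, 90\].
#' @param peak_speed peak angular speed, degrees/s.  Hand movements must
#'   lie in \[20, 600\].
#' @return a one-row `data.frame` with columns `kind`, `amplitude`,
#'   `peak_speed`, `speed_class`.
#' @export
movement_spec <- function(kind = c("wrist_flexext", "finger_flexext",
                                   "arm_only", "rest"),
                          amplitude = 45, peak_speed = 150) {
  kind <- match.arg(kind)
  if (kind %in% c("wrist_flexext", "finger_flexext")) {
    stopifnot(amplitude >= 5, amplitude <= 90,
              peak_speed >= 20, peak_speed <= 600)
  } else if (kind == "rest") {
    amplitude <- 0
    peak_speed <- 0
  }
  data.frame(
    kind = kind, amplitude = amplitude, peak_speed = peak_speed,
    speed_class = if (kind %in% c("wrist_flexext", "finger_flexext"))
      speed_class(peak_speed) else factor(NA, levels = levels(speed_class(1))),
    stringsAsFactors = FALSE
  )
}

#' Minimum-jerk joint-angle trajectory
#'
#' Bell-shaped velocity profile
#' `theta(tau) = A (10 tau^3 - 15 tau^4 + 6 tau^5)` over a duration
#' `T = 1.875 A / peak_speed`, so the absolute peak angular velocity
#' equals `peak_speed`.  Velocity and acceleration vanish at both ends.
#'
#' @param amplitude amplitude A, degrees.
#' @param peak_speed peak angular speed, degrees/s.
#' @param fs sampling rate, Hz.
#' @return `data.frame` with columns `t` (s) and `angle` (degrees),
#'   sampled at `fs` from 0 to T, with the exact endpoint T appended so
#'   the stroke closes at its full amplitude; duration T is attached as
#'   attribute `"duration"`.
#' @export
#' @examples
#' th <- minimum_jerk_angle(90, 600)   # 0.28125 s stroke
#' attr(th, "duration")
minimum_jerk_angle <- function(amplitude, peak_speed, fs = default_fs) {
  stopifnot(amplitude > 0, peak_speed > 0, fs > 0)
  duration <- min_jerk_speed_coef * amplitude / peak_speed
  if (duration < 3 / fs) {
    stop(sprintf(
      "movement duration %.4f s spans fewer than 3 samples at %g Hz",
      duration, fs
    ))
  }
  t <- seq(0, duration, by = 1 / fs)
  if (t[length(t)] < duration - 1e-12) t <- c(t, duration)
  out <- data.frame(t = t, angle = amplitude * min_jerk_pos(t / duration))
  attr(out, "duration") <- duration
  out
}
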