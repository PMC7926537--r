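#' manucount: magnetic counting of hand movements
#'
#' Counts hand movements from a wrist-worn 4-magnetometer array sensing a
#' finger-worn magnet ring.  The Earth's field is cancelled by a differential
#' reading across the array; movements are detected by tracking runs of
#' supra-threshold same-direction changes of the filtered differential
#' signal.  A dipole-physics simulator reproduces the robotic testbed and
#' in-lab exercise protocols used to characterise the algorithm.
#'
#' @section Units:
#' Magnetometer values are raw 16-bit LSB of a +/-4 gauss range
#' (1 LSB = 8/65536 gauss, about 0.122 milligauss); accelerometer in g;
#' gyroscope in degrees/s; time in seconds; sampling at 52.6 Hz.
#'
#' @keywords internal
"_PACKAGE"

## Nominal device constants: 52.6 Hz sampling, 16-bit +/-4 gauss magnetometers.
default_fs <- 52.6
lsb_per_gauss <- 65536 / 8

sensor_log_columns <- c(
  "t",
  "m1x", "m1y", "m1z", "m2x", "m2y", "m2z",
  "m3x", "m3y", "m3z", "m4x", "m4y", "m4z",
  "ax", "ay", "az", "gx", "gy", "gz"
)

#' Convert raw magnetometer LSB to gauss
#'
#' The magnetometers span +/-4 gauss over 16 bits, so one LSB is
#' 8/65536 gauss (about 0.122 milligauss).
#'
#' @param v numeric vector of raw LSB values.
#' @return field values in gauss.
#' @seealso [gauss_to_lsb()]
#' @export
#' @examples
#' lsb_to_gauss(8192)   # 1 gauss
lsb_to_gauss <- function(v) {
  v * (8 / 65536)
}

#' Convert gauss to raw magnetometer LSB
#'
#' Inverse of [lsb_to_gauss()].  With `quantize = TRUE` values are rounded
#' to integer LSB and clipped to the signed 16-bit range, emulating the
#' sensor's quantization.
#'
#' @param b numeric vector, gauss.
#' @param quantize round to integer LSB and clip to \[-32768, 32767\].
#' @return raw LSB values.
#' @export
gauss_to_lsb <- function(b, quantize = FALSE) {
  v <- b * lsb_per_gauss
  if (quantize) {
    v <- pmin(pmax(round(v), -32768), 32767)
  }
  v
}

#' Geometry of the wristband magnetometer array
#'
#' The four magnetometers sit on the corners of a rectangular board, 25 mm
#' apart along one side and 42 mm along the other.  Each lateral pair has a
#' "near" sensor (closer to the ring, larger x in the wristband frame) and
#' a "far" sensor.  The wristband frame has x along the forearm toward the
#' hand, y across the wrist, and z dorsal; which rectangle side lies along
#' the forearm is configurable because it is a property of how the board is
#' mounted.
#'
#' @param near_far_mm distance (mm) between the near and the far sensor of
#'   a pair, along the hand axis.  Default 25.
#' @param left_right_mm distance (mm) between the left and the right pair,
#'   across the wrist.  Default 42.
#' @param center_mm board-center position (mm) relative to the wrist crease,
#'   in the wristband frame.  Default `c(-10, 0, 10)`: 10 mm proximal and
#'   10 mm dorsal.
#' @return an `array_geometry` object: `positions` is a 4 x 3 matrix (mm),
#'   rows ordered near-left, far-left, near-right, far-right, i.e. sensors
#'   m1..m4 of the sensor log; `left_pair`/`right_pair` give (near, far)
#'   row indices.
#' @export
array_geometry <- function(near_far_mm = 25, left_right_mm = 42,
                           center_mm = c(-10, 0, 10)) {
  stopifnot(near_far_mm > 0, left_right_mm > 0, length(center_mm) == 3)
  dx <- near_far_mm / 2
  dy <- left_right_mm / 2
  positions <- rbind(
    near_left  = c(+dx, -dy, 0),
    far_left   = c(-dx, -dy, 0),
    near_right = c(+dx, +dy, 0),
    far_right  = c(-dx, +dy, 0)
  )
  positions <- sweep(positions, 2, as.numeric(center_mm), "+")
  colnames(positions) <- c("x", "y", "z")
  structure(
    list(
      positions = positions,
      left_pair = c(near = 1L, far = 2L),
      right_pair = c(near = 3L, far = 4L),
      near_far_mm = near_far_mm,
      left_right_mm = left_right_mm,
      center_mm = as.numeric(center_mm)
    ),
    class = "array_geometry"
  )
}

#' @export
print.array_geometry <- function(x, ...) {
  cat("Magnetometer array geometry (wristband frame, mm)\n")
  print(round(x$positions, 2))
  cat(sprintf(
    "near-far separation %.1f mm, left-right separation %.1f mm\n",
    x$near_far_mm, x$left_right_mm
  ))
  invisible(x)
}

mag_matrix <- function(log, sensor) {
  cols <- paste0("m", sensor, c("x", "y", "z"))
  as.matrix(log[, cols, drop = FALSE])
}

#' Differential reading of the magnetometer array
#'
#' Computes, per sample, the average of the near-minus-far magnetometer
#' difference of the left pair and of the right pair.  A spatially uniform
#' field (the Earth's) contributes identically to all four sensors and
#' cancels exactly; only the spatial gradient of the ring magnet's field
#' survives.  Averaging the two sides makes the reading identical for a
#' device worn on either hand.
#'
#' @param log a sensor log `data.frame` (see [read_sensor_log()] for the
#'   column layout) carrying columns `m1x` .. `m4z`.
#' @param geometry an [array_geometry()]; identifies which sensor indices
#'   form the near/far pairs.
#' @return `data.frame` with columns `t`, `dx`, `dy`, `dz` (signed LSB).
#' @export
compute_differential <- function(log, geometry = array_geometry()) {
  stopifnot(inherits(geometry, "array_geometry"), is.data.frame(log))
  mag_cols <- sensor_log_columns[2:13]
  missing <- setdiff(mag_cols, names(log))
  if (length(missing) > 0) {
    stop("sensor log is missing magnetometer columns: ",
         paste(missing, collapse = ", "))
  }
  bad <- which(!stats::complete.cases(log[, mag_cols, drop = FALSE]))
  if (length(bad) > 0) {
    stop(sprintf(
      "malformed magnetometer reading at frame %d%s",
      bad[1],
      if (length(bad) > 1) sprintf(" (and %d more)", length(bad) - 1L) else ""
    ))
  }
  nl <- mag_matrix(log, geometry$left_pair[["near"]])
  fl <- mag_matrix(log, geometry$left_pair[["far"]])
  nr <- mag_matrix(log, geometry$right_pair[["near"]])
  fr <- mag_matrix(log, geometry$right_pair[["far"]])
  d <- ((nl - fl) + (nr - fr)) / 2
  out <- data.frame(t = log$t, dx = d[, 1], dy = d[, 2], dz = d[, 3])
  rownames(out) <- NULL
  out
}

diff_matrix <- function(d) {
  stopifnot(all(c("dx", "dy", "dz") %in% names(d)))
  as.matrix(d[, c("dx", "dy", "dz"), drop = FALSE])
}
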