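mu0 <- 4e-7 * pi

#' Magnetic moment of a uniformly magnetised disk magnet
#'
#' `m = Br * V / mu0` for remanence `Br` and volume `V`.  Defaults are the
#' ring's N52 neodymium disk: 12.7 mm diameter, 3.18 mm thickness,
#' Br of about 1.45 T, giving roughly 0.465 A m^2.
#'
#' @param br remanence, tesla.
#' @param diameter,thickness disk dimensions, metres.
#' @return magnetic moment, A m^2.
#' @export
disk_magnet_moment <- function(br = 1.45, diameter = 12.7e-3,
                               thickness = 3.18e-3) {
  stopifnot(br > 0, diameter > 0, thickness > 0)
  volume <- pi * (diameter / 2)^2 * thickness
  br * volume / mu0
}

#' Point-dipole model of the ring magnet
#'
#' @param moment magnetic moment, A m^2.
#' @param axis unit vector of the dipole axis in the finger frame.  The
#'   default, normal to the ring band (perpendicular to the finger's long
#'   axis, dorsal at rest), reflects how a disk magnet sits in a ring.
#' @return a `magnet_model` object.
#' @export
magnet_model <- function(moment = disk_magnet_moment(), axis = c(0, 0, 1)) {
  stopifnot(moment > 0, length(axis) == 3)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(moment = moment, axis = axis), class = "magnet_model")
}

# Minimum source-sensor separation for the point-dipole approximation of
# the physical disk to be meaningful.
dipole_guard_m <- 5e-3

#' Magnetic field of a point dipole
#'
#' Exact dipole field `B(r) = (mu0 / 4 pi) (3 (m . rhat) rhat - m) / |r|^3`,
#' in gauss.  The field decays with the inverse cube of distance, which is
#' what makes the near/far differential reading sensitive to the ring but
#' blind to the (uniform) Earth field.
#'
#' @param moment scalar moment, A m^2.
#' @param axis dipole axis: a unit 3-vector, or an n x 3 matrix of per-row
#'   axes.
#' @param source_pos dipole position(s), metres: 3-vector or n x 3 matrix.
#' @param sensor_pos sensing position(s), metres: 3-vector or n x 3 matrix.
#' @return n x 3 matrix of field vectors, gauss.
#' @export
#' @examples
#' m <- disk_magnet_moment()
#' # on-axis field at 10 cm, about 0.93 gauss:
#' dipole_field(m, c(0, 0, 1), c(0, 0, 0), c(0, 0, 0.1))
dipole_field <- function(moment, axis, source_pos, sensor_pos) {
  as_mat <- function(v) {
    if (is.matrix(v)) v else matrix(v, nrow = 1)
  }
  s <- as_mat(source_pos)
  q <- as_mat(sensor_pos)
  ax <- as_mat(axis)
  n <- max(nrow(s), nrow(q), nrow(ax))
  expand <- function(m) {
    if (nrow(m) == n) m else m[rep(1, n), , drop = FALSE]
  }
  s <- expand(s); q <- expand(q); ax <- expand(ax)
  r <- q - s
  rn <- sqrt(rowSums(r^2))
  if (any(rn <= dipole_guard_m)) {
    stop(sprintf(
      "sensor within %.0f mm of the magnet (min distance %.2f mm): point-dipole model invalid",
      dipole_guard_m * 1000, min(rn) * 1000
    ))
  }
  rhat <- r / rn
  mvec <- moment * ax
  mdotr <- rowSums(mvec * rhat)
  b_tesla <- 1e-7 * (3 * mdotr * rhat - mvec) / rn^3
  b_tesla * 1e4
}
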