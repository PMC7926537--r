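## Default per-axis magnetometer noise, raw LSB.  12 LSB is about 1.5
## milligauss RMS, typical of this magnetometer class, and puts the
## calibrated same-direction run-length SD at the default 8 Hz / 8 LSB
## parameters in [1.0, 2.0] samples, the range observed on the physical
## device.
default_mag_noise_sd <- 12

#' Sensor noise and environment model for the simulator
#'
#' @param mag_noise_sd Gaussian noise SD per magnetometer axis, raw LSB.
#' @param earth_field Earth's magnetic field in the band frame at rest,
#'   gauss.  The default has magnitude close to 0.5 gauss (typical of
#'   mid-latitudes; 0.25-0.65 across the globe).
#' @param quantize round magnetometer readings to integer LSB and clip to
#'   the signed 16-bit range, as the hardware does.
#' @param accel_noise_sd accelerometer noise SD, g.
#' @param gyro_noise_sd gyroscope noise SD, degrees/s.
#' @param seed integer seed making a simulation bit-reproducible; `NULL`
#'   leaves the RNG state alone.
#' @return a `noise_model` object.
#' @export
noise_model <- function(mag_noise_sd = default_mag_noise_sd,
                        earth_field = c(0.22, 0.30, -0.33),
                        quantize = TRUE,
                        accel_noise_sd = 0.008,
                        gyro_noise_sd = 0.5,
                        seed = NULL) {
  stopifnot(mag_noise_sd >= 0, length(earth_field) == 3,
            accel_noise_sd >= 0, gyro_noise_sd >= 0)
  structure(
    list(
      mag_noise_sd = mag_noise_sd,
      earth_field = as.numeric(earth_field),
      quantize = isTRUE(quantize),
      accel_noise_sd = accel_noise_sd,
      gyro_noise_sd = gyro_noise_sd,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "noise_model"
  )
}

#' A noiseless, unquantized environment
#'
#' Convenience wrapper for deterministic simulations: no sensor noise, no
#' quantization, Earth field still present.
#'
#' @inheritParams noise_model
#' @return a `noise_model` object.
#' @export
noise_free <- function(earth_field = c(0.22, 0.30, -0.33)) {
  noise_model(mag_noise_sd = 0, earth_field = earth_field,
              quantize = FALSE, accel_noise_sd = 0, gyro_noise_sd = 0)
}

deg <- pi / 180

# Rotate a fixed 3-vector v by per-sample angles (degrees) about the x or
# z axis; returns an n x 3 matrix.
rotate_fixed <- function(v, angle_deg, axis = c("z", "x")) {
  axis <- match.arg(axis)
  ca <- cos(angle_deg * deg)
  sa <- sin(angle_deg * deg)
  if (axis == "z") {
    cbind(ca * v[1] - sa * v[2], sa * v[1] + ca * v[2],
          rep(v[3], length(ca)))
  } else {
    cbind(rep(v[1], length(ca)), ca * v[2] - sa * v[3],
          sa * v[2] + ca * v[3])
  }
}

# Piecewise timeline of a protocol: movement onsets/durations and the
# total sampling grid.
build_timeline <- function(specs, fs, spacing_s, gap_s, lead_s) {
  m <- nrow(specs)
  duration <- ifelse(specs$kind == "rest", 0,
                     min_jerk_speed_coef * specs$amplitude / specs$peak_speed)
  if (!is.null(spacing_s)) {
    if (any(duration >= spacing_s)) {
      stop("movement duration exceeds the prompt spacing")
    }
    onset <- lead_s + (seq_len(m) - 1) * spacing_s
    total <- lead_s + m * spacing_s
  } else {
    onset <- lead_s + c(0, cumsum(duration[-m] + gap_s))
    total <- onset[m] + duration[m] + gap_s
  }
  n <- floor(total * fs) + 1
  list(
    t = (seq_len(n) - 1) / fs,
    n = n,
    onset = onset,
    duration = duration,
    total = total
  )
}

# Fill joint-angle (and joint velocity/acceleration) tracks.  Each stroke
# starts from the joint's current angle and moves away from its current
# side (toward zero and beyond), so consecutive strokes of one joint
# alternate direction, as the robotic testbed's servo did.
angle_tracks <- function(specs, tl, fs) {
  n <- tl$n
  ang <- list(wrist = numeric(n), finger = numeric(n), arm = numeric(n))
  vel <- list(arm = numeric(n))
  acc <- list(arm = numeric(n))
  cur <- c(wrist = 0, finger = 0, arm = 0)
  arm_axis <- character(nrow(specs))
  n_arm <- 0L
  for (i in seq_len(nrow(specs))) {
    kind <- specs$kind[i]
    if (kind == "rest") next
    joint <- switch(kind,
      wrist_flexext = "wrist",
      finger_flexext = "finger",
      arm_only = "arm"
    )
    if (kind == "arm_only") {
      n_arm <- n_arm + 1L
      arm_axis[i] <- if (n_arm %% 2L == 1L) "z" else "x"
    }
    a <- specs$amplitude[i]
    s <- if (cur[[joint]] > 0) -1 else 1
    t0 <- tl$onset[i]
    dur <- tl$duration[i]
    k0 <- max(1L, ceiling(t0 * fs) + 1L)
    k1 <- min(n, floor((t0 + dur) * fs) + 1L)
    if (k1 >= k0) {
      tau <- (tl$t[k0:k1] - t0) / dur
      ang[[joint]][k0:k1] <- cur[[joint]] + s * a * min_jerk_pos(tau)
      if (joint == "arm") {
        vel$arm[k0:k1] <- s * a / dur * min_jerk_vel(tau)
        acc$arm[k0:k1] <- s * a / dur^2 *
          (60 * tau - 180 * tau^2 + 120 * tau^3)
      }
    }
    new <- cur[[joint]] + s * a
    if (k1 < n) ang[[joint]][(k1 + 1):n] <- new
    cur[[joint]] <- new
  }
  list(ang = ang, vel = vel, acc = acc, arm_axis = arm_axis)
}

# Synthesize raw sensor frames from joint-angle tracks.
synthesize_frames <- function(tl, tracks, hand, magnet, geometry, noise,
                              fs, arm_length_m = 0.3) {
  n <- tl$n
  thw <- tracks$ang$wrist
  thf <- tracks$ang$finger
  phi <- tracks$ang$arm

  dim1 <- hand$dim1 / 100   # cm -> m
  dim2 <- hand$dim2 / 100
  l2 <- dim2 - dim1

  # ring position in the band frame: MCP offset plus the finger segment,
  # both rotated by the wrist angle (rotation about the y axis)
  cf <- cos(thf * deg); sf <- sin(thf * deg)
  pfx <- dim1 + l2 * cf
  pfz <- -l2 * sf
  cw <- cos(thw * deg); sw <- sin(thw * deg)
  ring <- cbind(cw * pfx + sw * pfz, 0, -sw * pfx + cw * pfz)

  # magnet axis rotates with the total (wrist + finger) angle
  tht <- (thw + thf) * deg
  axis0 <- magnet$axis
  axm <- cbind(
    cos(tht) * axis0[1] + sin(tht) * axis0[3],
    rep(axis0[2], n),
    -sin(tht) * axis0[1] + cos(tht) * axis0[3]
  )

  # Earth field seen in the band frame under the arm rotation; the z/x
  # split follows which axis each arm stroke rotated about
  phi_z <- if (is.null(tracks$phi_z)) numeric(n) else tracks$phi_z
  phi_x <- if (is.null(tracks$phi_x)) numeric(n) else tracks$phi_x
  earth <- rotate_fixed(noise$earth_field, -phi_z, "z")
  if (any(phi_x != 0)) {
    e2 <- matrix(0, n, 3)
    ca <- cos(-phi_x * deg); sa <- sin(-phi_x * deg)
    e2[, 1] <- earth[, 1]
    e2[, 2] <- ca * earth[, 2] - sa * earth[, 3]
    e2[, 3] <- sa * earth[, 2] + ca * earth[, 3]
    earth <- e2
  }

  sens <- geometry$positions / 1000  # mm -> m
  mags <- vector("list", 4)
  for (i in 1:4) {
    b <- dipole_field(magnet$moment, axm, ring, sens[i, ]) + earth
    raw <- gauss_to_lsb(b)
    if (noise$mag_noise_sd > 0) {
      raw <- raw + matrix(stats::rnorm(3 * n, sd = noise$mag_noise_sd), n, 3)
    }
    if (noise$quantize) {
      raw <- pmin(pmax(round(raw), -32768), 32767)
    }
    mags[[i]] <- raw
  }

  # band-frame gravity under the arm rotation, plus the tangential linear
  # acceleration of the band during arm strokes
  grav <- rotate_fixed(c(0, 0, -1), -phi_z, "z")
  if (any(phi_x != 0)) {
    ca <- cos(-phi_x * deg); sa <- sin(-phi_x * deg)
    g2 <- grav
    g2[, 2] <- ca * grav[, 2] - sa * grav[, 3]
    g2[, 3] <- sa * grav[, 2] + ca * grav[, 3]
    grav <- g2
  }
  alin <- tracks$acc$arm * deg * arm_length_m / 9.80665
  accel <- grav
  accel[, 1] <- accel[, 1] + alin
  if (noise$accel_noise_sd > 0) {
    accel <- accel + matrix(stats::rnorm(3 * n, sd = noise$accel_noise_sd),
                            n, 3)
  }
  gyro <- matrix(0, n, 3)
  gyro[, 3] <- tracks$vel$arm
  if (noise$gyro_noise_sd > 0) {
    gyro <- gyro + matrix(stats::rnorm(3 * n, sd = noise$gyro_noise_sd),
                          n, 3)
  }

  frames <- data.frame(
    t = tl$t,
    m1x = mags[[1]][, 1], m1y = mags[[1]][, 2], m1z = mags[[1]][, 3],
    m2x = mags[[2]][, 1], m2y = mags[[2]][, 2], m2z = mags[[2]][, 3],
    m3x = mags[[3]][, 1], m3y = mags[[3]][, 2], m3z = mags[[3]][, 3],
    m4x = mags[[4]][, 1], m4y = mags[[4]][, 2], m4z = mags[[4]][, 3],
    ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
    gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3]
  )
  frames
}

#' Simulate a movement protocol
#'
#' Generates a raw sensor log for a sequence of movement commands: the
#' ring magnet follows minimum-jerk strokes of the wrist or MCP joint,
#' each of the four magnetometers sees the exact dipole field of the
#' magnet plus the Earth's field, Gaussian sensor noise and 16-bit
#' quantization; arm-only movements rotate band and ring rigidly together
#' (swinging the Earth field and gravity through the band frame without
#' changing the magnet's relative position).  Successive strokes of a
#' joint alternate direction, as on the robotic testbed.
#'
#' @param specs `data.frame` of movement commands (rows from
#'   [movement_spec()], or [testbed_protocol()] / [lab_protocols()]
#'   output).
#' @param hand a [hand_geometry()].
#' @param magnet a [magnet_model()].
#' @param geometry an [array_geometry()].
#' @param noise a [noise_model()].
#' @param fs sampling rate, Hz.
#' @param spacing_s fixed onset-to-onset prompt spacing, seconds;
#'   `NULL` (default) spaces movements by `gap_s` of rest after each.
#' @param gap_s rest gap after each movement, seconds.
#' @param lead_s initial rest, seconds.
#' @return list with `frames` (sensor log `data.frame`) and `truth`
#'   (`data.frame`: `idx`, `onset_s`, `offset_s`, `kind`,
#'   `amplitude_deg`, `peak_speed_dps`, `speed_class`).
#' @export
simulate_protocol <- function(specs, hand = hand_geometry("medium"),
                              magnet = magnet_model(),
                              geometry = array_geometry(),
                              noise = noise_model(),
                              fs = default_fs,
                              spacing_s = NULL, gap_s = 1.0, lead_s = 1.0) {
  stopifnot(is.data.frame(specs), nrow(specs) >= 1,
            inherits(hand, "hand_geometry"),
            inherits(magnet, "magnet_model"),
            inherits(geometry, "array_geometry"),
            inherits(noise, "noise_model"))
  if (!is.null(noise$seed)) set.seed(noise$seed)
  tl <- build_timeline(specs, fs, spacing_s, gap_s, lead_s)
  tracks <- angle_tracks(specs, tl, fs)
  tracks$phi_z <- arm_component(specs, tl, tracks, fs, "z")
  tracks$phi_x <- arm_component(specs, tl, tracks, fs, "x")
  frames <- synthesize_frames(tl, tracks, hand, magnet, geometry, noise, fs)
  truth <- data.frame(
    idx = seq_len(nrow(specs)),
    onset_s = tl$onset,
    offset_s = tl$onset + tl$duration,
    kind = specs$kind,
    amplitude_deg = specs$amplitude,
    peak_speed_dps = specs$peak_speed,
    speed_class = if ("speed_class" %in% names(specs)) specs$speed_class
      else speed_class(specs$peak_speed),
    stringsAsFactors = FALSE
  )
  list(frames = frames, truth = truth)
}

# Per-axis arm angle track: replay of the arm strokes restricted to those
# rotating about one axis.
arm_component <- function(specs, tl, tracks, fs, which_axis) {
  n <- tl$n
  out <- numeric(n)
  cur <- 0
  n_arm <- 0L
  for (i in seq_len(nrow(specs))) {
    if (specs$kind[i] != "arm_only") next
    n_arm <- n_arm + 1L
    ax <- if (n_arm %% 2L == 1L) "z" else "x"
    a <- specs$amplitude[i]
    s <- if (cur > 0) -1 else 1
    if (ax != which_axis) next
    t0 <- tl$onset[i]
    dur <- tl$duration[i]
    k0 <- max(1L, ceiling(t0 * fs) + 1L)
    k1 <- min(n, floor((t0 + dur) * fs) + 1L)
    if (k1 >= k0) {
      tau <- (tl$t[k0:k1] - t0) / dur
      out[k0:k1] <- cur + s * a * min_jerk_pos(tau)
    }
    cur <- cur + s * a
    if (k1 < n) out[(k1 + 1):n] <- cur
  }
  out
}

#' Simulate one movement
#'
#' Single-stroke convenience wrapper around [simulate_protocol()].
#'
#' @param spec a one-row [movement_spec()].
#' @inheritParams simulate_protocol
#' @return list with `frames` and `truth`, as [simulate_protocol()].
#' @export
simulate_movement <- function(spec, hand = hand_geometry("medium"),
                              magnet = magnet_model(),
                              geometry = array_geometry(),
                              noise = noise_model(),
                              fs = default_fs, gap_s = 1.0, lead_s = 1.0) {
  simulate_protocol(spec, hand = hand, magnet = magnet,
                    geometry = geometry, noise = noise, fs = fs,
                    gap_s = gap_s, lead_s = lead_s)
}

#' Simulate a movement-free (rest) log
#'
#' Everything held still: only sensor noise, quantization and the static
#' Earth field.  Suitable as calibration input for [calibrate()].
#'
#' @param duration_s length of the log, seconds.
#' @inheritParams simulate_protocol
#' @return a sensor log `data.frame`.
#' @export
simulate_rest <- function(duration_s = 120, hand = hand_geometry("medium"),
                          magnet = magnet_model(),
                          geometry = array_geometry(),
                          noise = noise_model(), fs = default_fs) {
  stopifnot(duration_s > 0)
  spec <- movement_spec("rest")
  out <- simulate_protocol(spec, hand = hand, magnet = magnet,
                           geometry = geometry, noise = noise, fs = fs,
                           gap_s = 0, lead_s = duration_s)
  out$frames
}
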