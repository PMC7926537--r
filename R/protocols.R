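## Servo angular-acceleration cap, degrees/s^2.  The testbed sweeps 18
## amplitudes (5:5:90 degrees) by 59 peak speeds (20:10:600 degrees/s) and
## drops combinations whose minimum-jerk peak acceleration
## (10/sqrt(3) * v^2 / (1.875^2 * A)) exceeds the cap.  The robotic
## protocol being emulated ran 986 movements per condition; on the regular
## grid the points (5 deg, 270 deg/s) and (20 deg, 540 deg/s) have exactly
## equal peak acceleration (equal v^2/A), so the kept count steps from 985
## directly to 987 and 986 is unattainable.  The default sits just above
## that tie (found by bisection with accel_limit_for_count()), keeping 987
## specs -- the closest inclusive replication.
default_accel_limit <- 23943.9

testbed_amplitudes <- seq(5, 90, by = 5)
testbed_speeds <- seq(20, 600, by = 10)

min_jerk_peak_accel <- function(amplitude, peak_speed) {
  min_jerk_accel_coef * peak_speed^2 / (min_jerk_speed_coef^2 * amplitude)
}

#' Movement grid of the robotic testbed
#'
#' Amplitudes 5 to 90 degrees in 5-degree steps; for each amplitude, peak
#' speeds 20 to 600 degrees/s in 10-degree/s steps, keeping only the
#' combinations whose minimum-jerk peak angular acceleration is within the
#' servo's limit (smaller amplitudes therefore reach lower top speeds).
#' Ordered small/slow to large/fast.  At the default acceleration limit
#' the grid holds 987 movement specs.
#'
#' @param kind `"wrist_flexext"` or `"finger_flexext"`.
#' @param accel_limit servo angular-acceleration cap, degrees/s^2.
#' @return `data.frame` of movement specs (`kind`, `amplitude`,
#'   `peak_speed`, `speed_class`).
#' @export
#' @examples
#' nrow(testbed_protocol())                       # 987
#' nrow(testbed_protocol(accel_limit = Inf))      # full 18 x 59 grid
testbed_protocol <- function(kind = c("wrist_flexext", "finger_flexext"),
                             accel_limit = default_accel_limit) {
  kind <- match.arg(kind)
  stopifnot(accel_limit > 0)
  g <- expand.grid(peak_speed = testbed_speeds,
                   amplitude = testbed_amplitudes)
  keep <- min_jerk_peak_accel(g$amplitude, g$peak_speed) <= accel_limit
  g <- g[keep, c("amplitude", "peak_speed")]
  g <- g[order(g$amplitude, g$peak_speed), ]
  rownames(g) <- NULL
  data.frame(
    kind = kind,
    amplitude = g$amplitude,
    peak_speed = g$peak_speed,
    speed_class = speed_class(g$peak_speed),
    stringsAsFactors = FALSE
  )
}

#' Acceleration cap reproducing a target grid size
#'
#' Bisects the servo acceleration limit to the smallest value at which the
#' testbed grid holds at least `n_target` movement specs.  Used to derive
#' `default_accel_limit`; because distinct grid points can share `v^2/A`
#' exactly, some counts are skipped and the achieved size may exceed
#' `n_target` by the tie multiplicity.
#'
#' @param n_target desired number of specs in [testbed_protocol()].
#' @return acceleration limit, degrees/s^2.
#' @keywords internal
accel_limit_for_count <- function(n_target = 986) {
  count <- function(a) nrow(testbed_protocol(accel_limit = a))
  lo <- 1e2
  hi <- 1e6
  stopifnot(count(lo) < n_target, count(hi) >= n_target)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (count(mid) >= n_target) hi <- mid else lo <- mid
  }
  hi
}

#' In-lab exercise protocols
#'
#' Labelled movement sequences mirroring the laboratory exercises used to
#' select the algorithm parameters:
#'
#' * `hand_only`: 10 hand postures (5 wrist positions, fingers flexed or
#'   extended), each prompted 5 times at 2 s spacing -- 50 single smooth
#'   hand movements with known count.  The emulation alternates wrist and
#'   finger strokes over a deterministic cycle of amplitudes and speeds
#'   typical of prompted posture changes.
#' * `arm_only`: 5 arm directions, each presented 20 times with 2
#'   movements per direction -- 200 arm movements at 1 s spacing with the
#'   wrist and fingers splinted, so every hand count is a false positive.
#'
#' @return list of two movement-spec `data.frame`s, `hand_only` (50 rows)
#'   and `arm_only` (200 rows), each with a `spacing_s` attribute to pass
#'   to [simulate_protocol()].
#' @export
lab_protocols <- function() {
  n_hand <- 50L
  kinds <- rep(c("wrist_flexext", "finger_flexext"), length.out = n_hand)
  amplitude <- rep(c(45, 60, 30, 50, 40), length.out = n_hand)
  speeds <- rep(c(150, 250, 120, 300, 200, 180, 260), length.out = n_hand)
  hand_only <- data.frame(
    kind = kinds, amplitude = amplitude, peak_speed = speeds,
    speed_class = speed_class(speeds), stringsAsFactors = FALSE
  )
  attr(hand_only, "spacing_s") <- 2

  n_arm <- 200L
  arm_only <- data.frame(
    kind = "arm_only",
    amplitude = rep(c(45, 60, 35, 50, 40), length.out = n_arm),
    peak_speed = rep(c(150, 200, 120, 180, 160), length.out = n_arm),
    speed_class = factor(NA, levels = levels(speed_class(1))),
    stringsAsFactors = FALSE
  )
  attr(arm_only, "spacing_s") <- 1

  list(hand_only = hand_only, arm_only = arm_only)
}
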