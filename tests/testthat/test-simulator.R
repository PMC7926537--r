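test_that("seeded simulations are bit-reproducible", {
  sp <- movement_spec("wrist_flexext", 40, 200)
  a <- simulate_movement(sp, noise = noise_model(seed = 77))
  b <- simulate_movement(sp, noise = noise_model(seed = 77))
  expect_identical(a, b)
  c2 <- simulate_movement(sp, noise = noise_model(seed = 78))
  expect_false(identical(a$frames, c2$frames))
})

test_that("rest with zero noise is constant and produces no counts", {
  log <- simulate_rest(10, noise = noise_free())
  expect_true(all(vapply(log[, 2:13], function(col)
    all(col == col[1]), logical(1))))
  d <- compute_differential(log)
  cal <- default_test_calibration()
  expect_identical(hand_count(d, hand_count_params(), cal)$count, 0L)
})

test_that("arm-only motion leaves the differential constant (rigid body)", {
  specs <- do.call(rbind, replicate(6, movement_spec("arm_only", 60, 150),
                                    simplify = FALSE))
  sim <- simulate_protocol(specs, noise = noise_free())
  d <- compute_differential(sim$frames)
  rng <- vapply(d[, 2:4], function(x) diff(range(x)), numeric(1))
  expect_lt(max(rng), 1e-6)
  cal <- default_test_calibration()
  expect_identical(hand_count(d, hand_count_params(), cal)$count, 0L)
  # but the arm swings do register as wrist-accelerometry activity
  expect_gt(activity_count(sim$frames)$count, 0)
})

test_that("a large medium-speed wrist movement is counted exactly once", {
  sp <- movement_spec("wrist_flexext", 90, 300)
  sim <- simulate_movement(sp, noise = noise_free())
  d <- compute_differential(sim$frames)
  cal <- default_test_calibration()
  res <- hand_count(d, hand_count_params(), cal)
  m <- match_events(res$events, sim$truth)
  expect_gte(m[1], 1)
  orc <- oracle_hand_count(d$t, as.matrix(lowpass(d)[, 2:4]),
                           8, cal$n_two_axes, cal$n_one_axis)
  expect_identical(res$count, as.integer(orc$count))
})

test_that("the magnet ring cannot be placed onto the sensor board", {
  # a geometry whose ring path passes within the point-dipole guard radius
  tiny <- hand_geometry(dim1 = 0.3, dim2 = 0.6)
  close_board <- array_geometry(near_far_mm = 6, left_right_mm = 6,
                                center_mm = c(0, 0, 0))
  sp <- movement_spec("wrist_flexext", 90, 100)
  expect_error(simulate_movement(sp, hand = tiny, geometry = close_board,
                                 noise = noise_free()),
               "dipole")
})

test_that("ground truth carries onsets, offsets and speed classes", {
  specs <- rbind(movement_spec("wrist_flexext", 30, 100),
                 movement_spec("finger_flexext", 60, 450))
  sim <- simulate_protocol(specs, noise = noise_model(seed = 5),
                           gap_s = 1, lead_s = 1)
  tr <- sim$truth
  expect_identical(nrow(tr), 2L)
  expect_equal(tr$onset_s[1], 1)
  expect_equal(tr$offset_s[1] - tr$onset_s[1], 1.875 * 30 / 100)
  expect_equal(as.character(tr$speed_class), c("slow", "fast"))
  expect_true(all(tr$offset_s[-nrow(tr)] < tr$onset_s[-1]))
  # frames span the protocol and time stamps are uniform
  expect_equal(diff(range(sim$frames$t)),
               (nrow(sim$frames) - 1) / 52.6)
})

test_that("spurious counts at rest match the arm-only condition", {
  cal <- default_test_calibration()
  p <- hand_count_params()
  rest <- compute_differential(
    simulate_rest(240, noise = noise_model(seed = 41)))
  n_rest <- hand_count(rest, p, cal)$count
  arm_specs <- do.call(rbind, replicate(
    120, movement_spec("arm_only", 45, 150), simplify = FALSE))
  arm <- simulate_protocol(arm_specs, noise = noise_model(seed = 42),
                           spacing_s = 2, lead_s = 1)
  n_arm <- hand_count(compute_differential(arm$frames), p, cal)$count
  # both are noise-driven; equal-duration logs should give similar rates
  expect_lt(abs(n_arm - n_rest), max(10, 3 * sqrt(max(n_rest, n_arm, 1))))
})
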