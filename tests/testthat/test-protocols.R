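test_that("the uncapped testbed grid is the full 18 x 59 sweep", {
  g <- testbed_protocol(accel_limit = Inf)
  expect_identical(nrow(g), 18L * 59L)
  expect_true(all(g$amplitude >= 5 & g$amplitude <= 90))
  expect_true(all(g$peak_speed >= 20 & g$peak_speed <= 600))
})

test_that("the default acceleration cap trims the grid as on the testbed", {
  g <- testbed_protocol()
  # target replication: 986 movements; the symmetric tie between
  # (5, 270) and (20, 540) makes the closest attainable count 987
  expect_identical(nrow(g), 987L)
  vmax <- tapply(g$peak_speed, g$amplitude, max)
  expect_true(all(diff(vmax) >= 0))   # max speed non-decreasing in amplitude
  # movements are ordered small/slow to large/fast
  expect_true(all(diff(g$amplitude) >= 0))
  # the bisected limit reproduces the default
  lim <- manucount:::accel_limit_for_count(986)
  expect_identical(nrow(testbed_protocol(accel_limit = lim)), 987L)
})

test_that("lab protocols have the prescribed movement counts", {
  lp <- lab_protocols()
  expect_identical(nrow(lp$hand_only), 50L)
  expect_identical(nrow(lp$arm_only), 200L)
  expect_true(all(lp$hand_only$kind %in%
                    c("wrist_flexext", "finger_flexext")))
  expect_true(all(lp$arm_only$kind == "arm_only"))
})

test_that("counting probability tables match a per-movement matcher", {
  truth <- data.frame(
    idx = 1:4,
    onset_s = c(1, 4, 7, 10), offset_s = c(2, 5, 8, 11),
    kind = "wrist_flexext",
    amplitude_deg = c(10, 10, 50, 50),
    peak_speed_dps = c(100, 500, 100, 500),
    speed_class = factor(c("slow", "fast", "slow", "fast"),
                         levels = c("slow", "medium", "fast")),
    stringsAsFactors = FALSE
  )
  # movement 1: 2 events; movement 2: 0; 3 and 4: 1 each (one inside the
  # 0.5 s window extension); one spurious event far from any movement
  events <- data.frame(t = c(1.2, 1.9, 7.5, 11.4, 20))
  m <- match_events(events, truth)
  expect_identical(m, c(2L, 0L, 1L, 1L))
  tab <- counting_probability(events, truth, by = "amplitude_deg")
  expect_equal(tab$probability, c(0.5, 1.0))
  expect_equal(tab$ratio, c(1.0, 1.0))
  tab2 <- counting_probability(events, truth, by = NULL)
  expect_equal(tab2$probability, 0.75)
  expect_equal(tab2$n_events, 4L)
  expect_equal(overall_accuracy(events, truth), 75)
})

test_that("an 83-of-100 bin reports probability 0.83", {
  truth <- data.frame(
    idx = 1:100, onset_s = seq(0, by = 3, length.out = 100),
    offset_s = seq(1, by = 3, length.out = 100),
    kind = "wrist_flexext", amplitude_deg = 40, peak_speed_dps = 100,
    speed_class = "slow", stringsAsFactors = FALSE
  )
  events <- data.frame(t = truth$onset_s[1:83] + 0.5)
  tab <- counting_probability(events, truth, by = "amplitude_deg")
  expect_equal(tab$probability, 0.83)
})

test_that("empty groups are absent rather than zero", {
  truth <- data.frame(idx = 1, onset_s = 1, offset_s = 2,
                      kind = "wrist_flexext", amplitude_deg = 10,
                      peak_speed_dps = 100,
                      speed_class = factor("slow",
                                           levels = c("slow", "medium", "fast")),
                      stringsAsFactors = FALSE)
  tab <- counting_probability(data.frame(t = 1.5), truth, by = "speed_class")
  expect_identical(nrow(tab), 1L)
  expect_equal(as.character(tab$speed_class), "slow")
})

test_that("intensity converts counts to rates", {
  expect_equal(intensity(0L, 5), 0)
  expect_equal(intensity(1000L, 1), 1000)
  expect_equal(intensity(50L, 1, unit = "minute"), 50)
  ev <- data.frame(t = 1:120)
  expect_equal(intensity(ev, 2), 60)
  expect_error(intensity(10L, 0), "positive")
})
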