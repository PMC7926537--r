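params_nf <- function(...) hand_count_params(lp_cutoff = NULL, ...)

test_that("a constant differential yields no counts", {
  cal <- calibration_from_sigma(1.5, params_nf())
  d <- data.frame(t = (0:199) / 52.6, dx = 50, dy = -30, dz = 10)
  expect_identical(hand_count(d, params_nf(), cal)$count, 0L)
})

test_that("a two-axis monotone ramp of sufficient run length counts once", {
  cal <- calibration_from_sigma(1.5, params_nf())   # n_two_axes = 8
  n_ramp <- cal$n_two_axes
  ramp <- c(rep(0, 5), cumsum(rep(20, n_ramp)))
  d <- data.frame(t = seq_along(ramp) / 52.6, dx = ramp, dy = ramp, dz = 0)
  res <- hand_count(d, params_nf(), cal)
  expect_identical(res$count, 1L)
  expect_identical(res$events$trigger, "two_axes")
  expect_identical(res$events$axes, "x|y")
  # one step short of the requirement: no count
  d2 <- d[1:(nrow(d) - 1), ]
  expect_identical(hand_count(d2, params_nf(), cal)$count, 0L)
})

test_that("a single axis needs the extra samples to trigger", {
  cal <- calibration_from_sigma(1.5, params_nf())   # n1 = n2 + 2
  ramp <- cumsum(rep(20, cal$n_one_axis + 1))
  d <- data.frame(t = seq_along(ramp) / 52.6, dx = ramp, dy = 0, dz = 0)
  res <- hand_count(d, params_nf(), cal)
  expect_identical(res$count, 1L)
  expect_identical(res$events$trigger, "one_axis")
  d2 <- d[1:(cal$n_one_axis - 1), ]   # n1 - 2 supra-threshold changes
  expect_identical(hand_count(d2, params_nf(), cal)$count, 0L)
})

test_that("sub-threshold samples neither break nor extend runs", {
  cal <- calibration_from_sigma(1.5, params_nf())
  n2 <- cal$n_two_axes
  # interleave sub-threshold wiggles inside a run
  steps <- rep(c(20, 1, -1), n2)[1:(3 * n2 - 2)]
  x <- cumsum(c(0, steps))
  d <- data.frame(t = seq_along(x) / 52.6, dx = x, dy = x, dz = 0)
  expect_identical(hand_count(d, params_nf(), cal)$count, 1L)
})

test_that("after a count, suppression lifts on reversal or after 2 s", {
  cal <- calibration_from_sigma(1.5, params_nf())
  n2 <- cal$n_two_axes
  fs <- 52.6
  up <- rep(20, n2)
  # two ramps separated by 0.5 s of rest, same direction: second suppressed
  x_same <- cumsum(c(0, up, rep(0, round(0.5 * fs)), up))
  d_same <- data.frame(t = seq_along(x_same) / fs,
                       dx = x_same, dy = x_same, dz = 0)
  expect_identical(hand_count(d_same, params_nf(), cal)$count, 1L)
  # opposite-direction second ramp: reversal re-arms, both counted
  x_rev <- cumsum(c(0, up, rep(0, round(0.5 * fs)), -up))
  d_rev <- data.frame(t = seq_along(x_rev) / fs,
                      dx = x_rev, dy = x_rev, dz = 0)
  expect_identical(hand_count(d_rev, params_nf(), cal)$count, 2L)
  # same direction but beyond the 2 s timeout: both counted
  x_late <- cumsum(c(0, up, rep(0, round(2.2 * fs)), up))
  d_late <- data.frame(t = seq_along(x_late) / fs,
                       dx = x_late, dy = x_late, dz = 0)
  expect_identical(hand_count(d_late, params_nf(), cal)$count, 2L)
})

test_that("counting is invariant under a global sign flip", {
  cal <- calibration_from_sigma(1.3, params_nf())
  for (seed in 1:20) {
    set.seed(seed)
    d <- random_diff_log(400)
    flipped <- d
    flipped[, 2:4] <- -flipped[, 2:4]
    a <- hand_count(d, params_nf(), cal)
    b <- hand_count(flipped, params_nf(), cal)
    expect_identical(a$count, b$count)
    expect_equal(a$events$t, b$events$t)
    expect_identical(a$events$trigger, b$events$trigger)
  }
})

test_that("identical input gives identical events (determinism)", {
  cal <- default_test_calibration()
  set.seed(21)
  d <- random_diff_log(600)
  p <- hand_count_params()
  expect_identical(hand_count(d, p, cal), hand_count(d, p, cal))
})

test_that("events within 2 s require an intervening reversal on a trigger axis", {
  # a laxer run requirement makes events frequent enough to find close pairs
  cal <- calibration_from_sigma(0.8, params_nf())
  thr <- params_nf()$threshold
  checked <- 0L
  for (seed in 1:25) {
    set.seed(seed)
    d <- random_diff_log(500)
    ev <- hand_count(d, params_nf(), cal)$events
    if (nrow(ev) < 2) next
    gaps <- diff(ev$t)
    expect_true(all(gaps > 0))
    for (i in which(gaps < 2)) {
      axes <- strsplit(ev$axes[i], "|", fixed = TRUE)[[1]]
      # on at least one triggering axis, the changes between the two events
      # must include a supra-threshold step opposite to the run direction
      # that fired event i
      found <- FALSE
      for (lab in axes) {
        x <- d[[paste0("d", lab)]]
        delta <- diff(x)
        td <- d$t[-1]
        before <- which(td <= ev$t[i] & abs(delta) > thr)
        run_dir <- sign(delta[max(before)])
        between <- which(td > ev$t[i] & td <= ev$t[i + 1])
        if (any(abs(delta[between]) > thr &
                sign(delta[between]) == -run_dir)) {
          found <- TRUE
          break
        }
      }
      expect_true(found)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 5)   # the property was actually exercised
})

test_that("streaming equals batch and both equal the literal offline oracle", {
  cal <- calibration_from_sigma(1.4, params_nf())
  p <- params_nf()
  for (seed in 1:100) {
    set.seed(seed)
    d <- random_diff_log(sample(50:500, 1))
    batch <- hand_count(d, p, cal)
    # chunked streaming
    st <- hand_count_state(p, cal)
    cuts <- sort(sample(nrow(d) - 1, 3))
    pieces <- split(seq_len(nrow(d)),
                    findInterval(seq_len(nrow(d)), cuts + 1))
    for (pc in pieces) st <- hand_count_stream(st, d[pc, ])
    expect_identical(st$count, batch$count)
    expect_equal(hand_events(st), batch$events)
    # literal transliteration oracle
    orc <- oracle_hand_count(d$t, as.matrix(d[, 2:4]),
                             p$threshold, cal$n_two_axes, cal$n_one_axis)
    expect_identical(batch$count, as.integer(orc$count))
    expect_equal(batch$events$t, orc$times)
    expect_identical(batch$events$trigger, orc$triggers)
  }
})

test_that("false-positive rate on iid noise matches a Monte-Carlo oracle", {
  # single-axis iid supra-threshold steps with fair signs; events need a
  # one-axis run of n1; compare the measured event count against an
  # independent Monte-Carlo replay on fresh sign sequences
  p <- params_nf()
  cal <- calibration_from_sigma(1.5, p)    # n1 = 10
  n1 <- cal$n_one_axis
  fs <- p$fs
  n <- 3e4
  set.seed(31)
  d <- data.frame(t = (seq_len(n) - 1) / fs,
                  dx = cumsum(sample(c(-20, 20), n, replace = TRUE)),
                  dy = 0, dz = 0)
  measured <- hand_count(d, p, cal)$count

  mc_events <- function(signs, n1, fs, timeout = 2) {
    len <- 0; dir <- 0; count <- 0; sup <- FALSE; sup_dir <- 0; sup_k <- -Inf
    for (k in seq_along(signs)) {
      s <- signs[k]
      if (sup) {
        if ((k - sup_k) / fs >= timeout || s == -sup_dir) sup <- FALSE
        else next
      }
      if (s == dir) len <- len + 1 else { dir <- s; len <- 1 }
      if (len >= n1) {
        count <- count + 1; sup <- TRUE; sup_dir <- dir
        sup_k <- k; len <- 0; dir <- 0
      }
    }
    count
  }
  set.seed(32)
  reps <- vapply(1:60, function(i)
    mc_events(sample(c(-1, 1), n, replace = TRUE), n1, fs), numeric(1))
  # measured is one realization of the same process: 3 sampling SDs
  expect_lt(abs(measured - mean(reps)), 3 * sd(reps) + 1)
  # and the run-reach probability itself is near 2^-(n-1) per run
  expect_lt(abs(mean(reps) / (n / 2 * 2^(-(n1 - 1))) - 1), 0.35)
})

test_that("a calibration from different settings is refused", {
  p8 <- hand_count_params(threshold = 8)
  p16 <- hand_count_params(threshold = 16)
  cal <- calibration_from_sigma(1.5, p16)
  expect_error(hand_count(random_diff_log(50), p8, cal), "calibration")
})

test_that("large time gaps reset the counter with a warning", {
  cal <- calibration_from_sigma(1.5, params_nf())
  n2 <- cal$n_two_axes
  half <- floor(n2 / 2)
  ramp1 <- cumsum(rep(20, half))
  ramp2 <- ramp1[half] + cumsum(rep(20, n2 - half))
  t1 <- seq_along(ramp1) / 52.6
  t2 <- max(t1) + 1 + seq_along(ramp2) / 52.6   # 1 s hole mid-run
  d <- data.frame(t = c(t1, t2), dx = c(ramp1, ramp2),
                  dy = c(ramp1, ramp2), dz = 0)
  expect_warning(res <- hand_count(d, params_nf(), cal), "gap")
  expect_identical(res$count, 0L)   # run did not survive the gap
})
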