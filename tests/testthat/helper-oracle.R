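# Independent reference implementations used as oracles.  These replay the
# documented detection rules offline, in deliberately plain code, separate
# from the package's streaming implementation.

# Literal offline replay of the run-length counting rules on an already
# filtered (or unfiltered) 3-axis signal.
oracle_hand_count <- function(tvec, x, threshold, n_two, n_one,
                              timeout = 2) {
  n <- nrow(x)
  dir <- c(0, 0, 0)
  len <- c(0, 0, 0)
  suppressed <- FALSE
  sup_axes <- integer(0)
  sup_dir <- c(0, 0, 0)
  sup_t <- -Inf
  count <- 0
  times <- numeric(0)
  triggers <- character(0)

  for (k in 2:n) {
    delta <- x[k, ] - x[k - 1, ]
    if (suppressed) {
      lifted <- (tvec[k] - sup_t) >= timeout
      if (!lifted) {
        for (a in sup_axes) {
          if (abs(delta[a]) > threshold &&
              sign(delta[a]) == -sup_dir[a]) {
            lifted <- TRUE
            break
          }
        }
      }
      if (!lifted) next
      suppressed <- FALSE
    }
    for (a in 1:3) {
      if (abs(delta[a]) > threshold) {
        s <- sign(delta[a])
        if (s == dir[a]) {
          len[a] <- len[a] + 1
        } else {
          dir[a] <- s
          len[a] <- 1
        }
      }
    }
    hit2 <- which(len >= n_two)
    if (length(hit2) >= 2) {
      ax <- hit2
      trig <- "two_axes"
    } else {
      ax <- which(len >= n_one)
      trig <- if (length(ax) >= 1) "one_axis" else NULL
    }
    if (!is.null(trig)) {
      count <- count + 1
      times <- c(times, tvec[k])
      triggers <- c(triggers, trig)
      sup_axes <- ax
      sup_dir <- dir
      dir <- c(0, 0, 0)
      len <- c(0, 0, 0)
      suppressed <- TRUE
      sup_t <- tvec[k]
    }
  }
  list(count = count, times = times, triggers = triggers)
}

# Direct O(n * w) windowed activity sum.
oracle_activity_signal <- function(a, w) {
  n <- nrow(a)
  step <- rowSums(abs(a[-1, , drop = FALSE] - a[-n, , drop = FALSE]))
  vapply((w + 1):n, function(k) sum(step[(k - w):(k - 1)]), numeric(1))
}

# Brute-force peak scan with the per-second cap.
oracle_activity_count <- function(tt, s, thr, cap) {
  accepted <- numeric(0)
  for (k in 2:(length(s) - 1)) {
    if (s[k] > thr && s[k] > s[k - 1] && s[k] >= s[k + 1]) {
      if (sum(accepted > tt[k] - 1) < cap) accepted <- c(accepted, tt[k])
    }
  }
  accepted
}

# Random-walk differential log for property tests: per-sample steps up to
# ~3x the default threshold, values bounded.
random_diff_log <- function(n, fs = 52.6, step_max = 25, bound = 100) {
  walk <- function() {
    x <- cumsum(sample(-step_max:step_max, n, replace = TRUE))
    ((x + bound) %% (2 * bound)) - bound
  }
  data.frame(
    t = (seq_len(n) - 1) / fs,
    dx = walk(), dy = walk(), dz = walk()
  )
}
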