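axis_labels <- c("x", "y", "z")

#' Create a streaming HAND counter state
#'
#' The counter is a deterministic state machine over the filtered
#' differential reading.  For every sample and axis it looks at the change
#' from the previous filtered sample: changes at or below the threshold are
#' ignored (they neither extend nor break a run); a supra-threshold change
#' extends the current same-direction run or restarts it in the new
#' direction.  A movement is counted when at least two axes simultaneously
#' hold runs of `n_two_axes` samples, or a single axis holds a run of
#' `n_one_axis` samples.  After a count all run states are cleared and
#' counting is suppressed until a triggering axis shows a supra-threshold
#' change of opposite sign, or `reset_timeout` (2 s) elapses.
#'
#' @param params a [hand_count_params()].
#' @param calib a `hand_calibration` from [calibrate()] or
#'   [calibration_from_sigma()]; must have been produced with the same
#'   filter cutoff, threshold and sampling rate.
#' @return a `hand_count_state` object to pass to [hand_count_stream()].
#' @seealso [hand_count()] for one-shot batch counting.
#' @export
hand_count_state <- function(params = hand_count_params(),
                             calib) {
  stopifnot(inherits(params, "hand_count_params"),
            inherits(calib, "hand_calibration"))
  cp <- calib$params
  same_cutoff <- (is.null(cp$lp_cutoff) && is.null(params$lp_cutoff)) ||
    (!is.null(cp$lp_cutoff) && !is.null(params$lp_cutoff) &&
       cp$lp_cutoff == params$lp_cutoff)
  if (!same_cutoff || cp$threshold != params$threshold ||
      cp$fs != params$fs) {
    stop("calibration was computed with a different filter cutoff, ",
         "threshold or sampling rate than the counting parameters")
  }
  structure(
    list(
      params = params,
      calib = calib,
      coef = if (is.null(params$lp_cutoff)) NULL else
        butter_lowpass(params$lp_cutoff, params$fs),
      fstate = NULL,
      prev = NULL,
      prev_t = NA_real_,
      dir = c(0, 0, 0),
      len = c(0L, 0L, 0L),
      suppressed = FALSE,
      sup_axes = integer(0),
      sup_dir = c(0, 0, 0),
      sup_t = NA_real_,
      count = 0L,
      events = list()
    ),
    class = "hand_count_state"
  )
}

empty_events <- function() {
  data.frame(
    t = numeric(0), trigger = character(0), axes = character(0),
    run_x = integer(0), run_y = integer(0), run_z = integer(0),
    stringsAsFactors = FALSE
  )
}

events_df <- function(ev_list) {
  if (length(ev_list) == 0) return(empty_events())
  out <- data.table::rbindlist(ev_list)
  data.table::setDF(out)
  out
}

# A time gap longer than 3 nominal periods means samples were lost; the
# filter memory and run states are then stale and are discarded.
reset_downstream <- function(state) {
  state$fstate <- NULL
  state$prev <- NULL
  state$dir <- c(0, 0, 0)
  state$len <- c(0L, 0L, 0L)
  state$suppressed <- FALSE
  state$sup_axes <- integer(0)
  state$sup_t <- NA_real_
  state
}

#' Feed samples to a streaming HAND counter
#'
#' Processes a chunk of differential samples, updating the counter state.
#' Feeding a log in one chunk or in arbitrary splits yields identical
#' counts and events.
#'
#' @param state a [hand_count_state()].
#' @param d differential reading `data.frame` (`t`, `dx`, `dy`, `dz`).
#' @return the updated state; `state$count` holds the running count and
#'   `hand_events(state)` the events so far.
#' @export
hand_count_stream <- function(state, d) {
  stopifnot(inherits(state, "hand_count_state"))
  n <- nrow(d)
  if (n == 0) return(state)
  tvec <- d$t
  x <- diff_matrix(d)

  # split at gaps > 3 nominal periods (including a gap to the previous chunk)
  gap_lim <- 3 / state$params$fs
  t_all <- c(state$prev_t, tvec)
  dts <- diff(t_all)
  if (any(!is.na(dts) & dts <= 0)) {
    stop("time stamps must be strictly increasing")
  }
  gap_before <- !is.na(dts) & dts > gap_lim
  seg_start <- c(TRUE, gap_before[-1])
  seg_id <- cumsum(seg_start)
  first_gap <- isTRUE(gap_before[1])
  if (any(gap_before)) {
    warning(sprintf(
      "gap(s) longer than 3 sampling periods in the log; filter and run states reset (%d gap(s))",
      sum(gap_before)
    ))
  }

  for (seg in split(seq_len(n), seg_id)) {
    if (seg[1] > 1 || first_gap) state <- reset_downstream(state)
    state <- process_segment(state, tvec[seg], x[seg, , drop = FALSE])
  }
  state$prev_t <- tvec[n]
  state
}

process_segment <- function(state, tvec, x) {
  p <- state$params
  thr <- p$threshold
  n2 <- state$calib$n_two_axes
  n1 <- state$calib$n_one_axis
  timeout <- p$reset_timeout
  n <- length(tvec)

  # filter the whole segment with carried-over state
  if (is.null(state$coef)) {
    y <- x
  } else {
    y <- x
    if (is.null(state$fstate)) {
      state$fstate <- lapply(1:3, function(j) biquad_init(state$coef, x[1, j]))
    }
    for (j in 1:3) {
      r <- biquad_apply(state$coef, x[, j], state$fstate[[j]])
      y[, j] <- r$y
      state$fstate[[j]] <- r$state
    }
  }

  start <- 1L
  if (is.null(state$prev)) {
    state$prev <- y[1, ]
    state$prev_t <- tvec[1]
    start <- 2L
  }
  if (start > n) return(state)

  dir <- state$dir
  len <- state$len
  suppressed <- state$suppressed
  sup_axes <- state$sup_axes
  sup_dir <- state$sup_dir
  sup_t <- state$sup_t
  count <- state$count
  events <- state$events
  prev <- state$prev

  for (k in start:n) {
    tk <- tvec[k]
    delta <- y[k, ] - prev
    prev <- y[k, ]

    if (suppressed) {
      if (tk - sup_t >= timeout) {
        suppressed <- FALSE
      } else {
        for (a in sup_axes) {
          da <- delta[a]
          if (abs(da) > thr && sign(da) == -sup_dir[a]) {
            suppressed <- FALSE
            break
          }
        }
      }
      if (suppressed) next
      # the sample that lifts suppression is processed normally below
    }

    for (a in 1:3) {
      da <- delta[a]
      if (abs(da) > thr) {
        s <- if (da > 0) 1 else -1
        if (s == dir[a]) {
          len[a] <- len[a] + 1L
        } else {
          dir[a] <- s
          len[a] <- 1L
        }
      }
    }

    ax2 <- which(len >= n2)
    trigger <- NULL
    if (length(ax2) >= 2) {
      trigger <- "two_axes"
      ax <- ax2
    } else {
      ax1 <- which(len >= n1)
      if (length(ax1) >= 1) {
        trigger <- "one_axis"
        ax <- ax1
      }
    }
    if (!is.null(trigger)) {
      count <- count + 1L
      events[[length(events) + 1L]] <- list(
        t = tk, trigger = trigger,
        axes = paste(axis_labels[ax], collapse = "|"),
        run_x = len[1], run_y = len[2], run_z = len[3]
      )
      sup_axes <- ax
      sup_dir <- dir
      dir <- c(0, 0, 0)
      len <- c(0L, 0L, 0L)
      suppressed <- TRUE
      sup_t <- tk
    }
  }

  state$prev <- prev
  state$dir <- dir
  state$len <- len
  state$suppressed <- suppressed
  state$sup_axes <- sup_axes
  state$sup_dir <- sup_dir
  state$sup_t <- sup_t
  state$count <- count
  state$events <- events
  state
}

#' Events accumulated by a streaming counter
#'
#' @param state a [hand_count_state()] after streaming.
#' @return events `data.frame` (`t`, `trigger`, `axes`, `run_x`, `run_y`,
#'   `run_z`).
#' @export
hand_events <- function(state) {
  stopifnot(inherits(state, "hand_count_state"))
  events_df(state$events)
}

#' Count hand movements in a differential log
#'
#' One-shot wrapper around the streaming counter: filters the log, tracks
#' per-axis same-direction runs and returns the detected movement events.
#' See [hand_count_state()] for the detection rules.
#'
#' @inheritParams hand_count_stream
#' @param params a [hand_count_params()].
#' @param calib a `hand_calibration` consistent with `params`.
#' @return list with `count` (integer) and `events` (`data.frame` with one
#'   row per detected movement: time, trigger type, triggering axes and the
#'   per-axis run lengths at the moment of the count).
#' @export
#' @examples
#' calib <- calibration_from_sigma(1.5, hand_count_params())
#' t <- seq(0, 1, by = 1 / 52.6)
#' ramp <- pmin(t, 0.5) * 2000           # supra-threshold rise on two axes
#' d <- data.frame(t = t, dx = ramp, dy = ramp, dz = 0)
#' hand_count(d, hand_count_params(), calib)$count
hand_count <- function(d, params = hand_count_params(), calib) {
  state <- hand_count_state(params, calib)
  state <- hand_count_stream(state, d)
  list(count = state$count, events = hand_events(state))
}
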