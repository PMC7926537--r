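#' Second-order Butterworth low-pass for the differential reading
#'
#' Causal (forward-only) filtering, applied independently per axis, as the
#' device does in real time.  The filter state is initialised to the
#' steady-state response for the first sample value, so a constant signal
#' passes through with no startup transient.  The same biquad recursion is
#' used for batch and for chunked (streaming) processing, so the two give
#' bit-identical outputs.
#'
#' @param d differential reading `data.frame` (`t`, `dx`, `dy`, `dz`) or a
#'   numeric matrix with one column per axis.
#' @param lp_cutoff cutoff frequency in Hz, or `NULL` for pass-through
#'   (no filtering).
#' @param fs sampling rate, Hz.
#' @return object of the same shape as `d` with filtered values.
#' @export
lowpass <- function(d, lp_cutoff = 8, fs = default_fs) {
  is_df <- is.data.frame(d)
  x <- if (is_df) diff_matrix(d) else as.matrix(d)
  if (is.null(lp_cutoff)) {
    y <- x
  } else {
    coef <- butter_lowpass(lp_cutoff, fs)
    y <- x
    for (j in seq_len(ncol(x))) {
      st <- biquad_init(coef, x[1, j])
      y[, j] <- biquad_apply(coef, x[, j], st)$y
    }
  }
  if (is_df) {
    out <- d
    out[, c("dx", "dy", "dz")] <- y
    out
  } else {
    y
  }
}

butter_lowpass <- function(lp_cutoff, fs) {
  if (!is.numeric(lp_cutoff) || lp_cutoff <= 0) {
    stop("lp_cutoff must be a positive frequency in Hz (or NULL for none)")
  }
  if (lp_cutoff >= fs / 2) {
    stop(sprintf(
      "lp_cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
      lp_cutoff, fs / 2
    ))
  }
  bt <- signal::butter(2, lp_cutoff / (fs / 2), type = "low")
  list(b = as.numeric(bt$b), a = as.numeric(bt$a))
}

# Transposed direct-form II state (z1, z2) at DC steady state for input x0.
# With unit DC gain, y = x0 and the state equations fix z1, z2 in closed form.
biquad_init <- function(coef, x0) {
  b <- coef$b
  a <- coef$a
  c(
    z1 = x0 * (1 - b[1]),
    z2 = x0 * (b[3] - a[3])
  )
}

biquad_apply <- function(coef, x, state) {
  b <- coef$b
  a <- coef$a
  n <- length(x)
  y <- numeric(n)
  z1 <- state[[1]]
  z2 <- state[[2]]
  for (k in seq_len(n)) {
    xk <- x[k]
    yk <- b[1] * xk + z1
    z1 <- b[2] * xk - a[2] * yk + z2
    z2 <- b[3] * xk - a[3] * yk
    y[k] <- yk
  }
  list(y = y, state = c(z1 = z1, z2 = z2))
}
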