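#' Uniformly sampled time series
#'
#' @param values numeric vector or n x d matrix (rows = time points); a
#'   vector-valued series correlates via the dot product of its rows
#' @param dt sampling interval in ps
#' @return object of class `"time_series"`
#' @export
time_series <- function(values, dt = 1) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  stopifnot(dt > 0, nrow(values) >= 2)
  structure(list(values = values, dt = dt), class = "time_series")
}

#' Normalised autocorrelation function (FFT-based)
#'
#' `C(t) = <Q(tau) . Q(tau + t)>_tau / <Q(tau) . Q(tau)>_tau`, evaluated by
#' zero-padded FFT (identical to the direct lag sum to round-off). `C(0)`
#' is 1 by construction. The tau average at lag t runs over the n - t
#' available origins.
#'
#' @param series a [time_series()], numeric vector, or matrix
#' @param dt sampling interval when `series` is not a time_series
#' @return data.frame(time, acf) with `time` in ps
#' @export
autocorrelation <- function(series, dt = 1) {
  if (!inherits(series, "time_series")) series <- time_series(series, dt)
  q <- series$values
  n <- nrow(q)
  if (n < 2) stop("series too short for correlation")
  norm0 <- sum(q^2)
  if (norm0 == 0) stop("all-zero series: normalisation undefined")
  npad <- 2^ceiling(log2(2 * n))
  raw <- numeric(n)
  for (c_i in seq_len(ncol(q))) {
    z <- c(q[, c_i], rep(0, npad - n))
    F <- stats::fft(z)
    r <- Re(stats::fft(F * Conj(F), inverse = TRUE)) / npad
    raw <- raw + r[1:n]
  }
  counts <- n - (0:(n - 1))
  cc <- (raw / counts) / (raw[1] / n)
  data.frame(time = (0:(n - 1)) * series$dt, acf = cc)
}

#' Spectral density from a truncated autocorrelation function
#'
#' Cosine transform of the initial fraction of the autocorrelation
#' function: `J(omega) = 2 dt (C(0)/2 + sum_{t>0} C(t) cos(omega t))`,
#' using only the first `fraction` of the available lags.
#'
#' @param acf_df data.frame(time, acf) from [autocorrelation()]
#' @param fraction fraction of the autocorrelation to use (default 0.02)
#' @param n_freq number of frequency points
#' @return data.frame(omega, density) with omega in rad/ps up to the
#'   Nyquist angular frequency
#' @export
spectral_density <- function(acf_df, fraction = 0.02, n_freq = 256) {
  stopifnot(fraction > 0, fraction <= 1)
  nlag <- max(2, floor(fraction * nrow(acf_df)))
  tt <- acf_df$time[seq_len(nlag)]
  cc <- acf_df$acf[seq_len(nlag)]
  dt <- if (nlag > 1) tt[2] - tt[1] else 1
  omega <- seq(0, pi / dt, length.out = n_freq)
  dens <- vapply(omega, function(w)
    2 * dt * (cc[1] / 2 + sum(cc[-1] * cos(w * tt[-1]))), numeric(1))
  data.frame(omega = omega, density = dens)
}
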