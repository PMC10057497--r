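#' Analytic signal via the discrete Hilbert transform
#'
#' Forms the analytic signal `x + i * H(x)` of a real series using the
#' frequency-domain construction: positive frequencies doubled, negative
#' frequencies zeroed.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  stopifnot(n >= 2, all(is.finite(x)))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Zero-lag Butterworth low-pass with mirror padding
#'
#' 2nd-order Butterworth applied forward and backward (effective 4th order,
#' zero phase). Series are mirror-extended about their endpoints before
#' filtering so the zero-initial-condition pass does not ring at the edges,
#' then cropped.
#'
#' @param x numeric vector.
#' @param cutoff_hz cutoff frequency (Hz).
#' @param fs sampling rate (Hz).
#' @return filtered vector, same length as `x`.
#' @keywords internal
lowpass <- function(x, cutoff_hz, fs) {
  n <- length(x)
  if (is.null(cutoff_hz)) return(x)
  stopifnot(cutoff_hz > 0, cutoff_hz < fs / 2)
  pad <- min(n - 1L, max(20L, ceiling(3 * fs / cutoff_hz)))
  # mirror about the end points without duplicating them
  xe <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  y <- signal::filtfilt(bf, xe)
  y[(pad + 1):(pad + n)]
}

# Central-difference derivative of a vector sampled at rate fs;
# one-sided differences at the ends.
deriv_central <- function(x, fs) {
  n <- length(x)
  stopifnot(n >= 3)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d
}

# Linear resampling of y (sampled at 1..n) onto n_out equally spaced
# points spanning the full extent; endpoints are preserved exactly.
resample_linear <- function(y, n_out) {
  n <- length(y)
  stopifnot(n >= 2, n_out >= 2)
  approx(seq_len(n), y, xout = seq(1, n, length.out = n_out))$y
}

# Run-length clusters of a logical vector: tibble(start, end), 1-based
# inclusive indices of maximal TRUE runs.
logical_clusters <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep])
}
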