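# Shared signal-processing primitives: Gaussian kernel smoothing, analytic
# signal, zero-phase FIR application, Slepian tapers. Internal.

#' Gaussian kernel smoothing on a regularly sampled series
#'
#' Convolves `x` with a discrete Gaussian kernel of standard deviation
#' `sd` (in samples), truncated at 4 SD, with reflective edge handling so
#' that a constant series passes through unchanged.
#'
#' If `x` contains `NA`s (e.g. unvisited spatial bins) normalized
#' convolution is used: the kernel mass falling on missing samples is
#' renormalized away, and bins with no valid mass in reach stay `NA`.
#'
#' @param x numeric vector.
#' @param sd kernel standard deviation in samples; `sd <= 0` returns `x`.
#' @return smoothed numeric vector, same length as `x`.
#' @keywords internal
gauss_smooth <- function(x, sd) {
  n <- length(x)
  if (sd <= 0 || n < 2L) return(x)
  half <- max(1L, ceiling(4 * sd))
  k <- stats::dnorm(seq(-half, half), sd = sd)
  k <- k / sum(k)
  # centered full convolution; stats::filter for small kernels, padded FFT
  # otherwise (power-of-two length avoids mixed-radix worst cases)
  conv_mid <- function(z) {
    if (length(k) <= 256L) {
      as.numeric(stats::filter(z, k, sides = 2))[(half + 1L):(length(z) - half)]
    } else {
      m <- length(z) + length(k) - 1L
      nfft <- stats::nextn(m, 2)
      y <- Re(stats::fft(stats::fft(c(z, numeric(nfft - length(z)))) *
                         stats::fft(c(k, numeric(nfft - length(k)))),
              inverse = TRUE)) / nfft
      y[(2L * half + 1L):(2L * half + (length(z) - 2L * half))]
    }
  }
  refl <- function(z) c(z[pmin(n, (half + 1L):2L)], z,
                        z[pmax(1L, (n - 1L):(n - half))])
  if (!anyNA(x)) return(conv_mid(refl(x)))
  valid <- !is.na(x)
  num <- conv_mid(refl(ifelse(valid, x, 0)))
  den <- conv_mid(refl(as.numeric(valid)))
  out <- ifelse(den > 1e-12, num / den, NA_real_)
  out[!valid] <- NA_real_
  out
}

#' Analytic signal via the frequency-domain Hilbert construction
#'
#' @param x real numeric vector.
#' @return complex vector; `Mod()` of it is the envelope.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Design a Kaiser-window FIR band-pass filter
#'
#' Linear-phase FIR design via `signal::fir1` with a Kaiser window.
#'
#' @param order filter order (taps = order + 1).
#' @param band length-2 numeric, pass band in Hz (use `c(0, f)` for low-pass).
#' @param fs sampling rate, Hz.
#' @param beta Kaiser shape parameter.
#' @return numeric vector of filter taps.
#' @keywords internal
fir_design <- function(order, band, fs, beta = 5) {
  nyq <- fs / 2
  stopifnot(order >= 2, all(band >= 0), max(band) < nyq)
  w <- signal::kaiser(order + 1L, beta)
  if (band[1] <= 0) {
    taps <- signal::fir1(order, band[2] / nyq, type = "low", window = w)
  } else {
    taps <- signal::fir1(order, band / nyq, type = "pass", window = w)
  }
  as.numeric(taps)
}

#' Apply a symmetric FIR filter with zero phase shift
#'
#' For linear-phase (symmetric) taps a single pass plus compensation of the
#' constant group delay (order/2 samples) is exactly zero-phase, so the
#' forward-backward trick is unnecessary. Convolution is done in the
#' frequency domain; edges are handled by reflective padding of one filter
#' length.
#'
#' @param x numeric signal.
#' @param taps symmetric FIR taps (odd or even length).
#' @return filtered signal, same length as `x`.
#' @keywords internal
filt_zerophase <- function(x, taps) {
  n <- length(x)
  L <- length(taps)
  if (n <= 2L * L) stop("signal shorter than twice the filter length")
  pad <- L
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  m <- length(xp) + L - 1L
  nfft <- stats::nextn(m, 2)
  y <- Re(stats::fft(stats::fft(c(xp, numeric(nfft - length(xp)))) *
                     stats::fft(c(taps, numeric(nfft - L))), inverse = TRUE)) / nfft
  gd <- (L - 1) / 2           # group delay of a symmetric FIR
  idx <- pad + seq_len(n) + gd
  if (gd %% 1 == 0) y[idx] else stats::approx(seq_along(y), y, xout = idx)$y
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed as eigenvectors of the standard symmetric tridiagonal matrix
#' whose eigenvectors coincide with the DPSS (Percival & Walden
#' formulation), ordered by decreasing eigenvalue and normalized to unit
#' energy.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers.
#' @return n x k matrix, one taper per column.
#' @keywords internal
dpss_tapers <- function(n, nw = 2, k = 3) {
  stopifnot(n > 2L * k, nw > 0)
  w <- nw / n
  t <- 0:(n - 1L)
  dg <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  od <- (1:(n - 1L)) * ((n - 1L):1L) / 2
  A <- diag(dg)
  A[cbind(1:(n - 1L), 2:n)] <- od
  A[cbind(2:n, 1:(n - 1L))] <- od
  e <- eigen(A, symmetric = TRUE)
  tp <- e$vectors[, seq_len(k), drop = FALSE]
  # sign convention: positive mean for symmetric tapers
  for (j in seq_len(k)) {
    s <- sum(tp[, j])
    if ((j %% 2L == 1L && s < 0) ||
        (j %% 2L == 0L && sum(tp[seq_len(n %/% 2L), j]) < 0)) tp[, j] <- -tp[, j]
    tp[, j] <- tp[, j] / sqrt(sum(tp[, j]^2))
  }
  tp
}

#' Maximal runs of TRUE in a logical vector
#'
#' @return data.frame with columns `start`, `end` (inclusive indices),
#'   zero rows if no run.
#' @keywords internal
true_runs <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
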