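# LFP conditioning, Welch PSD, theta phase and spike phase-locking.

#' Construct an LFP signal
#'
#' @param samples numeric vector of samples (arbitrary units or uV).
#' @param fs_hz sampling rate, Hz.
#' @param channel_id channel label.
#' @param t0 session time of the first sample, seconds (default 0).
#' @return object of class `lfp_signal`.
#' @export
lfp_signal <- function(samples, fs_hz, channel_id = "ch1", t0 = 0) {
  stopifnot(fs_hz > 0, is.numeric(samples))
  structure(list(samples = as.numeric(samples), fs_hz = fs_hz,
                 channel_id = channel_id, t0 = t0),
            class = "lfp_signal")
}

#' @export
print.lfp_signal <- function(x, ...) {
  cat(sprintf("<lfp_signal> %s: %d samples @ %.1f Hz (%.1f s from t0=%.1f)\n",
              x$channel_id, length(x$samples), x$fs_hz,
              length(x$samples) / x$fs_hz, x$t0))
  invisible(x)
}

#' Sample times of an LFP signal
#' @param lfp an [lfp_signal()].
#' @return numeric vector of sample times, seconds.
#' @export
lfp_times <- function(lfp) lfp$t0 + (seq_along(lfp$samples) - 1L) / lfp$fs_hz

#' Anti-aliased downsampling of a wide-band LFP
#'
#' A zero-phase FIR low-pass with cut-off at half the target sampling
#' rate is applied before decimation, preventing aliasing distortion.
#' The canonical use is reducing a 32556 Hz wide-band recording by a
#' factor of 20 to 1627.8 Hz for all spectral analyses.
#'
#' @param lfp an [lfp_signal()].
#' @param factor integer decimation factor (default 20).
#' @param order FIR order for the anti-aliasing low-pass (default 200).
#' @return an [lfp_signal()] at `fs_hz / factor`.
#' @export
downsample_lfp <- function(lfp, factor = 20, order = 200) {
  if (factor < 1) stop("decimation factor must be >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(lfp)
  taps <- fir_design(order, c(0, lfp$fs_hz / (2 * factor) * 0.9), lfp$fs_hz,
                     beta = 5)
  y <- filt_zerophase(lfp$samples, taps)
  lfp_signal(y[seq(1L, length(y), by = factor)], lfp$fs_hz / factor,
             lfp$channel_id, lfp$t0)
}

#' Welch power spectral density with delta-band normalization
#'
#' Averaged modified periodograms (Hamming window) over sliding
#' segments. When a velocity trace is supplied, only segments whose
#' midpoint running speed is at least `vmin` cm/s are retained, so the
#' spectrum reflects exploratory movement. The averaged PSD is
#' normalized by its own mean power in the delta band (1-3 Hz), making
#' curves comparable across animals despite electrode impedance and
#' position differences.
#'
#' @param lfp an [lfp_signal()] (typically at 1627.8 Hz).
#' @param vel optional [compute_velocity()] trace on the same time base.
#' @param win segment length in samples (default 2048, i.e. 1.26 s at
#'   1627.8 Hz).
#' @param overlap fractional overlap between segments (default 0.5).
#' @param nfft FFT length, zero-padded (default 4096, i.e. 2.52 s).
#' @param vmin speed threshold, cm/s (default 2).
#' @param norm_band band whose mean power is normalized to 1 (default
#'   `c(1, 3)` Hz); `NULL` skips normalization.
#' @return list with `freq_hz`, `power_norm`, `power_raw` (units^2/Hz),
#'   `n_segments`.
#' @export
welch_psd <- function(lfp, vel = NULL, win = 2048, overlap = 0.5,
                      nfft = 4096, vmin = 2, norm_band = c(1, 3)) {
  x <- lfp$samples
  fs <- lfp$fs_hz
  step <- max(1L, round(win * (1 - overlap)))
  starts <- seq(1L, length(x) - win + 1L, by = step)
  if (!length(starts)) stop("signal shorter than one Welch segment")
  if (!is.null(vel)) {
    mid_t <- lfp$t0 + (starts - 1L + win / 2) / fs
    v <- stats::approx(vel$t, vel$speed, xout = mid_t, rule = 2)$y
    starts <- starts[v >= vmin]
    if (!length(starts)) stop("no Welch segments above the speed threshold")
  }
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(win - 1L)) / (win - 1L))  # Hamming
  U <- sum(w^2)
  nkeep <- nfft %/% 2L + 1L
  acc <- numeric(nkeep)
  for (s in starts) {
    seg <- (x[s:(s + win - 1L)] - mean(x[s:(s + win - 1L)])) * w
    X <- stats::fft(c(seg, numeric(nfft - win)))
    acc <- acc + Mod(X[seq_len(nkeep)])^2
  }
  psd <- acc / (length(starts) * fs * U)
  psd[2:(nkeep - 1L)] <- 2 * psd[2:(nkeep - 1L)]   # one-sided
  freq <- (seq_len(nkeep) - 1L) * fs / nfft
  power_norm <- psd
  if (!is.null(norm_band)) {
    sel <- freq >= norm_band[1] & freq <= norm_band[2]
    power_norm <- psd / mean(psd[sel])
  }
  list(freq_hz = freq, power_norm = power_norm, power_raw = psd,
       n_segments = length(starts))
}

#' Instantaneous theta phase by peak/trough interpolation
#'
#' The LFP is band-pass filtered in the theta band with a zero-phase
#' FIR; peaks and troughs of the filtered trace are assigned phases of 0
#' and 180 degrees, and phase is linearly interpolated in time between
#' successive extrema. Because each half-cycle is interpolated
#' independently, the phase estimate is not biased by theta wave
#' asymmetry.
#'
#' @param lfp an [lfp_signal()] at the analysis rate.
#' @param band theta band, Hz (default `c(6, 12)`).
#' @param order FIR order; the default (1650 at 1627.8 Hz, scaled with
#'   fs) gives at least 40 dB attenuation at 3 and 20 Hz.
#' @return object of class `theta_phase`: list with `phase_deg` per
#'   sample (`NA` before the first/after the last extremum), `t` sample
#'   times, `peaks_t`, `troughs_t`, `extrema_t`, `extrema_phase`, and
#'   the `filtered` trace.
#' @export
theta_phase <- function(lfp, band = c(6, 12), order = NULL) {
  fs <- lfp$fs_hz
  if (is.null(order)) {
    order <- 2L * round(fs / 2)   # ~1 s of taps; narrow transition at 3 Hz
    order <- min(order, floor(length(lfp$samples) / 3) * 2L - 2L)
  }
  taps <- fir_design(order, band, fs, beta = 6)
  f <- filt_zerophase(lfp$samples, taps)
  d <- diff(f)
  pk <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  tr <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  if (!length(pk) || !length(tr)) stop("no theta extrema found (flat signal?)")
  ext <- rbind(data.frame(i = pk, ph = 0), data.frame(i = tr, ph = 180))
  ext <- ext[sort.list(ext$i), ]
  # enforce strict peak/trough alternation: collapse same-type runs to the
  # more extreme sample
  keep <- rep(TRUE, nrow(ext))
  j <- 1L
  for (k in seq_len(nrow(ext))[-1L]) {
    if (ext$ph[k] == ext$ph[j]) {
      better <- if (ext$ph[k] == 0) f[ext$i[k]] > f[ext$i[j]]
                else f[ext$i[k]] < f[ext$i[j]]
      if (better) { keep[j] <- FALSE; j <- k } else keep[k] <- FALSE
    } else j <- k
  }
  ext <- ext[keep, ]
  tt <- lfp_times(lfp)
  # unwrapped phase at extrema: 0,180,360,540,... in alternation
  unph <- ext$ph[1L] + 180 * (seq_len(nrow(ext)) - 1L)
  phase <- rep(NA_real_, length(tt))
  inside <- seq(ext$i[1L], ext$i[nrow(ext)])
  phase[inside] <- stats::approx(tt[ext$i], unph, xout = tt[inside])$y %% 360
  structure(list(phase_deg = phase, t = tt,
                 peaks_t = tt[ext$i[ext$ph == 0]],
                 troughs_t = tt[ext$i[ext$ph == 180]],
                 extrema_t = tt[ext$i], extrema_phase_unwrapped = unph,
                 filtered = f, fs_hz = fs, band = band),
            class = "theta_phase")
}

#' Theta phase at arbitrary event times
#'
#' Linear interpolation of the unwrapped extremum-anchored phase at the
#' given times (e.g. spike times); times outside the first/last extremum
#' give `NA`.
#'
#' @param tp a [theta_phase()] object.
#' @param times numeric, seconds.
#' @return phases in degrees, `[0, 360)`.
#' @export
phase_at_times <- function(tp, times) {
  ph <- stats::approx(tp$extrema_t, tp$extrema_phase_unwrapped, xout = times)$y
  ph %% 360
}

#' Circular mean, resultant length and Rayleigh test
#'
#' Standard first-trigonometric-moment statistics for angular data: the
#' mean direction, the mean resultant length r in \[0, 1\], and the
#' Rayleigh test of uniformity (p-value via the standard large-sample
#' approximation, accurate for n >= 10).
#'
#' @param theta_deg angles in degrees.
#' @return list with `mean_deg`, `r`, `n`, `p`.
#' @export
rayleigh_test <- function(theta_deg) {
  th <- theta_deg[!is.na(theta_deg)] * pi / 180
  n <- length(th)
  if (!n) return(list(mean_deg = NA_real_, r = NA_real_, n = 0L, p = NA_real_))
  C <- mean(cos(th)); S <- mean(sin(th))
  r <- sqrt(C^2 + S^2)
  R <- n * r
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(mean_deg = (atan2(S, C) * 180 / pi) %% 360, r = r, n = n,
       p = min(1, p))
}

#' Theta phase-locking statistics of a unit
#'
#' Spike theta phases (interpolated at spike times) are restricted to
#' periods of running above `vmin` cm/s and summarized as a 36-bin
#' (10 degree) firing-probability histogram, the circular mean
#' (preferred phase), the mean resultant length, the Rayleigh test of
#' uniformity, the Kullback-Leibler divergence of the histogram from
#' uniform (nats), and the modulation index MI = KL / ln(36) in
#' \[0, 1\] (0 for a uniform histogram, 1 when all spikes fall in one
#' bin).
#'
#' @param spikes a [spike_train()] or numeric spike times.
#' @param tp a [theta_phase()] object.
#' @param vel optional [compute_velocity()] trace for speed gating.
#' @param vmin speed threshold, cm/s (default 6).
#' @param n_bins histogram bins (default 36).
#' @param alpha Rayleigh significance level (default 0.05).
#' @return list with `hist` (probabilities, sums to 1), `bin_deg` (bin
#'   centers), `preferred_phase_deg`, `resultant_r`, `rayleigh_p`,
#'   `kl_div`, `mod_index`, `significant`, `n_spikes`, `low_n` (TRUE
#'   when fewer than 10 phase-assigned spikes).
#' @export
spike_phase_stats <- function(spikes, tp, vel = NULL, vmin = 6,
                              n_bins = 36, alpha = 0.05) {
  st <- if (inherits(spikes, "spike_train")) spikes$t else as.numeric(spikes)
  if (!is.null(vel)) {
    v <- stats::approx(vel$t, vel$speed, xout = st, rule = 2)$y
    st <- st[v >= vmin]
  }
  ph <- phase_at_times(tp, st)
  ph <- ph[!is.na(ph)]
  if (!length(ph)) stop("no spikes with defined theta phase above the speed threshold")
  breaks <- seq(0, 360, length.out = n_bins + 1L)
  cnt <- graphics::hist(ph, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE)$counts
  h <- cnt / sum(cnt)
  rl <- rayleigh_test(ph)
  pos <- h > 0
  kl <- sum(h[pos] * log(h[pos] * n_bins))
  list(hist = h, bin_deg = breaks[-1] - 180 / n_bins,
       preferred_phase_deg = rl$mean_deg, resultant_r = rl$r,
       rayleigh_p = rl$p, kl_div = kl, mod_index = kl / log(n_bins),
       significant = isTRUE(rl$p < alpha), n_spikes = length(ph),
       low_n = length(ph) < 10L)
}
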