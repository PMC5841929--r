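# Downsampling, Welch PSD, theta phase extraction, phase-locking stats.

test_that("anti-aliased decimation preserves passband and kills stopband", {
  fs <- 32556
  t <- seq(0, 1.5, by = 1 / fs)
  ds <- downsample_lfp(lfp_signal(sin(2 * pi * 10 * t), fs), 20)
  expect_equal(ds$fs_hz, 1627.8)
  mid <- 500:2000
  expect_lt(abs(max(abs(ds$samples[mid])) - 1), 0.01)

  # 1500 Hz is above the new Nyquist: attenuated by >= 40 dB
  hi <- downsample_lfp(lfp_signal(sin(2 * pi * 1500 * t), fs), 20)
  expect_lt(20 * log10(max(abs(hi$samples[mid]))), -40)

  expect_error(downsample_lfp(lfp_signal(rnorm(100), fs), 0), "factor")
})

test_that("Welch PSD is delta-normalized and localizes spectral peaks", {
  fs <- 1627.8
  t <- seq(0, 40, by = 1 / fs)
  set.seed(61)
  x <- sin(2 * pi * 8 * t) + rnorm(length(t))
  ps <- welch_psd(lfp_signal(x, fs))
  expect_equal(mean(ps$power_norm[ps$freq_hz >= 1 & ps$freq_hz <= 3]), 1,
               tolerance = 1e-9)
  expect_lt(abs(ps$freq_hz[which.max(ps$power_norm)] - 8), 0.5)

  # white noise: flat on log-log over 1-100 Hz
  pw <- welch_psd(lfp_signal(rnorm(length(t)), fs))
  sel <- pw$freq_hz >= 1 & pw$freq_hz <= 100
  b <- coef(lm(log10(pw$power_raw[sel]) ~ log10(pw$freq_hz[sel])))[2]
  expect_lt(abs(b), 0.05)

  # velocity gating drops immobile segments
  vel <- structure(data.frame(t = t, speed = ifelse(t < 20, 0, 10)),
                   class = c("velocity_trace", "data.frame"))
  gated <- welch_psd(lfp_signal(x, fs), vel)
  expect_lt(gated$n_segments, ps$n_segments * 0.6)
  still <- structure(data.frame(t = t, speed = rep(0, length(t))),
                     class = c("velocity_trace", "data.frame"))
  expect_error(welch_psd(lfp_signal(x, fs), still), "speed")
})

test_that("theta phase anchors extrema at 0/180 and advances linearly", {
  fs <- 1627.8
  t <- seq(0, 20, by = 1 / fs)
  tp <- theta_phase(lfp_signal(cos(2 * pi * 8 * t), fs))
  # one cycle per 125 ms
  expect_lt(abs(mean(diff(tp$peaks_t)) - 0.125), 1e-3)
  # interpolated phase at detected peaks/troughs is exactly 0/180
  pk_ph <- phase_at_times(tp, tp$peaks_t[5:100])
  expect_true(all(pmin(pk_ph, 360 - pk_ph) < 1e-6))
  tr_ph <- phase_at_times(tp, tp$troughs_t[5:100])
  expect_true(all(abs(tr_ph - 180) < 1e-6))

  # asymmetric theta (frequency-modulated): anchoring still exact
  inst <- 2 * pi * (8 * t + 0.8 * sin(2 * pi * 0.7 * t))
  tpa <- theta_phase(lfp_signal(cos(inst), fs))
  pk2 <- phase_at_times(tpa, tpa$peaks_t[5:50])
  expect_true(all(pmin(pk2, 360 - pk2) < 1e-6))

  # phase evaluated at random times on a sine is uniform (equal time in
  # the linear-phase half-cycles)
  set.seed(62)
  ph <- phase_at_times(tp, runif(4e5, 1, 19))
  h <- hist(ph, breaks = seq(0, 360, 10), plot = FALSE)$counts
  expect_lt(mean(abs(h / sum(h) - 1 / 36)) * 36, 0.02)

  expect_error(theta_phase(lfp_signal(rep(0, 40000), fs)), "extrema|flat")
})

test_that("phase-locking statistics recover delta, uniform and von Mises cases", {
  fs <- 1627.8
  t <- seq(0, 30, by = 1 / fs)
  tp <- theta_phase(lfp_signal(cos(2 * pi * 8 * t), fs))

  # all spikes at 85 degrees (placed by inverting the peak-to-trough
  # interpolation, so they land mid-bin): r = 1, MI = 1
  pk <- tp$peaks_t[5:200]
  next_tr <- vapply(pk, function(p) tp$troughs_t[tp$troughs_t > p][1],
                    numeric(1))
  spikes_85 <- pk + (85 / 180) * (next_tr - pk)
  st <- spike_phase_stats(spikes_85, tp)
  expect_lt(abs(st$preferred_phase_deg - 85), 2)
  expect_gt(st$resultant_r, 0.99)
  expect_equal(st$mod_index, 1, tolerance = 1e-6)
  expect_true(st$significant)
  expect_equal(sum(st$hist), 1, tolerance = 1e-12)

  # uniform spikes: no locking
  set.seed(63)
  st0 <- spike_phase_stats(runif(2000, 1, 29), tp)
  expect_lt(st0$resultant_r, 0.05)
  expect_lt(st0$mod_index, 0.01)
  expect_gt(st0$rayleigh_p, 0.001)

  # von Mises kappa = 1 at 180 deg: r ~ I1(1)/I0(1) = 0.446, mean ~ 180
  rvm <- function(n, mu, k) {
    a <- 1 + sqrt(1 + 4 * k^2); b <- (a - sqrt(2 * a)) / (2 * k)
    rho <- (1 + b^2) / (2 * b)
    out <- numeric(n); i <- 1
    while (i <= n) {
      u <- runif(3); z <- cos(pi * u[1]); f <- (1 + rho * z) / (rho + z)
      c0 <- k * (rho - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(f); i <- i + 1
      }
    }
    out %% (2 * pi)
  }
  target <- rvm(1000, pi, 1) / (2 * pi)          # cycle fraction
  # place spikes at the target phase within successive cycles
  cyc2 <- rep(tp$peaks_t[5:800], length.out = 1000)
  stv <- spike_phase_stats(sort(cyc2 + target * 0.125), tp)
  expect_lt(abs(stv$preferred_phase_deg - 180), 10)
  expect_lt(abs(stv$resultant_r - besselI(1, 1) / besselI(1, 0)), 0.05)
})

test_that("modulation index is bounded and zero only at uniformity", {
  fs <- 1627.8
  t <- seq(0, 10, by = 1 / fs)
  tp <- theta_phase(lfp_signal(cos(2 * pi * 8 * t), fs))
  set.seed(64)
  st <- spike_phase_stats(runif(500, 1, 9), tp)
  expect_gte(st$mod_index, 0)
  expect_lte(st$mod_index, 1)
  expect_gte(st$kl_div, 0)
})
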