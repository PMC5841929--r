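# Ripple envelope, event detection, MUA gating, frequency, sweeps.

make_packet_lfp <- function(centers, amp, dur_s = 0.08, freq = 150,
                            total_s = 30, fs = 1627.8, noise_sd = 0.2,
                            seed = 71) {
  set.seed(seed)
  t <- seq(0, total_s, by = 1 / fs)
  x <- rnorm(length(t)) * noise_sd
  for (ct in centers) {
    i0 <- round((ct - dur_s / 2) * fs) + 1L
    m <- round(dur_s * fs)
    u <- (0:(m - 1L)) / (m - 1L)
    tuk <- rep(1, m)
    tuk[u < 0.25] <- 0.5 * (1 - cos(pi * u[u < 0.25] / 0.25))
    tuk[u > 0.75] <- 0.5 * (1 - cos(pi * (1 - u[u > 0.75]) / 0.25))
    x[i0:(i0 + m - 1L)] <- x[i0:(i0 + m - 1L)] +
      amp * tuk * cos(2 * pi * freq * (t[i0:(i0 + m - 1L)] - ct))
  }
  lfp_signal(x, fs)
}

test_that("ripple-band envelope tracks amplitude and rejects the stopband", {
  fs <- 1627.8
  t <- seq(0, 10, by = 1 / fs)
  env <- ripple_envelope(lfp_signal(0.7 * cos(2 * pi * 150 * t), fs))
  mid <- 3000:13000
  expect_lt(abs(mean(env$env[mid]) - 0.7) / 0.7, 0.05)

  # silence and out-of-band signal leave a near-zero envelope
  silent <- ripple_envelope(lfp_signal(rep(1e-9, length(t)), fs))
  expect_lt(max(silent$env), 1e-6)
  # 60 Hz sits in the 69-tap filter's lower transition band: strongly
  # attenuated relative to the passband, though not to zero
  slow <- ripple_envelope(lfp_signal(cos(2 * pi * 60 * t), fs))
  expect_lt(mean(slow$env[mid]), 0.15)
  mains <- ripple_envelope(lfp_signal(cos(2 * pi * 40 * t), fs))
  expect_lt(mean(mains$env[mid]), 0.02)

  expect_error(ripple_envelope(lfp_signal(rnorm(300), fs)), "filter length")
})

test_that("threshold rule detects strong packets and rejects brief ones", {
  lfp <- make_packet_lfp(centers = c(10, 20), amp = 1.2)
  env <- ripple_envelope(lfp)
  ev <- detect_ripples(env)
  expect_equal(nrow(ev), 2L)
  expect_true(all(abs(ev$t_peak - c(10, 20)) < 0.05))
  expect_true(all(ev$t_start < ev$t_peak & ev$t_peak < ev$t_end))
  expect_true(all(ev$core_dur_ms > 30))

  # a moderate 20 ms packet fails the >30 ms core rule (its smoothed
  # envelope cannot stay above threshold long enough)
  short <- make_packet_lfp(centers = 15, amp = 0.25, dur_s = 0.02)
  expect_equal(nrow(detect_ripples(ripple_envelope(short))), 0L)
})

test_that("event counts nest monotonically across detection thresholds", {
  lfp <- make_packet_lfp(centers = c(5, 12, 19, 26), amp = 0.9)
  env <- ripple_envelope(lfp)
  counts <- vapply(c(2, 3, 6), function(th)
    nrow(detect_ripples(env, ripple_params(threshold_sd = th))), integer(1))
  expect_true(all(diff(counts) <= 0))
  # every 6 SD event core lies inside some 3 SD event
  e6 <- detect_ripples(env, ripple_params(threshold_sd = 6))
  e3 <- detect_ripples(env, ripple_params(threshold_sd = 3))
  if (nrow(e6)) {
    ok <- vapply(seq_len(nrow(e6)), function(k)
      any(e3$t_start <= e6$core_start[k] & e3$t_end >= e6$core_end[k]),
      logical(1))
    expect_true(all(ok))
  }
})

test_that("MUA gating keeps spiking-coincident events and drops artifacts", {
  lfp <- make_packet_lfp(centers = c(10, 20), amp = 1.2)
  env <- ripple_envelope(lfp)
  ev <- detect_ripples(env)
  set.seed(72)
  # background spiking plus a strong population burst at the first packet
  spikes <- lapply(1:8, function(u) {
    bg <- sort(runif(30, 0, 30))
    sort(c(bg, runif(6, 9.96, 10.04)))
  })
  gated <- mua_gate(ev, spikes, c(0, 30))
  expect_equal(nrow(gated), 1L)
  expect_lt(abs(gated$t_peak - 10), 0.05)

  # pure-LFP artifact packets with no spikes anywhere: nothing survives
  none <- mua_gate(ev, list(sort(runif(20, 0, 8))), c(0, 30))
  expect_equal(nrow(none), 0L)
})

test_that("multitaper peak frequency resolves packet carriers", {
  for (f0 in c(150, 200)) {
    lfp <- make_packet_lfp(centers = 10, amp = 1.2, freq = f0, total_s = 20)
    env <- ripple_envelope(lfp)
    ev <- detect_ripples(env)
    expect_gte(nrow(ev), 1L)
    expect_lt(abs(ripple_frequency(ev[1, ], env) - f0), 5)
  }
  # two-component packet: the dominant component wins
  fs <- 1627.8
  t <- seq(0, 20, by = 1 / fs)
  set.seed(73)
  x <- rnorm(length(t)) * 0.1
  i <- round(10 * fs):round(10.1 * fs)
  x[i] <- x[i] + 0.4 * cos(2 * pi * 120 * t[i]) + 1.0 * cos(2 * pi * 180 * t[i])
  env <- ripple_envelope(lfp_signal(x, fs))
  ev <- detect_ripples(env)
  expect_lt(abs(ripple_frequency(ev[1, ], env) - 180), 5)
})

test_that("ripple metrics and unit statistics summarize events correctly", {
  ev <- data.frame(t_start = seq(0, 290, by = 10) + 0.0,
                   t_end = seq(0, 290, by = 10) + 0.1,
                   t_peak = seq(0, 290, by = 10) + 0.05,
                   duration_ms = 100, amplitude_sd = 5,
                   peak_freq_hz = 150)
  m <- ripple_metrics(ev, epoch_duration_s = 30 * 60)
  expect_equal(m$rate_per_min, 1.0)
  expect_equal(m$mean_iri_s, 10)

  # silent unit: participation 0; unit firing in every event: 1
  silent <- numeric(0)
  busy <- ev$t_peak
  us <- ripple_unit_stats(ev, list(silent, busy))
  expect_equal(us$per_unit$participation, c(0, 1))
  expect_equal(us$per_unit$spikes_per_ripple, c(0, 1))
  expect_equal(sum(us$participation_hist$prop_cells), 1)

  # Poisson unit at rate r over events of duration d: participation
  # ~ 1 - exp(-r d)
  set.seed(74)
  r <- 5; d <- 0.1
  pois <- sort(runif(rpois(1, r * 300), 0, 300))
  up <- ripple_unit_stats(ev, list(pois))$per_unit
  expect_lt(abs(up$participation - (1 - exp(-r * d))), 0.08)
})

test_that("MUA-only events recover injected population bursts", {
  set.seed(75)
  # background 1 Hz/unit over 60 s plus three dense population bursts
  bursts_at <- c(15, 30, 45)
  spikes <- lapply(1:10, function(u) {
    bg <- runif(60, 0, 60)
    sort(c(bg, unlist(lapply(bursts_at, function(b) runif(8, b, b + 0.08)))))
  })
  ev <- detect_events_mua_only(spikes, c(0, 60))
  expect_equal(nrow(ev), 3L)
  expect_true(all(abs(ev$t_peak - (bursts_at + 0.04)) < 0.08))
  expect_equal(nrow(detect_events_mua_only(list(numeric(0)), c(0, 60))), 0L)
})

test_that("full synthetic detection: recall, precision, amplitude ordering", {
  ses <- default_session()
  an <- default_analysis()
  tr <- ses$truth$ripples
  ev <- an$ripple_events
  hit <- vapply(seq_len(nrow(tr)), function(k)
    any(ev$t_start <= tr$t_end[k] & ev$t_end >= tr$t_start[k]), logical(1))
  expect_gt(mean(hit), 0.85)
  matched <- vapply(seq_len(nrow(ev)), function(k)
    any(tr$t_start <= ev$t_end[k] & tr$t_end >= ev$t_start[k]), logical(1))
  expect_gt(mean(matched), 0.85)

  # MUA-only detection overlaps the LFP-gated events substantially
  rest <- ses$epochs[ses$epochs$epoch == "rest", ]
  mu <- detect_events_mua_only(an$included_units |>
                                 (\(ids) ses$spikes[as.integer(ids)])(),
                               c(rest$t_start, rest$t_end))
  inter <- sum(vapply(seq_len(nrow(ev)), function(k)
    any(mu$t_start <= ev$t_end[k] & mu$t_end >= ev$t_start[k]), logical(1)))
  expect_gt(inter / max(1, nrow(ev)), 0.8)
})

test_that("detected amplitude rises with injected packet amplitude", {
  amps <- vapply(c(4, 6, 9), function(a) {
    cfg <- synth_config(seed = 15, n_units = 8, n_laps = 2,
                        rest_duration_s = 60, ripple_amp_sd = a)
    ses <- simulate_session(cfg)
    rest <- ses$epochs[2, ]
    lt <- lfp_times(ses$lfp)
    sel <- lt >= rest$t_start & lt < rest$t_end
    env <- ripple_envelope(lfp_signal(ses$lfp$samples[sel], ses$lfp$fs_hz,
                                      t0 = rest$t_start))
    ev <- detect_ripples(env)
    mean(ev$amplitude_sd)
  }, numeric(1))
  expect_true(all(diff(amps) > 0))
})
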