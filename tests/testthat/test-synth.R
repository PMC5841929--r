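# Synthetic session generator: determinism, truth consistency, calibration.

test_that("configuration validation rejects impossible settings", {
  expect_error(synth_config(run_speed_cm_s = 0), "positive")
  expect_error(synth_config(rest_duration_s = -5), "positive")
  expect_error(synth_config(burst_prob = 1.5), "range")
  expect_error(synth_config(amp_attenuation = 0), "range")
  expect_error(synth_config(phase_kappa = -1), "range")
})

test_that("trajectories traverse the track the configured number of times", {
  cfg <- synth_config(seed = 81, n_laps = 10, n_units = 1)
  pos <- generate_trajectory(cfg)
  laps <- detect_laps(pos, track_length_cm = 170)
  expect_equal(nrow(laps), 10L)
  expect_equal(sum(laps$direction == "right"), 5L)
  # speeds near the configured running speed (after the pipeline's
  # position smoothing, which removes tracking-jitter speed)
  vel <- compute_velocity(smooth_positions(pos))
  expect_lt(abs(median(vel$speed) - cfg$run_speed_cm_s), 2)
  expect_true(all(pos$x >= 0 & pos$x <= 170))
})

test_that("identical configurations generate bit-identical sessions", {
  cfg <- synth_config(seed = 82, n_units = 3, n_laps = 2,
                      rest_duration_s = 20)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$position, s2$position)
  expect_identical(s1$lfp$samples, s2$lfp$samples)
  expect_identical(lapply(s1$spikes, `[[`, "t"),
                   lapply(s2$spikes, `[[`, "t"))
  expect_identical(s1$truth, s2$truth)
  # a different seed changes the data
  s3 <- simulate_session(synth_config(seed = 83, n_units = 3, n_laps = 2,
                                      rest_duration_s = 20))
  expect_false(identical(s1$lfp$samples, s3$lfp$samples))
})

test_that("ground truth is internally consistent", {
  ses <- default_session()
  cfg <- ses$config
  rest <- ses$epochs[ses$epochs$epoch == "rest", ]
  tr <- ses$truth$ripples
  # every injected ripple lies inside a rest epoch
  expect_true(all(tr$t_start >= rest$t_start & tr$t_end <= rest$t_end))
  # ripples do not overlap
  expect_true(all(tr$t_start[-1] > tr$t_end[-nrow(tr)]))
  # every spike lies inside the session
  for (s in ses$spikes) {
    expect_true(all(s$t >= 0 & s$t <= max(ses$epochs$t_end)))
    expect_false(is.unsorted(s$t))
    # refractory respected (the QC bound is 2 ms)
    if (length(s$t) > 1) expect_gt(min(diff(s$t)) * 1000, 2)
  }
  # truth bursts: member spikes within the jittered intra-burst ISI bound
  stt <- ses$truth$spike_truth
  for (b in sample(unique(stt$burst_id[stt$burst_id > 0]), 50)) {
    bt <- sort(stt$t[stt$burst_id == b])
    if (length(bt) > 1)
      expect_lte(max(diff(bt)) * 1000, cfg$intra_burst_isi_ms * 1.3 + 1e-6)
  }
})

test_that("unmodulated and burst-free configurations produce null structure", {
  cfg0 <- synth_config(seed = 84, n_units = 3, n_laps = 10, phase_kappa = 0,
                       burst_prob = 0, peak_rate_hz = 20, field_width_cm = 15,
                       directional_gain = 1, rest_duration_s = 60)
  pos <- generate_trajectory(cfg0)
  sp <- generate_spikes(cfg0, pos)
  stt <- sp$truth$spike_truth
  ph <- stt$theta_phase_deg[stt$in_run]
  expect_gt(length(ph), 1000)
  expect_lt(rayleigh_test(ph)$r, 0.05)
  # no injected bursts: at rest-epoch rates, chance chaining is ~0/min
  T_run <- attr(pos, "run_duration_s")
  t1 <- sp$spikes[[1]]$t[sp$spikes[[1]]$t > T_run]
  bs <- burst_statistics(detect_bursts(t1), t1, 60)
  expect_lt(bs$bursts_per_min, 0.5)
})

test_that("empirical unit rates match the analytic tuning expectation", {
  # burst- and theta-free so the expected count is a plain rate integral;
  # negligible refractory so thinning is unbiased
  cfg <- synth_config(seed = 85, n_units = 1, n_laps = 10, burst_prob = 0,
                      phase_kappa = 0, peak_rate_hz = 5,
                      field_center_cm = 85, field_width_cm = 12,
                      refractory_ms = 0.01, rest_duration_s = 10,
                      rest_rate_hz = 1e-6)
  counts <- vapply(0:9, function(k) {
    cfgk <- cfg; cfgk$seed <- cfg$seed + k
    pos <- generate_trajectory(cfgk)
    length(generate_spikes(cfgk, pos)$spikes[[1]]$t)
  }, numeric(1))
  pos <- generate_trajectory(cfg)
  tg <- seq(0, max(pos$t), by = 1e-3)
  xg <- approx(pos$t, pos$x, xout = tg)$y
  expected <- sum(5 * exp(-(xg - 85)^2 / (2 * 144)) *
                    ifelse(c(diff(xg) >= 0, TRUE), 1, cfg$directional_gain)) *
    1e-3
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.05 * expected)
})

test_that("burst amplitudes attenuate within bursts as configured", {
  ses <- default_session()
  stt <- ses$truth$spike_truth
  s1 <- ses$spikes[[1]]
  st1 <- stt[stt$unit == 1, ]
  # align truth rows to the stored train (MUA merge preserved order)
  bids <- unique(st1$burst_id[st1$burst_id > 0])[1:20]
  drops <- vapply(bids, function(b) {
    bt <- st1$t[st1$burst_id == b]
    idx <- match(round(bt, 9), round(s1$t, 9))
    if (anyNA(idx) || length(idx) < 2) return(NA_real_)
    a <- s1$amp[idx, 1]
    mean(a[-1] / a[-length(a)])
  }, numeric(1))
  expect_lt(mean(drops, na.rm = TRUE), 0.95)
  expect_gt(mean(drops, na.rm = TRUE), 0.7)
})
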