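# Rate maps, place fields, spatial information, sparsity, directionality.

toy_map <- function(rate, p_occ = rep(1 / length(rate), length(rate)),
                    occ = rep(1, length(rate))) {
  structure(list(bin_size_cm = 1,
                 bin_centers = seq_along(rate) - 0.5,
                 rate = rate, n_spikes = rate * occ, occ_time_s = occ,
                 p_occ = p_occ, visited = rep(TRUE, length(rate)),
                 mean_rate = sum(p_occ * rate), peak_rate = max(rate),
                 smooth_sd_bins = 1, smooth_mode = "divide-then-smooth"),
            class = "rate_map")
}

test_that("rate maps conserve spike mass and handle silent units", {
  pos <- make_triangle_pos(n_laps = 6)
  vel <- compute_velocity(pos)
  set.seed(41)
  spikes <- sort(runif(400, 0, max(pos$t)))
  map <- compute_rate_map(spikes, pos, vel, track_length_cm = 170)

  expect_equal(sum(map$p_occ), 1, tolerance = 1e-9)
  expect_true(all(map$rate[map$visited] >= 0))
  # total spike mass: sum over bins of rate*occupancy ~ run-epoch spikes
  v_at <- approx(vel$t, vel$speed, xout = spikes)$y
  n_run <- sum(v_at >= 2)
  expect_lt(abs(sum(map$n_spikes) - n_run) / n_run, 0.01)
  # peak of the smoothed map never falls below the mean
  expect_gte(map$peak_rate, map$mean_rate)

  empty <- compute_rate_map(numeric(0), pos, vel, track_length_cm = 170)
  expect_equal(empty$mean_rate, 0)
  expect_true(all(empty$rate[empty$visited] == 0))

  still <- position_trace(pos$t, rep(80, nrow(pos)), pos$y)
  expect_error(compute_rate_map(spikes, still, compute_velocity(still)),
               "occupancy")
})

test_that("place-field width matches the analytic 20%-of-peak width", {
  # Gaussian field, SD 5 bins: width at 20% of peak = 2*5*sqrt(2*ln 5)
  r <- 10 * exp(-((1:170) - 85)^2 / (2 * 25))
  fl <- detect_place_fields(toy_map(r))
  analytic <- 2 * 5 * sqrt(2 * log(5))
  expect_lt(abs(fl$fields$size_bins[fl$main_field] - analytic), 2)
  expect_true(fl$is_place_cell)
  expect_equal(fl$fields$peak_bin[fl$main_field], 85L)

  # sub-threshold peak rate: not a place cell
  expect_false(detect_place_fields(toy_map(r * 0.09))$is_place_cell)

  # a 5-bin field is rejected by the minimum-size criterion
  narrow <- rep(0.01, 170); narrow[83:87] <- 5
  fl5 <- detect_place_fields(toy_map(narrow))
  expect_equal(fl5$fields$size_bins[fl5$main_field], 5L)
  expect_false(fl5$is_place_cell)

  # in-field rate exceeds out-field rate for a real field; SNR positive
  expect_gt(fl$infield_rate, fl$outfield_rate)
  expect_gt(fl$snr, 0)
})

test_that("spatial information follows the Skaggs formula", {
  # hand computation: p = (.5, .5), rates (2, 0) -> mean 1 Hz, SI = 1 bit/s
  expect_equal(spatial_information(toy_map(c(2, 0))), 1.0, tolerance = 1e-12)
  # uniform map carries no information
  expect_equal(spatial_information(toy_map(rep(3.7, 50))), 0, tolerance = 1e-12)
  # silent map: defined as zero
  expect_equal(spatial_information(toy_map(rep(0, 50))), 0)
  # invariant under bin relabeling
  set.seed(42)
  r <- rexp(100)
  expect_equal(spatial_information(toy_map(r)),
               spatial_information(toy_map(sample(r))), tolerance = 1e-12)
  # nonnegative on random maps
  for (k in 1:5) expect_gte(spatial_information(toy_map(rexp(60))), 0)
})

test_that("sparsity has the documented endpoints and plug-in values", {
  expect_equal(map_sparsity(toy_map(rep(2.5, 40))), 0, tolerance = 1e-12)
  # all spikes in one of N equiprobable bins -> 1 - 1/N
  for (N in c(4, 25, 100)) {
    r <- rep(0, N); r[3] <- 8
    expect_equal(map_sparsity(toy_map(r)), 1 - 1 / N, tolerance = 1e-12)
  }
  expect_equal(map_sparsity(toy_map(c(2, 0))), 0.5, tolerance = 1e-12)
  expect_warning(s <- map_sparsity(toy_map(rep(0, 10))), "undefined")
  expect_true(is.na(s))
})

test_that("SI and sparsity sharpen together on narrowing Gaussian fields", {
  # maps normalized to a common mean rate, so sharpening concentrates the
  # same total firing into fewer bins
  vals <- t(vapply(c(40, 20, 10, 5, 2.5), function(sd) {
    r <- exp(-((1:170) - 85)^2 / (2 * sd^2))
    r <- r / mean(r)
    c(spatial_information(toy_map(r)), map_sparsity(toy_map(r)))
  }, numeric(2)))
  expect_true(all(diff(vals[, 1]) > 0))
  expect_true(all(diff(vals[, 2]) > 0))
})

test_that("directionality index matches its formula and edge cases", {
  expect_equal(directionality_index(2, 0), 1)
  expect_equal(directionality_index(1.4, 1.4), 0)
  expect_equal(directionality_index(3, 1), 0.5, tolerance = 1e-12)
  expect_warning(d <- directionality_index(0, 0), "undefined")
  expect_true(is.na(d))
})

test_that("generator tunings are recovered by the full spatial pipeline", {
  cfg <- synth_config(seed = 9, n_units = 4, n_laps = 10,
                      field_center_cm = c(40, 70, 100, 130),
                      directional_gain = 1, rest_duration_s = 30)
  pos <- generate_trajectory(cfg)
  vel <- compute_velocity(pos)
  laps <- detect_laps(pos, track_length_cm = 170)
  sp <- generate_spikes(cfg, pos)
  errs <- vapply(1:4, function(u) {
    met <- spatial_metrics(sp$spikes[[u]], pos, vel, laps,
                           track_length_cm = 170)
    expect_true(met$is_place_cell)
    # direction-independent cells have a low directionality index
    expect_lt(met$di, 0.3)
    abs(met$field_center_cm - cfg$field_center_cm[u])
  }, numeric(1))
  # single 10-lap session: approximate recovery (the seeded studies in
  # the acceptance suite pin the precision)
  expect_lt(mean(errs), 5)
  expect_lt(max(errs), 10)
})

test_that("mean rate of a homogeneous Poisson unit is recovered", {
  pos <- make_triangle_pos(n_laps = 6)
  vel <- compute_velocity(pos)
  set.seed(44)
  dur <- max(pos$t)
  spikes <- sort(runif(rpois(1, 3 * dur), 0, dur))
  map <- compute_rate_map(spikes, pos, vel, track_length_cm = 170)
  expect_lt(abs(map$mean_rate - 3) / 3, 3 / sqrt(3 * dur))
})
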