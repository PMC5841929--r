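# Shared fixtures, built in code. Sessions are memoized across test files
# to keep the suite fast; everything is seeded and deterministic.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# a mid-sized annotated session used by several files
default_session <- function() {
  cached("default_session",
         simulate_session(synth_config(seed = 42, n_units = 12,
                                       rest_duration_s = 90)))
}

default_analysis <- function() {
  cached("default_analysis",
         suppressMessages(analyze_session(default_session())))
}

# clean constant-speed back-and-forth trajectory without jitter
make_triangle_pos <- function(n_laps = 4, L = 170, speed = 15, fs = 30) {
  lap_T <- L / speed
  t <- seq(0, n_laps * lap_T, by = 1 / fs)
  ph <- (t / lap_T) %% 2
  position_trace(t, L * ifelse(ph <= 1, ph, 2 - ph), rep(5, length(t)))
}

# regular spike train helper (times in seconds)
ms <- function(x) x / 1000
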