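# Shared fixtures. Sessions are generated once per test run and memoised here;
# sizes are kept small except where a check genuinely needs trial counts.

.fixture_env <- new.env(parent = emptyenv())

fixture_session <- function(key = "small", config = NULL) {
  if (is.null(.fixture_env[[key]])) {
    cfg <- config %||% laminar_config(n_trials = 40, tasks = "VG", seed = 42)
    .fixture_env[[key]] <- generate_session(cfg)
  }
  .fixture_env[[key]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a rate_waveform directly from a deterministic trial-mean trace plus
# optional per-trial noise, bypassing spike simulation.
make_waveform <- function(time, values, n_trials = 20, noise_sd = 0,
                          alignment = "saccade_onset", seed = 1) {
  stopifnot(length(values) == length(time))
  set.seed(seed)
  trials <- matrix(rep(values, each = n_trials), nrow = n_trials) +
    if (noise_sd > 0) matrix(rnorm(n_trials * length(time), 0, noise_sd),
                             nrow = n_trials) else 0
  sclaminar:::new_rate_waveform(time, colMeans(trials), trials,
                                alignment_event = alignment)
}

# Independent simple implementation of the two-segment least-squares fit used
# as the brute-force oracle: plain lm() per candidate breakpoint.
oracle_two_piecewise <- function(x, y, min_points = 3) {
  n <- length(x)
  best <- NULL
  for (i in min_points:(n - min_points + 1)) {
    r1 <- sum(resid(lm(y[1:i] ~ x[1:i]))^2)
    r2 <- sum(resid(lm(y[i:n] ~ x[i:n]))^2)
    if (is.null(best) || r1 + r2 < best$rss - 1e-12) {
      best <- list(breakpoint = x[i], rss = r1 + r2)
    }
  }
  best
}

# The parameter-recovery batch: 10 synthetic sessions x 200 VG trials at the
# generator's default study conditions, analysed end to end. Generated once
# per test run and shared by the recovery and shape tests.
fixture_batch <- function() {
  if (is.null(.fixture_env$batch)) {
    cfg <- laminar_config(n_trials = 200, tasks = "VG")
    .fixture_env$batch <- run_pipeline(10, config = cfg, seed = 100,
                                       n_boot = 100, n_perm = 1000)
  }
  .fixture_env$batch
}
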