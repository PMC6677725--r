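test_that("a seed fully determines the generated session", {
  cfg <- laminar_config(n_trials = 8, tasks = "VG", seed = 9)
  expect_identical(generate_session(cfg), generate_session(cfg))
  cfg2 <- laminar_config(n_trials = 8, tasks = "VG", seed = 10)
  expect_false(identical(generate_session(cfg)$spikes,
                         generate_session(cfg2)$spikes))
})

test_that("zero-rate configurations yield empty spike trains", {
  cfg <- laminar_config(n_trials = 5, tasks = "VG", seed = 1,
                        baseline_rate = 0, visual_peak_rate = 0,
                        motor_peak_rate = 0)
  s <- generate_session(cfg)
  expect_equal(nrow(s$spikes), 0)
})

test_that("trial events respect the task timing invariants", {
  s <- fixture_session()
  ev <- s$events
  expect_true(all(ev$target_onset < ev$go_cue))
  expect_true(all(ev$go_cue < ev$saccade_onset))
  expect_true(all(ev$delay_duration >= 600 & ev$delay_duration <= 900))
  expect_true(all(ev$saccade_latency >= 200 & ev$saccade_latency <= 400))
  expect_equal(ev$go_cue - ev$target_onset, ev$delay_duration)
  sp <- s$spikes
  expect_true(all(sp$time_ms >= 0))
  expect_true(all(sp$time_ms <= ev$trial_end[sp$trial_id]))
})

test_that("visual-epoch spike counts match the template rate integral", {
  cfg <- laminar_config(n_trials = 250, tasks = "VG", seed = 7)
  s <- generate_session(cfg)
  ch <- cfg$reference_channel + cfg$visual_peak_channel
  gt <- s$ground_truth$channels
  ev <- s$events
  v_on <- ev$target_onset + gt$visual_latency_ms[ch] + ev$visual_jitter
  sp <- s$spikes[s$spikes$channel == ch, ]
  counts <- vapply(seq_len(nrow(ev)), function(i) {
    sum(sp$trial_id == ev$trial_id[i] &
          sp$time_ms >= v_on[i] & sp$time_ms <= v_on[i] + 100)
  }, numeric(1))
  # oracle: numerical integral of the expected rate over the same window
  # (multiplicative jitters are lognormal with mean 1, so they drop out of
  # the expectation)
  ev1 <- ev[1, ]
  rate <- laminar_rate_template(ch, "VG", cfg, ev1)
  tt <- seq(0, 100, by = 0.1)
  expected <- mean(rate(v_on[1] + tt)) * 0.1  # spk: 100 ms at spk/s / 1000
  sem <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * sem + 1e-9)
})

test_that("thinning sampler matches the Poisson closed form and rescaling", {
  const_rate <- function(t) rep(100, length(t))
  counts <- vapply(1:200, function(i) {
    set.seed(i)
    length(sample_inhomogeneous_poisson(const_rate, c(0, 1000), 100))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100 / 200))

  # time-rescaling: rescaled ISIs of an inhomogeneous train are unit-rate
  # exponential; KS should be non-significant at alpha = 0.01 almost always
  rate_fn <- function(t) 60 + 40 * sin(t / 150)
  grid <- seq(0, 3000, by = 0.5)
  cum <- cumsum(rate_fn(grid)) * 0.5 / 1000   # integrated intensity
  rejections <- 0L
  for (i in 1:100) {
    set.seed(1000 + i)
    st <- sample_inhomogeneous_poisson(rate_fn, c(0, 3000), 100)
    u <- approx(grid, cum, xout = st)$y
    isi <- diff(u)
    p <- suppressWarnings(ks.test(isi, "pexp", 1)$p.value)
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 5)
})

test_that("the thinning sampler refuses unbounded rates", {
  expect_error(sample_inhomogeneous_poisson(function(t) t, c(0, 10)),
               "unbounded")
  expect_error(sample_inhomogeneous_poisson(function(t) t, c(0, 10), Inf),
               "unbounded")
  expect_length(sample_inhomogeneous_poisson(function(t) rep(0, length(t)),
                                             c(0, 100), 0), 0)
})

test_that("rate templates encode the configured laminar structure", {
  cfg <- laminar_config(seed = 1)
  prof <- channel_profiles(cfg)
  peak_ch <- cfg$reference_channel + cfg$visual_peak_channel
  expect_equal(which.max(prof$visual_amp), peak_ch)
  expect_equal(max(prof$visual_amp), cfg$visual_peak_rate)
  # dorsoventral latency gradient spans the configured value
  expect_equal(prof$visual_latency_ms[1] - prof$visual_latency_ms[16],
               cfg$visual_latency_span)
  # motor burst is synchronous across contacts by construction
  expect_equal(diff(range(prof$burst_onset)), 0)
  # Buildup earliest at the origin channel, later with distance
  bu <- prof$buildup_onset[prof$has_buildup]
  al <- prof$aligned[prof$has_buildup]
  expect_equal(al[which.min(bu)], cfg$buildup_origin_channel)
  expect_true(all(diff(bu[order(abs(al - cfg$buildup_origin_channel))]) >= 0))
})

test_that("noise-free LFP recovers the configured reference channel exactly", {
  cfg <- laminar_config(n_trials = 4, tasks = "VG", seed = 5)
  s <- generate_session(cfg)
  lfp <- synth_lfp(cfg, s$events, noise_sd = 0)
  avg <- apply(lfp, c(1, 2), mean)
  csd <- compute_csd(avg, time_ms = attr(lfp, "time_ms"))
  prof <- csd_mean_profile(csd, window = c(0, 150))
  ref <- detect_reference_channel(prof)
  expect_equal(ref$reference_channel, cfg$reference_channel)
  expect_false(ref$flagged)
})

test_that("pre-target LFP is zero-mean noise", {
  cfg <- laminar_config(n_trials = 30, tasks = "VG", seed = 5)
  s <- generate_session(cfg)
  time_ms <- attr(s$lfp, "time_ms")
  pre <- s$lfp[, time_ms < 0, ]
  sem <- sd(pre) / sqrt(length(pre))
  expect_lt(abs(mean(pre)), 3 * sem)
})

test_that("session bundles survive a plain-text round trip", {
  cfg <- laminar_config(n_trials = 4, tasks = c("VG", "MG"), seed = 3)
  s <- generate_session(cfg)
  dir <- withr::local_tempdir()
  write_session(s, dir)
  expect_true(file.exists(file.path(dir, "events.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  s2 <- read_session(dir)
  expect_equal(as.data.frame(s2$events), as.data.frame(s$events))
  expect_equal(s2$spikes$time_ms, s$spikes$time_ms, tolerance = 1e-9)
  expect_equal(as.numeric(s2$lfp), as.numeric(s$lfp), tolerance = 1e-6)
  expect_equal(s2$config$seed, s$config$seed)
  expect_equal(s2$ground_truth$reference_channel,
               s$ground_truth$reference_channel)
})

test_that("invalid configurations are rejected", {
  expect_error(laminar_config(delay_range = c(900, 600)), "configuration")
  expect_error(laminar_config(n_channels = 3), "n_channels")
  expect_error(laminar_config(baseline_rate = -1), "rates")
  expect_error(laminar_config(reference_channel = 40), "reference_channel")
})

test_that("the synthetic eye-velocity trace crosses threshold at saccade onset", {
  v <- synth_eye_velocity(saccade_onset = 1250, duration = 1400)
  expect_equal(detect_saccade_onset(v, go_cue = 1000), 250)
})
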