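test_that("detrending removes an exact line and leaves trend-free data alone", {
  time <- -300:100
  line <- 2 + 0.1 * time
  wv <- make_waveform(time, line)
  d <- detrend_presaccadic(wv)
  expect_true(all(abs(d$values) < 1e-9))

  # a trend-free (zero-level) waveform with a late burst passes through
  trendfree <- make_waveform(time, ifelse(time > -40, (time + 40) * 0.5, 0))
  df <- detrend_presaccadic(trendfree)
  expect_equal(df$values, trendfree$values, tolerance = 1e-9)
  expect_lt(abs(unname(df$trend["slope"])), 1e-12)

  burst <- ifelse(time > -50, (time + 50) * 0.8, 0)
  comp <- make_waveform(time, line + burst)
  dc <- detrend_presaccadic(comp)
  expect_equal(dc$values, burst, tolerance = 1e-6)
})

test_that("E1 finds the first sustained departure from baseline", {
  time <- -300:100
  n <- 20
  base <- matrix(5, n, 100)
  flat <- matrix(5, n, length(time))
  expect_true(is.na(detect_E1_single(flat, time, as.numeric(base))))

  step <- ifelse(time >= -120, 35, 5)
  trials <- matrix(rep(step, each = n), nrow = n)
  expect_equal(detect_E1_single(trials, time, as.numeric(base)), -120)
})

test_that("E1 on noisy steps matches a brute-force scan and lands on time", {
  time <- -300:100
  n <- 50
  hits <- 0L
  for (i in 1:100) {
    set.seed(i)
    step <- ifelse(time >= -120, 14, 0)
    trials <- matrix(rep(step, each = n), nrow = n) +
      matrix(rnorm(n * length(time), 0, 12), nrow = n)
    base <- matrix(rnorm(n * 100, 0, 12), nrow = n)
    e1 <- detect_E1_single(trials, time, as.numeric(base))
    if (!is.na(e1) && e1 >= -120 && e1 <= -100) hits <- hits + 1L
    if (i == 1) {
      # brute-force oracle: per-bin t tests plus an explicit run scan
      p <- vapply(seq_along(time), function(j)
        t.test(trials[, j], as.numeric(base))$p.value, numeric(1))
      sig <- p < 0.01
      first <- match(-200, time)
      oracle <- NA_real_
      for (j in first:(length(time) - 99)) {
        if (all(sig[j:(j + 99)])) { oracle <- time[j]; break }
      }
      expect_equal(e1, oracle)
    }
  }
  expect_gte(hits, 90)
})

test_that("E2 locates the hinge preceding E1", {
  time <- -300:100
  vals <- ifelse(time >= -60, (time + 60) * 0.9, 0) + 3
  e2 <- detect_E2_single(vals, time, e1b = -20)
  expect_lte(abs(e2 - (-60)), 1)

  # pure line inside the window: residual ties resolve to the earliest point
  line <- 1 + 0.2 * time
  expect_equal(detect_E2_single(line, time, e1b = -50), -150 + 2)

  # hinge at the admissible edge of the window stays at/before E1b
  edge <- ifelse(time >= -22, (time + 22) * 2, 0)
  e2e <- detect_E2_single(edge, time, e1b = -20)
  expect_lte(e2e, -20)
  expect_gte(e2e, -25)
})

test_that("E3 separates slow accumulation from the burst", {
  time <- -300:100
  vals <- ifelse(time < -80, 0,
                 ifelse(time < -30, (time + 80) * 0.3,
                        15 + (time + 30) * 2.5))
  e3 <- detect_E3_single(vals, time, e2b = -80, pb = 0)
  expect_lte(abs(e3$e3b - (-30)), 1)
  expect_gt(e3$slope_after, e3$slope_before)
  expect_true(is.na(detect_E3_single(vals, time, e2b = -4, pb = 0)$e3b))
})

test_that("noiseless bootstrap replicates collapse to a single estimate", {
  time <- -300:100
  vals <- 5 + ifelse(time < -100, 0,
                     ifelse(time < -27, ((time + 100) / 73)^1.5 * 35,
                            ifelse(time < -5, 35 + (time + 27) * 4,
                                   ifelse(time <= 35, 123, pmax(0, 123 - (time - 35) * 2)))))
  wv <- make_waveform(time, vals, n_trials = 15)
  base <- matrix(5, 15, 100)
  evb <- bootstrap_events(wv, base, n_boot = 30, seed = 7)
  ev <- evb$events
  e1 <- ev[ev$event == "E1", ]
  expect_true(e1$reliable)
  expect_equal(e1$ci_hi - e1$ci_lo, 0)
  expect_equal(e1$detect_rate, 1)
  # identical replicates throughout
  expect_equal(length(unique(evb$replicates$E2b)), 1)
  e3 <- ev[ev$event == "E3", ]
  expect_true(e3$reliable)
  expect_lte(abs(e3$mean - (-27)), 3)
  p <- ev[ev$event == "P", ]
  expect_true(p$mean >= -5 && p$mean <= 40)
  # triangular peak: Pb = argmax
  tri <- make_waveform(time, 5 + pmax(0, 60 - abs(time - 2) * 2), n_trials = 10)
  evt <- bootstrap_events(tri, matrix(5, 10, 100), n_boot = 5, seed = 1)
  expect_equal(unique(evt$replicates$Pb), 2)
})

test_that("unmodulated channels yield no reliable events", {
  time <- -300:100
  reliable_any <- 0L
  for (i in 1:12) {
    wv <- make_waveform(time, rep(8, length(time)), n_trials = 40,
                        noise_sd = 6, seed = 100 + i)
    set.seed(200 + i)
    base <- matrix(rnorm(40 * 100, 8, 6), nrow = 40)
    evb <- bootstrap_events(wv, base, n_boot = 40, seed = 300 + i)
    ev <- evb$events
    e1 <- ev[ev$event == "E1", ]
    expect_lte(e1$detect_rate, 0.5)
    if (any(ev$reliable[ev$event %in% c("E2", "E3")])) {
      reliable_any <- reliable_any + 1L
    }
  }
  expect_lte(reliable_any, 2)
})

test_that("events order correctly on every replicate where defined", {
  s <- fixture_session()
  ev0 <- s$events
  mv <- ev0[ev0$saccade_latency >= 200 & ev0$saccade_latency <= 400, ]
  sp <- s$spikes[s$spikes$channel == 8, ]
  ws <- spike_density(sp, tibble::tibble(trial_id = mv$trial_id,
                                         align_time = mv$saccade_onset),
                      c(-300, 100), "saccade_onset")
  wg <- spike_density(sp, tibble::tibble(trial_id = mv$trial_id,
                                         align_time = mv$go_cue),
                      c(-100, 0), "go_cue")
  evb <- bootstrap_events(ws, wg$trials[, 1:100], n_boot = 25, seed = 5)
  r <- evb$replicates
  ok <- !is.na(r$E2b)
  expect_true(all(r$E2b[ok] <= r$E1b[ok]))
  ok3 <- !is.na(r$E3b)
  expect_true(all(r$E3b[ok3] > r$E2b[ok3] & r$E3b[ok3] <= r$Pb[ok3]))
})

test_that("classification follows the -50 ms boundary rule", {
  mk_events <- function(e2, e3, e2_rel = TRUE, e3_rel = TRUE,
                        w = 5) {
    ev <- tibble::tibble(
      event = c("E1", "E2", "E3", "P"),
      mean = c(-120, e2, e3, 10),
      ci_lo = c(-130, e2 - w, e3 - w, 5),
      ci_hi = c(-110, e2 + w, e3 + w, 15),
      normalized_ci_range = 0.1,
      detect_rate = 1,
      reliable = c(TRUE, e2_rel, e3_rel, TRUE)
    )
    structure(list(events = ev, replicates = NULL, slope_significant = TRUE),
              class = "presaccadic_events")
  }
  wv <- make_waveform(-300:100, seq(0, 80, length.out = 401))

  both <- classify_channel(mk_events(-90, -20), wv)
  expect_equal(both$category, "Buildup-Burst")
  expect_equal(both$buildup_onset, -90)
  expect_equal(both$burst_onset, -20)

  e3only <- classify_channel(mk_events(NA, -25, e2_rel = FALSE), wv)
  expect_equal(e3only$category, "Burst-only")

  # a lone event later than the boundary is a Burst even if it is E2
  e2only <- classify_channel(mk_events(-30, NA, e3_rel = FALSE), wv)
  expect_equal(e2only$category, "Burst-only")
  expect_equal(e2only$burst_onset, -30)

  none <- classify_channel(mk_events(-90, -20, FALSE, FALSE), wv)
  expect_equal(none$category, "none")

  # overlapping CIs collapse to a single event at E3
  overlap <- classify_channel(mk_events(-56, -48, w = 30), wv)
  expect_equal(overlap$category, "Burst-only")
})
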