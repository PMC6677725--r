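test_that("the visuomotor index hits its endpoints and is monotone in M", {
  expect_equal(vmi(50, 0)$vmi, -1)
  expect_equal(vmi(0, 120)$vmi, 1)
  expect_equal(vmi(40, 40)$vmi, 0)
  expect_equal(vmi(30, 90)$vmi, 0.5)
  expect_false(vmi(0, 0)$defined)
  m_seq <- vmi(rep(25, 5), c(5, 15, 30, 60, 120))$vmi
  expect_true(all(diff(m_seq) > 0))
})

test_that("unit categorization applies both the rank-sum and rate gates", {
  set.seed(1)
  n <- 100
  vis <- rnorm(n, 60, 8); vb <- rnorm(n, 10, 8)
  mov <- rnorm(n, 10, 8); mb <- rnorm(n, 10, 8)
  expect_equal(categorize_unit(vis, vb, mov, mb)$category, "visual-only")
  expect_equal(categorize_unit(vb, vb, mov + 60, mb)$category, "movement-only")
  expect_equal(categorize_unit(vis, vb, mov + 60, mb)$category, "visuo-movement")

  # 8 spk/s above baseline with tiny variance: p < 0.001 but fails the gate
  tiny <- rnorm(n, 18, 0.1); tb <- rnorm(n, 10, 0.1)
  out <- categorize_unit(tiny, tb, mov, mb)
  expect_false(out$visual_significant)
  expect_error(categorize_unit(vis[1:3], vb[1:3], mov, mb), ">= 5 trials")
})

test_that("delay bins tile the delay period and match template integrals", {
  wv <- make_waveform(-100:400, rep(15, 501))
  db <- delay_bins(wv, from = 60, to = 350)   # 290 ms window
  expect_equal(nrow(db), 5)
  expect_true(all(abs(db$rate - 15) < 1e-9))
  expect_equal(nrow(delay_bins(wv, 0, 40)), 0)

  decay <- 40 * exp(-(0:400) / 300)
  wd <- make_waveform(0:400, decay)
  dbd <- delay_bins(wd, from = 50, to = 350)
  oracle <- vapply(seq_len(nrow(dbd)), function(b) {
    f <- function(t) 40 * exp(-t / 300)
    integrate(f, dbd$t_start[b], dbd$t_end[b])$value / 49
  }, numeric(1))
  expect_true(all(abs(dbd$rate - oracle) / oracle < 0.02))
})

test_that("the last visual peak skips minor late bumps", {
  time <- -50:150
  two_peaks <- 60 * exp(-(time - 20)^2 / 200) + 45 * exp(-(time - 90)^2 / 200)
  wv <- make_waveform(time, two_peaks)
  expect_equal(last_visual_peak(wv), 90, tolerance = 2)
  with_minor <- two_peaks + 10 * exp(-(time - 130)^2 / 50)
  expect_equal(last_visual_peak(make_waveform(time, with_minor)), 90,
               tolerance = 2)
})

test_that("cubic fits report exact and degenerate cases correctly", {
  x <- -8:8
  y <- 0.02 * x^3 - 0.1 * x^2 + x + 2
  fit <- cubic_fit_permutation(x, y, n_perm = 200, seed = 1)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_true(fit$significant)
  expect_equal(unname(fit$coefficients["a"]), 0.02, tolerance = 1e-9)
  expect_equal(fit$predict(2), 0.02 * 8 - 0.4 + 2 + 2, tolerance = 1e-9)

  flat <- cubic_fit_permutation(x, rep(3, 17), n_perm = 100, seed = 1)
  expect_equal(flat$r_squared, 0)
  expect_false(flat$significant)
  expect_equal(flat$p_perm, 1)
  expect_error(cubic_fit_permutation(1:4, 1:4), ">= 5 points")

  expect_equal(nrow(tidy(fit)), 4)
  expect_true(glance(fit)$significant)
})

test_that("burst-to-peak scaling recovers curve ratios", {
  x <- -8:8
  base <- 30 + 5 * x - 0.4 * x^2
  f_burst <- cubic_fit_permutation(x, base, n_perm = 10, seed = 1)
  f_same <- cubic_fit_permutation(x, base, n_perm = 10, seed = 1)
  s1 <- burst_peak_scaling(f_burst, f_same)
  expect_equal(s1$factor, 1, tolerance = 1e-9)
  expect_equal(s1$curve$burst_rescaled, s1$curve$peak, tolerance = 1e-9)

  f_peak <- cubic_fit_permutation(x, 3 * base, n_perm = 10, seed = 1)
  expect_equal(burst_peak_scaling(f_burst, f_peak)$factor, 3, tolerance = 1e-9)

  f_neg <- cubic_fit_permutation(x, -base - 100, n_perm = 10, seed = 1)
  expect_error(burst_peak_scaling(f_neg, f_peak), "non-positive")
})

test_that("scaling-factor recovery from template-anchored amplitude profiles", {
  # generator invariant: peak amplitudes are a constant multiple of
  # burst-onset amplitudes; amplitudes measured from simulated activity at
  # the true onset times must recover that multiple
  cfg <- laminar_config(n_trials = 200, tasks = "VG", seed = 17)
  s <- generate_session(cfg)
  gt <- s$ground_truth$channels
  ev <- s$events
  mv <- ev[ev$saccade_latency >= 200 & ev$saccade_latency <= 400, ]
  sacc <- tibble::tibble(trial_id = mv$trial_id, align_time = mv$saccade_onset)
  go <- tibble::tibble(trial_id = mv$trial_id, align_time = mv$go_cue)
  # count-based (kernel-free) amplitude estimates: the burst-onset rate is
  # the rise regression extrapolated to the true onset; the peak rate is the
  # mean plateau rate
  base_rate <- function(sp) {
    pre <- dplyr::inner_join(sp, go, by = "trial_id")
    rel <- pre$time_ms - pre$align_time
    sum(rel >= -100 & rel < 0) / nrow(go) / 0.1
  }
  rows <- purrr::map_dfr(seq(2, 14, by = 2), function(ch) {
    sp <- s$spikes[s$spikes$channel == ch, ]
    rel <- dplyr::inner_join(sp, sacc, by = "trial_id")
    rel <- rel$time_ms - rel$align_time
    bins <- seq(ceiling(cfg$burst_onset), cfg$burst_plateau[1] - 1)
    rate <- vapply(bins, function(b)
      sum(rel >= b & rel < b + 1) / nrow(sacc) * 1000, numeric(1))
    rise <- lm(rate ~ bins)
    b0 <- unname(predict(rise, newdata = data.frame(bins = cfg$burst_onset)))
    peak <- sum(rel >= cfg$burst_plateau[1] & rel < cfg$burst_plateau[2]) /
      nrow(sacc) / (diff(cfg$burst_plateau) / 1000)
    b <- base_rate(sp)
    tibble::tibble(aligned = ch - cfg$reference_channel,
                   burst_amp = b0 - b, peak_amp = peak - b)
  })
  fb <- cubic_fit_permutation(rows$aligned, rows$burst_amp, n_perm = 10, seed = 1)
  fp <- cubic_fit_permutation(rows$aligned, rows$peak_amp, n_perm = 10, seed = 1)
  k <- burst_peak_scaling(fb, fp)$factor
  expect_lt(abs(k - cfg$burst_peak_scale_vg) / cfg$burst_peak_scale_vg, 0.15)
})

test_that("population aggregation reports sensible CIs", {
  one <- tibble::tibble(aligned = 0, value = 5)
  agg1 <- population_aggregate(one, n_boot = 50)
  expect_true(agg1$single_session)
  expect_equal(agg1$mean, 5)

  same <- tibble::tibble(aligned = rep(1, 6), value = rep(2.5, 6))
  agg2 <- population_aggregate(same, n_boot = 100)
  expect_equal(agg2$ci_lo, agg2$ci_hi)
  expect_equal(agg2$mean, 2.5)
})

test_that("the KS gate picks t tests for normal data and rank-sum otherwise", {
  set.seed(3)
  a <- rnorm(80); b <- rnorm(80, 0.2)
  expect_equal(compare_samples(a, b)$test, "t")
  x <- exp(rnorm(200, 0, 1.5)); y <- exp(rnorm(200, 0.3, 1.5))
  expect_equal(compare_samples(x, y)$test, "ranksum")
})
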