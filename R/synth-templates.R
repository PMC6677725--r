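gauss_profile <- function(dist, sigma) exp(-(dist^2) / (2 * sigma^2))

# alpha-shaped transient, peak value 1 at u = 1, zero for u < 0
alpha_bump <- function(u) ifelse(u >= 0, u * exp(1 - u), 0)

# fast-attack/slow-decay transient (EPSP-like), normalized to unit peak
epsp_bump <- function(t, attack, decay) {
  tpk <- attack * log(1 + decay / attack)
  pk <- (1 - exp(-tpk / attack)) * exp(-tpk / decay)
  ifelse(t >= 0, (1 - exp(-t / attack)) * exp(-t / decay) / pk, 0)
}

#' Per-channel ground-truth laminar profiles implied by a generator config
#'
#' Expands an [laminar_config()] into one row per probe contact with the true
#' visual latency, visual amplitude, Buildup onset (where present), Burst
#' onset, and movement-burst amplitudes used by the rate templates.
#'
#' @param config An `sc_config` from [laminar_config()].
#' @return A tibble with one row per contact. `channel` is the probe index
#'   (1 = most ventral), `aligned` the index relative to the true reference
#'   channel.
#' @export
channel_profiles <- function(config) {
  k <- seq_len(config$n_channels)
  aligned <- k - config$reference_channel
  visual_amp <- config$visual_peak_rate *
    gauss_profile(aligned - config$visual_peak_channel, config$visual_sigma)
  burst_amp <- (config$motor_peak_rate / config$burst_peak_scale_vg) *
    gauss_profile(aligned - config$motor_peak_channel, config$motor_sigma)
  # dorsal (high index) contacts see the target earliest
  visual_latency <- config$visual_latency_base +
    config$visual_latency_span * (config$n_channels - k) / (config$n_channels - 1)
  has_buildup <- aligned >= config$buildup_channels[1] &
    aligned <= config$buildup_channels[2]
  buildup_onset <- config$buildup_onset_earliest +
    config$buildup_onset_slope * abs(aligned - config$buildup_origin_channel)
  buildup_onset <- pmin(buildup_onset, config$burst_onset - 20)
  buildup_onset[!has_buildup] <- NA_real_
  tibble::tibble(
    channel = k,
    aligned = aligned,
    visual_latency_ms = visual_latency,
    visual_amp = visual_amp,
    has_buildup = has_buildup,
    buildup_onset = buildup_onset,
    burst_onset = config$burst_onset,
    burst_onset_amp = burst_amp,
    peak_amp_vg = config$burst_peak_scale_vg * burst_amp,
    peak_amp_mg = config$burst_peak_scale_mg * burst_amp
  )
}

#' Closed-form firing-rate template for one channel and trial
#'
#' Builds the inhomogeneous Poisson rate function (spk/s as a function of
#' trial time in ms) for a given contact, task and trial-event row. The
#' template is a sum of: a constant baseline; a fast-attack, slow-decay
#' visual transient with depth-dependent latency and amplitude; a slowly decaying delay-period
#' plateau proportional to the visual amplitude; a convex Buildup ramp that
#' accumulates from the channel's Buildup onset to its Burst-onset level; and
#' a piecewise-linear motor burst
#' starting at the common Burst onset, rising to its peak just before saccade
#' onset, holding it over `burst_plateau` and decaying thereafter. MG trials share the Burst-onset amplitude but have an
#' attenuated peak.
#'
#' @param channel Probe contact index.
#' @param task `"VG"` or `"MG"`.
#' @param config An `sc_config`.
#' @param events One trial-event row (needs `target_onset`, `saccade_onset`,
#'   and `target_in_rf` if present).
#' @param gain_jitter Multiplicative trial gain on the visual transient
#'   (default 1; drawn by the generator from a lognormal with CV
#'   `visual_gain_cv`).
#' @param level_jitter Multiplicative trial gain on the ongoing level
#'   (baseline + delay; default 1; lognormal with CV `excitability_cv`).
#' @return A vectorized function of time (ms from trial start) returning
#'   spk/s, with attributes `rate_max` (a finite supremum bound usable for
#'   thinning) and `info` (the channel's ground-truth parameters).
#' @export
laminar_rate_template <- function(channel, task, config, events, gain_jitter = 1,
                                  level_jitter = 1) {
  stopifnot(channel >= 1, channel <= config$n_channels)
  task <- match.arg(task, c("VG", "MG"))
  prof <- channel_profiles(config)[channel, ]
  in_rf <- if ("target_in_rf" %in% names(events)) isTRUE(events$target_in_rf[1]) else TRUE

  t_target <- events$target_onset[1]
  t_sacc <- events$saccade_onset[1]
  tau <- config$visual_tau
  jit <- if ("visual_jitter" %in% names(events)) events$visual_jitter[1] else 0
  v_on <- t_target + prof$visual_latency_ms + jit
  f0 <- config$delay_frac_start
  f1 <- config$delay_frac_end

  # delay-period envelope (fraction of the visual amplitude), building up
  # after the transient has passed and decaying slowly over the delay
  delay_env <- function(t) {
    dt <- t - v_on - config$delay_lag
    ifelse(dt >= 0,
           (1 - exp(-dt / 30)) * (f1 + (f0 - f1) * exp(-dt / config$delay_tau)),
           0)
  }
  gain <- config$visual_trial_gain

  peak_amp <- if (task == "VG") prof$peak_amp_vg else prof$peak_amp_mg
  b_amp <- prof$burst_onset_amp
  bo <- config$burst_onset          # ms re saccade, < 0
  b0 <- prof$buildup_onset          # ms re saccade or NA
  p1 <- config$burst_plateau[1]
  p2 <- config$burst_plateau[2]
  decay <- config$burst_decay_ms

  movement <- function(s) {
    out <- numeric(length(s))
    if (prof$has_buildup) {
      # convex accumulator ramp up to the Burst-onset level
      i <- s >= b0 & s < bo
      out[i] <- b_amp * ((s[i] - b0) / (bo - b0))^config$buildup_rise_exponent
      start_amp <- b_amp
    } else {
      start_amp <- 0
    }
    i <- s >= bo & s < p1
    out[i] <- start_amp + (peak_amp - start_amp) * (s[i] - bo) / (p1 - bo)
    i <- s >= p1 & s <= p2
    out[i] <- peak_amp
    i <- s > p2 & s <= p2 + decay
    out[i] <- peak_amp * (1 - (s[i] - p2) / decay)
    out
  }

  rate <- if (!in_rf) {
    function(t) rep(level_jitter * config$baseline_rate, length(t))
  } else {
    function(t) {
      level_jitter * (config$baseline_rate + prof$visual_amp * delay_env(t)) +
        gain_jitter * prof$visual_amp * gain *
          epsp_bump(t - v_on, config$visual_attack, tau) +
        movement(t - t_sacc)
    }
  }
  rate_max <- level_jitter * (config$baseline_rate +
                                (if (in_rf) prof$visual_amp * f0 else 0)) +
    (if (in_rf) gain_jitter * prof$visual_amp * gain else 0) +
    max(peak_amp, b_amp)
  attr(rate, "rate_max") <- rate_max
  attr(rate, "info") <- as.list(prof)
  rate
}

#' Sample an inhomogeneous Poisson spike train by thinning
#'
#' Draws candidate events from a homogeneous Poisson process at `rate_max`
#' and retains each with probability `rate(t) / rate_max`.
#'
#' @param rate_fn Vectorized rate function, spk/s over ms.
#' @param window Two-element ms interval to simulate over.
#' @param rate_max Finite upper bound of `rate_fn` on `window`. Defaults to
#'   the function's `rate_max` attribute.
#' @return Sorted numeric vector of spike times (ms).
#' @export
#' @examples
#' set.seed(1)
#' length(sample_inhomogeneous_poisson(function(t) rep(100, length(t)),
#'                                     c(0, 1000), 100))
sample_inhomogeneous_poisson <- function(rate_fn, window,
                                         rate_max = attr(rate_fn, "rate_max")) {
  if (is.null(rate_max) || !is.finite(rate_max) || rate_max < 0) {
    stop("unbounded rate: a finite non-negative `rate_max` is required", call. = FALSE)
  }
  dur_s <- (window[2] - window[1]) / 1000
  if (dur_s <= 0 || rate_max == 0) return(numeric(0))
  n <- rpois(1, rate_max * dur_s)
  if (n == 0) return(numeric(0))
  cand <- runif(n, window[1], window[2])
  lambda <- rate_fn(cand)
  if (any(lambda > rate_max * (1 + 1e-8))) {
    stop("unbounded rate: rate exceeds the supplied `rate_max`", call. = FALSE)
  }
  sort(cand[runif(n) * rate_max < lambda])
}

#' Synthetic eye-velocity trace for one trial
#'
#' A monotone velocity profile that crosses `threshold` exactly at the
#' trial's saccade onset, for exercising the velocity-criterion saccade
#' detector.
#'
#' @param saccade_onset Saccade onset time (ms from trial start).
#' @param duration Trace duration (ms); sampled at 1 kHz from time 0.
#' @param threshold Velocity reached exactly at `saccade_onset` (deg/s).
#' @param v_max Saturation velocity (deg/s).
#' @return Tibble with `time_ms` and `velocity`.
#' @export
synth_eye_velocity <- function(saccade_onset, duration = saccade_onset + 100,
                               threshold = 30, v_max = 400) {
  time_ms <- seq(0, duration)
  v <- threshold * 2^((time_ms - saccade_onset) / 5)
  tibble::tibble(time_ms = time_ms, velocity = pmin(v, v_max))
}
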