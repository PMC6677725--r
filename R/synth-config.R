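#' Configuration for the synthetic laminar-session generator
#'
#' Builds the parameter set that [generate_session()] turns into a synthetic
#' 16-channel superior-colliculus recording. The defaults encode the laminar
#' structure reported for primate SC during delayed saccade tasks: a visual
#' burst whose amplitude peaks a few contacts dorsal of the depth-alignment
#' reference channel, a movement burst peaking just ventral of it, a
#' dorsal-to-ventral visual-latency gradient of ~7 ms across the probe,
#' Buildup activity that starts earliest (~-100 ms before the saccade) at a
#' central contact and later with distance, and a motor Burst that begins
#' synchronously (~-27 ms) on every contact.
#'
#' Channel numbering follows the probe convention: contact 1 is the most
#' ventral, contact `n_channels` the most dorsal. "Aligned" indices are probe
#' indices minus `reference_channel`, so aligned index 0 is the contact at the
#' ventral edge of the visual CSD sink.
#'
#' @param n_channels Number of probe contacts (default 16).
#' @param contact_spacing_um Inter-contact distance in micrometres (150).
#' @param n_trials Trials generated per task.
#' @param tasks Character vector of tasks to simulate, subset of
#'   `c("VG", "MG")` (visually guided / memory guided).
#' @param fixation_range,delay_range,saccade_latency_range Two-element ms
#'   ranges for the initial fixation duration, the post-target delay, and the
#'   go-cue-to-saccade latency. Per-trial values are drawn uniformly.
#' @param mg_flash_ms Target flash duration on MG trials (300 ms).
#' @param reference_channel True depth-reference contact (probe index): the
#'   contact at the ventral edge of the visual CSD sink.
#' @param visual_peak_channel,motor_peak_channel Aligned indices of the
#'   visual-burst and movement-burst amplitude maxima.
#' @param visual_peak_rate Peak firing rate (spk/s) of the visual transient on
#'   the best visual channel.
#' @param motor_peak_rate Peak firing rate (spk/s) of the movement burst on
#'   the best motor channel, VG task.
#' @param burst_peak_scale_vg,burst_peak_scale_mg Ratio of movement-burst peak
#'   rate to the rate at Burst onset, per task. The rate at Burst onset is
#'   `motor_peak_rate / burst_peak_scale_vg` on the best channel for both
#'   tasks; MG peaks are scaled down accordingly.
#' @param visual_sigma,motor_sigma Gaussian widths (in channels) of the
#'   visual- and movement-amplitude depth profiles.
#' @param visual_latency_base Visual-burst latency (ms after target onset) on
#'   the most dorsal contact.
#' @param visual_latency_span Total dorsal-to-ventral latency gradient (ms)
#'   across the probe.
#' @param visual_tau Decay time constant (ms) of the visual transient.
#' @param visual_attack Attack time constant (ms) of the visual transient;
#'   the rapid rise makes single-trial burst onsets sharply defined.
#' @param visual_trial_gain Per-trial transient amplitude as a multiple of the
#'   channel's `visual_amp`: single-trial bursts are stronger than the
#'   jitter-smeared trial average they produce.
#' @param visual_gain_cv Coefficient of variation of a lognormal per-trial,
#'   per-channel multiplicative gain on the visual transient, emulating
#'   trial-to-trial response variability.
#' @param excitability_cv Coefficient of variation of a lognormal per-trial,
#'   per-channel multiplicative gain on the ongoing level (baseline plus
#'   delay activity), emulating slow excitability fluctuations that persist
#'   from the delay period into the pre-saccadic epoch.
#' @param visual_jitter_sd SD (ms) of a per-trial visual-latency jitter shared
#'   by all contacts (stochastic circuit latency); burst alignment removes it.
#' @param delay_lag Lag (ms) after the visual onset before delay-period
#'   activity starts to build.
#' @param buildup_origin_channel Aligned index where Buildup starts earliest.
#' @param buildup_onset_earliest Buildup onset (ms re saccade) at the origin
#'   channel.
#' @param buildup_onset_slope Additional Buildup-onset delay (ms) per channel
#'   of distance from the origin channel.
#' @param buildup_channels Aligned-index range (two elements) of contacts that
#'   express Buildup activity; contacts outside it are Burst-only.
#' @param buildup_rise_exponent Exponent of the convex Buildup ramp: activity
#'   accumulates as ((t - onset)/interval)^exponent toward the Burst-onset
#'   level, so the rise accelerates gradually (default 2).
#' @param burst_onset Motor-burst onset (ms re saccade), identical on all
#'   contacts.
#' @param burst_plateau Two-element ms window (re saccade) over which the
#'   burst holds its peak rate; the rise spans `burst_onset` to its start.
#' @param burst_decay_ms Time (ms) for the burst to decay back to rest after
#'   the plateau.
#' @param baseline_rate Background rate (spk/s) on every contact.
#' @param delay_frac_start,delay_frac_end Delay-period activity expressed as a
#'   fraction of the channel's visual amplitude, at the start of the delay and
#'   asymptotically.
#' @param delay_tau Decay time constant (ms) of the delay-period activity.
#' @param lfp_sink_channels Aligned-index range of the visual CSD sink.
#' @param lfp_window Window (ms re target onset) over which LFP traces are
#'   generated.
#' @param lfp_amp Amplitude scale (arbitrary microvolts) of the evoked LFP.
#' @param lfp_noise_sd Standard deviation of additive white LFP noise.
#' @param anti_rf If `TRUE`, also generate trials with the target diametrically
#'   opposite the response field (flat response); default `FALSE`.
#' @param trial_pad_ms Recording time retained after saccade onset.
#' @param seed Integer seed; fully determines the generated session.
#'
#' @return A list of class `"sc_config"`.
#' @export
#' @examples
#' cfg <- laminar_config(n_trials = 20, tasks = "VG", seed = 1)
#' cfg$visual_peak_rate
laminar_config <- function(n_channels = 16,
                           contact_spacing_um = 150,
                           n_trials = 200,
                           tasks = c("VG", "MG"),
                           fixation_range = c(200, 350),
                           delay_range = c(600, 900),
                           saccade_latency_range = c(200, 400),
                           mg_flash_ms = 300,
                           reference_channel = 7,
                           visual_peak_channel = 4,
                           motor_peak_channel = -2,
                           visual_peak_rate = 88.2,
                           motor_peak_rate = 136.7,
                           burst_peak_scale_vg = 3.3,
                           burst_peak_scale_mg = 2.4,
                           visual_sigma = 4,
                           motor_sigma = 4,
                           visual_latency_base = 45,
                           visual_latency_span = 7.3,
                           visual_tau = 20,
                           visual_attack = 0.5,
                           visual_gain_cv = 0.35,
                           excitability_cv = 1.2,
                           visual_trial_gain = 8,
                           visual_jitter_sd = 4,
                           delay_lag = 80,
                           buildup_origin_channel = 2,
                           buildup_onset_earliest = -102.7,
                           buildup_onset_slope = 3.95,
                           buildup_channels = c(-6, 4),
                           buildup_rise_exponent = 1.5,
                           burst_onset = -26.9,
                           burst_plateau = c(-5, 35),
                           burst_decay_ms = 60,
                           baseline_rate = 20,
                           delay_frac_start = 0.15,
                           delay_frac_end = 0.15,
                           delay_tau = 1200,
                           lfp_sink_channels = c(1, 6),
                           lfp_window = c(-100, 400),
                           lfp_amp = 40,
                           lfp_noise_sd = 20,
                           anti_rf = FALSE,
                           trial_pad_ms = 300,
                           seed = 1L) {
  cfg <- list(
    n_channels = as.integer(n_channels),
    contact_spacing_um = contact_spacing_um,
    n_trials = as.integer(n_trials),
    tasks = match.arg(tasks, c("VG", "MG"), several.ok = TRUE),
    fixation_range = fixation_range,
    delay_range = delay_range,
    saccade_latency_range = saccade_latency_range,
    mg_flash_ms = mg_flash_ms,
    reference_channel = as.integer(reference_channel),
    visual_peak_channel = visual_peak_channel,
    motor_peak_channel = motor_peak_channel,
    visual_peak_rate = visual_peak_rate,
    motor_peak_rate = motor_peak_rate,
    burst_peak_scale_vg = burst_peak_scale_vg,
    burst_peak_scale_mg = burst_peak_scale_mg,
    visual_sigma = visual_sigma,
    motor_sigma = motor_sigma,
    visual_latency_base = visual_latency_base,
    visual_latency_span = visual_latency_span,
    visual_tau = visual_tau,
    visual_attack = visual_attack,
    visual_trial_gain = visual_trial_gain,
    visual_gain_cv = visual_gain_cv,
    excitability_cv = excitability_cv,
    visual_jitter_sd = visual_jitter_sd,
    delay_lag = delay_lag,
    buildup_origin_channel = buildup_origin_channel,
    buildup_onset_earliest = buildup_onset_earliest,
    buildup_onset_slope = buildup_onset_slope,
    buildup_channels = buildup_channels,
    buildup_rise_exponent = buildup_rise_exponent,
    burst_onset = burst_onset,
    burst_plateau = burst_plateau,
    burst_decay_ms = burst_decay_ms,
    baseline_rate = baseline_rate,
    delay_frac_start = delay_frac_start,
    delay_frac_end = delay_frac_end,
    delay_tau = delay_tau,
    lfp_sink_channels = lfp_sink_channels,
    lfp_window = lfp_window,
    lfp_amp = lfp_amp,
    lfp_noise_sd = lfp_noise_sd,
    anti_rf = isTRUE(anti_rf),
    trial_pad_ms = trial_pad_ms,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "sc_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_channels >= 4)
  rng_ok <- function(r) length(r) == 2 && is.numeric(r) && r[1] <= r[2]
  for (f in c("fixation_range", "delay_range", "saccade_latency_range",
              "lfp_sink_channels", "lfp_window", "buildup_channels",
              "burst_plateau")) {
    if (!rng_ok(cfg[[f]])) {
      stop("configuration error: `", f, "` must be a non-decreasing length-2 range",
           call. = FALSE)
    }
  }
  if (cfg$delay_range[1] < 0 || cfg$delay_range[2] > 3000) {
    stop("configuration error: `delay_range` outside task window", call. = FALSE)
  }
  rates <- c(cfg$visual_peak_rate, cfg$motor_peak_rate, cfg$baseline_rate)
  if (any(rates < 0)) {
    stop("configuration error: rates must be >= 0", call. = FALSE)
  }
  if (cfg$reference_channel < 1 || cfg$reference_channel > cfg$n_channels) {
    stop("configuration error: `reference_channel` outside probe", call. = FALSE)
  }
  if (cfg$n_trials < 1) stop("configuration error: `n_trials` must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sc_config <- function(x, ...) {
  cat("<sc_config> synthetic laminar session generator\n")
  cat("  channels:", x$n_channels, "@", x$contact_spacing_um, "um;",
      "reference channel", x$reference_channel, "\n")
  cat("  tasks:", paste(x$tasks, collapse = "/"),
      "-", x$n_trials, "trials each; seed", x$seed, "\n")
  cat("  visual peak", x$visual_peak_rate, "spk/s @ aligned", x$visual_peak_channel,
      "| motor peak", x$motor_peak_rate, "spk/s @ aligned", x$motor_peak_channel, "\n")
  invisible(x)
}

# Evaluate code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
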