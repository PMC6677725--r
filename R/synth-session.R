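#' Synthetic laminar LFP traces for a set of trials
#'
#' Generates per-channel, per-trial LFP snippets around target onset. The
#' evoked component is a spatial potential profile whose discrete second
#' spatial derivative (the CSD) is, by construction, a contiguous current
#' sink spanning `lfp_sink_channels` with its ventral negative-to-positive
#' transition at the configured reference channel; the temporal course is an
#' alpha-shaped deflection after target onset (the visual input current).
#' Additive white noise is controlled by `lfp_noise_sd`.
#'
#' @param config An `sc_config`.
#' @param events Trial-event tibble (one row per trial; needs `target_onset`,
#'   and `target_in_rf` if anti-RF trials are present).
#' @param noise_sd Noise standard deviation; defaults to the config value.
#' @return A numeric array `[channel, time, trial]` with attribute `time_ms`
#'   giving the time axis relative to target onset.
#' @export
synth_lfp <- function(config, events, noise_sd = config$lfp_noise_sd) {
  n_ch <- config$n_channels
  time_ms <- seq(config$lfp_window[1], config$lfp_window[2])
  n_t <- length(time_ms)
  n_trials <- nrow(events)

  f_spatial <- lfp_spatial_profile(config)
  w <- alpha_bump((time_ms - 40) / 30)   # input current ~40 ms after target

  in_rf <- if ("target_in_rf" %in% names(events)) events$target_in_rf else rep(TRUE, n_trials)
  evoked <- config$lfp_amp * outer(f_spatial, w)   # [channel, time]

  lfp <- array(rnorm(n_ch * n_t * n_trials, sd = noise_sd),
               dim = c(n_ch, n_t, n_trials))
  for (tr in seq_len(n_trials)) {
    if (in_rf[tr]) lfp[, , tr] <- lfp[, , tr] + evoked
  }
  attr(lfp, "time_ms") <- time_ms
  lfp
}

# Spatial potential profile whose second spatial difference realises the
# configured sink: target CSD is a half-sine sink over the sink channels with
# balancing sources at its two edges, integrated twice from the ventral end.
lfp_spatial_profile <- function(config) {
  n_ch <- config$n_channels
  ref <- config$reference_channel
  s1 <- config$lfp_sink_channels[1] + ref
  s2 <- config$lfp_sink_channels[2] + ref
  if (s1 < 2 || s2 > n_ch - 1) {
    stop("configuration error: `lfp_sink_channels` must lie on interior contacts",
         call. = FALSE)
  }
  d <- numeric(n_ch)
  len <- s2 - s1 + 1
  d[s1:s2] <- -sin(pi * seq_len(len) / (len + 1))
  src <- -sum(d) / 2
  d[s1 - 1] <- d[s1 - 1] + src
  d[min(s2 + 1, n_ch)] <- d[min(s2 + 1, n_ch)] + src
  f <- numeric(n_ch)
  for (k in 2:(n_ch - 1)) f[k + 1] <- 2 * f[k] - f[k - 1] - d[k]
  f
}

#' Generate a synthetic laminar recording session
#'
#' Draws trial events, per-channel inhomogeneous Poisson spike trains and
#' laminar LFP traces for one simulated probe penetration, following the
#' depth templates of [channel_profiles()]. The result is fully determined by
#' `config$seed`.
#'
#' @param config An `sc_config` from [laminar_config()].
#' @return An `sc_session` list with elements `meta`, `config`, `events`
#'   (tibble, times in ms from trial start), `spikes` (tibble: `channel`,
#'   `trial_id`, `time_ms`), `lfp` (array `[channel, time, trial]`, time axis
#'   relative to target onset) and `ground_truth` (reference channel plus the
#'   per-channel template parameters).
#' @export
#' @examples
#' s <- generate_session(laminar_config(n_trials = 5, tasks = "VG", seed = 1))
#' s$events
generate_session <- function(config) {
  stopifnot(inherits(config, "sc_config"))
  validate_config(config)
  with_local_seed(config$seed, {
    events <- draw_trial_events(config)
    spikes <- draw_spikes(config, events)
    lfp <- synth_lfp(config, events)
    gt <- list(
      reference_channel = config$reference_channel,
      channels = channel_profiles(config)
    )
    structure(
      list(
        meta = list(
          n_channels = config$n_channels,
          contact_spacing_um = config$contact_spacing_um,
          seed = config$seed
        ),
        config = config,
        events = events,
        spikes = spikes,
        lfp = lfp,
        ground_truth = gt
      ),
      class = "sc_session"
    )
  })
}

draw_trial_events <- function(config) {
  one_task <- function(task) {
    n <- config$n_trials
    rf <- rep(TRUE, n)
    if (config$anti_rf) {
      n <- 2L * n
      rf <- rep(c(TRUE, FALSE), length.out = n)
    }
    fixation <- round(runif(n, config$fixation_range[1], config$fixation_range[2]))
    delay <- round(runif(n, config$delay_range[1], config$delay_range[2]))
    latency <- round(runif(n, config$saccade_latency_range[1],
                           config$saccade_latency_range[2]))
    jitter <- round(rnorm(n, 0, config$visual_jitter_sd))
    tibble::tibble(
      task = task,
      target_in_rf = rf,
      target_onset = fixation,
      visual_jitter = jitter,
      delay_duration = delay,
      go_cue = fixation + delay,
      saccade_latency = latency,
      saccade_onset = fixation + delay + latency,
      trial_end = fixation + delay + latency + config$trial_pad_ms
    )
  }
  ev <- dplyr::bind_rows(lapply(config$tasks, one_task))
  dplyr::mutate(ev, trial_id = dplyr::row_number(), .before = 1)
}

draw_spikes <- function(config, events) {
  out <- vector("list", config$n_channels * nrow(events))
  idx <- 1L
  cv <- config$visual_gain_cv %||% 0
  ecv <- config$excitability_cv %||% 0
  sdlog <- sqrt(log(1 + cv^2))
  esdlog <- sqrt(log(1 + ecv^2))
  for (ch in seq_len(config$n_channels)) {
    for (tr in seq_len(nrow(events))) {
      ev <- events[tr, ]
      gj <- if (cv > 0) exp(rnorm(1, -sdlog^2 / 2, sdlog)) else 1
      lj <- if (ecv > 0) exp(rnorm(1, -esdlog^2 / 2, esdlog)) else 1
      rate <- laminar_rate_template(ch, ev$task, config, ev, gain_jitter = gj,
                                    level_jitter = lj)
      st <- sample_inhomogeneous_poisson(rate, c(0, ev$trial_end))
      out[[idx]] <- if (length(st)) {
        tibble::tibble(channel = ch, trial_id = ev$trial_id, time_ms = st)
      } else NULL
      idx <- idx + 1L
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(channel = integer(0), trial_id = integer(0),
                          time_ms = numeric(0))
  }
  res
}

#' @export
print.sc_session <- function(x, ...) {
  cat("<sc_session> synthetic laminar recording\n")
  cat("  ", x$meta$n_channels, " channels, ", nrow(x$events), " trials (",
      paste(unique(x$events$task), collapse = "/"), "), ",
      nrow(x$spikes), " spikes, seed ", x$meta$seed, "\n", sep = "")
  cat("  true reference channel:", x$ground_truth$reference_channel, "\n")
  invisible(x)
}

#' Write / read a session bundle as plain-text files
#'
#' `write_session()` lays a session out as one directory holding
#' `events.csv`, one `spikes_ch<k>.csv` per channel, `lfp.csv` (long over
#' trials: `trial_id`, `time_ms` relative to target onset, one column per
#' channel), `meta.json`, and `ground_truth.json` for synthetic sessions.
#' `read_session()` restores the bundle.
#'
#' @param session An `sc_session`.
#' @param dir Directory to create/read.
#' @return `write_session()` returns `dir` invisibly; `read_session()` an
#'   `sc_session`.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(session$events, file.path(dir, "events.csv"))
  for (ch in seq_len(session$meta$n_channels)) {
    sp <- dplyr::filter(session$spikes, .data$channel == ch)
    readr::write_csv(dplyr::select(sp, "trial_id", "time_ms"),
                     file.path(dir, sprintf("spikes_ch%d.csv", ch)))
  }
  time_ms <- attr(session$lfp, "time_ms")
  lfp_tbl <- do.call(rbind, lapply(seq_len(dim(session$lfp)[3]), function(tr) {
    m <- t(session$lfp[, , tr])
    colnames(m) <- paste0("ch", seq_len(ncol(m)))
    cbind(trial_id = tr, time_ms = time_ms, m)
  }))
  readr::write_csv(tibble::as_tibble(lfp_tbl), file.path(dir, "lfp.csv"))
  meta <- session$meta
  meta$config <- unclass(session$config)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(session$ground_truth)) {
    jsonlite::write_json(session$ground_truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  cfg <- meta$config
  cfg <- structure(cfg, class = "sc_config")
  events <- readr::read_csv(file.path(dir, "events.csv"), show_col_types = FALSE)
  n_ch <- meta$n_channels
  spikes <- dplyr::bind_rows(lapply(seq_len(n_ch), function(ch) {
    f <- file.path(dir, sprintf("spikes_ch%d.csv", ch))
    sp <- readr::read_csv(f, show_col_types = FALSE)
    if (nrow(sp) == 0) return(NULL)
    dplyr::mutate(sp, channel = ch, .before = 1)
  }))
  lfp_tbl <- readr::read_csv(file.path(dir, "lfp.csv"), show_col_types = FALSE)
  trials <- sort(unique(lfp_tbl$trial_id))
  time_ms <- sort(unique(lfp_tbl$time_ms))
  lfp <- array(NA_real_, dim = c(n_ch, length(time_ms), length(trials)))
  ch_cols <- paste0("ch", seq_len(n_ch))
  for (i in seq_along(trials)) {
    sub <- lfp_tbl[lfp_tbl$trial_id == trials[i], ]
    sub <- sub[order(sub$time_ms), ]
    lfp[, , i] <- t(as.matrix(sub[, ch_cols]))
  }
  attr(lfp, "time_ms") <- time_ms
  gt_file <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_file)) {
    g <- jsonlite::read_json(gt_file, simplifyVector = TRUE)
    g$channels <- tibble::as_tibble(g$channels)
    g
  } else NULL
  structure(
    list(
      meta = meta[c("n_channels", "contact_spacing_um", "seed")],
      config = cfg,
      events = events,
      spikes = spikes,
      lfp = lfp,
      ground_truth = gt
    ),
    class = "sc_session"
  )
}
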