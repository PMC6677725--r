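#' Run the full laminar analysis on one session
#'
#' Sequences the per-session stages: per-trial Poisson-surprise visual-burst
#' detection and alignment-channel selection; visual-frame spike densities,
#' onset-latency estimation, visual epoch rates and delay bins; CSD
#' reference-channel detection; movement-frame spike densities, epoch rates
#' and VMI; bootstrap pre-saccadic event detection and Buildup/Burst
#' classification; unit categorization.
#'
#' @param session An `sc_session` (from [generate_session()] or
#'   [read_session()]).
#' @param tasks Tasks to analyse (default: those present).
#' @param n_boot Bootstrap replicates for event detection (default 100).
#' @param seed Seed for the bootstrap (default: the session seed).
#' @param boundary Buildup/Burst classification boundary, ms (default -50).
#' @param csd_window CSD detection window re visual burst onset, ms
#'   (default `c(-50, 100)`, a 150 ms window starting before the burst).
#' @param visual_epoch Poisson-surprise search epoch re target onset
#'   (default `c(30, 150)`).
#' @param label Session label carried into outputs.
#' @return An `sc_session_result`: `label`, `channels` (one row per task x
#'   channel with latencies, epoch rates, VMI, categories and event
#'   estimates), `delay` (per-bin delay activity), `alignment` (per-task
#'   alignment channel and retained-trial count), `reference_channel`,
#'   `csd_flagged`, `unalignable` (no visual bursts anywhere; partial
#'   result), `log` (discarded trials/channels with reasons).
#' @export
run_session <- function(session, tasks = NULL, n_boot = 100, seed = NULL,
                        boundary = -50, csd_window = c(-50, 100),
                        visual_epoch = c(30, 150), label = "session") {
  ev_all <- session$events
  if ("target_in_rf" %in% names(ev_all)) {
    ev_all <- ev_all[ev_all$target_in_rf, ]
  }
  tasks <- tasks %||% unique(ev_all$task)
  seed <- seed %||% (session$meta$seed %||% 1L)
  log <- character(0)

  # --- session-level CSD depth reference (tasks pooled) ---
  det_all <- detect_visual_bursts(session, trials = ev_all$trial_id,
                                  epoch_re_target = visual_epoch)
  if (nrow(det_all) == 0) {
    return(structure(list(
      label = label, channels = tibble::tibble(), delay = tibble::tibble(),
      alignment = tibble::tibble(), reference_channel = NA_integer_,
      csd_flagged = NA, csd_profile = NULL, unalignable = TRUE,
      log = sprintf("%s: no visual bursts detected on any channel; session unalignable",
                    label)
    ), class = "sc_session_result"))
  }
  sel_all <- select_alignment_channel(det_all)
  tr_idx <- sel_all$align_times$trial_id
  burst_lat <- mean(sel_all$align_times$align_time -
                      ev_all$target_onset[match(tr_idx, ev_all$trial_id)])
  lfp_time <- attr(session$lfp, "time_ms")
  avg_lfp <- apply(session$lfp[, , tr_idx, drop = FALSE], c(1, 2), mean)
  csd <- compute_csd(avg_lfp, spacing = 1, time_ms = lfp_time - burst_lat)
  prof <- csd_mean_profile(csd, window = csd_window)
  ref <- detect_reference_channel(prof)

  rows <- list()
  delay_rows <- list()
  align_rows <- list()
  for (task in tasks) {
    ev <- ev_all[ev_all$task == task, ]
    det <- det_all[det_all$trial_id %in% ev$trial_id, ]
    sel <- select_alignment_channel(det)
    n_disc <- nrow(ev) - nrow(sel$align_times)
    if (n_disc > 0) {
      log <- c(log, sprintf(
        "%s/%s: discarded %d trials with no burst on alignment channel %d",
        label, task, n_disc, sel$channel))
    }
    align_rows[[task]] <- tibble::tibble(
      task = task, alignment_channel = sel$channel,
      n_trials_retained = nrow(sel$align_times))
    vis_win <- c(-200, 900)
    delay_end <- min(c(ev$go_cue[match(sel$align_times$trial_id, ev$trial_id)] -
                         sel$align_times$align_time, vis_win[2]))
    mv <- ev[ev$saccade_latency >= 200 & ev$saccade_latency <= 400, ]
    if (nrow(mv) < nrow(ev)) {
      log <- c(log, sprintf(
        "%s/%s: excluded %d trials outside the 200-400 ms saccade-latency range",
        label, task, nrow(ev) - nrow(mv)))
    }
    sacc_align <- tibble::tibble(trial_id = mv$trial_id,
                                 align_time = mv$saccade_onset)
    go_align <- tibble::tibble(trial_id = mv$trial_id,
                               align_time = mv$go_cue)

    for (ch in seq_len(session$meta$n_channels)) {
      sp <- session$spikes[session$spikes$channel == ch, ]

      # visual frame
      wv_raw <- spike_density(sp, sel$align_times, vis_win, "visual_burst")
      vis_base_tr <- attr(epoch_mean(wv_raw, c(-150, -50)), "per_trial")
      wv <- baseline_correct(wv_raw, c(-150, -50))
      onset <- estimate_visual_onset(wv)
      v_rate <- epoch_mean(wv, c(0, 100))
      vis_tr <- attr(epoch_mean(wv_raw, c(0, 100)), "per_trial")
      pk <- last_visual_peak(wv)
      db <- delay_bins(wv, from = pk, to = delay_end)
      if (nrow(db) > 0) {
        delay_rows[[length(delay_rows) + 1]] <-
          dplyr::mutate(db, task = task, channel = ch, .before = 1)
      }

      # movement frame
      wg <- spike_density(sp, go_align, c(-100, 0), "go_cue")
      b_go <- mean(wg$values)
      ws_raw <- spike_density(sp, sacc_align, c(-300, 100), "saccade_onset")
      ws <- ws_raw
      ws$values <- ws$values - b_go
      ws$trials <- ws$trials - b_go
      ws$baseline_window <- c(-100, 0)
      m_rate <- epoch_mean(ws, c(-25, 25))
      mov_tr <- attr(epoch_mean(ws_raw, c(-25, 25)), "per_trial")
      mov_base_tr <- rowMeans(wg$trials)

      vm <- vmi(as.numeric(v_rate), as.numeric(m_rate))
      cat_row <- dplyr::rename(
        categorize_unit(vis_tr, vis_base_tr, mov_tr, mov_base_tr),
        vm_category = "category")

      evb <- bootstrap_events(ws_raw, wg$trials[, seq_len(100), drop = FALSE],
                              go_offsets = -mv$saccade_latency,
                              n_boot = n_boot, seed = seed + 1000L * ch)
      cls <- dplyr::rename(classify_channel(evb, ws, boundary = boundary),
                           presaccadic_category = "category")
      ev_wide <- tidyr::pivot_wider(
        evb$events[, c("event", "mean", "ci_lo", "ci_hi", "reliable")],
        names_from = "event",
        values_from = c("mean", "ci_lo", "ci_hi", "reliable"),
        names_glue = "{event}_{.value}")
      p_mean <- ev_wide$P_mean
      peak_rate <- if (is.finite(p_mean %||% NA_real_)) {
        i <- match(round(p_mean), ws$time)
        if (is.na(i)) NA_real_ else ws$values[i]
      } else NA_real_

      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(task = task, channel = ch,
                       alignment_channel = sel$channel,
                       n_trials_visual = nrow(sel$align_times),
                       n_trials_movement = nrow(mv)),
        onset,
        tibble::tibble(V = vm$V, M = vm$M, vmi = vm$vmi,
                       vmi_defined = vm$defined),
        cat_row,
        ev_wide,
        cls,
        tibble::tibble(peak_rate = peak_rate)
      )
    }
  }
  structure(list(
    label = label,
    channels = dplyr::bind_rows(rows),
    delay = dplyr::bind_rows(delay_rows),
    alignment = dplyr::bind_rows(align_rows),
    reference_channel = ref$reference_channel,
    csd_flagged = ref$flagged,
    csd_profile = prof,
    unalignable = FALSE,
    log = log
  ), class = "sc_session_result")
}

#' @export
print.sc_session_result <- function(x, ...) {
  cat("<sc_session_result> ", x$label, ": reference channel ",
      x$reference_channel,
      if (x$csd_flagged) " (flagged)" else "", "\n", sep = "")
  print(x$alignment)
  invisible(x)
}

#' Aggregate per-session results into laminar population profiles
#'
#' Aligns all sessions on their CSD reference channels, then builds
#' session-averaged depth profiles (visual/movement epoch rates, VMI,
#' relative visual latency, Buildup/Burst onsets and onset rates, peak
#' rates) with bootstrap CIs, cubic depth-trend fits with permutation
#' p-values, the Burst-to-peak scaling factor, and per-depth category
#' proportions.
#'
#' @param results List of `sc_session_result` objects.
#' @param n_boot Bootstrap resamples for profile CIs (default 1000).
#' @param n_perm Permutations for cubic-fit p-values (default 1000).
#' @param seed Seed.
#' @param clip Aligned-index range retained (default `c(-8, 8)`).
#' @return An `sc_population`: `channels` (aligned per-channel table),
#'   `profiles` (named list of tibbles per task and quantity), `fits`
#'   (named list of `cubic_fit`), `scaling` (per task), `categories`
#'   (per-depth proportions), `references`.
#' @export
run_population <- function(results, n_boot = 1000, n_perm = 1000, seed = 1,
                           clip = c(-8, 8)) {
  if (length(results) == 0) stop("no session results", call. = FALSE)
  refs <- purrr::map_dfr(results, function(r) {
    tibble::tibble(session = r$label, reference_channel = r$reference_channel,
                   flagged = r$csd_flagged)
  })
  channels <- purrr::map_dfr(results, function(r) {
    dplyr::mutate(r$channels, session = r$label, .before = 1)
  })
  channels <- align_sessions(channels, refs, clip = clip)

  # visual latency relative to each session's reference channel
  channels <- channels |>
    dplyr::group_by(.data$session, .data$task) |>
    dplyr::mutate(rel_latency = ifelse(
      .data$detected & any(.data$aligned == 0 & .data$detected),
      .data$Lv - .data$Lv[match(0, .data$aligned)],
      NA_real_)) |>
    dplyr::ungroup()

  quantities <- c(
    V = "V", M = "M", vmi = "vmi", rel_latency = "rel_latency",
    buildup_onset = "buildup_onset", burst_onset = "burst_onset",
    buildup_rate = "buildup_rate", burst_rate = "burst_rate",
    peak_rate = "peak_rate"
  )
  profiles <- list()
  fits <- list()
  scaling <- list()
  for (task in unique(channels$task)) {
    sub <- channels[channels$task == task, ]
    for (q in names(quantities)) {
      d <- tibble::tibble(session = sub$session, aligned = sub$aligned,
                          value = sub[[quantities[[q]]]])
      profiles[[paste(task, q, sep = ".")]] <-
        population_aggregate(d, n_boot = n_boot, seed = seed)
    }
    fit_q <- function(q) {
      pr <- profiles[[paste(task, q, sep = ".")]]
      ok <- is.finite(pr$mean)
      if (sum(ok) < 5) return(NULL)
      cubic_fit_permutation(pr$aligned[ok], pr$mean[ok], n_perm = n_perm,
                            seed = seed)
    }
    for (q in c("rel_latency", "buildup_onset", "burst_onset",
                "burst_rate", "peak_rate", "vmi")) {
      fits[[paste(task, q, sep = ".")]] <- fit_q(q)
    }
    bf <- fits[[paste(task, "burst_rate", sep = ".")]]
    pf <- fits[[paste(task, "peak_rate", sep = ".")]]
    if (!is.null(bf) && !is.null(pf)) {
      scaling[[task]] <- burst_peak_scaling(bf, pf)
    }
  }

  categories <- dplyr::bind_rows(
    channels |>
      dplyr::count(.data$task, .data$aligned,
                   category = .data$presaccadic_category) |>
      dplyr::group_by(.data$task, .data$aligned) |>
      dplyr::mutate(kind = "presaccadic", proportion = .data$n / sum(.data$n)) |>
      dplyr::ungroup(),
    channels |>
      dplyr::count(.data$task, .data$aligned, category = .data$vm_category) |>
      dplyr::group_by(.data$task, .data$aligned) |>
      dplyr::mutate(kind = "visuomotor", proportion = .data$n / sum(.data$n)) |>
      dplyr::ungroup()
  )

  structure(list(channels = channels, profiles = profiles, fits = fits,
                 scaling = scaling, categories = categories,
                 references = refs),
            class = "sc_population")
}

#' @export
print.sc_population <- function(x, ...) {
  cat("<sc_population>", length(unique(x$channels$session)), "sessions,",
      nrow(x$channels), "aligned channel records\n")
  for (nm in names(x$scaling)) {
    cat("  ", nm, " Burst-to-peak scaling factor: ",
        round(x$scaling[[nm]]$factor, 2), "\n", sep = "")
  }
  invisible(x)
}

#' Depth-profile plot for an aggregated quantity
#'
#' @param population An `sc_population`.
#' @param quantity Profile name, e.g. `"VG.vmi"` (see
#'   `names(population$profiles)`).
#' @return A ggplot.
#' @export
plot_depth_profile <- function(population, quantity) {
  pr <- population$profiles[[quantity]]
  if (is.null(pr)) stop("unknown profile: ", quantity, call. = FALSE)
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$mean, y = .data$aligned)) +
    ggplot2::geom_ribbon(ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
                         alpha = 0.2, orientation = "y") +
    ggplot2::geom_path(orientation = "y") +
    ggplot2::geom_point() +
    ggplot2::labs(x = quantity, y = "aligned channel index (0 = reference)")
}

#' Generate and analyse a batch of synthetic sessions end to end
#'
#' @param n_sessions Number of sessions.
#' @param config Base `sc_config`; session i uses `seed + i` and, when
#'   `vary_reference`, a reference channel shifted by `(i %% 3) - 1` to
#'   emulate different probe depths.
#' @param seed Master seed.
#' @param vary_reference Vary probe depth across sessions (default TRUE).
#' @param n_boot,n_perm,... Passed to [run_session()] / [run_population()].
#' @return List: `sessions` (results per session), `population`.
#' @export
run_pipeline <- function(n_sessions, config = laminar_config(), seed = 1,
                         vary_reference = TRUE, n_boot = 100,
                         n_perm = 1000, ...) {
  results <- vector("list", n_sessions)
  for (i in seq_len(n_sessions)) {
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    if (vary_reference) {
      cfg$reference_channel <- config$reference_channel + (i %% 3L) - 1L
    }
    s <- generate_session(cfg)
    results[[i]] <- run_session(s, n_boot = n_boot, seed = seed + i,
                                label = sprintf("session%02d", i), ...)
  }
  pop <- run_population(results, n_perm = n_perm, seed = seed)
  list(sessions = results, population = pop)
}
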