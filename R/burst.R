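#' Poisson surprise of a spike cluster
#'
#' S = -log P(X >= n) for X ~ Poisson(rate * duration), the improbability of
#' observing at least `n` spikes in `duration_ms` at the background rate.
#'
#' @param n Spike count in the cluster.
#' @param duration_ms Cluster duration in ms.
#' @param rate Background rate in spk/s.
#' @return Surprise value (natural log units); `Inf` when `rate * duration`
#'   is zero and `n > 0`.
#' @export
poisson_surprise <- function(n, duration_ms, rate) {
  lambda <- rate * duration_ms / 1000
  -ppois(n - 1, lambda, lower.tail = FALSE, log.p = TRUE)
}

#' Detect bursts in a spike train by Poisson surprise
#'
#' Finds, within `epoch`, contiguous spike runs whose Poisson surprise
#' against the trial's mean rate exceeds `surprise_threshold` with at least
#' `min_spikes` spikes. The surprise of every contiguous run is evaluated
#' exhaustively (the global maximizer, which the classic grow/shrink search
#' approximates); non-overlapping runs are then retained greedily from the
#' highest surprise down.
#'
#' @param spike_times Sorted spike times for one trial (ms).
#' @param epoch Two-element ms search window.
#' @param rate Background rate in spk/s; defaults to the train's mean rate
#'   over `trial_duration`.
#' @param trial_duration Trial length (ms) used for the default rate.
#' @param min_spikes Minimum spikes per burst (default 3).
#' @param surprise_threshold Minimum surprise, default -log(0.025).
#' @return Tibble of bursts, earliest first: `onset`, `offset`, `n_spikes`,
#'   `surprise`.
#' @export
poisson_surprise_bursts <- function(spike_times, epoch,
                                    rate = NULL, trial_duration = NULL,
                                    min_spikes = 3,
                                    surprise_threshold = -log(0.025)) {
  stopifnot(diff(epoch) > 0)
  empty <- tibble::tibble(onset = numeric(0), offset = numeric(0),
                          n_spikes = integer(0), surprise = numeric(0))
  if (is.null(rate)) {
    if (is.null(trial_duration)) {
      stop("supply `rate` or `trial_duration` for the background rate", call. = FALSE)
    }
    rate <- length(spike_times) / trial_duration * 1000
  }
  if (rate <= 0) return(empty)
  s <- sort(spike_times[spike_times >= epoch[1] & spike_times <= epoch[2]])
  n <- length(s)
  if (n < min_spikes) return(empty)

  cand_i <- integer(0); cand_j <- integer(0); cand_s <- numeric(0)
  for (i in seq_len(n - min_spikes + 1)) {
    j <- (i + min_spikes - 1):n
    surp <- poisson_surprise(j - i + 1, pmax(s[j] - s[i], 1e-9), rate)
    keep <- surp >= surprise_threshold
    cand_i <- c(cand_i, rep(i, sum(keep)))
    cand_j <- c(cand_j, j[keep])
    cand_s <- c(cand_s, surp[keep])
  }
  if (length(cand_s) == 0) return(empty)
  ord <- order(-cand_s, cand_i)
  used <- rep(FALSE, n)
  out <- list()
  for (k in ord) {
    span <- cand_i[k]:cand_j[k]
    if (any(used[span])) next
    used[span] <- TRUE
    out[[length(out) + 1]] <- tibble::tibble(
      onset = s[cand_i[k]], offset = s[cand_j[k]],
      n_spikes = length(span), surprise = cand_s[k]
    )
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$onset)
}

#' Per-trial visual-burst detection across a session
#'
#' Runs [poisson_surprise_bursts()] on every channel and trial in the epoch
#' `epoch_re_target` after target onset, using each trial's own mean rate on
#' that channel as the background rate. Where several bursts pass the
#' criteria in one trial the one with the highest surprise is taken as the
#' visual burst.
#'
#' @param session An `sc_session` (or any list with `spikes` and `events` in
#'   the same layout).
#' @param trials Optional trial ids to restrict to.
#' @param epoch_re_target Search epoch in ms after target onset, default
#'   `c(30, 150)`.
#' @param ... Passed to [poisson_surprise_bursts()].
#' @return Tibble with one row per (channel, trial) with a detected burst:
#'   `channel`, `trial_id`, `onset` (ms from trial start, first burst),
#'   `surprise`, `n_spikes`.
#' @export
detect_visual_bursts <- function(session, trials = NULL,
                                 epoch_re_target = c(30, 150), ...) {
  ev <- session$events
  if (!is.null(trials)) ev <- ev[ev$trial_id %in% trials, ]
  sp <- session$spikes[session$spikes$trial_id %in% ev$trial_id, ]
  totals <- dplyr::count(sp, .data$channel, .data$trial_id, name = "n_spk")
  key <- paste(sp$channel, sp$trial_id)
  groups <- split(sp$time_ms, key)
  t_target <- setNames(ev$target_onset, ev$trial_id)
  t_end <- setNames(ev$trial_end, ev$trial_id)

  out <- vector("list", length(groups))
  nms <- names(groups)
  for (g in seq_along(groups)) {
    parts <- strsplit(nms[g], " ", fixed = TRUE)[[1]]
    ch <- as.integer(parts[1]); tr <- parts[2]
    st <- groups[[g]]
    rate <- length(st) / t_end[[tr]] * 1000
    b <- poisson_surprise_bursts(
      st, epoch = t_target[[tr]] + epoch_re_target, rate = rate, ...
    )
    if (nrow(b) > 0) {
      i <- which.max(b$surprise)  # the visual burst = the dominant burst
      out[[g]] <- tibble::tibble(channel = ch, trial_id = as.integer(tr),
                                 onset = b$onset[i], surprise = b$surprise[i],
                                 n_spikes = b$n_spikes[i])
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(channel = integer(0), trial_id = integer(0),
                          onset = numeric(0), surprise = numeric(0),
                          n_spikes = integer(0)))
  }
  dplyr::arrange(res, .data$channel, .data$trial_id)
}

#' Pick the session's visual alignment channel
#'
#' The channel with bursts detected on the largest number of trials becomes
#' the alignment channel (ties broken toward the more dorsal, i.e. higher,
#' contact); trials without a burst on it are discarded, and every retained
#' trial is realigned on that channel's burst onset.
#'
#' @param detections Tibble from [detect_visual_bursts()]: one row per
#'   (channel, trial) with columns `channel`, `trial_id`, `onset`.
#' @return List with `channel` (alignment channel), `align_times` (tibble
#'   `trial_id`, `align_time`), and `n_detected` (per-channel trial counts).
#' @export
select_alignment_channel <- function(detections) {
  if (nrow(detections) == 0) {
    stop("no visual bursts detected on any channel", call. = FALSE)
  }
  counts <- dplyr::count(detections, .data$channel, name = "n")
  best <- counts[counts$n == max(counts$n), ]
  ch <- max(best$channel)   # dorsal-most among ties
  keep <- detections[detections$channel == ch, ]
  list(
    channel = ch,
    align_times = tibble::tibble(trial_id = keep$trial_id,
                                 align_time = keep$onset),
    n_detected = counts
  )
}
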