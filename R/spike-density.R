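EPSP_TAU_GROWTH <- 1
EPSP_TAU_DECAY <- 20

# Discrete 1 ms EPSP-shaped kernel R(t) = (1 - exp(-t/tau_g)) * exp(-t/tau_d),
# causal, truncated at `support` ms and renormalized to unit area so that a
# lone spike integrates to exactly 1 within `support` ms.
epsp_kernel <- function(support = 100) {
  t <- 0:support
  k <- (1 - exp(-t / EPSP_TAU_GROWTH)) * exp(-t / EPSP_TAU_DECAY)
  k / sum(k)
}

#' Spike-density waveform aligned on a per-trial event
#'
#' Shifts each trial's spikes into the alignment frame, bins at 1 ms,
#' convolves with a causal EPSP-shaped kernel (growth and decay time
#' constants 1 and 20 ms) normalized to unit area, and averages across
#' trials. The per-trial rate matrix is retained for distribution-based
#' tests.
#'
#' @param spikes Data frame with `trial_id` and `time_ms` (spike times, ms
#'   from trial start) for one channel.
#' @param align_times Data frame with `trial_id` and `align_time` (ms from
#'   trial start), one row per included trial. Trials listed here but without
#'   spikes contribute zero traces.
#' @param window Two-element ms window relative to the alignment event.
#' @param alignment_event Label recorded on the result.
#' @return A `rate_waveform`: list with `time` (ms, 1 ms grid), `values`
#'   (trial-averaged spk/s), `trials` (trials x time matrix), `n_trials`,
#'   `alignment_event`, `baseline_window` (`NULL` until
#'   [baseline_correct()]).
#' @export
spike_density <- function(spikes, align_times, window,
                          alignment_event = "event") {
  stopifnot(all(c("trial_id", "align_time") %in% names(align_times)))
  if (nrow(align_times) == 0) stop("empty trial set", call. = FALSE)
  support <- 100
  kern <- epsp_kernel(support)
  time <- seq(window[1], window[2])
  pad <- support
  bins <- seq(window[1] - pad, window[2])
  n_bins <- length(bins)
  n_trials <- nrow(align_times)

  counts <- matrix(0, nrow = n_bins, ncol = n_trials)
  if (nrow(spikes) > 0) {
    sp <- dplyr::inner_join(spikes, align_times, by = "trial_id")
    rel <- sp$time_ms - sp$align_time
    b <- floor(rel - (window[1] - pad) + 0.5) + 1L
    tr <- match(sp$trial_id, align_times$trial_id)
    keep <- b >= 1L & b <= n_bins
    if (any(keep)) {
      tab <- table(factor(b[keep], levels = seq_len(n_bins)),
                   factor(tr[keep], levels = seq_len(n_trials)))
      counts <- counts + unclass(tab)
    }
  }
  dens <- stats::filter(counts, kern, method = "convolution", sides = 1)
  dens <- matrix(as.numeric(dens), nrow = n_bins)
  dens <- dens[(pad + 1):n_bins, , drop = FALSE] * 1000  # spk/s
  trials <- t(dens)
  rownames(trials) <- align_times$trial_id
  new_rate_waveform(time, colMeans(trials), trials,
                    alignment_event = alignment_event)
}

new_rate_waveform <- function(time, values, trials, alignment_event = "event",
                              baseline_window = NULL) {
  structure(
    list(
      time = time,
      values = as.numeric(values),
      trials = trials,
      n_trials = nrow(trials),
      alignment_event = alignment_event,
      baseline_window = baseline_window
    ),
    class = "rate_waveform"
  )
}

#' @export
print.rate_waveform <- function(x, ...) {
  cat("<rate_waveform> aligned on ", x$alignment_event, ", [",
      x$time[1], ", ", x$time[length(x$time)], "] ms, ",
      x$n_trials, " trials",
      if (!is.null(x$baseline_window)) {
        paste0(", baseline [", x$baseline_window[1], ", ",
               x$baseline_window[2], "] ms")
      } else "",
      "\n", sep = "")
  invisible(x)
}

#' @method tidy rate_waveform
#' @export
tidy.rate_waveform <- function(x, ...) {
  tibble::tibble(time_ms = x$time, rate = x$values)
}

#' @method autoplot rate_waveform
#' @export
autoplot.rate_waveform <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$time_ms, y = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = paste0("time re ", object$alignment_event, " (ms)"),
                  y = "rate (spk/s)")
}

wv_index <- function(waveform, window) {
  i1 <- match(window[1], waveform$time)
  i2 <- match(window[2], waveform$time)
  if (is.na(i1) || is.na(i2)) {
    stop("window [", window[1], ", ", window[2],
         "] ms outside waveform support", call. = FALSE)
  }
  i1:i2
}

#' Baseline-correct a rate waveform
#'
#' Subtracts the scalar mean of the trial-averaged waveform over
#' `baseline_window` from the average and from every per-trial trace, and
#' records the window used.
#'
#' @param waveform A `rate_waveform`.
#' @param baseline_window Two-element ms window inside the waveform support.
#' @return The corrected `rate_waveform`.
#' @export
baseline_correct <- function(waveform, baseline_window) {
  idx <- wv_index(waveform, baseline_window)
  b <- mean(waveform$values[idx])
  waveform$values <- waveform$values - b
  waveform$trials <- waveform$trials - b
  waveform$baseline_window <- baseline_window
  waveform
}

#' Mean rate over an epoch
#'
#' Arithmetic mean of the trial-averaged waveform over `window`; per-trial
#' epoch means (for rank-sum tests) are attached as attribute `per_trial`.
#'
#' @param waveform A `rate_waveform`.
#' @param window Two-element ms window inside the waveform support.
#' @return Scalar spk/s with attribute `per_trial`.
#' @export
epoch_mean <- function(waveform, window) {
  idx <- wv_index(waveform, window)
  out <- mean(waveform$values[idx])
  attr(out, "per_trial") <- rowMeans(waveform$trials[, idx, drop = FALSE])
  out
}

#' Velocity-criterion saccade onset detection
#'
#' Returns the time (ms after the go cue) of the first 1 kHz sample at or
#' after the go cue whose eye velocity reaches `threshold`.
#'
#' @param velocity Data frame with `time_ms` (ms from trial start, 1 kHz) and
#'   `velocity` (deg/s).
#' @param go_cue Go-cue time (ms from trial start).
#' @param threshold Velocity criterion in deg/s (default 30).
#' @return Onset in ms re go cue, or `NA_real_` if the threshold is never
#'   crossed.
#' @export
detect_saccade_onset <- function(velocity, go_cue, threshold = 30) {
  stopifnot(threshold > 0)
  if (max(velocity$time_ms) < go_cue) {
    stop("velocity trace ends before the go cue", call. = FALSE)
  }
  v <- velocity[velocity$time_ms >= go_cue, ]
  v <- v[order(v$time_ms), ]
  hit <- which(v$velocity >= threshold)
  if (length(hit) == 0) return(NA_real_)
  v$time_ms[hit[1]] - go_cue
}
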