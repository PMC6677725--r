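#' Remove the delay-period linear trend from a saccade-aligned waveform
#'
#' Fits a least-squares line to the trial-averaged activity on
#' \[-300, -200\] ms before saccade onset, extrapolates it over the whole
#' support and subtracts it (from the average and every per-trial trace).
#' Used only for the E1 significance scan; later event detections operate on
#' the raw waveform.
#'
#' @param waveform A saccade-aligned `rate_waveform` covering
#'   \[-300, +50\] ms or more.
#' @param trend_window Fit window, default `c(-300, -200)`.
#' @return The detrended `rate_waveform` with a `trend` element
#'   `(intercept, slope)`.
#' @export
detrend_presaccadic <- function(waveform, trend_window = c(-300, -200)) {
  idx <- wv_index(waveform, trend_window)
  tt <- waveform$time[idx]
  fit <- segment_regression(tt, waveform$values[idx])$fit(1, length(idx))
  line <- fit["intercept"] + fit["slope"] * waveform$time
  waveform$values <- waveform$values - line
  waveform$trials <- sweep(waveform$trials, 2, line)
  waveform$trend <- fit
  waveform
}

# Vectorized per-bin Welch t test of the across-trial activity distribution
# against a pooled baseline distribution. Returns two-sided p per column.
bin_welch_p <- function(trials, base_mean, base_var, base_n, tol = 1e-12) {
  n <- nrow(trials)
  m <- colMeans(trials)
  v <- (colSums(trials^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  p <- numeric(length(m))
  degen <- v < tol & base_var < tol
  p[degen] <- ifelse(abs(m[degen] - base_mean) < tol, 1, 0)
  i <- !degen
  if (any(i)) {
    se2a <- v[i] / n
    se2b <- base_var / base_n
    tstat <- (m[i] - base_mean) / sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 /
      (se2a^2 / (n - 1) + se2b^2 / (base_n - 1))
    p[i] <- 2 * pt(-abs(tstat), df)
  }
  p
}

#' Single-replicate E1: first sustained significant departure from baseline
#'
#' Scans 1 ms bins from `scan_from` (default -200 ms re saccade): E1b is the
#' first bin whose across-trial activity differs from the pooled baseline
#' distribution (Welch t test, two-sided, P < `alpha`) and stays significant
#' for at least `persist_ms` consecutive bins. Bins whose activity and
#' baseline both have zero variance are significant iff the means differ.
#'
#' @param trials Detrended trials x time matrix (saccade-aligned).
#' @param time Time axis (ms) matching the columns.
#' @param baseline Numeric vector pooling the per-trial activity in the
#'   100 ms before the go cue (time points x trials values).
#' @param scan_from First candidate bin (ms), default -200.
#' @param persist_ms Required run of significance (default 100).
#' @param alpha Test level (default 0.01).
#' @return E1b in ms, or `NA_real_`.
#' @export
detect_E1_single <- function(trials, time, baseline, scan_from = -200,
                             persist_ms = 100, alpha = 0.01) {
  if (nrow(trials) < 2) stop("need >= 2 trials", call. = FALSE)
  p <- bin_welch_p(trials, mean(baseline), var(baseline), length(baseline))
  sig <- p < alpha
  first <- match(scan_from, time)
  if (is.na(first)) stop("scan start outside waveform support", call. = FALSE)
  nb <- length(time)
  # reverse cumulative run length of significant bins starting at each index
  runs <- integer(nb)
  acc <- 0L
  for (i in nb:1) {
    acc <- if (sig[i]) acc + 1L else 0L
    runs[i] <- acc
  }
  hit <- which(runs[first:nb] >= persist_ms)
  if (length(hit) == 0) return(NA_real_)
  time[first + hit[1] - 1]
}

#' Single-replicate E2: hinge point at or before E1
#'
#' Exhaustive two-piecewise fit of the raw averaged waveform on
#' \[E1b - 100, E1b\]; the breakpoint minimizing total residuals is E2b
#' (E2b <= E1b by construction).
#'
#' @param values Raw trial-averaged waveform.
#' @param time Matching time axis (ms).
#' @param e1b E1 estimate for this replicate (ms).
#' @return E2b in ms, or `NA_real_` if the window is too short.
#' @export
detect_E2_single <- function(values, time, e1b) {
  if (is.na(e1b)) return(NA_real_)
  lo <- max(e1b - 100, time[1])
  idx <- which(time >= lo & time <= e1b)
  if (length(idx) < 5) return(NA_real_)
  two_piecewise_fit(time[idx], values[idx])$breakpoint
}

#' Single-replicate E3: hinge point between E2 and the peak
#'
#' Two-piecewise fit of the raw averaged waveform between E2b and Pb; the
#' slopes of the two segments are returned for the cross-bootstrap
#' slope-overlap significance test.
#'
#' @param values Raw trial-averaged waveform.
#' @param time Matching time axis (ms).
#' @param e2b,pb Replicate E2 and peak-time estimates (ms).
#' @return List `e3b`, `slope_before`, `slope_after` (all `NA` if the window
#'   has fewer than 6 points).
#' @export
detect_E3_single <- function(values, time, e2b, pb) {
  miss <- list(e3b = NA_real_, slope_before = NA_real_, slope_after = NA_real_)
  if (is.na(e2b) || is.na(pb) || pb <= e2b) return(miss)
  idx <- which(time >= e2b & time <= pb)
  if (length(idx) < 6) return(miss)
  fit <- two_piecewise_fit(time[idx], values[idx])
  list(e3b = fit$breakpoint, slope_before = fit$slope1,
       slope_after = fit$slope2)
}

#' Bootstrap estimation of pre-saccadic events E1, E2, E3 and P
#'
#' Resamples trials with replacement `n_boot` times; each replicate fits the
#' delay-period trend on \[-300, -200\], subtracts its extrapolation from
#' the resampled trials, expresses the pre-go baseline distribution relative
#' to the fitted level over the trend window (activity and baseline are then
#' on the same pre-movement reference), and runs the E1 significance scan;
#' the E2 and E3 hinge fits and the peak search use the raw resampled
#' average. Events
#' are aggregated as the mean of the replicate estimates with 95% quantile
#' CIs; a CI range, normalized per event (E1: 200 ms; E2: 100 ms; E3: the
#' mean E2b-to-Pb interval; P: the peak-window length), above
#' `reliability_threshold` marks the event unreliable, as does detection in
#' fewer than `min_detect_rate` of replicates. E3 additionally requires the
#' 95% quantile intervals of the before/after slope distributions to be
#' disjoint.
#'
#' @param waveform Raw saccade-aligned `rate_waveform` covering
#'   \[-300, +100\] ms, restricted to trials with saccade latency in the
#'   standard 200-400 ms range.
#' @param baseline_trials Trials x time matrix of go-cue-aligned activity in
#'   the 100 ms before the go cue, rows matching `waveform$trials`.
#' @param go_offsets Per-trial go-cue times relative to saccade onset (ms,
#'   negative); retained for provenance in outputs.
#' @param n_boot Bootstrap replicates (default 100).
#' @param seed Master seed; replicate r uses `seed + r`.
#' @param peak_window Search window for P (default `c(-50, 100)`).
#' @param reliability_threshold Normalized-CI-range gate (default 0.6).
#' @param min_detect_rate Minimum fraction of replicates detecting an event
#'   (default 0.5).
#' @return A `presaccadic_events` list: `events` tibble (one row per event:
#'   `event`, `mean`, `ci_lo`, `ci_hi`, `normalized_ci_range`, `detect_rate`,
#'   `reliable`), `replicates` tibble, and `slope_significant`.
#' @export
bootstrap_events <- function(waveform, baseline_trials, go_offsets = NULL,
                             n_boot = 100,
                             seed = 1, peak_window = c(-50, 100),
                             reliability_threshold = 0.6,
                             min_detect_rate = 0.5) {
  trials <- waveform$trials
  time <- waveform$time
  n <- nrow(trials)
  if (n < 2) stop("need >= 2 trials for bootstrapping", call. = FALSE)
  stopifnot(nrow(baseline_trials) == n)
  trend_idx <- wv_index(waveform, c(-300, -200))
  pk_idx <- wv_index(waveform, peak_window)

  reps <- vector("list", n_boot)
  for (r in seq_len(n_boot)) {
    idx <- with_local_seed(seed + r, sample.int(n, n, replace = TRUE))
    sub <- trials[idx, , drop = FALSE]
    avg <- colMeans(sub)
    # detrend for E1 only
    fit <- segment_regression(time[trend_idx], avg[trend_idx])$fit(1, length(trend_idx))
    line <- fit["intercept"] + fit["slope"] * time
    detr <- sweep(sub, 2, line)
    # express the baseline relative to the same fitted pre-movement level
    base <- as.numeric(baseline_trials[idx, , drop = FALSE]) -
      mean(line[trend_idx])
    e1b <- detect_E1_single(detr, time, base)
    e2b <- detect_E2_single(avg, time, e1b)
    pb <- time[pk_idx][which.max(avg[pk_idx])]
    e3 <- detect_E3_single(avg, time, e2b, pb)
    reps[[r]] <- tibble::tibble(rep = r, E1b = e1b, E2b = e2b, Pb = pb,
                                E3b = e3$e3b, slope_before = e3$slope_before,
                                slope_after = e3$slope_after)
  }
  reps <- dplyr::bind_rows(reps)

  summarize_event <- function(x, normalizer) {
    det <- x[!is.na(x)]
    rate <- length(det) / n_boot
    if (length(det) == 0) {
      return(tibble::tibble(mean = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                            normalized_ci_range = NA_real_, detect_rate = rate,
                            reliable = FALSE))
    }
    ci <- unname(quantile(det, c(0.025, 0.975), type = 7))
    nrm <- (ci[2] - ci[1]) / normalizer
    tibble::tibble(mean = mean(det), ci_lo = ci[1], ci_hi = ci[2],
                   normalized_ci_range = nrm, detect_rate = rate,
                   reliable = nrm <= reliability_threshold &&
                     rate >= min_detect_rate)
  }
  e3_norm <- mean(reps$Pb - reps$E2b, na.rm = TRUE)
  if (!is.finite(e3_norm) || e3_norm <= 0) e3_norm <- diff(peak_window)
  ev <- dplyr::bind_rows(
    dplyr::mutate(summarize_event(reps$E1b, 200), event = "E1", .before = 1),
    dplyr::mutate(summarize_event(reps$E2b, 100), event = "E2", .before = 1),
    dplyr::mutate(summarize_event(reps$E3b, e3_norm), event = "E3", .before = 1),
    dplyr::mutate(summarize_event(reps$Pb, diff(peak_window)), event = "P", .before = 1)
  )
  # E3 is a hinge only if the before/after slope CIs do not overlap
  sb <- reps$slope_before[!is.na(reps$slope_before)]
  sa <- reps$slope_after[!is.na(reps$slope_after)]
  slope_sig <- FALSE
  if (length(sb) >= 2 && length(sa) >= 2) {
    ci_b <- quantile(sb, c(0.025, 0.975))
    ci_a <- quantile(sa, c(0.025, 0.975))
    slope_sig <- ci_b[2] < ci_a[1] || ci_a[2] < ci_b[1]
  }
  ev$reliable[ev$event == "E3"] <- ev$reliable[ev$event == "E3"] && slope_sig
  structure(list(events = ev, replicates = reps,
                 slope_significant = slope_sig,
                 params = list(n_boot = n_boot, seed = seed,
                               peak_window = peak_window,
                               reliability_threshold = reliability_threshold,
                               min_detect_rate = min_detect_rate)),
            class = "presaccadic_events")
}

#' @export
print.presaccadic_events <- function(x, ...) {
  cat("<presaccadic_events>", x$params$n_boot, "bootstrap replicates\n")
  print(x$events)
  invisible(x)
}

#' @method tidy presaccadic_events
#' @export
tidy.presaccadic_events <- function(x, ...) x$events

#' Classify a channel's pre-saccadic activity into Buildup / Burst
#'
#' Events are labeled by the boundary at `boundary` ms re saccade onset:
#' earlier events are Buildup, later ones Burst. When E2 and E3 are both
#' reliable with disjoint CIs each is labeled separately; when their CIs
#' overlap they are treated as a single event at E3; when only one is
#' reliable it is labeled by the boundary alone. Rates at the event onsets
#' are read from the supplied (baseline-corrected) waveform.
#'
#' @param events A `presaccadic_events` object.
#' @param waveform Baseline-corrected saccade-aligned `rate_waveform`.
#' @param boundary Buildup/Burst boundary in ms (default -50).
#' @return One-row tibble: `buildup_present`, `buildup_onset`,
#'   `buildup_rate`, `burst_present`, `burst_onset`, `burst_rate`,
#'   `category` (one of `"Buildup-only"`, `"Burst-only"`,
#'   `"Buildup-Burst"`, `"none"`).
#' @export
classify_channel <- function(events, waveform, boundary = -50) {
  ev <- events$events
  get <- function(nm) ev[ev$event == nm, ]
  e2 <- get("E2"); e3 <- get("E3")
  cand <- numeric(0)
  if (e2$reliable && e3$reliable) {
    disjoint <- e2$ci_hi < e3$ci_lo || e3$ci_hi < e2$ci_lo
    cand <- if (disjoint) c(e2$mean, e3$mean) else e3$mean
  } else if (e2$reliable) {
    cand <- e2$mean
  } else if (e3$reliable) {
    cand <- e3$mean
  }
  rate_at <- function(t) {
    i <- match(round(t), waveform$time)
    if (is.na(i)) NA_real_ else waveform$values[i]
  }
  bu <- cand[cand < boundary]
  br <- cand[cand >= boundary]
  buildup_present <- length(bu) > 0
  burst_present <- length(br) > 0
  tibble::tibble(
    buildup_present = buildup_present,
    buildup_onset = if (buildup_present) min(bu) else NA_real_,
    buildup_rate = if (buildup_present) rate_at(min(bu)) else NA_real_,
    burst_present = burst_present,
    burst_onset = if (burst_present) min(br) else NA_real_,
    burst_rate = if (burst_present) rate_at(min(br)) else NA_real_,
    category = if (buildup_present && burst_present) "Buildup-Burst"
               else if (buildup_present) "Buildup-only"
               else if (burst_present) "Burst-only"
               else "none"
  )
}
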