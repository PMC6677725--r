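#' Visuomotor index
#'
#' `VMI = (M - V) / (M + V)` contrasting the movement-epoch rate M (mean
#' over \[-25, 25\] ms re saccade onset, baseline corrected) with the
#' visual-epoch rate V (mean over \[0, 100\] ms after visual burst onset,
#' baseline corrected). -1 is a purely visual unit, +1 purely motor.
#'
#' @param v,m Baseline-corrected epoch rates in spk/s (vectorized).
#' @return Tibble with `V`, `M`, `vmi`, `defined` (`FALSE` where
#'   `V + M == 0`).
#' @export
#' @examples
#' vmi(50, 0)$vmi   # -1
#' vmi(0, 120)$vmi  # +1
vmi <- function(v, m) {
  denom <- v + m
  defined <- denom != 0
  tibble::tibble(V = v, M = m,
                 vmi = ifelse(defined, (m - v) / denom, NA_real_),
                 defined = defined)
}

#' Categorize a channel as visual-only / visuo-movement / movement-only
#'
#' Each epoch counts as significant if the across-trial distribution of its
#' (non-baseline-corrected) epoch rates differs from the matched per-trial
#' baseline rates (Wilcoxon rank-sum, P < `p_threshold`) AND the
#' baseline-corrected mean rate reaches `rate_threshold` spk/s.
#'
#' @param visual,visual_baseline Per-trial visual-epoch and visual-baseline
#'   mean rates (spk/s, not baseline corrected).
#' @param movement,movement_baseline Per-trial movement-epoch and go-cue
#'   baseline mean rates.
#' @param p_threshold Rank-sum significance level (default 0.001).
#' @param rate_threshold Minimum baseline-corrected rate (default 10 spk/s).
#' @return One-row tibble: `visual_significant`, `movement_significant`,
#'   `category` (`"visual-only"`, `"visuo-movement"`, `"movement-only"` or
#'   `"none"`).
#' @export
categorize_unit <- function(visual, visual_baseline, movement,
                            movement_baseline, p_threshold = 0.001,
                            rate_threshold = 10) {
  if (length(visual) < 5 || length(movement) < 5) {
    stop("need >= 5 trials per epoch to categorize", call. = FALSE)
  }
  sig <- function(x, b) {
    corrected <- mean(x) - mean(b)
    if (corrected < rate_threshold) return(FALSE)
    if (all(x == x[1]) && all(b == b[1])) return(x[1] != b[1])
    suppressWarnings(wilcox.test(x, b)$p.value) < p_threshold
  }
  vs <- sig(visual, visual_baseline)
  ms <- sig(movement, movement_baseline)
  tibble::tibble(
    visual_significant = vs,
    movement_significant = ms,
    category = if (vs && ms) "visuo-movement"
               else if (vs) "visual-only"
               else if (ms) "movement-only"
               else "none"
  )
}

#' Time of the last visual-burst peak
#'
#' Final local maximum of the trial-averaged waveform within `epoch` whose
#' amplitude exceeds `frac` of the epoch maximum (visual bursts often show
#' two peaks).
#'
#' @param waveform Visual-burst-aligned `rate_waveform`.
#' @param epoch Search epoch, default `c(0, 150)` ms.
#' @param frac Amplitude fraction of the epoch maximum (default 0.5).
#' @return Peak time in ms.
#' @export
last_visual_peak <- function(waveform, epoch = c(0, 150), frac = 0.5) {
  idx <- wv_index(waveform, epoch)
  v <- waveform$values[idx]
  tt <- waveform$time[idx]
  n <- length(v)
  is_peak <- c(FALSE, v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n],
               FALSE)
  qual <- is_peak & v >= frac * max(v)
  if (!any(qual)) return(tt[which.max(v)])
  tt[max(which(qual))]
}

#' Delay-period activity in 50 ms bins
#'
#' Baseline-corrected mean activity in non-overlapping `bin_ms` bins from
#' the last peak of the visual burst to the end of the shortest delay
#' period.
#'
#' @param waveform Baseline-corrected visual-burst-aligned `rate_waveform`.
#' @param from Start time (ms), typically [last_visual_peak()].
#' @param to End time (ms), the end of the shortest delay period in the
#'   visual-burst frame.
#' @param bin_ms Bin width (default 50).
#' @return Tibble with `bin`, `t_start`, `t_end`, `rate`; zero rows if the
#'   window is shorter than one bin.
#' @export
delay_bins <- function(waveform, from, to, bin_ms = 50) {
  n_bins <- floor((to - from) / bin_ms)
  if (n_bins < 1) {
    return(tibble::tibble(bin = integer(0), t_start = numeric(0),
                          t_end = numeric(0), rate = numeric(0)))
  }
  purrr::map_dfr(seq_len(n_bins), function(b) {
    w <- c(from + (b - 1) * bin_ms, from + b * bin_ms - 1)
    tibble::tibble(bin = b, t_start = w[1], t_end = w[2],
                   rate = mean(waveform$values[wv_index(waveform, w)]))
  })
}

#' Cubic depth-trend fit with a permutation p-value
#'
#' Least-squares fit of `y = a x^3 + b x^2 + c x + d` against aligned depth
#' index `x`. Significance is assessed by shuffling `y` `n_perm` times,
#' refitting, and reporting the fraction of shuffled R-squared values
#' greater than or equal to the observed one.
#'
#' @param x Aligned depth indices.
#' @param y Values (one per index).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the permutations.
#' @return A `cubic_fit`: `coefficients` (d, c, b, a order as returned by
#'   the linear model), `r_squared`, `p_perm`, `n_perm`, `significant`
#'   (p < 0.05), and `predict(x)`.
#' @export
cubic_fit_permutation <- function(x, y, n_perm = 1000, seed = 1) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5) stop("need >= 5 points for a cubic fit", call. = FALSE)
  X <- cbind(1, x, x^2, x^3)
  r2 <- function(yy) {
    fit <- stats::lm.fit(X, yy)
    tss <- sum((yy - mean(yy))^2)
    if (tss <= 0) return(0)
    1 - sum(fit$residuals^2) / tss
  }
  obs_fit <- stats::lm.fit(X, y)
  obs_r2 <- r2(y)
  perm_r2 <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) r2(sample(y)), numeric(1))
  })
  p <- sum(perm_r2 >= obs_r2) / n_perm
  beta <- unname(obs_fit$coefficients)
  structure(list(
    coefficients = c(d = beta[1], c = beta[2], b = beta[3], a = beta[4]),
    r_squared = obs_r2,
    p_perm = p,
    n_perm = n_perm,
    significant = p < 0.05,
    x_range = range(x),
    predict = function(xx) beta[1] + beta[2] * xx + beta[3] * xx^2 + beta[4] * xx^3
  ), class = "cubic_fit")
}

#' @export
print.cubic_fit <- function(x, ...) {
  cat("<cubic_fit> R^2 =", round(x$r_squared, 3),
      "; permutation p =", x$p_perm,
      if (x$significant) "(significant)" else "(n.s.)", "\n")
  invisible(x)
}

#' @method tidy cubic_fit
#' @export
tidy.cubic_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @method glance cubic_fit
#' @export
glance.cubic_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, p.value = x$p_perm,
                 n.perm = x$n_perm, significant = x$significant)
}

#' Burst-to-peak scaling factor between two depth-trend fits
#'
#' Ratio of the maxima of two cubic fits (peak-amplitude over
#' burst-onset-amplitude) evaluated on a fine grid over their common index
#' range, plus the rescaled burst curve for comparison.
#'
#' @param burst_fit,peak_fit `cubic_fit` objects over the same aligned-index
#'   range.
#' @param step Grid step (default 0.01 channel).
#' @return List: `factor`, `curve` (tibble `x`, `burst`, `peak`,
#'   `burst_rescaled`).
#' @export
burst_peak_scaling <- function(burst_fit, peak_fit, step = 0.01) {
  lo <- max(burst_fit$x_range[1], peak_fit$x_range[1])
  hi <- min(burst_fit$x_range[2], peak_fit$x_range[2])
  xx <- seq(lo, hi, by = step)
  b <- burst_fit$predict(xx)
  p <- peak_fit$predict(xx)
  if (max(b) <= 0) stop("non-positive burst-fit maximum", call. = FALSE)
  k <- max(p) / max(b)
  list(factor = k,
       curve = tibble::tibble(x = xx, burst = b, peak = p,
                              burst_rescaled = k * b))
}

#' Aggregate a per-session depth profile across sessions
#'
#' For each aligned index, averages the per-session values and attaches a
#' 95% bootstrap CI (`n_boot` resamples of sessions with replacement).
#' Indices observed in a single session are reported without a CI and
#' flagged.
#'
#' @param data Data frame with columns `aligned` and `value` (one row per
#'   session x index); extra grouping columns may be included via `group`.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed.
#' @param conf Confidence level (default 0.95).
#' @return Tibble: `aligned`, `n_sessions`, `mean`, `ci_lo`, `ci_hi`,
#'   `single_session`.
#' @export
population_aggregate <- function(data, n_boot = 1000, seed = 1, conf = 0.95) {
  stopifnot(all(c("aligned", "value") %in% names(data)))
  a <- (1 - conf) / 2
  with_local_seed(seed, {
    data |>
      dplyr::filter(is.finite(.data$value)) |>
      dplyr::group_by(.data$aligned) |>
      dplyr::group_modify(function(d, key) {
        v <- d$value
        if (length(v) < 2) {
          return(tibble::tibble(n_sessions = length(v), mean = mean(v),
                                ci_lo = mean(v), ci_hi = mean(v),
                                single_session = TRUE))
        }
        bm <- matrix(sample(v, length(v) * n_boot, replace = TRUE),
                     nrow = n_boot)
        ci <- unname(quantile(rowMeans(bm), c(a, 1 - a)))
        tibble::tibble(n_sessions = length(v), mean = mean(v),
                       ci_lo = ci[1], ci_hi = ci[2], single_session = FALSE)
      }) |>
      dplyr::ungroup()
  })
}

#' Two-sample comparison with KS-gated test choice
#'
#' Standardizes each sample and checks normality with a Kolmogorov-Smirnov
#' test; if neither sample rejects normality a two-sided Welch t test is
#' used, otherwise a two-sided Wilcoxon rank-sum test.
#'
#' @param x,y Numeric samples.
#' @param ks_alpha Normality-rejection level (default 0.05).
#' @return Tibble: `test` (`"t"` or `"ranksum"`), `p.value`.
#' @export
compare_samples <- function(x, y, ks_alpha = 0.05) {
  normal <- function(v) {
    if (length(v) < 3 || sd(v) == 0) return(FALSE)
    suppressWarnings(ks.test((v - mean(v)) / sd(v), "pnorm")$p.value) > ks_alpha
  }
  if (normal(x) && normal(y)) {
    tibble::tibble(test = "t", p.value = t.test(x, y)$p.value)
  } else {
    tibble::tibble(test = "ranksum",
                   p.value = suppressWarnings(wilcox.test(x, y)$p.value))
  }
}
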