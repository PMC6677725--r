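# Prefix-sum machinery for O(1) simple-regression residual sums on any
# contiguous index range. Returns closures `rss(i, j)` and `fit(i, j)`.
segment_regression <- function(x, y) {
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x * x); cxy <- cumsum(x * y); cyy <- cumsum(y * y)
  seg <- function(c, i, j) c[j] - if (i > 1) c[i - 1] else 0
  rss <- function(i, j) {
    n <- j - i + 1
    sx <- seg(cx, i, j); sy <- seg(cy, i, j)
    sxx <- seg(cxx, i, j) - sx^2 / n
    sxy <- seg(cxy, i, j) - sx * sy / n
    syy <- seg(cyy, i, j) - sy^2 / n
    if (sxx <= 0) return(max(syy, 0))
    max(syy - sxy^2 / sxx, 0)
  }
  fit <- function(i, j) {
    n <- j - i + 1
    sx <- seg(cx, i, j); sy <- seg(cy, i, j)
    sxx <- seg(cxx, i, j) - sx^2 / n
    sxy <- seg(cxy, i, j) - sx * sy / n
    slope <- if (sxx > 0) sxy / sxx else 0
    intercept <- sy / n - slope * sx / n
    c(intercept = intercept, slope = slope)
  }
  list(rss = rss, fit = fit)
}

#' Two-piecewise ("hinge point") linear regression
#'
#' Fits two independent least-squares lines to `(x, y)` split at a
#' breakpoint, searching every admissible breakpoint exhaustively and
#' returning the global minimizer of the summed squared residuals. The
#' breakpoint sample belongs to both segments. Ties go to the earliest
#' breakpoint.
#'
#' @param x Sorted numeric predictor (typically integer ms).
#' @param y Response, same length.
#' @param search Optional two-element range restricting candidate breakpoint
#'   `x` values.
#' @param min_points Minimum points per segment (default 3).
#' @return List: `breakpoint`, `slope1`, `intercept1`, `slope2`,
#'   `intercept2`, `rss`.
#' @export
two_piecewise_fit <- function(x, y, search = NULL, min_points = 3) {
  n <- length(x)
  stopifnot(length(y) == n, !is.unsorted(x))
  if (n < 2 * min_points - 1) {
    stop("too few points for a two-piecewise fit (need >= ",
         2 * min_points - 1, ")", call. = FALSE)
  }
  sr <- segment_regression(x, y)
  cand <- min_points:(n - min_points + 1)
  if (!is.null(search)) {
    cand <- cand[x[cand] >= search[1] & x[cand] <= search[2]]
    if (length(cand) == 0) {
      stop("no admissible breakpoint in the search range", call. = FALSE)
    }
  }
  total <- vapply(cand, function(i) sr$rss(1, i) + sr$rss(i, n), numeric(1))
  # earliest breakpoint among (numerical) ties
  tol <- 1e-9 * (1 + min(total))
  best <- cand[which(total <= min(total) + tol)[1]]
  f1 <- sr$fit(1, best); f2 <- sr$fit(best, n)
  list(
    breakpoint = x[best],
    slope1 = unname(f1["slope"]), intercept1 = unname(f1["intercept"]),
    slope2 = unname(f2["slope"]), intercept2 = unname(f2["intercept"]),
    rss = min(total)
  )
}

# Welch two-sample p with an exact-equality fallback for degenerate
# zero-variance inputs: significant iff the means differ.
welch_p <- function(a, b, tol = 1e-12) {
  va <- var(a); vb <- var(b)
  if (va < tol && vb < tol) {
    return(if (abs(mean(a) - mean(b)) < tol) 1 else 0)
  }
  t.test(a, b)$p.value
}

#' Estimate the visual-onset latency of one channel
#'
#' Implements the sliding-window + two-piecewise procedure on a
#' baseline-corrected, visual-burst-aligned trial-averaged waveform:
#' the peak time Pv is located in `peak_window`; two 20 ms windows W1 and
#' W2 (W2 10 ms earlier) start against Pv and slide backwards in 1 ms steps
#' until W2 reaches \[-50, -30\] ms; Bv is the start of W1 at the first
#' instantiation whose Welch t test (P < `alpha`) is non-significant and
#' stays non-significant for the next 10 iterations (or through the end of
#' the slide); Lv is the breakpoint of the two-piecewise fit over
#' \[Bv, Pv\].
#'
#' @param waveform A baseline-corrected `rate_waveform` aligned on visual
#'   burst onset, covering at least \[-50, 150\] ms.
#' @param peak_window Window for Pv, default `c(-50, 150)`.
#' @param alpha Significance level of the W1/W2 t test (default 0.01).
#' @param window_len Sliding-window length in samples (default 20).
#' @return One-row tibble: `Pv`, `Bv`, `Lv`, `detected`.
#' @export
estimate_visual_onset <- function(waveform, peak_window = c(-50, 150),
                                  alpha = 0.01, window_len = 20) {
  time <- waveform$time
  v <- waveform$values
  undetected <- tibble::tibble(Pv = NA_real_, Bv = NA_real_, Lv = NA_real_,
                               detected = FALSE)
  idx_pk <- wv_index(waveform, peak_window)
  if (diff(range(v[idx_pk])) < 1e-9) return(undetected)  # flat: no peak structure
  pv <- time[idx_pk][which.max(v[idx_pk])]

  at <- function(t0) v[match(t0, time) + 0:(window_len - 1)]
  k_max <- pv - (-50) - 30            # last step: W2 starts at -50
  if (k_max < 0) return(undetected)
  ns <- logical(k_max + 1)
  for (k in 0:k_max) {
    w1 <- at(pv - window_len - k)
    w2 <- at(pv - window_len - 10 - k)
    if (anyNA(w1) || anyNA(w2)) {
      stop("waveform support too short for the W1/W2 slide", call. = FALSE)
    }
    ns[k + 1] <- welch_p(w1, w2) >= alpha
  }
  bv <- NA_real_
  for (k in 0:k_max) {
    upto <- min(k + 10, k_max)
    if (ns[k + 1] && all(ns[(k + 1):(upto + 1)])) {
      bv <- pv - window_len - k
      break
    }
  }
  if (is.na(bv)) return(undetected)
  seg <- wv_index(waveform, c(bv, pv))
  if (length(seg) < 5) return(undetected)
  fit <- two_piecewise_fit(time[seg], v[seg])
  tibble::tibble(Pv = pv, Bv = bv, Lv = fit$breakpoint, detected = TRUE)
}
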