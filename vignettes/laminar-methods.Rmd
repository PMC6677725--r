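---
title: "Laminar analysis of superior colliculus population activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar analysis of superior colliculus population activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sclaminar)
```

## The scientific problem

The superior colliculus (SC) transforms visual input into saccade commands
across its dorsoventral depth: superficial layers are visually driven,
intermediate and deep layers carry pre-saccadic buildup and motor-burst
activity. Multi-contact laminar probes record multi-unit activity (MUA) and
local field potentials (LFPs) simultaneously on 16 contacts spaced 150 µm
apart, so the spatial organization of sensory, delay-period and motor
signals can be measured within single penetrations and, after depth
alignment, across sessions.

`sclaminar` implements that analysis as a reusable pipeline:

1. **Spike-density waveforms.** Spike trains are convolved with a causal
   EPSP-shaped kernel, `R(t) = (1 - exp(-t/1 ms)) * exp(-t/20 ms)`,
   normalized to unit area so a density is in spk/s and epoch means equal
   rates. The kernel is truncated at 100 ms and renormalized: the truncation
   discards < 1% of mass while making a lone spike integrate to exactly 1
   within a 100 ms window. Binning is 1 ms throughout.
2. **Visual-burst alignment.** Per trial and channel, burst onsets are
   detected in the 30-150 ms epoch after target onset by the Poisson
   surprise statistic `S = -log P(>= n spikes | Poisson at the trial's mean
   rate)`, with at least 3 spikes and `S >= -log(0.025)`. The channel with
   detected bursts on the most trials becomes the alignment channel;
   trials without a burst there are discarded and all channels are
   realigned on its per-trial onsets, removing shared trial-to-trial
   latency jitter.
3. **Visual-onset latencies.** On each baseline-corrected (\[-150, -50\] ms)
   trial-averaged waveform, the peak `Pv` is located in \[-50, 150\] ms; two
   20 ms windows slide backwards from it in 1 ms steps (the trailing window
   10 ms earlier) until their Welch t test (P < 0.01) stays non-significant
   for 10 further iterations, defining `Bv`; a two-piecewise linear
   regression over \[`Bv`, `Pv`\] with an exhaustive integer breakpoint
   search yields the latency `Lv` (the "hinge point" minimizing the summed
   residuals of two independently fitted lines).
4. **Pre-saccadic events.** On saccade-aligned waveforms (trials with
   200-400 ms saccade latency), 100 bootstrap resamples each estimate:
   `E1b`, the first 1 ms bin from -200 ms whose across-trial activity
   differs from the pooled pre-go baseline distribution (Welch t, P < 0.01)
   for 100 consecutive ms, computed after subtracting a linear trend fitted
   on \[-300, -200\] ms; `E2b`, the hinge point on \[`E1b` - 100, `E1b`\] of
   the raw average; `Pb`, the peak in \[-50, 100\] ms; and `E3b`, the hinge
   between `E2b` and `Pb`, with the two segment slopes retained. Events are
   aggregated as replicate means with 95% quantile CIs; the CI range,
   normalized per event (E1: 200 ms; E2: 100 ms; E3: the mean `E2b`-to-`Pb`
   interval; P: the peak-window length), must stay at or below 0.6, and E3
   additionally requires disjoint before/after slope CIs. Events earlier
   than -50 ms are classified as Buildup, later ones as Burst.
5. **CSD depth alignment.** The second spatial difference of the
   trial-averaged, burst-aligned LFP estimates the current-source density;
   the mean CSD over a 150 ms window starting 50 ms before burst onset shows
   a contiguous sink (negative) over the visually driven contacts, and the
   contact immediately ventral to the sink's negative-to-positive transition
   becomes aligned index 0. Index-based alignment quantizes depth to the
   150 µm contact grid, so the worst-case residual is 75 µm.
6. **Population statistics.** Depth profiles are averaged across sessions
   with 1000-resample bootstrap CIs; trends over aligned depth use a cubic
   fit whose p-value is the fraction of 1000 y-shuffles achieving an equal
   or higher R²; the Burst-to-peak scaling factor is the ratio of the maxima
   of the cubic fits to the peak-rate and Burst-onset-rate profiles.

## The synthetic laminar session generator

No public recordings accompany this method, so the package ships a seeded
generator (`laminar_config()` / `generate_session()`) whose defaults *are*
the study conditions used by the recovery tests: 16 contacts at 150 µm,
200 trials per task, visually and memory-guided delayed saccades with
200-350 ms fixation, 600-900 ms delay and 200-400 ms saccade latency.

Per-channel rate templates are sums of smooth, simple components chosen so
that every downstream changepoint is well defined:

* a constant MUA **baseline** (20 spk/s);
* a fast-attack, slow-decay **visual transient** (attack 0.5 ms, decay
  20 ms) with a Gaussian amplitude profile over depth (peak 88.2 spk/s at
  aligned index +4, width 4 channels) and a linear dorsal-to-ventral latency
  gradient spanning 7.3 ms; per-trial transients are 8 times the profile
  scale with a lognormal gain (CV 0.35) — single-trial MUA bursts must carry
  enough spikes (~10 at the best contact) for single-trial Poisson-surprise
  onsets to be sharp, while latency jitter (shared across contacts, SD 4 ms)
  and detection jitter smear the trial average back down;
* **sustained delay activity** at 15% of the channel's visual amplitude,
  building up 80 ms after the visual onset and persisting to the trial end.
  A flat (rather than decaying) delay level is a deliberate choice: the
  pre-saccadic detrending step fits a line on \[-300, -200\] ms and
  extrapolates it, and any curvature of the true delay course turns into a
  systematic activity-versus-baseline offset across the differently aligned
  frames;
* a lognormal per-trial **excitability gain** (CV 1.2) on baseline plus
  delay. This emulates slow MUA state fluctuations that persist from the
  delay period into the pre-saccadic epoch; because the same factor scales
  the pre-go baseline and the pre-saccadic activity of a trial, the E1
  per-bin t tests see it as extra variance (raising the detection threshold)
  while the per-replicate trend fit absorbs it from the resampled mean —
  without it, the smooth spike-density noise makes the detrend extrapolation
  spuriously "significant" in a fraction of bootstrap replicates;
* a convex **Buildup ramp** (`u^1.5`) from the channel's Buildup onset
  (earliest -102.7 ms at aligned index +2, 3.95 ms later per channel of
  distance, on aligned channels -6..+4) to the Burst-onset level. The convex
  shape delays E1 relative to the hinge so that the E2 search window
  \[`E1b` - 100, `E1b`\] brackets it;
* a **motor burst** starting at -26.9 ms on every contact, rising to its
  peak just before saccade onset, holding a ~40 ms plateau and decaying over
  60 ms. Peak rates are `3.3x` (VG) or `2.4x` (MG) the Burst-onset
  amplitude, whose Gaussian profile peaks at `136.7 / 3.3 = 41.4` spk/s at
  aligned index -2. The plateau keeps the peak measurable under the
  kernel's smoothing; a razor-sharp triangular peak would lose ~20% of its
  amplitude to the 20 ms decay constant.

LFP snippets are generated around target onset only (the CSD stage uses
nothing else): a spatial potential profile constructed by twice integrating
a half-sine sink over aligned channels +1..+6 (sources at its edges), an
alpha-shaped time course peaking ~70 ms after target onset, and white noise
(SD 20 µV against a 40 µV scale). By construction the CSD's ventral
negative-to-positive transition falls exactly at the configured reference
channel.

### What the generator does not emulate

Spike waveforms, bursting/refractory spike statistics (trains are
inhomogeneous Poisson), biophysical LFP forward models, eye-movement
kinematics beyond a single velocity trace, anti-RF response structure, and
the decaying delay-period profile seen in real SC. Passing recovery tests
therefore demonstrate that the estimators invert the generative model they
were designed for — not that they are robust to every property of real
recordings.

## Numerical and design choices

* **Poisson surprise maximization.** The classic burst search grows and
  shrinks candidate runs to increase S; with at most a few dozen spikes in
  the 120 ms epoch we instead evaluate every contiguous run exhaustively
  and keep non-overlapping runs greedily from the highest S down. This
  attains the global maximum the heuristic approximates and is exactly
  checkable against the tail-sum definition. Where several bursts pass, the
  highest-surprise one is taken as the visual burst.
* **Piecewise fits.** Segments are fitted independently (no continuity
  constraint), following the hinge-point definition as the breakpoint
  minimizing total residuals; breakpoints are searched exhaustively on the
  integer-ms grid with at least 3 points per segment, ties resolving to the
  earliest breakpoint. A consequence is that a hinge lying exactly at the
  window edge is reported at the nearest admissible breakpoint.
* **W1/W2 slide.** Distributions are the 20 per-window samples of the
  trial-averaged waveform, compared with an unpaired two-sided Welch test;
  windows with exactly equal constant values count as non-significant, and
  a non-significant stretch that persists to the end of the slide (when
  fewer than 10 further iterations exist) also defines `Bv`.
* **E1 baseline referencing.** The trend line fitted on \[-300, -200\] ms is
  subtracted from the saccade-aligned trials; the pre-go baseline
  distribution is expressed relative to the same fitted level over the
  trend window. Mapping the line backward into each trial's go frame
  instead would double the leverage of slope noise over the ~150-350 ms
  extrapolation span and destabilize E1.
* **Bootstrap conventions.** Resamples draw the original number of trials
  with replacement; replicate `r` uses `seed + r`. Replicates that detect
  no event are excluded from that event's mean and CI, and an event
  detected in fewer than half the replicates is treated as absent.
* **Classification edge cases.** If E2 and E3 are both reliable but their
  CIs overlap they are treated as one event at E3; a lone event is labeled
  purely by the -50 ms boundary, so an isolated late E2 yields Burst-only.
* **Cubic permutation p.** `p = #(shuffled R² >= observed R²) / n_perm`
  exactly; for noiseless polynomial data this can be 0 (no shuffle ties the
  perfect fit), and for constant data it is 1.
* **CSD non-contiguity flag.** Rather than flagging any stray negative value
  (which per-session noise guarantees), a session is flagged when a
  secondary negative region reaches 20% of the sink's global minimum, or
  when the sink touches the ventral edge of the interior profile.
* **Per-channel task comparisons** are reported with raw p-values (no
  multiple-testing correction), with the KS-gated choice between Welch t and
  rank-sum tests.

## Known limitations

* **Kernel group delay.** The EPSP kernel's centroid (~13-20 ms after
  smoothing and windowing) delays every waveform-domain onset estimate by a
  common amount. Relative quantities across depth — latency gradients,
  onset profiles, Burst synchrony — are unaffected, and the recovery tests
  compare profiles shape-wise; absolute onsets are systematically late
  relative to the underlying rate functions, exactly as for any analysis of
  spike-density waveforms with this kernel.
* **Burst-to-peak scaling from hinge reads.** The pipeline reads the rate
  "at Burst onset" from the smoothed waveform at the recovered E3 hinge,
  which sits part-way up the rapid burst rise; the resulting scaling factor
  overestimates a rate-level peak-to-onset ratio (about 4.1 on the default
  synthetic batch whose generative ratio is 3.3). The
  `burst_peak_scaling()` operation itself is exact, as its template-anchored
  unit test shows; the bias lives in the amplitude estimate, and the same
  caveat applies to any hinge-read amplitude on smoothed data.
* **E2 reliability is a strict gate.** The 0.6 threshold on the normalized
  95% CI range of 100 bootstrap replicates tolerates at most a couple of
  outlying replicates. Because E1's significance scan runs over smooth,
  autocorrelated spike-density noise, a small fraction of resamples bridge
  noise stretches to the real signal and return early `E1b` values, and the
  induced `E2b` outliers inflate its CI. On the default synthetic
  conditions only a minority (roughly a tenth to a quarter, varying by
  amplitude) of buildup channel-sessions pass the E2 gate; Buildup
  estimates therefore accumulate across sessions more slowly than Burst
  (E3) estimates, which pass routinely. This is a property of the
  estimator's reliability criterion, not of the implementation; the burst
  and latency recoveries do not depend on it.
* **Problem sizes.** The recovery tests use 10 sessions of 200 VG trials
  with 100 bootstrap replicates per channel, 1000-resample profile CIs and
  1000-permutation fits — the sizes the method itself prescribes; the
  statistical calibration checks use 200 outer replicates.
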