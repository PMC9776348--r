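---
title: "Feature-based self-similarity segmentation of biosignals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based self-similarity segmentation of biosignals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssmseg)
```

## The model

`ssmseg` retrieves structure from uni- or multichannel time series without
training data. The pipeline has four stages.

**1. Windowed feature representation.** A window of `w` samples slides over
each channel with hop `max(1, round(w * (1 - overlap_frac)))`. For each
window and channel, a registry of statistical (moments, order statistics),
temporal (differences, zero crossings, trend, lag-1 autocorrelation,
histogram entropy) and spectral (periodogram moments, median and peak
frequency, spectral entropy) features is evaluated — 22 per channel by
default, see `feature_names()`. The stacked feature matrix FM has one row
per feature series (channel-major) and one column per frame. The window size
acts like a camera zoom: it sets the timescale at which two stretches of
signal are compared. The overlap sets the frame resolution of everything
downstream.

**2. Self-similarity matrix.** After double normalization — each row
z-scored, then each column scaled to unit Euclidean norm — the SSM is the
plain Gram matrix `t(FM) %*% FM`, i.e. the cosine similarity between every
pair of frames. Homogeneous stretches of signal appear as bright square
blocks on the diagonal; recurring patterns appear as diagonal paths off it.

**3. Retrieval on the SSM.**

* *Change points* (`novelty_function()`, `pick_peaks()`): a block boundary
  looks locally like a 2×2 checkerboard. Correlating a Gaussian-tapered
  checkerboard kernel of half-size `L` along the diagonal yields the
  novelty curve; its peaks are change points.
* *Period starts* (`similarity_function()`, `pick_valleys()`): the column
  sums of the SSM dip at frames whose window straddles a cycle boundary;
  valleys of this similarity curve mark period starts. The same curve,
  read as an average similarity per frame, also ranks frames for
  *anomaly* screening (`rank_by_similarity()`); the ranking is exposed
  without a detection threshold because that use has not been validated.
* *Segment comparison* (`similarity_profile()`, `cluster_segments()`): a
  segment's profile is its average similarity to every frame. Profiles of
  segments produced by the same behaviour are close in Euclidean distance
  regardless of segment length, so agglomerative clustering of profiles
  labels recurring regimes.

**4. Evaluation.** Detections are matched to ground truth inside a
tolerance zone (`evaluate_events()`): a detection within `tolerance`
samples of an unmatched truth event is a true positive; extra in-zone
detections duplicate the counted TP and become false positives; unmatched
truth events are false negatives. Precision, recall and F1 follow, and
dataset-level F1 values are macro-averaged with `macro_f1()`.

## Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `w` | window size, samples | required | the timescale of interest; larger windows see coarser structure |
| `overlap_frac` | window overlap, fraction | 0.95 | hop `= max(1, round(w(1-o)))`; higher overlap = finer frame grid |
| `L` | kernel half-size, frames | `round(0.1 m)`, clamped to [2, 50] | kernel size `D = 2L+1` ≈ one fifth of the frame count; larger = smoother novelty |
| `sigma` | kernel taper, relative to `L` | 0.5 | see numerical notes below |
| `theta` | peak threshold on the [0,1] novelty curve | 0.3 | per-record choice in practice |
| `min_separation` | peak suppression radius, frames | `L` in the pipeline | novelty peaks are about one kernel half-size wide |
| `tolerance` | evaluation zone half-width, samples | `w` | a boundary estimate is only meaningful to within the window |

## The synthetic generator

The generator produces the conditions the detection stages are supposed to
handle, with exact ground truth:

* `make_piecewise_signal()` — concatenated regimes of
  `amplitude*sin(2*pi*frequency*t) + N(mean, std^2)`, emulating
  activity-style data where regimes differ in level, variance and dominant
  frequency. Boundaries (excluding the record ends) are the ground truth.
* `make_periodic_signal()` — a repeated template cycle (sine, Gaussian
  pulse, or spike train) plus white noise; period starts are the ground
  truth.
* `add_noise_at_snr()` — a noise episode over a stated interval,
  rescaled so the realized in-interval SNR equals the request exactly;
  entering and leaving the episode are both ground-truth events. Burst
  noise is Gaussian with 10× spread (an EMG-activation surrogate);
  low-frequency wander is a random-phase 0.3 Hz drift.

The frozen validation fixture `make_activity_record()` is a 6-channel
record emulating a 6-axis inertial unit: four 7.5 s regimes at 100 Hz — two
static postures whose baselines differ by six noise standard deviations,
then two dynamic regimes with 5 Hz and 15 Hz oscillations (frequency ratio
3, amplitude 3). Six channels were chosen because multichannel records are
the normal case for wearable inertial sensing and because averaging
independent channels is what keeps the cosine similarity's sampling noise
below detection thresholds; a single noisy channel at the same contrasts
leaves hop-correlation fluctuations in the novelty curve that a fixed
threshold cannot separate cleanly.

What the generator does **not** emulate: physiological waveform morphology
(no PQRS complexes, no pulse shapes), amplitude drift, heteroscedastic or
autocorrelated noise, missing samples, or asynchronous channels. Passing
the recovery suites therefore demonstrates that the machinery is correct
and that the method works under its own assumptions — not that any
particular clinical signal will segment at these parameter values.

## Numerical choices

* **Row z-scoring** uses the population standard deviation
  (denominator `m`). Zero-variance rows become all-zero with a warning, so
  uninformative features drop out of the cosine rather than injecting a
  constant. All-zero frame columns are left unnormalized (similarity 0 to
  everything, including themselves).
* **Non-finite features** (moment ratios or spectral summaries of flat
  windows) are replaced by 0 with a warning, keeping the FM dense.
* **Kernel taper.** The Gaussian is
  `exp(-(a^2 + b^2) / (2 L^2 sigma^2))`, making `sigma` dimensionless
  relative to the kernel half-size; `sigma = 0.5` tapers the corners to
  `e^-4` of the centre weight regardless of `L`. The kernel is divided by
  `sum(|K|)` so novelty amplitudes are comparable across kernel sizes.
* **Borders.** The SSM is zero-padded by `L` frames for the correlation,
  and the first and last `L` novelty values are then set to zero: there
  the kernel overlaps the padding, and on a constant similarity field the
  padding itself would fake a change point at each end.
* **Curve normalization.** The novelty curve is min-max scaled to [0, 1]
  (a flat raw curve maps to zeros), which makes thresholds portable across
  records; the raw curve is kept alongside. Valley picking negates the raw
  similarity curve and min-max scales the result, so valley "depth" is
  thresholded exactly like peak height.
* **Ties.** Equal-height peaks resolve to the earlier frame, both in
  ranking and in non-maximum suppression. Equal-distance matches in
  evaluation resolve to the earlier detection. Cluster labels are
  renumbered by first appearance.
* **Matching** is greedy in truth order (nearest unassigned detection
  within the zone). On instances whose tolerance zones do not overlap this
  attains the optimal assignment (property-tested against an exhaustive
  matcher); with overlapping zones the greedy result is simply the
  documented deterministic convention.

## Design choices where the design was open

* **Hop convention.** "Overlap" is specified as a fraction in [0, 1) and
  the hop derived from it, never below one sample. At `w = 50,
  overlap_frac = 0.95` the derived hop is 3 (floating-point `1 - 0.95`
  lands a hair above 0.05); exact per-record hops are always echoed in the
  artifact metadata.
* **Feature registry.** The default 22-feature set spans the statistical,
  temporal and spectral domains at modest cost; it is deliberately
  configurable (`feature_set` argument) because no single registry suits
  every signal class.
* **Linkage.** `cluster_segments()` defaults to average linkage (UPGMA),
  the conventional choice when nothing is known about cluster shapes;
  complete and single linkage are available. Profiles are compared raw by
  default; optional z-scoring is a flag.
* **Valley picking for period estimation.** Two conventions matter for
  cyclic signals: a short moving average over the similarity curve
  (9 frames in the package's validation runs, about a tenth of the design
  period) suppresses sample-noise valleys, and a minimum valley separation
  above half the expected period suppresses sub-harmonic valleys — a
  symmetric waveform genuinely produces two valley families per cycle.
  Both correspond to the known-periodicity thresholding strategy: when the
  rough period is known, the picker should not be allowed to report two
  events within one cycle.
* **Evaluation tolerance.** The default zone is ±`w` samples around each
  truth event — the permissive reading of "within a window" — and is a
  flag (`tolerance`) since the strict reading (±`w/2`) is equally
  defensible.

## Problem sizes used in the validation suites

The recovery suites run on records of 3000 samples × 6 channels (change
points, 20 seeds), 1000 samples × 1 channel (period recovery, 10 seeds) and
1800–2400 samples × 3 channels (clustering, 10 seeds × 2 patterns) — sizes
chosen so the full suite and the acceptance script each complete in about a
minute on a laptop core while leaving comfortable statistical margins (the
worst spurious novelty peak across the 20 segmentation seeds sits at 0.23
on the normalized curve against the 0.3 threshold).

## Known limitations

* The SSM is dense: memory and time grow quadratically with the frame
  count. Long records need a lower overlap or a coarser window; a banded
  SSM restricted to the kernel's diagonal neighbourhood would serve
  novelty detection alone but is not implemented.
* The method is offline and single-timescale per run; hierarchical
  multi-scale search is out of scope.
* Threshold choice remains per-record; the package ships strategies
  (absolute threshold, top-N, peak fraction) but no automatic tuning.
* The anomaly reading of the similarity curve is exposed as a ranking
  only.

## A worked example

```{r example, eval = FALSE}
rec <- make_activity_record(seed = 1)
cfg <- run_config(fs = 100, w = 50, overlap_frac = 0.95, kernel_L = 20,
                  theta = 0.3, seed = 1)
res <- run_pipeline(cfg, rec)
as.data.frame(res$novelty$events)
res$evaluation
```
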