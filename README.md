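# ssmseg

Unsupervised information retrieval from uni- and multichannel biosignal
time series — change-point segmentation, periodic-pattern detection and
segment clustering — built on a feature-based **self-similarity matrix
(SSM)**.

Biosignal archives (wearable accelerometry, ECG, EMG, blood-pressure
recordings) are mostly unlabelled, and labelling them is the expensive
step before any supervised analysis. `ssmseg` is for researchers who need
to split such recordings into homogeneous regimes, find cycle boundaries,
and group recurring segments without training data or a signal-specific
model.

## The method

A window of `w` samples slides over each channel with hop
`max(1, round(w(1-o)))` for overlap fraction `o`. Per window and channel,
22 statistical/temporal/spectral features are extracted and stacked into a
feature matrix `FM` (rows = feature series, columns = frames). After
z-scoring each row and scaling each column to unit norm, the SSM is the
cosine Gram matrix

```
SSM = FMᵀ · FM ,      SSM(i, j) = cos(frame_i, frame_j) .
```

Three retrieval operations read the SSM:

* **Novelty.** A Gaussian-tapered checkerboard kernel
  `K(a,b) = sign(a)·sign(b)·exp(-(a²+b²)/(2L²σ²))`, `a, b ∈ [-L, L]`, is
  correlated along the diagonal: `nf(c) = Σ K(a,b)·SSM(c+a, c+b)`. Peaks
  of `nf` are change points between homogeneous blocks.
* **Periodicity.** The similarity function `sf(x) = Σᵢ SSM(i, x)` dips
  where a frame straddles a cycle boundary; valleys of `sf` are period
  starts.
* **Similarity profiles.** A segment's profile
  `P(c) = (1/l) Σᵢ∈segment SSM(i, c)` is its average similarity to every
  frame; profiles are compared by Euclidean distance and clustered
  agglomeratively to label recurring regimes.

Detections are scored against ground truth with tolerance-zone matching:
`P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`, macro-averaged
across datasets.

A seeded synthetic-signal generator (piecewise regimes, periodic
waveforms, SNR-calibrated noise episodes) provides labelled inputs so the
whole chain is testable offline.

## Worked example

```r
library(ssmseg)

rec <- make_activity_record(seed = 1)   # 6-channel, 4 regimes, 100 Hz
rec
#> <ts_record> 3000 samples x 6 channel(s) @ 100 Hz (30.000 s), 3 ground-truth event(s)

cfg <- run_config(fs = 100, w = 50, overlap_frac = 0.95, kernel_L = 20,
                  theta = 0.3, seed = 1)
res <- run_pipeline(cfg, rec)

as.data.frame(res$novelty$events)
#>   frame sample time_s     score         type
#> 1   249    772   7.72 1.0000000 novelty_peak
#> 2   489   1492  14.92 0.6660655 novelty_peak
#> 3   749   2272  22.72 0.5532528 novelty_peak

res$evaluation
#> <eval_result> TP=3 FP=0 FN=0 | P=1.00 R=1.00 F1=1.00 (tolerance 50 samples)
```

The three detected change points (samples 772, 1492, 2272) each fall
within one window (±50 samples) of the true regime transitions at samples
750, 1500 and 2250, so all three count as true positives and the record
scores a perfect F1.

Published aggregate counts for three segmentation methods on four
biosignal datasets ship with the package; recomputing the metrics from the
raw counts reproduces every printed precision/recall/F1 cell:

```r
counts <- benchmark_counts()
met <- metrics_from_counts(counts[counts$method == "novelty", ])
round(macro_f1(met$f1), 2)
#> [1] 0.94
```

## Command line

A thin CLI over the same functions lives at `inst/cli/ssmseg.R`:

```sh
Rscript inst/cli/ssmseg.R simulate --spec spec.json --seed 1 --out signal.csv --events truth.csv
Rscript inst/cli/ssmseg.R ssm      --input signal.csv --fs 100 --window 50 --overlap 0.95 --out ssm.csv
Rscript inst/cli/ssmseg.R segment  --ssm ssm.csv --kernel-L 20 --theta 0.3 --min-sep 20 --out events.csv
Rscript inst/cli/ssmseg.R eval     --truth truth.csv --detected events.csv --tolerance 50 --out eval.json
```

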