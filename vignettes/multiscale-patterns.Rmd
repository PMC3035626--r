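---
title: "Detecting and decoding multineuronal patterns across timescales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and decoding multineuronal patterns across timescales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spikescales)
```

## The problem and the model

Trial-based multielectrode recordings give, for every trial, one spike
train per unit plus a stimulus label. The question this package addresses
is: on which timescale do the *joint* firing patterns of the population
carry stimulus information, and how precisely are those patterns locked to
the stimulus? The pipeline treats the timescale as an explicit parameter
τ and keeps every downstream step identical across τ, so that slow
(rate-like) and fast (synchrony-like) coding are measured with one and the
same instrument.

**Activation.** Each unit's train is convolved with a causal exponential
kernel of unit height, `a_i(t) = Σ_{t_s ≤ t} exp(−(t − t_s)/τ)`. The
kernel mimics the shape of a post-synaptic current; an activity vector
`AV(t)` is the instantaneous snapshot of all n activations, sampled at
1 kHz by default. Two properties matter for interpretation: activations
are non-negative and contain the decaying trace of *all* past spikes, so a
single vector already encodes local spike history; and the kernel height
(not area) is normalized, so a vector component of 1 means "a spike right
now" regardless of τ. Height normalization is this package's choice; an
area-normalized kernel would rescale vectors per τ without changing any
of the decoders that compare vectors at equal τ.

**Pattern detection.** Activity vectors are vector-quantized on a 3D
Kohonen lattice (N³ model vectors; N = 10 by default, i.e. 1,000
patterns). Each training step draws one vector uniformly (seeded), finds
its best-matching unit (BMU) by Euclidean distance, and updates every
model vector within Chebyshev lattice radius `R(k)` of the BMU by
`MV ← MV + L(k)·G·(AV − MV)`, with a Gaussian envelope `G` of SD `R(k)/3`
in squared Euclidean lattice distance, `G(BMU) = 1`. The schedule uses
`L(k) = L0·(LM/L0)^{k/M}` (defaults L0 = 1, LM = 0.01) and
`R(k) = round(R0·max(0, 1 − k/(gM/100)))` with R0 = N/2 and g = 66: the
first two thirds of training establish the map topology, the rest
fine-tunes individual model vectors (only the BMU learns once R = 0). The
geometric form of L and the linear decay of R are this package's reading
of the verbal constraints ("monotonically decreasing", endpoints L0/LM,
radius 0 after g% of steps); any pair of schedules satisfying those
constraints should behave equivalently at this problem scale. Replacing
every sample by its BMU id yields *model trials*; the lattice position
doubles as an RGB color for sequence visualization. A K-means backend
(`stats::kmeans`, Lloyd iterations) is provided for checks where lattice
ordering is unnecessary.

**Specificity, decoding, effect size.** Pattern specificity is the
row-normalized pattern × stimulus occurrence table (occurrences counted
per 1 ms sample). Decoding uses repeated random half-splits per stimulus
(odd counts put the extra trial in training); three decoders span the
feature hierarchy: mean rate (nearest per-stimulus mean rate vector),
specificity (sum of count-weighted training-set specificities; blind to
position within the trial), and trajectory (summed window-wise Euclidean
distance between a trial's window-averaged model-vector sequence and each
stimulus's average training trajectory; sensitive to position). The
weighted-sum form of the specificity score — rather than a naive-Bayes
product — avoids zeroing a stimulus when one pattern is absent from its
training trials. Time-resolved analysis slides the trajectory window with
a step ≤ 5 ms and standardizes `d_O(t) − d_T(t)` by the pooled SD over
test trials (for `d_O`, the SD of per-trial means over other stimuli),
giving a Cohen's-d timecourse interpretable as a signal-to-noise ratio of
discrimination at each moment.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| τ (`tau_ms`) | swept: 1–500 ms | integration constant; the analysis timescale |
| `dt_ms` | 1 | sampling step (1 kHz) |
| N | 10 | lattice side; N³ patterns available |
| M | min(20·#vectors, 1e5) | SOM training steps |
| L0, LM | 1, 0.01 | learning-rate endpoints |
| R0, g | N/2, 66 | initial radius; % of M at which radius reaches 0 |
| `n_splits` | 100 (reference 1,000) | half-split repetitions |
| `tau_bins` | τ/dt | trajectory window, in samples |
| jitter SDs | 10/20/50/100 ms | control: spike-time Gaussian jitter |
| shuffle window | 20 ms | control: per-trial window permutation |
| burst threshold | 8 ms | control: ISI defining a burst |

The M cap and the 200,000-vector training subsample keep a full τ sweep on
a desk-scale dataset (tens of units, ~100 trials, 1.2–4.8 s trials) in the
minutes range on one CPU; assignment of patterns always uses every sample.
Decoding cost is dominated by map training, not by the splits, because
per-trial features (rate vectors, pattern counts, trajectories) are
computed once and re-partitioned.

## The synthetic generator

The generator produces the statistical structure the analysis assumes,
not a biophysical simulation. All spikes come from inhomogeneous Poisson
processes (thinning against a 1 ms rate grid), optionally with doublets or
triplets at 3–6 ms ISIs replacing single spikes with probability
`burst_prob`. Three regimes:

* **Grating-like** (trials of 4,800 ms: 1,000 ms spontaneous, 3,500 ms
  stimulus, 300 ms off): sinusoidal rate modulation at 0.83 Hz (2 °/s over
  2.4 °/cycle) with von-Mises direction tuning across 12 directions,
  20 trials each. Information lives in slow rate structure.
* **Flash-sequence-like** (1,200 ms trials; items at 500/700/900 ms,
  100 ms flashes): letter-specific unit subsets emit a transient onset
  bump (per-unit latency 30–40 ms, Gaussian width ~10 ms) and a sustained
  offset response (latency 70 ms), with per-trial locking jitter
  (`locking_jitter_sd`, default 3 ms — the order of cortical onset-latency
  variability) and optional unreliability (`onset_reliability`, fraction
  or exact trial count). Information lives in fast, stimulus-locked
  transients.
* **Movie-like**: user-tiled slow epochs (low-frequency sinusoid mixtures)
  and fast epochs (jittered population transients), per-stimulus fixed
  profiles, for slow-vs-fast segment analyses.

Defaults (rates: ~3–5 Hz background, 12–15 Hz slow gains, ~120 Hz onset
peaks, ~25 Hz sustained offsets; subsets of ~n/3 units per letter) were
chosen once as typical anesthetized-V1 magnitudes with clear but not
trivial separability. What the generator does *not* emulate: refractory
periods and spike-sorting artifacts, cross-unit noise correlations beyond
shared events, adaptation, and any image-computable stimulus→rate mapping.
Tests passing on these data therefore validate the *machinery* (the
estimators, their invariances, and their sensitivity to locking), not the
biological effect sizes reported from real cortex.

All randomness descends from one master seed via fixed integer sub-seeds
(profile structure; per-trial spike streams; analysis-side seeds for map
training and splits are separate arguments), so every figure and table is
exactly reproducible and controls can be varied independently.

## Numerical and design choices

* Spikes between sample points enter the recursion with their exact
  fractional decay — the trace equals direct summation to 1e−9 relative
  tolerance (tested), with O(samples + spikes) cost.
* BMU ties break to the lowest linear lattice index; classifier ties break
  to the lowest stimulus index. Both are deterministic and exercised by
  tests.
* Jittered spikes leaving `[0, TD)` are reflected at the boundaries,
  preserving counts and local density (clipping would pile spikes at the
  edges). Burst membership is decided on the *original* train's ISIs, so
  burst removal is idempotent.
* Trailing partial windows are dropped in trajectory segmentation; window
  shuffling leaves a trailing partial window in place.
* In the Cohen's-d timecourse, windows whose pooled SD is below 1e−9 of
  the distance scale are treated as zero-variability: d is 0 if the means
  agree at that tolerance and ±Inf otherwise. Without this guard,
  round-off-scale SDs (all test trajectories sitting on the identical
  background pattern) produce meaningless finite values around 1e12.
* One map is trained per (dataset, condition, τ) and reused across all
  half-splits; controls (shuffle/jitter/deburst) always retrain the map.
  Retraining per split would multiply cost ~100-fold for little benefit,
  since map training never sees the labels.
* Injected-event recovery (see the acceptance tests) aggregates the
  *family* of high-specificity patterns (SP > 0.6 against chance 1/3,
  recurring in ≥ 3 trials) inside the onset search window, because a
  single physiological event fragments across adjacent lattice patterns
  at fast τ; demanding one exclusive id would understate recovery.

## Limitations

* The specificity decoder's per-sample occurrence counting weights long
  patterns more than brief ones; at very large τ this shades into a rate
  code by construction.
* With few stimuli, chance specificity (1/s) is high, and specificity
  thresholds must be read against it — 0.25 is a stringent threshold for
  49 stimuli and a weak one for 3.
* SOM training is stochastic vector quantization: pattern identities are
  stable only up to the training seed, which is why every cross-condition
  comparison retrains the map rather than matching pattern ids across
  conditions.
* Performance SDs over half-splits understate uncertainty about new
  datasets (splits share trials); the harness reports them as split
  variability, not as standard errors.
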