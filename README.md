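# spikescales

Multi-timescale analysis of multineuronal spike patterns in R.

Simultaneously recorded neurons express joint activity structure on many
timescales at once — from near-coincident spiking (a few ms) through fast
rate transients (tens of ms) up to mean firing rate (seconds). Most analyses
commit to a single timescale up front. `spikescales` implements a unified
pipeline that makes the timescale an explicit parameter and asks, for any
choice of it, how much stimulus information the recurring population
patterns carry and how precisely they are locked to the stimulus. It is
aimed at systems neuroscientists working with trial-based multielectrode
spike data (and at anyone who wants a compact, fully seeded testbed for
population-decoding methodology).

## The method

1. **Exponential activation (low-pass filtering).** Each unit's spike train
   becomes a continuous activation
   `a_i(t) = Σ_{t_s ≤ t} exp(−(t − t_s)/τ)` — a causal kernel of unit
   height whose decay constant τ sets the analysis timescale (τ = 1–5 ms
   resolves spike synchrony; τ > 100 ms resolves rate modulation). Sampling
   all n traces at 1 kHz yields *activity vectors*
   `AV(t) = [a_1(t), …, a_n(t)]`.
2. **Pattern detection by 3D Kohonen mapping.** The activity vectors are
   clustered on an N×N×N self-organizing lattice (default N = 10, i.e.
   1,000 *model vectors* or "patterns"), trained with learning rate
   `L(k) = L0·(LM/L0)^(k/M)` and neighborhood radius
   `R(k) = round(R0·max(0, 1 − k/(gM/100)))` under a 3D Gaussian envelope
   of SD `R(k)/3`. Replacing each sample by its best-matching unit gives
   *model trials* — symbol sequences in pattern space. The lattice ordering
   doubles as an RGB color code for visualization; a flat K-means backend
   is available where ordering is not needed.
3. **Pattern specificity.** `SP_p(j) = r_p(j) / Σ_c r_p(c)` — the fraction
   of pattern p's occurrences that fall in stimulus j's trials. Rows sum to
   1; chance level is 1/s.
4. **Three decoders under repeated half-split cross-validation.**
   *Mean rate* (nearest model rate vector, Euclidean), *specificity*
   (`SCORE_l(j) = Σ_p r_l(p)·SP_p(j)`, position-blind), and *trajectory*
   (summed window-wise distances between a trial's sequence of
   window-averaged model vectors and per-stimulus model trajectories —
   sensitive to both pattern identity and stimulus locking).
5. **Time-resolved effect size.** Sliding-window distances of test trials
   to the true stimulus's model trajectory (`d_T(t)`) versus other
   stimuli's (`d_O(t)`), standardized as Cohen's
   `d(t) = (d_O − d_T)/s_pooled`, localize *when* the discriminative
   patterns occur.
6. **Controls.** Spike-time jitter (Gaussian, SD 0–100 ms, reflected at
   trial bounds), independent permutation of 20 ms windows per trial, and
   burst removal (keep the first spike of every ISI < 8 ms run), each
   followed by full map retraining.

Real recordings of this kind are rarely shareable, so the package ships a
seeded inhomogeneous-Poisson generator emulating three stimulus regimes —
slow drifting-grating-like trials, flashed-letter-sequence trials with
transient onset (30–40 ms latency) and sustained offset (70 ms latency)
responses, and movie-like trials mixing slow and fast epochs — with
controllable burstiness, response reliability and stimulus-locking jitter,
plus ground-truth sidecars for parameter-recovery tests.

## Worked example

Three flashed-letter sequences that are cyclic permutations of the same
letters ("A-B-C", "B-C-A", "C-A-B"): total spike counts and pattern
inventories are then matched across stimuli, so only the *temporal order*
of patterns identifies the stimulus.

```r
library(spikescales)

seqs <- list(c("A","B","C"), c("B","C","A"), c("C","A","B"))
ds <- gen_flash_sequence_like(n_units = 10, sequences = seqs,
                              n_trials = 20, seed = 42)
ds
#> <spike_dataset> 10 units, 60 trials, 3 stimuli, TD = 1200 ms
#>   total spikes: 4716

pp <- pattern_pipeline(ds, tau_ms = 10)     # activation -> SOM -> model trials
pp$map
#> <som_map> 10^3 = 1000 model vectors of dimension 10 (M = 100000 steps)

pattern_specificity(pp$model_trials)
#> <specificity_table> 984 observed patterns x 3 stimuli (chance 1/s = 0.333)

run_performance(ds, pp$model_trials, tau_bins = 10, n_splits = 50, seed = 1)
#> <performance_result> fraction correct over 50 half-splits (chance 0.333 )
#>    classifier  mean     sd chance n_splits
#> 1        rate 0.409 0.0703  0.333       50
#> 2 specificity 0.355 0.0638  0.333       50
#> 3  trajectory 0.935 0.0428  0.333       50
```

Reading: the mean-rate and specificity decoders hover near the 1/3 chance
level — by construction the stimuli differ in neither rate nor pattern
inventory — while the trajectory decoder, which sees *where* in the trial
each pattern occurs, reaches 94% at τ = 10 ms. Sweeping τ with
`run_timescale_analysis()` shows this advantage peaking at fast time
constants (5–20 ms) and shrinking for large τ; `shuffle_windows()` abolishes
it while leaving the position-blind decoders untouched, and
`jitter_spikes()` with SD ≥ 50 ms degrades it significantly. Use
`plot_color_sequences()`, `plot_performance()` and `plot_effect_size()` for
the corresponding figures, and `effect_size_timecourse()` to localize the
informative moments in time.

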