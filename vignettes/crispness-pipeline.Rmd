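---
title: "Predicting crispness from instrumented chew recordings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting crispness from instrumented chew recordings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(crisptex)
```

## The problem

Crispness is perceived through three simultaneous channels: compression
force at the teeth, bone-conducted vibration, and air-conducted fracture
sound. An instrumented analogue of a two-chew bite — a probe compressing a
snack sample twice at 10 mm/s to 80% of its height while force (10 kHz),
probe vibration (10 kHz) and sound pressure (51.2 kHz) are recorded — lets
one ask whether panel ratings of four texture descriptors (*sakusaku*,
*karikari*, *paripari*, *zakuzaku*, each on a 0–120 line scale) can be
predicted from instrumental data alone, including under degraded sensory
conditions: condition 1 is normal chewing, condition 2 blocks air sound,
condition 3 presents only the air sound. `crisptex` implements the whole
chain — simulation, 66-dimensional feature extraction, condition masking,
Gaussian process regression, leave-one-out evaluation — as tested,
composable functions.

Because no raw data of this kind are publicly deposited, the package ships
a first-class synthetic-data module. Its outputs are the package's test
bed; everything downstream treats them exactly as it would treat real
recordings read from CSV/WAV.

## The chew simulator and what it emulates

`simulate_recording()` renders one trial from a `sample_archetype` and a
`chew_sim_config`:

* **Actuation.** A pre-motion baseline (0.3 s of pure amplifier noise —
  the noise-gate's sigma source; its length is a package choice, as only
  the existence of a quiet window is given), then two descent/ascent
  ramps at 10 mm/s covering 80% of sample height, separated by a 0.2 s
  dwell.
* **Force.** A smooth compression hump per cycle
  (`peak_force_N * (depth/travel)^1.5`), a sustained drop of fraction
  `brittleness` at the major fracture near the end of the first descent,
  a second-cycle envelope scaled by `0.9 * (1 - brittleness)` so the
  second peak never exceeds the first for a brittle food, short transient
  dips at ordinary fracture events, and an optional negative adhesive
  half-sine after the first ascent.
* **Fracture events.** A Poisson process during the first descent;
  second-descent events are a *binomial thinning* of the first-cycle count
  with probability `second_bite_event_ratio`, so the expected second-bite
  count is exactly the first-bite count times the ratio — the second bite
  of an already shattered food is quieter. Each event emits one
  exponentially decaying sinusoid burst per channel (1 ms decay,
  hard-truncated at 4 ms so one burst registers as exactly one peak under
  the 5 ms peak-separation rule). Carrier frequencies differ per
  archetype, giving archetypes distinct octave-band signatures.
* **Noise.** Stationary Gaussian amplifier noise on vibration and sound.

The default eight archetypes take their heights (6.2, 5.1, 8.3, 4.3, 3.4,
12.5, 5.1, 17.9 mm) from the measured study samples; peak forces, event
rates, burst amplitudes, carriers and latent texture intensities are
simulator assumptions chosen once to reproduce the qualitative contrasts
between the foods (chips loud and *paripari*-heavy, pretzel/sweet-potato
sticks *karikari*-heavy, the hard cubic cracker *zakuzaku*-heavy with the
highest force).

`simulate_sensory_study()` draws line-scale scores as
`clip(latent + condition_effect + panelist_bias + noise, 0, 120)` over the
full panelist × sample × condition × texture × replicate factorial
(defaults 10 × 8 × 3 × 4 × 5). The condition-3 shifts for *karikari*
(+11.8) and *paripari* (+19.0) are the reported condition-1 vs condition-3
mean differences; the remaining shifts (mild negatives under condition 2,
−15/−12 for *sakusaku*/*zakuzaku* under condition 3) reproduce the
reported directions with magnitudes chosen by us. Per-panelist bias
(SD 5, drawn once per panelist per texture) and score noise (SD 8) are
stated assumptions — pooled box plots are all the source material reports,
so these defaults are conventions of the simulator, not estimates.

What the simulator does **not** emulate: real fracture mechanics (bursts
are stylized), room acoustics and binaural playback of condition 3,
inter-replicate drift, panelist fatigue or scale-use habits. Passing tests
therefore demonstrate the pipeline's internal correctness and its ability
to recover structure the generator encodes — not instrument-grade validity
on real foods.

## Feature extraction

**Force (6).** Classical double-compression TPA: hardness (cycle-1
maximum), fracturability (force at the first pre-peak drop exceeding 5% of
the cycle-1 maximum — the threshold must exceed sensor ripple and is
configurable; equals hardness if no drop), adhesive force and
adhesiveness (magnitude and |area| of negative force between the cycles;
the window deliberately excludes the post-cycle-2 tail), cohesiveness
(cycle-2/cycle-1 positive-force area, trapezoidal on the recorded grid)
and gumminess = hardness × cohesiveness. Cycle bounds come from the
actuation timeline when available, else from the force-quiescent gap
(longest run below 2% of the global maximum).

**Vibration (22).** Baseline zeroing, noise SD from the pre-motion window,
3σ gate (samples with |x| ≤ 3σ set to 0), rectification; then the
cycle-wise maxima of a 10 ms moving average, peak count and mean peak
interval (local maxima of the rectified gated series, minimum separation
5 ms, height > 0), the five sample moments (SD, variance, Fisher skewness,
non-excess kurtosis m₄/m₂²) and 12 octave-band means (exact centers 2⁰…2¹¹
Hz, nominal 1–2000 Hz, edges fc·2^±½) of the gated record's magnitude
spectrum. The enumerable time-series list has nine entries but the block
totals 22 with 12 bands; the tenth value used here is the overall
rectified maximum (mirroring the sound block's explicit maximum). It is
configurable off, in which case the column is emitted as zero to keep the
schema frozen. Moments are computed on the rectified series, consistent
with rectification preceding feature computation.

**Sound (38).** The identical gating pipeline with the sound channel's own
baseline, ten time statistics, loudness and sharpness maxima and means
over non-overlapping 50 ms frames, the overall A-weighted level (dBA; the
documented 38th value, reported as 0 for an all-zero record and
configurable off), and 23 A-weighted 1/3-octave band means (exact centers
1000·2^(k/3), k = −11…11, nominal 80–12500 Hz, edges fc·2^±1/6; bands above
Nyquist are zeroed with a warning). A-weighting uses the IEC 61672 closed
form normalized to exactly 0 dB at 1 kHz.

Loudness is a *band-level Zwicker-style approximation*: per frame, each
1/3-octave band SPL maps to specific loudness via the 1-sone-at-40-phon
power law `N' = 2^((L−40)/10)` (bands below 0 dB SPL contribute nothing),
integrated over the bands' Bark widths; sharpness is the von
Bismarck-weighted first moment of specific loudness over critical-band
rate (weight 1 below 15.8 Bark, rising exponentially above), 0 when total
loudness is 0. Spectral masking spread and the threshold-in-quiet contour
of the full standard are omitted: the values feed a learned regressor, so
monotone, band-resolved psychoacoustic magnitudes suffice, and the tests
assert exactly those properties (silence → 0, monotone in level,
high-passed noise sharper than low-passed).

Full-record spectra are computed after zero-padding to the next
2-3-5-smooth length (magnitudes normalized by the true record length);
circular-shift invariance of band sums holds exactly at smooth lengths.

## Masking, dataset, scaling

Each trial's 66-vector is masked by its condition: condition 2 zeroes the
38 sound features, condition 3 zeroes the 6+22 force and vibration
features. The zeros are then treated as ordinary values — they carry the
"this sense was absent" signal the model must learn. The default design
yields 360 rows (120 per condition); each row's objective is the panel
mean of its (sample, condition) cell for one texture, so one dataset — and
one GPR model — per texture, four in all.

Features mix units (N, V, Pa, sone, dB), and the kernel depends on raw
squared distances, so one unit could dominate. Per-fold z-scoring (fitted
on the training rows of each fold only; zero-variance columns map to 0) is
therefore the default, with `scale = FALSE` available to run the literal
unscaled pipeline.

## Gaussian process regression

The kernel is `k(x,x') = θ₁ exp(−‖x−x'‖²/θ₂)`. The rendering of the kernel
with `θ₂` adjacent to the squared distance is typographically ambiguous
between dividing and multiplying; we adopt the standard RBF division
reading, and `theta2_multiplies = TRUE` provides the other.

The textbook predictive equations are noiseless, but with 15 replicate
rows per cell mapping to identical objectives and near-identical features,
`K` is ill-conditioned; we add an observation-noise term `σₙ²` to the
diagonal (setting `σₙ = 0` recovers the literal equations). `K + σₙ²I` is
factorized by Cholesky with escalating jitter (0, then 10⁻¹⁰…10⁻⁴ of the
mean kernel diagonal) and all solves are triangular — forming an explicit
inverse is forbidden in the implementation and the tests compare against a
dense-inverse oracle instead. Predictive variances within 10⁻⁹ of zero are
clamped; larger negatives warn.

Hyperparameters `(θ₁, θ₂, σₙ)` are chosen by maximizing the log marginal
likelihood with analytic gradients (L-BFGS-B on log scale) from five
multi-starts: a data-driven start (θ₁ = var(y), θ₂ = median pairwise
squared distance, σₙ = 0.1·sd(y)) plus seeded log-scale perturbations.

For LOOCV the default policy is **frozen**: one evidence optimization on
the full standardized dataset, hyperparameters then held fixed while every
fold refits its own scaler and kernel matrix. Leave-one-out folds differ
by a single row, so the evidence surface is essentially identical across
folds and refitting it 360 times changes nothing but the runtime; the
`"per_fold"` policy is available for designs where folds differ more. The
frozen policy does let every fold's hyperparameters see all rows — a mild,
documented information leak confined to three scalars.

## Evaluation

`loocv()` performs exactly N fit/predict rounds and records, alongside the
model predictions, a mean-predictor baseline (training-fold mean). MAE is
reported per condition and overall, assembled by `mae_table()` into the
standard layout (rows: conditions + Mean; columns: textures).
`prediction_summary()` gives per-(sample, condition) prediction means and
SDs — the SD across the replicate rows of a cell, which is the natural
reading of replicate-level LOOCV output.

Pairwise condition differences in the raw panel scores are tested by
`condition_contrasts()`: within each (sample, texture) cell, condition
labels are permuted and each pair's adjusted p-value is computed against
the null distribution of the *maximum* absolute pair difference (max-T),
keeping the familywise error across the three pairs at α. This seeded,
assumption-light procedure replaces the classical studentized-range
(Tukey HSD) test while preserving its contract.

## Numerical and design choices, in brief

* Trapezoidal integration everywhere an area is needed; piecewise-linear
  test fixtures have closed-form areas.
* Peak definition: local maximum of the rectified gated series, height
  > 0, greedy 5 ms minimum separation; the mean peak interval is 0 with
  fewer than two peaks.
* Moving-average window 10 ms; windows and thresholds are arguments, the
  defaults are package conventions.
* All randomness derives from one global seed via stage-labelled hashing
  (`derive_seed`), so runs are bit-reproducible end to end and stages are
  statistically decoupled.
* Degenerate inputs have defined behavior: zero signals give zero feature
  blocks; constant baselines give σ = 0 (gate = identity on nonzero
  samples); zero cycle-1 area is an explicit cohesiveness error; a
  missing sensory cell aborts dataset assembly with the offending key.

## Problem sizes used by the tests

Unit tests run on reduced fixtures (3 mm archetypes, 32 kHz or 8 kHz sound
where spectral coverage permits). The end-to-end suite and
`scripts/acceptance.R` run the full default study — 360 recordings at
native rates, four models, 360 LOOCV folds each with per-fold scaling —
which the package completes in about a minute on a single core; these
sizes are the study design itself, not reductions of it.

## Known limitations

* Synthetic recordings are stylized; none of the archetype mechanical
  parameters beyond the heights are empirical.
* The loudness/sharpness block approximates, and does not implement, the
  full psychoacoustic standard.
* The identity of the source's tenth vibration feature and 38th sound
  feature is unknown; our reconciliations are documented and can be
  disabled (the schema keeps their columns as zeros).
* One GPR model per texture ignores correlations between textures.
* With `hyper_policy = "frozen"`, hyperparameter selection sees all rows
  (see above).
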