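---
title: "Methods: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the scientific model behind `semgvowel`, the
parameters that matter, and every place where the design was genuinely
open and a choice had to be made.  It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The recognition problem

A facial sEMG channel records the summed motor-unit action potentials
(MUAPs) of the articulator muscles.  During silent articulation the
spectral envelope, amplitude dynamics and regularity of this
interference pattern differ between phonemes, so a single 1000 Hz
bipolar channel carries class information about which of the 11 Bangla
vowels was mouthed.  The pipeline turns each isolated utterance into a
57-dimensional feature vector, selects a compact subset by mutual
information, and classifies with a small tanh network.

## Preprocessing

Three linear, zero-phase stages in fixed order:

1. **DC removal**: `x - mean(x)`.
2. **Band-pass** 0.15–450 Hz: the informative surface-EMG band; below
   0.15 Hz lies electrode drift and motion artifact, above 450 Hz
   mostly amplifier noise (and the 500 Hz Nyquist).  Realized as a
   4th-order Butterworth band-pass (analog prototype → lowpass-to-
   bandpass transform → bilinear transform → second-order sections),
   applied forward–backward so the net phase is zero and the magnitude
   response is squared.  No filter design or order is canonical for
   this application; zero-phase Butterworth is the conservative choice
   when downstream features include waveform-shape statistics that
   phase distortion would bias.
3. **Mains notch**: constrained biquad band-stop at 50 Hz with
   Q = 30 (−3 dB width ≈ 1.7 Hz), also run forward–backward.

Edge handling: the signal is extended by odd reflection and each
section starts from its steady-state (unit-step) initial conditions,
which suppresses start-up transients for all but the very slowest
components.  A 0.15 Hz high-pass has a ≈1 s time constant, so on a
~1 s isolated utterance it is effectively inert; the CLI therefore
filters the *continuous* recording before segmentation, and the
preprocessing test measures drift suppression on long signals.  The
filters are verified in the suite against closed-form expectations
(pass-band flatness within 1 dB over 5–400 Hz, ≥10 dB attenuation at
0.05 Hz, 50 Hz tone RMS reduced below 10 %).

## The 57-feature catalogue

Fixed canonical order: time (9) ‖ entropy (13) ‖ frequency (9) ‖
time–frequency (26).  Where the catalogue's names admit more than one
standard definition, the package fixes these:

- **Moments** are population moments (divide by N); kurtosis is excess
  kurtosis.  Guards: a constant signal has CoV = skewness =
  kurtosis = 0, keeping vectors finite on degenerate input.
- **Amplitude-distribution entropies** (Shannon, Rényi α = 2, Tsallis
  q = 2) use a 100-bin equal-width histogram, probabilities =
  counts/N, log base 2 (bits), empty bins skipped.  The orders and bin
  count are configurable; α = q = 2 are the common defaults when a
  source does not state them.
- **"Higuchi algorithmic entropy"** has no citable standard
  definition; the package implements normalized Lempel–Ziv (LZ76)
  complexity of the median-thresholded binary sequence, scaled by
  log2(n)/n, under the canonical name `lz_complexity`.  This measures
  the same "algorithmic randomness" notion and is the nearest
  well-defined surrogate.
- **Envelope means**: upper/lower envelopes by natural cubic spline
  through local maxima/minima (EMD-style), endpoints anchored to the
  first/last sample; with fewer than two extrema the envelope
  degenerates to the signal mean.
- **Mean diff operator** = mean(|x[i+1] − x[i]|).  The plain mean of
  differences telescopes to (x[n] − x[1])/(n − 1), which is ≈0 for any
  band-passed signal and carries no information.
- **Hjorth**: mobility = sqrt(var(Δx)/var(x)), complexity =
  mobility(Δx)/mobility(x).  For a sinusoid of frequency f at rate fs,
  mobility has the closed form 2|sin(πf/fs)|, which the suite checks.
- **Higuchi FD** with kmax = 8; **Hurst** by rescaled range over
  dyadic windows 8, 16, …, n/2; **ApEn/SampEn** with m = 2,
  r = 0.2·sd(x) (the conventional defaults), constant signals guarded
  to 0.  ApEn includes self-matches (Pincus), SampEn excludes them.
- **Spectral features** are computed on the one-sided periodogram with
  density scaling (`sum(power)·df = mean(x²)`, Parseval-checked).
  Spectral entropy is normalized by log2(#bins) into [0, 1].  Spectral
  flux uses 256-sample frames at 50 % overlap with per-frame
  L1-normalized magnitude spectra; on trials too short for two frames
  the frame shrinks to the largest power of two ≤ n/2.  SEF-x is the
  lowest bin where cumulative power reaches x % of total; SEP-x the
  cumulative power there in absolute units.
- **Wavelet features** come from a 3-level Symlet-4 DWT (4 vanishing
  moments), symmetric boundary extension, filter-bank convention
  matched coefficient-for-coefficient against an independent reference
  implementation and frozen in a fixture test.  Per band (a3, d3, d2,
  d1): histogram entropy, variance, sd, median, mean, and the max/min
  ratio of absolute coefficients with a 1e−12 denominator floor (the
  unfloored ratio is unbounded whenever a coefficient crosses zero).
  EA = 100·E(a3)/E(total) and ED = 100 − EA are the energy shares; ED
  is reported as a single total-detail share so the family totals 26
  (6 × 4 + 2).  Per-level detail shares are available from
  `dwt_decompose()` but are not part of the 57.

## mRMR feature selection

Features are discretized to 3 states at thresholds μ ± σ (z-threshold
scheme), which makes the ranking invariant to affine rescaling and is
robust at the n ≈ 880 scale where continuous density estimation is
fragile.  Mutual information is the plug-in estimate in bits.
Relevance of a set is the mean I(x_i; c); redundancy is the pairwise
sum normalized by |S|² — the redundancy expression is printed without
normalization in some sources, but the 1/|S|² form (from the original
mRMR literature) is required for D and R to be commensurate in
φ = D − R, and is what the package implements.  Ranking is greedy:
argmax I(x; c) first, then argmax of I(x; c) − mean over selected
I(x; x_j); ties break to the lower feature index.  The suite proves the
greedy trace equal to an independent brute-force evaluation of the same
incremental rule on small tables.  Default selection size k = 12.

## Classifier

One hidden layer, tanh in both layers, hidden size 2·n_inputs + 1
(Kolmogorov-mapping heuristic; 12 inputs → 25 hidden, 11 outputs).
Inputs are z-scored with training-split statistics only, stored in the
model artifact.  Targets are one-hot; the tanh outputs are mapped
affinely to (0, 1) and scored by cross-entropy (the "entropy"
performance function).  Training is Møller's scaled conjugate gradient
with σ = 5·10⁻⁵ and initial λ = 5·10⁻⁷ (the published defaults),
max 1000 epochs.  The data split is random 70/15/15, stratified by
class — strictly the split is described as plain random, but at ~80
trials per class an unstratified 15 % validation fold can lose a class
entirely; `stratify = FALSE` restores the literal reading.  Early
stopping: training stops after 6 consecutive epochs without a new
validation-loss minimum and the best-validation weights are returned.
The analytic gradient is verified against central finite differences at
relative error < 10⁻⁶, which is the core correctness test for SCG.

## Evaluation protocol

The two stated protocols — a 70/15/15 split and tenfold CV — are
reconciled the only way that avoids test leakage: an outer stratified
10-fold CV produces the reported accuracy, and the 70/15/15 split
lives *inside* each training fold solely to drive early stopping.
mRMR is refit per fold (a `fixed_selection` argument reproduces the
simpler fixed-selection reading), and z-scoring statistics come from
the training data of each fold.  The suite audits this by recomputing
fold-1's selection from the training rows alone and comparing.  ROC is
one-vs-rest on the continuous output scores with AUC by the
Mann–Whitney identity.  Whether the original protocol stratified by
trial or held out whole subjects is not stated anywhere; both modes are
available (`groups =` subject ids gives subject-wise folds), and the
benchmark default is trial-stratified.

## Synthetic data: what it emulates and what it does not

Each vowel class is a **vowel_class_spec**: a primary resonance
(centers spread evenly over 20–350 Hz with seeded jitter, 25 Hz
bandwidth) plus a weaker secondary resonance, an attack–sustain–decay
envelope (raised-cosine 20 %/20 %), and a nominal 1 mV RMS amplitude.
A trial is Gaussian noise shaped by those resonances — the standard
stochastic-interference model of MUAP trains — under the envelope.
Artifacts are injected afterwards: 0.5 mV DC, 0.2 mV 50 Hz mains with
random phase, 0.3 mV slow drift (0.05 Hz), 0.02 mV white noise;
per-subject log-normal gains with sd 0.15.  Defaults (1 s trials,
8 subjects × 11 classes × 10 trials, generator seed 11, spec seed 7)
define the benchmark world; amplitudes and SNR are plausibility
choices, since no amplitude figures exist to copy, and are not tuned
against any test outcome.

Randomness: every trial's substream seed is derived from the global
seed and a trial counter by integer arithmetic kept below 2³¹, so
generation is order-independent and the dataset is a pure function of
the configuration — the determinism the acceptance suite asserts
byte-for-byte.

What a green benchmark establishes: the full chain (preprocessing →
57 features → mRMR → SCG network → stratified CV) recovers
class-conditioned *spectral* structure far above the 1/11 chance
level, and collapses to chance when labels are shuffled or when class
spectra are made identical (both tested).  What it does **not**
establish: performance on real facial sEMG, where class differences
are subtler, nonstationary and subject-dependent; the motivating
study's accuracies (82.3 % overall, 84.2691 % tenfold, 94.5 % best
class, 72.2 % worst class) were measured on 8-subject recordings that
were never deposited and cannot be reproduced here.  The synthetic
benchmark also omits MUAP-level physiology, muscle crosstalk and
electrode-lift artifacts by design.

## Numerical and degenerate-input choices

- Filters run in double precision; odd-reflection padding, ≥250
  samples per edge (capped at n − 1).
- DWT boundary mode is symmetric half-point reflection: approximate
  energy conservation (within 1 % on ≥512-sample interior-dominated
  signals, tested) without periodicity artifacts.
- Spectral flatness uses a `double.xmin` floor inside the geometric
  mean so exact-zero bins yield flatness ≈ 0 rather than NaN.  On a
  raw (unsmoothed) periodogram of white noise the flatness statistic
  concentrates near exp(−γ) ≈ 0.56, not near 1 — the suite asserts
  noise ≫ tone rather than an unattainable absolute level.
- Zero-power spectra: spectral entropy and flatness guard to 0;
  SEF/SEP guard to (0, 0).  Zero-energy DWT raises an error at the
  energy-share step (EA/ED undefined).
- Trials shorter than 64 samples are rejected outright: a 3-level DWT
  and spectral framing need the headroom.
- mRMR ties break to the lower feature index; `which.max` makes this
  deterministic.
- Minimum 10 samples for `mrmr_rank`: below that the plug-in MI
  estimate is dominated by bias and any ranking would be noise.

## Known limitations

- Single-channel only; no montage support.
- The SCG implementation is batch (full-gradient); fine at n ≈ 10³,
  not intended for much larger corpora.
- Periodogram features use no tapering or Welch averaging; estimates
  are unbiased in location but high-variance per bin, which is
  acceptable because features feed a classifier rather than a
  spectral report.
- The synthetic world is stationary within a trial apart from the
  envelope; real articulation has formant-like trajectories the
  generator does not model.
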