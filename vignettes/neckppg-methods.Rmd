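---
title: "Classifying artifacts and detecting apneas in neck PPG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying artifacts and detecting apneas in neck PPG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Photoplethysmography (PPG) sensed at the suprasternal notch of the neck is an
attractive site for multi-modal respiratory monitoring: unlike finger or wrist
PPG, the neck signal is strongly modulated by respiration, so a breath-hold
(apnea) is visible almost immediately as a loss of amplitude modulation of the
pulse train, rather than tens of seconds later as an SpO2 desaturation. The
price is vulnerability to motion and contact artifacts (talking, swallowing,
coughing, head and body movement, sensor rubbing), which corrupt the signal
badly enough to make any derived vital sign unreliable.

`neckppg` implements a two-classifier pipeline over sliding windows of a
single-channel neck PPG trace:

* an **artifacts classifier** separating corrupted windows from clean PPG
  (where "clean" includes normal, slow breathing and apnea signal), and
* an **apnea classifier** separating apneic windows from the rest of the
  clean-PPG universe.

Both are soft-margin support vector machines with a Gaussian (RBF) kernel,
trained on a catalogue of 51 window features, with feature selection and
hyperparameter search performed under leave-one-subject-out cross-validation
(LOSO-CV) inside subject-safe outer data partitions, and the whole procedure
repeated with re-randomized partitions to measure stability.

## Data model

A *recording* is one subject's PPG trace at 75 Hz, by protocol 140 s long,
z-score normalized per recording before any processing. Ground truth is an
*annotation table* of half-open `[onset, offset)` intervals in seconds, with
labels `normal`, `slow_breathing`, `apnea`, or `artifact_<subtype>`; gaps
default to `normal`. A *cohort* bundles recordings, annotations and the
subject roster; per protocol each subject contributes one control, one
slow-breathing, one breath-hold and ten artifact recordings.

## Windowing and labelling

Windows of length $W \in \{4,5,6,7,8,10\}$ s slide by 2 s. The corruption
fraction of a window is the summed overlap of positive-class segments with the
window, divided by $W$; the window is positive when that fraction reaches the
threshold $Thd \in \{20,30,40,50\}\%$. For the apnea task, windows touching
any artifact segment are excluded rather than relabelled: the apnea classifier
is defined on the clean-PPG universe, and a corrupted window should be handled
by the artifacts classifier upstream. Positive/negative classes are balanced
by seeded downsampling of the majority class (no synthetic oversampling).

The apnea task is restricted to breath-hold recordings. Their interleaved
apnea / spontaneous-breathing structure supplies both classes, it is the only
universe on which the thirds partition (below) is defined, and the per-window
test counts it produces match the scale of the published evaluation of this
design.

## The 51 features

Time-domain features anchor on detected pulses: per pulse, amplitude
(onset-to-peak), width, rise time, and the value-distribution skewness and
kurtosis of the pulse segment; per consecutive pulse pair, peak-height
difference, peak distance and trough difference. Per window the pipeline
reports the mean of each per-pulse series (F1–F8), the mean absolute
consecutive difference ("Change", F9–F16), the sample (n−1) standard
deviation ("Std", F17–F24), and the zero-crossing rate of the windowed
signal (F25). Pairwise features are taken signed per pulse pair and
absolute-averaged, so sign cancellation cannot mask instability.

Correlogram features (F26–F29) are the values and lags of the first two local
maxima of the biased normalized autocorrelation of the mean-removed window,
searched from lag 0.25 s upward (skipping the trivial lag-0 peak; 0.25 s
corresponds to a 240 bpm guard) to at most `min(4 s, W/2)`.

Spectral features (F30–F41) come from a short-time Fourier transform with
10 s Hamming-tapered frames hopping by 1 s (90% overlap), stored as one-sided
modified-periodogram densities in dB/Hz with a floor at −120 dB. A window's
PSD is the linear-domain mean over frames whose centers fall inside it.
Shannon spectral entropies over 0–1.5 Hz and 1–4 Hz are normalized by
`log(#bins)` so they live in [0, 1]; spectral kurtosis is the per-bin
normalized fourth moment of the real STFT part over in-window frames
(falling back to frames merely overlapping the window when fewer than four
centers are inside), band-averaged; relative powers use disjoint half-open
bands 0–0.8, 0.8–1.3 and 1.3–1.8 Hz over the total; average band powers add
2.2–2.8 and 3.2–3.8 Hz.

Envelope features (F42–F51) ride on the upper envelope: a cubic spline
through local maxima at least 50 samples (0.667 s) apart, constant beyond the
outer knots. The block reports standard deviation, max, min, range,
approximate entropy, trapezoidal area of the absolute envelope, and mean
periodogram power of the mean-removed envelope in 0–0.15, 0.2–0.5, 0–0.5 and
0.5–1 Hz. Approximate entropy uses the Pincus convention (self-matches
included, Chebyshev distance) with `m = 2`, `r = 0.2·sd(x)`; the radius is
tied to the envelope's own scale so the statistic is invariant under the
per-recording z-scoring. The O(n²·m) pair count is implemented in C++; an
independent vectorized R implementation backs it in the test suite.

Windows with fewer than two detected pulses yield `NaN` for pulse-based
features and are dropped (with counts recorded) at table assembly, as are the
few edge windows without an in-window spectrogram frame center.

## Pulse detection

The pulse detector is deliberately simple and auditable: systolic peaks are
prominence-gated local maxima of a zero-phase (forward-backward) Butterworth
0.5–8 Hz band-pass of the normalized signal, with an enforced minimum
separation of `60/max_rate` s (default 180 bpm); the prominence gate adapts
per recording as one MAD of the band-passed signal, a robust scale that clean
pulsatile segments dominate even when a minority of the recording is
corrupted. Onsets are raw-signal minima between consecutive peaks; each
offset is the next onset; pulses truncated by the recording edge are dropped.
Band edges sit below the minimum heart rate and above the pulse harmonics of
interest; zero-phase filtering avoids index bias, verified by a
shift-equivariance test.

## Model training and validation

Features are z-scored with training-fold statistics before the kernel (the
model stores these, so test data never contributes scaling information).
The RBF kernel is the standard Gaussian `exp(-γ‖x_i − x_j‖²)`; cost grids are
task-specific (artifacts: 0.5, 1, 4, 6, 8, 16, 32, 64, 80, 128; apnea: 0.125,
0.75, 1, 2, 3, 4, 5, 6, 8, 32) crossed with the shared kernel-width ladder
`2^-15, 2^-13, …, 2^-1, 2^1, 2^3`. The quadratic program is solved by libsvm
via `e1071`.

Each outer repetition proceeds, strictly on the training side:

1. chi-square ranking of all 51 features — each feature is discretized into
   10 equal-frequency bins (equal-frequency avoids empty cells on skewed
   features) and tested for independence against the label; ties in p-value
   break by feature index;
2. LOSO grid search over the 100-point hyperparameter grid at the top-30
   ranked base set — artifacts selects by fold-mean accuracy, apnea by F1 of
   the pooled LOSO predictions (F1 is ill-defined on tiny per-fold
   contingency tables); ties break towards smaller C, then smaller γ,
   preferring smoother models;
3. forward sequential selection — candidates ranked 31–51 are added in rank
   order while each addition lowers the LOSO misclassification error
   (1 − accuracy of concatenated predictions) by a relative tolerance of at
   least 1e-6, with hyperparameters held fixed;
4. a final re-fit on the full training table with the selected features.

Fixing hyperparameters during the forward search (and tuning them at the
base set beforehand) is one of two defensible orderings; it is documented
here and held fixed everywhere.

Outer partitions are subject-safe. The artifacts task uses
leave-30%-of-subjects-out: `round(0.3·n)` subjects, all of whose windows
travel together, form the test side. The apnea task splits each breath-hold
recording into three duration-equal segments, drops windows straddling
segment borders from both sides, balances classes within each
subject-segment cell, and rotates which segment is held out. A subject whose
held-out segment lacks one class — possible at low thresholds when an
episode saturates a third of the recording — is dropped from both sides of
that repetition (recorded in the partition plan) rather than aborting it. All randomness
derives deterministically from a single experiment seed and the repetition
index, so reruns with the same seed are bit-identical.

The repeated-randomization driver runs every requested (W, Thd) combination
for n repetitions (30 in the full protocol), aggregates mean ± sd per metric
(ACC, SE, SP, precision, F1, each recomputable from the confusion counts it
also stores), counts per-feature selection frequencies, and selects the best
model by mean accuracy (artifacts) or mean F1 (apnea). Repetitions failing
with an empty class are recorded and skipped; more than 20% failures aborts.
Undefined metrics (zero denominators) are excluded from aggregation with a
recorded count, never imputed as 0.

## The synthetic cohort

The human dataset behind this design is not deposited, so the package ships
a generator that emulates the acquisition protocol: per subject, heart rate
(55–90 bpm), respiratory rate (0.15–0.35 Hz), pulse rise time and dicrotic
notch depth are drawn once (giving LOSO-visible between-subject variance);
each recording is a 140 s train of per-beat pulse templates at lognormally
jittered intervals (CV 3%, so correlogram peaks are defined but not
degenerate), amplitude-modulated by a phase-continuous respiratory waveform
(depth 0.3), plus slow baseline wander and white sensor noise (sd 0.02).
Breath-hold recordings contain three 20–30 s episodes in which modulation
depth drops to 0.02 and interval jitter shrinks; slow-breathing recordings
halve the respiratory rate in three such episodes; artifact recordings add a
subtype-specific corruption — band-limited noise bursts, step/ramp
excursions, or large low-frequency oscillations — in three exact 20 s bursts
at +6 dB artifact-to-pulse power, alternating with annotated normal gaps.
Annotations are exact generator truth.

The generator is a test harness, not a physiological claim: it is designed
so that the features this pipeline relies on (envelope variability, spectral
entropy, pulse-height differences) separate the classes. Passing the
end-to-end tests therefore demonstrates that the pipeline recovers structure
the generator put in — correctness of the machinery, not clinical
performance. Real neck PPG differs in ways the simulator does not attempt:
artifact morphologies here are schematic stand-ins, apneas in patients are
obstructive/central/mixed rather than clean breath-holds, and no SpO2 or JVP
physiology is modelled.

## Problem sizes and numerical choices

Simulation scale is chosen for desk-scale reproducibility: the default
cohort has 12 subjects (156 recordings); the shipped experiment runs use 5
repetitions per (W, Thd) combination; and balanced tables are capped at 300
windows per class by seeded downsampling (`max_per_class`), which keeps the
100-configuration LOSO grid search tractable while leaving class balance and
subject structure intact. The full-protocol settings (30 repetitions,
uncapped tables) are a parameter change, not a code path change.

Other numerical choices, fixed and documented: the spectrogram taper is
Hamming and the dB floor −120 dB; band powers are computed in the linear
power domain (dB is presentation-only); entropy uses natural logs with
`log(#bins)` normalization; standard deviations use the sample (n−1)
convention throughout (the oracle tests recompute with the same convention);
half-open interval conventions everywhere (windows, annotations, frequency
bands), with overlap ties at boundaries going to the earlier segment;
degenerate inputs return `NaN` (too few pulses), a constant envelope (fewer
than two maxima), p = 1 (constant feature under chi-square), or 0
(approximate entropy of a constant sequence).

## Known limitations

The pulse detector is not an ectopy-aware beat classifier; it assumes a
quasi-periodic pulse train. The apnea classifier is trained and evaluated on
breath-hold recordings only, by construction of the partition. Multi-class
artifact-subtype labelling, signal reconstruction of corrupted segments,
SpO2/heart-rate derivation and streaming deployment are out of scope.
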