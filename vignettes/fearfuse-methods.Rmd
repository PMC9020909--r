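---
title: "Decoding fear from EEG by fusing activation, spatial, and connectivity features"
author: "fearfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding fear from EEG by fusing activation, spatial, and connectivity features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The decoding problem

`fearfuse` classifies 30-second EEG trials into *fear* versus *neutral*
from a 30-channel 10-20 montage sampled at 250 Hz. The premise is that
an emotional state expresses itself in (at least) three distinct ways
in scalp EEG:

* **Activation** — how much band-limited power each channel carries.
  The feature is differential entropy (DE): for a band-limited signal
  treated as Gaussian, `DE = 1/2 ln(2*pi*e*sigma^2)` nats, with
  `sigma^2` estimated as the mean of the one-sided zero-padded
  periodogram over the band. DE is a logarithm of band power, so a
  multiplicative amplitude change becomes an additive feature shift.
* **Spatial distribution** — which linear combinations of channels
  carry class-dependent variance. Common spatial patterns (CSP) finds
  spatial filters by whitening the composite class covariance and
  eigendecomposing the whitened class-1 covariance; the first and last
  three filters (the variance-ratio extremes) yield a 6-value
  log-energy feature per band.
* **Connectivity** — how stably pairs of channels hold their phase
  relation. The phase-locking value (PLV) of a channel pair is the
  magnitude of the window-averaged unit phasor of their instantaneous
  phase difference (Hilbert-transform phases): 1 under perfect
  locking, falling to the Rayleigh floor `~1/sqrt(N)` for independent
  phases. All 435 channel pairs per band form the network-pattern
  (ENP) feature block.

Each 30-s trial is cut into thirty 1-second segments. Per segment the
three feature blocks are concatenated — 150 DE + 2175 ENP + 30 CSP =
2355 features — z-scored with training statistics, and classified by a
linear soft-margin SVM (C = 1) whose segments inherit their trial's
label. A trial's label is the majority vote of its 30 segment
predictions, ties broken toward "neutral" (a documented convention;
with 30 votes ties are rare). Evaluation is leave-one-out over trials:
per fold, the per-band CSP models, the feature normalization, and the
SVM are refit on the 39 training trials only. Refitting CSP inside
every fold is deliberate: CSP is supervised, and fitting it on all
trials would leak the held-out label.

## Preprocessing

The fixed chain is: per-channel baseline correction (subtract the mean
of the 1-s pre-stimulus window), a zero-phase biquad notch at 50 Hz
(Q = 30, about 1.7 Hz wide), and a zero-phase Butterworth bandpass of
effective order 10 between 0.1 and 70 Hz. The order is enforced by
pipeline-state tags on the epoch objects; running a step out of order
raises an error. Band-restricted analysis (the filter bank: delta 1-3,
theta 4-7, alpha 8-13, beta 14-30, gamma 31-48 Hz) uses zero-phase
4th-order Butterworth filters applied to whole epochs before
segmentation, so filter transients never sit at segment boundaries.

Numerically, all IIR filters are factored into second-order sections
(conjugate pole pairs matched with their nearest zeros) and run as a
compiled cascade with steady-state initial conditions and
odd-reflection padding. A single direct-form realization of an
order-10 bandpass with a 0.1 Hz edge is ill-conditioned; the cascade
realization is the standard fix. One caveat worth knowing: a 0.1 Hz
high-pass pole has a settling time of more than a minute, so *any*
zero-phase implementation (ours, or the common Python/Matlab ones)
leaves a slowly decaying low-frequency edge transient on records of a
few seconds. Filter tests therefore assess the realized frequency
response at the probe frequency rather than total output power, and
phase-based analysis excludes 0.1 s at each trial edge.

The phase path computes the analytic signal by FFT over the whole
trial, then windows the phases: PLV windows are 1 s long, stepped by
0.4 s, and aggregated to the shared 1-s segment grid by averaging the
windows whose centers fall inside each segment. (The source
description of the PLV average is ambiguous about whether the sum runs
over trials or samples; summing over a window's samples is the
standard reading and the one that keeps the connectivity features
aligned with the DE/CSP segment grid.)

## The classifier

The SVM is linear so that the primal weight vector exists: per-channel
weight maps are the band-averaged absolute DE-block weights, and
feature-recovery tests rely on them. Internally the solver is a
deterministic dual coordinate-descent routine (the liblinear
algorithm) compiled in C++, with the bias as an augmented constant
feature. The evaluation protocol fits roughly two thousand SVMs
(40 folds x feature sets x seeds); kernel-cache SMO solvers take
seconds to tens of seconds per fit on the 1170 x 2355 fold problem,
while dual coordinate descent takes well under a second at equal
solutions (the test suite cross-checks its decision direction against
an independent SMO implementation). z-scoring before the SVM is
necessary because the three blocks live on incompatible scales (nats,
log10 energy, and [0, 1] PLV).

## The synthetic study conditions

Real recordings of the target paradigm are not redistributable, so the
package ships a generative model of a session: 40 trials (20 per
class) in seeded random order, each 2 s of pre-stimulus plus 30 s of
stimulus at 250 Hz, on a 1/f-shaped background (10 uV RMS per channel)
with a 2 uV common-mode 50 Hz line component. Class information enters
through three independently controllable dials, each designed to be
visible mainly to one feature family:

* **Activation**: a diffuse alpha-band oscillator on every channel
  whose amplitude is 3 uV for neutral and 1.1x that for fear. A
  uniform, channel-independent power shift moves per-channel log power
  (DE) but hardly moves trace-normalized covariance topography (CSP)
  or pairwise phase locking (ENP).
* **Spatial**: two 8-channel beta-band sources (frontal and parietal)
  at 0.45 uV whose channel loadings are all `+1` for fear but
  alternate `+1/-1` for neutral. Per-channel power is identical, and a
  sign flip is a constant pi phase offset that PLV cannot see, but the
  cross-covariance structure flips — a CSP-only contrast.
* **Connectivity**: two 4-channel theta-band groups (central,
  parietal) at 4.5 uV sharing one oscillator per group, with
  per-channel phase jitter of SD 0.35 rad (fear) versus 1.7 rad
  (neutral). The jitter is low-passed at 5 Hz so it decorrelates
  within a 1-s window, a slow drift tops the total phase variance up
  to the larger class SD so the *expected* cross-covariance matches
  across classes (keeping CSP blind), and the injected signal is
  re-band-limited and re-normalized after phase modulation so both
  classes inject identical power (keeping DE blind).

Amplitudes were calibrated once, against sessions from seeds outside
the evaluation grid, so that each single feature family decodes in the
80-95% range and the fused feature set above it — the accuracy regime
the method is designed for — and then frozen. Additionally, each fear
trial expresses each dial independently with probability 0.95
("expression"): emotion induction in real subjects is not uniformly
successful, and occasional silent modalities are what give feature
fusion its practical advantage over any single family. The realized
expression draws are recorded on the generated session (attribute
`expressed`) for diagnostics.

What the generator does *not* emulate: ocular and muscle artifacts,
electrode drift and impedance changes, volume-conduction mixing of the
background, non-stationarity across the session, and
subject-to-subject variability. Passing recovery tests therefore shows
the pipeline extracts exactly the kinds of structure it claims to
extract, at realistic SNR — not that it would reach the same numbers
on any particular recording.

## Statistics

Differential-connectivity analysis runs a one-way ANOVA across trials
on trial-mean PLV for every channel pair (equivalent to the squared
pooled two-sample t statistic for two groups), flagging edges at
`p < 0.05` by default, with optional Benjamini-Hochberg correction.
(The source analysis is described in one place as repeated-measures
and in another as one-way ANOVA; one-way across trials is what is
implemented.) Accuracy comparisons between feature sets use a paired
two-sided t test across subjects, with the degenerate zero-variance
case mapped to p = 1 (equal means) or p = 0 (unequal), flagged by a
warning.

## Numerical choices and degenerate inputs

* Band power is averaged over DFT bins with `low <= f <= high`
  (closed on both ends) on the 1024-point zero-padded grid.
* Zero or negative power is floored at 1e-20 before logs, with a
  warning; zero projected CSP variance likewise.
* CSP eigenvalue ties are broken by the channel index of the dominant
  coefficient, and each filter is scaled so its largest-magnitude
  coefficient is positive — signs are mathematically arbitrary, fixing
  them makes outputs reproducible. A ridge of `1e-8 * trace / n` is
  added to rank-deficient composite covariances.
* Constant features are dropped before z-scoring (logged); the SVM
  solver is deterministic (fixed sweep order), so identical inputs
  give bit-identical cross-validation results.
* All generator randomness flows from one seed through a private RNG
  stream; the global RNG state is saved and restored.

## Problem sizes used in validation

The test suite validates the full study geometry — 40 trials of 30 s
at 250 Hz, 40-fold leave-one-out, the 2355-wide fused feature space —
on a ten-seed grid for the recovery and fusion-superiority checks, and
uses reduced sessions (6 trials of 6 s) for unit-level contracts where
the geometry is irrelevant. Null-calibration checks for the edge-wise
ANOVA use one full-size null session per run; the Rayleigh and
permutation oracles use 200-1000 replicates.

## Known limitations

* EDF support covers the common 16-bit single-rate case with events in
  a plain-text sidecar; EDF+ annotation channels are not parsed.
* No re-referencing is applied beyond the hardware reference of the
  recording; the acquisition description leaves software re-referencing
  unspecified, so none is guessed.
* Resampling is out of scope: sessions must arrive at the configured
  sampling rate.
* The delta band is barely resolved by 1-s windows (two to three
  periods); its DE estimates are correspondingly noisy, which mirrors
  the method rather than a defect of the implementation.
* Causal (single-pass) filtering is available via `zeroPhase = FALSE`
  but the pipeline default is zero-phase throughout.
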