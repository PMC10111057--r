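---
title: "Evaluating acoustic tinnitus therapies with AERPs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating acoustic tinnitus therapies with AERPs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tinnaerp)
```

## The problem

Chronic tinnitus is commonly treated with personalized sound: retraining
noise bands (TRT), auditory-discrimination oddball trains (ADT), enriched
acoustic environments (TEAE), binaural beats (BBT), and untuned relaxing
music as placebo. Whether a therapy works is usually judged from
questionnaires (THI, HADS), which are subjective. This package implements an
objective complement: auditory event-related potentials (AERPs) evoked by
the therapy sound itself, recorded before (S0) and after (Sf) an eight-week
program, compared channel-by-channel through the area under the curve (AUC)
of the grand-average difference, and tested nonparametrically.

Because the interesting claims concern a processing chain rather than a
closed-form statistic, the package pairs every stage with a ground-truth
simulator: a cohort generator, therapy-sound synthesizers, and an EEG
simulator whose evoked components, trial coherence, alpha peak and artifacts
are all known and inventoried. Every downstream estimate can therefore be
checked against what was embedded.

## The monitoring protocol the simulator emulates

One stimulation session is 50 one-second auditory stimuli with a 2-s
inter-trial interval (150 s). EEG is 16 scalp channels (10/20 layout:
Fp1, Fp2, F3, F4, F7, F8, C3, C4, T7, T8, P3, P4, P7, P8, O1, O2) at
256 Hz. Epochs run from 200 ms before to 800 ms after onset — 256 samples
per epoch at 256 Hz. A resting eyes-closed recording (default 180 s)
provides the individual alpha frequency (IAF). The simulated session places
the first stimulus 0.5 s into the recording so the pre-stimulus window of
the first epoch exists while the total length stays at the schedule length.

The default cohort reproduces the completed-procedure group sizes
(placebo 11, BBT 14, TRT 15, TEAE 15, ADT 8, healthy controls 8; 71 of 103
recruits, 32 non-completers kept only as a count).

## Evoked-component templates

Templates are sums of Gaussian deflections with literature-informed signed
amplitudes and latencies: for tinnitus sufferers N1 (−1.7 µV, 150 ms),
P2 (2.4 µV, 250 ms), P3 (2.6 µV, 380 ms); for controls N1 (−2.2 µV, 80 ms),
P2 (2.9 µV, 207 ms), P3 (4 µV, 340 ms). The Gaussian widths are not part of
the published parameter set; we chose sd = 15, 25 and 40 ms for N1, P2, P3
respectively — each component's conventional time scale — and kept them
fixed. The single-trace template is projected onto the montage with a
fronto-central weight map (F3/F4/C3/C4 = 1 down to O1/O2 = 0.3),
configurable per call.

Trial-to-trial phase locking is controlled by `itc_level` in [0, 1], mapped
to a latency-jitter sd of `(1 − itc_level) × 40` ms. The mapping is a
simulator convention, chosen so the range spans perfect locking to heavy
smearing. Background noise is 1/f-shaped Gaussian noise with a 20% white
floor, independent per channel (no volume-conduction correlation — a known
simplification).

## The six-step cleaning chain

1. Baseline (DC) removal per channel, plus conventional pre-stimulus mean
   subtraction at epoching (switchable off).
2. Band-pass 0.1–100 Hz, IIR Butterworth of order 8, applied
   forward-backward. Zero-phase filtering is required because latency
   claims downstream would otherwise be biased; the effective order doubles.
3. 60-Hz rejection, realized as an order-2 Butterworth band-stop at
   58–62 Hz, also forward-backward.
4. Artifact subspace reconstruction (ASR), simplified operator: a
   principal-component basis and per-component spread are learned from the
   quietest 60 s (sliding-RMS search, or a user calibration segment of at
   least 30 s); stretches where a component's sliding 0.5-s RMS exceeds
   `cutoff_k = 20` calibration standard deviations are zeroed with
   half-window dilation and the data reconstructed from the retained
   subspace. `cutoff_k = Inf` is the identity; clean data pass through.
5. Wavelet-ICA removal of stationary (ocular/cardiac-type) artifacts:
   seeded symmetric FastICA (tanh contrast), components flagged when excess
   kurtosis exceeds 5 or the sub-4-Hz power fraction exceeds 0.6, flagged
   components wavelet-thresholded (periodized sym4, 5 levels) and the
   large-coefficient part subtracted before remixing.
6. Segmentation into −200…+800 ms epochs; epochs that would cross the
   recording boundary are dropped and logged.

Two numerical choices in steps 4–5 deserve emphasis. First, ASR detection
uses a per-sample sliding RMS with dilation rather than disjoint blocks:
with disjoint blocks, the low-coverage edges of a step artifact escape the
threshold and survive as residual spikes. Second, the wavelet thresholds
are per-level (each level's own robust MAD spread, universal factor
`sqrt(2 log n)`): a single threshold derived from the finest-detail noise
also flags the large approximation coefficients that encode legitimate slow
evoked activity, and measurably flattens the recovered P3; per-level
thresholds remove only within-level outliers (blink lobes, residual
spikes). The multi-level transform caps its depth so the coarsest band is
never shorter than the 8-tap filter, where periodization would wrap the
filter onto itself and break orthogonality.

FastICA runs with a seeded orthonormal initialization; if the tolerance is
not met within the iteration cap the last symmetric-decorrelated rotation
is used. Directions within a near-Gaussian subspace have no preferred
rotation and oscillate indefinitely without affecting the non-Gaussian
(artifact) components; only true decomposition failure — rank deficiency —
triggers the degraded mode, which returns the input unchanged with a
warning and a report flag.

## AERP estimation, ITC and IAF weighting

Per-channel AERPs are plain arithmetic trial means. Inter-trial coherence
(ITC) is computed in a band of ±2 Hz around the IAF (the band half-width is
our choice; the procedure prescribes only "around the IAF"): each epoch's
band-limited analytic signal (FFT band selection — robust on 256-sample
epochs where an IIR band-pass is dominated by edge transients) is reduced
to unit phasors over the post-stimulus window, and ITC is the magnitude of
the across-trial phasor mean, averaged over the window. A variant that
samples each trial's phase at its envelope peak is available
(`method = "peak"`), but it is *not* the default: under realistic trial
noise the envelope maximum lands on noise excursions at random latencies,
which destroys the estimator's monotonicity in the true phase locking (we
measured ITC 0.10 at full locking vs 0.21 at none with the peak variant,
against 0.49 vs 0.11 for the per-sample form). ITC is 1 for identical
trials and ~`N^{-1/2}`-scale for random phase; a single trial degenerates
to 1 with a warning.

Each channel's AERP is multiplied by its ITC (suppressing random peaks
relative to phase-locked components) and by a channel-independent factor
`10 / IAF` that normalizes the participant's alpha frequency to the
canonical 10-Hz peak. The weighting *formula* is a package convention: the
procedure states the intent (compensating demographic IAF differences) but
no formula, so the factor is prominently stored in every result and trivial
to disable (`iaf = NULL`).

The IAF itself is the peak of the mean O1/O2 Welch spectrum restricted to
7–14 Hz, on a zero-padded grid finer than 0.25 Hz; a peak below twice the
in-band median power warns of low prominence.

## AUC comparison and statistics

Grand averages are unweighted means across participants. The per-channel
AUC is the signed trapezoidal integral of the Sf − S0 grand-average
difference over the full −200…800 ms window, in µV·ms; the magnitude ranks
channels, giving AUCmax and its channel AUCch (earliest channel on ties).
Signed integration over the full window is our reading — the source
procedure does not state signed vs absolute or the window.

Group evaluation mirrors the published decision chain: a D'Agostino–Pearson
omnibus normality test on the AUC inputs (pooled over the two sessions by
default; per-session behind a flag), then a Wilcoxon comparison of the 16
paired per-channel AUCs, rejecting the null of no therapy effect at
p < 0.05. The published description names the rank-sum test but describes
16 *paired* samples; the paired design mandates the signed-rank form, which
is the default (zero differences dropped, exact distribution for small
tie-free samples); the rank-sum form is available for literal replication.
The omnibus test itself is implemented from the standard skewness and
kurtosis z-approximations (K² against chi-square with 2 df), since no
installed package provides it; it matches an independent implementation to
ten decimals and is calibrated by simulation in the test suite. No
multiple-testing correction is applied across the six groups, mirroring the
published analysis.

The correlation screen uses Spearman rank correlations (Pearson behind a
flag) between demographic/audiological variables and the AUC attributes,
with categorical variables integer-coded and AUCch coded by montage index —
an explicit, imperfect convention (channel labels have no natural order).

## What the generator does and does not emulate

The cohort generator reproduces group sizes, hearing-level bands, tinnitus
pitch/intensity/laterality ranges, a built-in dependence of tinnitus
intensity on right-ear hearing loss (so the correlation screen has a known
positive to recover), and mostly-unchanged questionnaire trajectories. It
does not attempt to match the real cohort's exact marginal distributions or
dropout process. The EEG simulator omits volume conduction, heartbeat
artifacts and eyes-open segments. Passing tests therefore demonstrate that
the chain recovers what it embeds under these idealizations — not
performance on recorded patient data, whose group-level p-values are
outside this package's reach.

## Desk-scale study sizes used by the tests

Simulation-backed tests run at sizes chosen once for identifiability and
speed: IAF recovery over 50 seeded resting minutes; ITC monotonicity over
20 seeds × 4 coherence levels at 2 µV background; the type-I error of the
evaluation chain over 1000 null replicates; and the end-to-end localization
check — a 1.5× amplification of C4 in the final sessions of a group of 8
(the completed ADT/control group size) at 2.5 µV residual background, i.e.
cleaned-data conditions, recovered as AUCch in ≥ 90% of 20 replicates. The
analysis drivers use 3 participants per group to keep a full-chain
walk-through short; at that size single-channel effects show up in AUCch
but, as expected, not in the 16-channel paired test, and spurious AUCch
winners occur in null groups — the scripts print the embedded truth next
to each estimate so this is visible.

## Known limitations

- The tinnitus-intensity-to-digital-level calibration is a free parameter
  (default: intensity 100 maps to 0 dB FS, therapy presented 5 dB below);
  no physical calibration is modeled.
- TEAE amplitude scaling is linear in dB HL (floor amplitude at zero
  loss); linear-in-pressure is equally defensible and not implemented.
- The BBT beat frequency defaults to 10 Hz (alpha-band entrainment) and is
  configurable; the target band is a design choice.
- ASR and wavelet-ICA are simplified operators with the published
  algorithms' structure, not bit-exact re-implementations of the EEGLAB
  plug-ins.
- ITC band width, estimator form and the IAF weighting factor are package
  conventions (flagged above); results that depend on them should not be
  read as exact replications.
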