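---
title: "Methods: simulating and analysing infant block-design fNIRS"
author: "nirsblock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing infant block-design fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsblock)
```

## What this package computes

`nirsblock` implements the full computational chain of a block-design
infant fNIRS experiment on synthetic data with known ground truth: a
forward simulator of dual-wavelength (695/830 nm) raw intensity
recordings, a HOMER-style preprocessing cascade down to oxy-/deoxy-Hb
concentration changes, block averaging with per-block and per-participant
exclusion rules, and channel-wise t-tests corrected for multiplicity by
max-|t| permutation null distributions. The target design is an
auditory prosody paradigm: two conditions (`HL`, heavy-light, and `LH`,
light-heavy bisyllabic word forms) in 14 alternating 15-s blocks
(10 stimuli at 1.5 s SOA) separated by silent baselines of 18, 20 or
22 s, measured over 24 lateral channels of which six — 6, 7, 9 (right)
and 18, 19, 21 (left) — cover the superior temporal regions and form the
region of interest (ROI).

## The forward model

### Design scheduler

`make_block_design()` draws one baseline duration per block uniformly
and independently from \{18, 20, 22\} s (the jitter policy is not
prescribed by the paradigm; independent uniform sampling is the simplest
exchangeable choice) and alternates conditions strictly. The first
condition is randomized per participant (counterbalancing is not
prescribed either; randomization by seed makes the cohort symmetric in
expectation). `total_duration` is the end of the last block — with all
baselines at their 20 s mean this is exactly 14 × 15 + 14 × 20 = 490 s —
and the simulated recording runs `scan_padding` (default 20 s) longer so
the final epoch window fits.

### Hemodynamic response

The infant hemodynamic response function is not well characterised, and
no specific kernel is prescribed for this paradigm; the simulator uses a
canonical double-gamma stand-in (gamma bump peaking at 5 s minus a
0.2-scaled undershoot bump peaking at 14 s), peak-normalised to 1.
Block responses are boxcar convolutions of this kernel rescaled so that a
single isolated block peaks at exactly the configured amplitude; this
makes `peak_amplitude` interpretable in concentration units regardless of
kernel shape. Deoxy-Hb is modelled as a negative scaled copy of the
noiseless oxy-Hb response (ratio −1/3, the typical anticorrelation), plus
its own noise.

Ground-truth amplitudes default to a left-lateralised condition effect:
left ROI channels respond at 0.40 µM to HL and 0.15 µM to LH, right ROI
channels at 0.25 µM to both, non-ROI channels at 0.05 µM. These are the
"study conditions" of every simulation-based check in the package.

### Noise and artifacts

Concentration-domain noise per channel: a slow sinusoidal drift
(0.3 µM at 0.002 Hz), a Mayer-wave component (0.10 µM at 0.1 Hz), a
respiratory component (0.05 µM at 0.5 Hz) — each with an independent
random phase — and white noise (sd 0.05 µM per sample). Motion artifacts
are injected in the optical-density domain, where they physically arise:
brief half-sine spikes (0.2-0.8 s) and plateau-like baseline shifts
(3-10 s of displaced baseline bounded by two steps). Shifts are modelled
as plateaus rather than persistent steps so that the ground-truth mask
can mark every contaminated sample and segment-local correction is
well-posed; persistent slow displacement is the band-pass filter's job.
Every artifact event displaces all channels at both wavelengths with
per-channel random amplitude and sign — the spatially global signature of
a head movement. Artifact amplitudes default to 0.005-0.05 OD (spikes)
and 0.01-0.1 OD (shifts), i.e. roughly 3-30 times the evoked
hemodynamic OD change under the package's extinction scale — large, as
infant artifacts are, but on the same footing as the physiology.

What the generator does **not** emulate: superficial/systemic physiology
distinct from the cortical signal, heart-rate pulsation (above the
band of interest at 10 Hz sampling it aliases little and is omitted),
optode-specific coupling losses, non-stationary noise, and real infant
behavioural states. Passing tests therefore demonstrate that the
*procedure* is implemented correctly and calibrated under a plausible
generative model — not that it is robust to everything real data can do.

### Optics

`forward_beer_lambert()` maps concentrations to OD via the modified
Beer-Lambert law `dOD(λ) = d · ppf · (ε_oxy(λ) Δoxy + ε_deoxy(λ) Δdeoxy)`
with `d = 3` cm and `ppf = 1`; `od_to_intensity()` applies
`I = I0 · exp(−dOD)` with optional multiplicative log-normal measurement
noise. The shipped extinction coefficients are interpolated from a
standard compilation of hemoglobin absorption spectra and expressed in
1/(µM·cm); because `ppf = 1` absorbs the true partial pathlength, the
absolute concentration scale is a convention — every t statistic in the
pipeline is scale-invariant — and the table is overridable.

## The preprocessing cascade

Stage order is fixed and logged: prune → OD → motion detection → spline
correction → wavelet correction → residual re-detection with per-block
validity flagging → band-pass → concentration. Parameters default to the
published recommendations this package mirrors: SNRthresh = 2,
tMotion = 1.0 s, tMask = 1 s, AMPthresh = 4 OD, STDEVthresh = 15,
spline p = 0.99, wavelet IQR = 0.5, band-pass 0.01-0.09 Hz, ppf = 1.

Reconstruction choices the parameter list alone does not determine
(flagged here because they are choices, not published facts):

* **OD convention.** Natural logarithm: `dOD = −ln(I / mean(I))`. A
  log10 dialect exists in the field; the natural-log form matches the
  reference processing stream and makes `od_to_intensity()` /
  `intensity_to_od()` exact inverses up to a per-channel constant.
* **Motion detection statistic.** A window is flagged when its
  peak-to-peak OD change exceeds AMPthresh, **or** when its largest
  sample-to-sample change exceeds STDEVthresh times a spread estimate of
  the channel's OD changes. The spread is the sd of the changes after
  trimming the top 2% of |changes|: untrimmed, sparse artifacts inflate
  their own threshold; a fully robust (median-based) scale, conversely,
  collapses on smooth low-noise signals whose slope distribution is
  heavy-tailed, and fires on clean data. The change statistic (rather
  than the raw OD sd) keeps the threshold insensitive to slow
  physiological swings. Detection runs on OD at both wavelengths and a
  channel is flagged if either triggers.
* **Spline correction.** Within each flagged segment a smoothing spline
  (`spar = 1 − p`, so p = 0.99 tracks the artifact trajectory closely)
  is fitted and subtracted, and the segment is re-anchored to the mean of
  up to 2 s of immediately preceding clean signal (one-sided at the
  recording edges; linear fallback for segments shorter than 8 samples).
  Unflagged samples are never modified.
* **Wavelet correction.** Orthonormal Daubechies-2 transform with
  periodic boundaries after reflection-padding to a power of two,
  implemented in-package (verified against an independent reference
  decomposition in the tests). Per detail level, coefficients outside
  `[Q1 − 0.5·IQR, Q3 + 0.5·IQR]` are zeroed. Two restrictions keep the
  step surgical: (i) only levels whose passband lies above the 0.09 Hz
  analysis cutoff are thresholded (5 levels at 10 Hz) — transients are
  broadband and dominate fine scales, while evoked structure lives in
  the coarse scales, which thresholding would otherwise distort; (ii)
  coefficients whose support touches the padding junction are exempt,
  because reflection kinks are not motion.
* **Band-pass.** 3rd-order Butterworth applied forward and backward
  (zero-phase, no lag of in-band components). 0.03 Hz passes with gain
  ≥ 0.9; 0.5 Hz is attenuated below 0.1.
* **Boundary policies.** SNR exactly at threshold retains the channel;
  constant traces (sd 0) count as infinite SNR; channels with
  non-positive intensities are unavailable, never patched.

Pruned channels are carried as `NA` with all-invalid blocks — masks only
ever shrink availability, never fabricate data.

## Block averaging and exclusions

Epochs span −3 to +30 s around block onset with inclusive endpoints
(331 samples at 10 Hz). The pre-onset interval \[−3, 0) — half-open, so
the onset sample belongs to the response — supplies the baseline mean
subtracted per epoch, channel and Hb species. The per-participant
statistic is the mean over \[0, 30\] s of the average of valid epochs,
computed within participant; blocks are never pooled across
participants. The baseline is read from the −3 to 0 s window (the
conventional block-average reading; whether the original analysis used
the preceding silence's tail instead is not stated, and this choice is
fixed and documented rather than configurable).

A block is invalid for a channel if residual motion is detected anywhere
in its epoch window or the window leaves the recording. An ROI channel
is *available* for a participant iff both conditions retain at least 3
valid blocks on it; a participant is *retained* iff at least 5 of the 6
ROI channels are available. Both thresholds are parameters
(`exclusion_params()`), and raising either can only shrink the cohort.

## Inference

For each family — age group × \{HL vs baseline, LH vs baseline,
HL vs LH\} × \{oxy, deoxy\} — channel-wise one-sample t-tests (or paired
tests, computed as one-sample tests on HL − LH differences) run over the
six ROI channels, with Cohen's d = mean/sd (the `t/√n`-consistent
one-sample/paired convention; the alternative averaged-variance paired
convention would differ, and exact agreement with any published table is
not asserted).

Family-wise error control follows the max-statistic permutation scheme:
10,000 repetitions by default; per repetition one Rademacher sign per
participant is applied jointly to all channels (label swaps in the paired
case are algebraically identical sign flips of the differences, and the
implementation makes them literally identical given the seed), t is
recomputed per channel, and the maximum |t| over channels with at least
two contributors is recorded. Per-channel flipping is deliberately
rejected — it would destroy the spatial correlation the max statistic
exists to respect. Each family gets its own null and its own seed,
derived deterministically from the master seed (documented offsets, as is
the per-participant seed rule `master + 104729·i mod 2³¹−1`).

The corrected p value is the add-one smoothed tail proportion
`(1 + #{max-|t| ≥ |t_obs|}) / (1 + n_permutations)`: never exactly zero,
monotone in |t|, and exact-in-expectation for exchangeable nulls. Sign
flips leave per-channel sums of squares invariant, so the permutation
engine recomputes every t from the flipped means alone — one matrix
product per family — which is what makes 500-cohort calibration sweeps
cheap. Participants missing a channel contribute to the channels they
have; degrees of freedom and d use each channel's own n; a channel with
fewer than two contributors is dropped from the max with a warning.

## Calibration and power, as verified by the test-suite

The acceptance suite simulates at summary level (the statistic the tests
consume), holding the full pipeline fixed: 500 global-null cohorts of
n = 30 participants over 6 channels with pairwise correlation 0.3 and
2,000 permutations each must give a family-wise rejection rate in
\[0.03, 0.07\] at α = 0.05; 100 cohorts with a 0.8-SD paired effect in
channel 18 only must reject that channel in ≥ 80% of cohorts and not
systematically elsewhere. Exhaustive sign-flip enumeration (2ⁿ patterns,
n ≤ 10, up to 3 channels) pins the sampled corrected p to the exact
permutation p within Monte-Carlo error. These problem sizes are the
package's chosen verification scale: large enough for the binomial error
on a 5% rate to resolve the \[0.03, 0.07\] band, small enough to run
routinely.

## Known limitations

* The simulator's HRF, noise spectra and artifact statistics are
  plausible stand-ins, not measurements of any real infant cohort; all
  power statements are internal to that generative model.
* Spline re-anchoring trusts the 2 s before a flagged segment; artifacts
  longer than the anchor window or covering a recording edge are
  corrected one-sidedly and can retain level error.
* Sub-threshold artifacts (below the detection criteria) pass through
  correction and inflate between-participant variance — visible in the
  demo cohort as paired effects weaker than the configured amplitudes
  would suggest. This mirrors the real method's behaviour rather than a
  defect, but it means simulated effect recovery understates noiseless
  recovery.
* Short-separation regression, PCA/tCCA artifact removal and GLM-based
  inference are out of scope by design.
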