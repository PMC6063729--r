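---
title: "Methods: membrane-potential analysis of LSO principal and non-principal neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane-potential analysis of LSO principal and non-principal neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

The lateral superior olive (LSO) encodes interaural level differences
(ILD): ipsilateral sound excites its neurons via EPSPs from the cochlear
nucleus, contralateral sound inhibits them via glycinergic IPSPs relayed by
the MNTB, and the firing rate falls as the contralateral level rises. This
package implements the physiology feature set that separates *principal*
LSO neurons (fast sub-millisecond PSPs, small non-overshooting action
potentials, onset-only firing) from *non-principal* neurons (slow summing
PSPs, large overshooting spikes, sustained "chopper" firing), together with
a synthetic-recording generator so the entire pipeline is testable without
experimental data.

Throughout, time 0 is stimulus (or current-step) onset and every analysis
window is half-open `[a, b)` in milliseconds. The ILD sign convention is
`ILD = contralateral SPL − ipsilateral SPL`, so negative ILDs mean the
excitatory ear is louder. Membrane potentials are liquid-junction-corrected
by subtracting 10 mV at ingest, recorded by a flag and never inferred.

## The spectral cutoff statistic

The headline membrane statistic is the **upper cutoff frequency** of
spontaneous activity: the frequency at which the normalized amplitude
spectrum of the denoised spontaneous membrane potential falls to 50%
(−6 dB) of its maximum. Fast membranes pass fast synaptic events, so
principal cells show cutoffs of several hundred Hz while non-principal
cells fall around a hundred Hz.

The pipeline (`preprocess_spontaneous()` then `amplitude_spectrum()` then
`upper_cutoff()`):

1. subtract the median Vm of the first 10 ms;
2. high-pass filter at 10 Hz. The filter is a linear-phase windowed
   (Hamming) FIR whose order is chosen for a transition band of at most
   5 Hz; at 50 kHz that is ~33,000 taps, so it is applied by FFT
   convolution, forward and time-reversed, for zero net phase with
   reflection-padded edges;
3. wavelet-denoise with a symlet-8 transform at level 5, soft-thresholding
   each detail level with a heuristic-SURE threshold on the raw coefficient
   scale (no noise rescaling). No wavelet transform was available in the
   dependency set, so the periodized orthogonal DWT/IDWT and the threshold
   rules are implemented in `R/wavelet.R`; orthonormality makes the
   transform exactly invertible, which the tests assert. Because the
   thresholds are absolute (no rescaling), the *denoising* step is not
   scale invariant; the spectrum normalization is, and the scale-invariance
   property is therefore stated at the spectrum level;
4. compute one single-sided DFT magnitude over the whole sample (2–6 s;
   2.5 s is the package default — a deliberate compromise between spectral
   stability and simulation cost), smooth it with a running median over a
   1/24-octave log-spaced grid, and normalize to the maximum. A raw
   multi-second DFT is far too noisy for a stable half-maximum crossing:
   single bins are Rayleigh distributed, and at low frequencies a
   1/24-octave window spans only a couple of bins. Each window therefore
   contains at least 41 raw bins, and the gridded curve is settled with a
   5-point running median. The smoothing method is recorded in the
   `lso_spectrum` object; `smooth = "none"` gives the raw normalized DFT;
5. search upward from the global maximum above 10 Hz (ties broken toward
   the lowest frequency) for the first downward crossing of 0.5, linearly
   interpolated between bins.

## Action-potential amplitude and evoked profiles

`detect_spikes()` finds local maxima preceded by a depolarization slope
above 10 mV/ms (measured over 0.3 ms on a 0.2 ms-smoothed trace) with
≥1 ms separation. A peak-prominence criterion (8 mV above the local 2 ms
median) is part of the detector: sub-millisecond EPSPs reach slopes of
tens of mV/ms, so a slope rule alone cannot distinguish a fast EPSP from a
small principal-cell action potential, while an absolute voltage threshold
would miss those same small spikes. All three values are configurable.

`ap_amplitude()` is the mean over all detected spikes (pooled across all
presented ipsilateral levels) of the Vm at the spike peak minus the median
Vm of the first 2 ms of the same sweep.

`peak_to_sustained()` works on the pointwise median across spike-free
repetitions (repetitions with any detected spike in the onset `[5, 15)` or
sustained window are excluded; at least 3 must survive). The peak is the
maximum absolute deviation from the pre-stimulus baseline in the onset
window; the sustained level is the mean absolute deviation in `[40, 50)`
for stimuli of ≥50 ms, else `[20, 25)`. A sustained level below 0.1 mV is
treated as below the noise floor and refused rather than returned as an
unstable ratio.

`input_resistance()` uses hyperpolarizing steps only: steady state from
the median Vm over the last 10% of the step, peak from the minimum Vm
during the step, baseline from the 10 ms before onset.

## Spike-train statistics

`regularity_curve()` implements per-time-bin interval statistics: each
interspike interval is assigned to the 1 ms bin containing its *first*
spike (no fractional spreading — the simplest assignment consistent with
the published inclusion criterion; it is isolated in one function so it can
be swapped), and a bin is included only when at least 20% of repetitions
contribute an interval to it. Onset-only cells therefore produce no
includable bins — the dissociation the analysis relies on — while chopper
cells yield sustained-bin CVs near their renewal CV. The gamma-renewal
generator provides the analytic oracle: the measured sustained-bin CV runs
a few percent below the ISI CV because binning conditions on interval
starts, which the 15% test tolerance absorbs.

`window_rate()` (mean count per repetition over window duration),
`onset_fraction()` (share of stimulus-window spikes in `[0, 10)`) and
`bf_from_counts()` (argmax with low-frequency tie break) are deliberately
plain; their tests compare against brute-force counting.

## ILD functions

`build_ild_curve()` computes windowed rates per ILD — onset `[0, 10)`,
sustained `[10, 25)` (the shortest stimulus in the design is 25 ms) — and
requires a fixed ipsilateral level. `fit_ild_sigmoid()` fits a descending
four-parameter logistic by Levenberg–Marquardt least squares with
deterministic initialization from data quantiles; absolute rates are
fitted, normalized rates are for display. The "slope range" is reported as
the 20–80% span of the fitted curve (configurable to 10–90%), i.e.
`midpoint ± width·ln 4`. Shifting all contralateral level labels by +Δ dB
shifts the fitted midpoint by exactly +Δ: the initialization and box
constraints are shift-covariant, so the whole optimization path translates.

## The synthetic generator

Every generator is a pure function of `(params, seed)`; the caller's RNG
state is saved and restored. Design choices, in order of consequence:

* **PSP shape** — difference of exponentials with the rise constant fixed
  at 1/5 of the decay constant, solved so the FWHM equals the requested
  half-width exactly. The source measurements constrain only half-widths;
  a difference of exponentials keeps rise and decay independently
  controllable where an alpha function would not.
* **Class distributions** — principal EPSP half-widths uniform on
  0.4–0.9 ms and AP amplitudes Normal(28, 8) mV truncated above 10;
  non-principal half-widths 2–6 ms and amplitudes Normal(66, 10) mV.
  Spontaneous PSP rates and amplitudes are not quantified in the source
  material; the defaults (EPSPs ~150–200/s of ~3 mV on 0.3 mV recording
  noise) are chosen for qualitative fidelity to published spontaneous
  traces and flagged as free parameters.
* **Firing** — onset cells fire one spike ~1 ms after the excitatory
  response latency with 0.3 ms jitter; chopper cells fire a gamma-renewal
  train (ISI mean and CV configurable). A renewal process rather than a
  biophysical integrator keeps an analytic CV oracle available to the
  tests, which is all the downstream analysis consumes.
* **ILD dependence** — binaural spiking is thinned by an explicit logistic
  `p(ILD)` whose midpoint and width are stored as ground truth; the
  recovery tests compare fitted midpoints against it. The contralateral
  IPSP latency still trades with level (default −0.12 ms/dB around 6 ms at
  50 dB), and in suppressed repetitions the excitatory drive is scaled
  down, mimicking shunting inhibition — without this, the full-amplitude
  EPSP volley in a no-spike repetition can masquerade as a small spike.
* **Spike waveform** — a stereotyped 1 ms template scaled so the peak sits
  `ap_amp` above the resting baseline; the source does not specify a
  waveform.
* **Current steps** — linear single-compartment charging `I·R·(1−e^{−t/τ})`
  plus, for hyperpolarizing steps, a delayed slow relaxation (onset 5τ,
  time constant 20τ) of the peak toward steady state by `sag_fraction`, so
  the peak/steady deflection ratio is `1/(1−sag)` to within ~1%. An
  undelayed two-exponential sag misses that closed form by ~5%, which is
  why the delay exists.
* **Sampling** — 50 kHz by default (the low end of the published
  digitization range) to keep simulated cohorts affordable. Acoustic
  cross-talk is out of scope; the generator caps effective drive above
  90 dB SPL but models no interaural leak.

What the generator does *not* emulate: conductance dynamics (Kv1/I_h are
phenomenological), bridge-balance artifacts, non-monotonic rate-level
functions from acoustic cross-talk, and recording drift. Passing tests
demonstrate that the estimators recover known structure of this synthetic
kind, not that real recordings satisfy the generator's assumptions.

## Classification and statistics

`cluster_cells()` works in z-scored `(log10 cutoff, AP amplitude)` space.
With anatomical anchors it assigns unlabeled cells to anchor-defined
centroids — the procedure used when only part of a cohort is histologically
confirmed; without anchors it runs 2-means from a deterministic
farthest-pair initialization and names the higher-cutoff cluster
"principal". The confidence is a silhouette-style contrast of the distances
to the two centroids. Fewer than four complete cells is reported as
"unassignable" rather than guessed.

`pooled_t_from_summaries()` and `hedges_g()` operate on printed group
summaries (`sd = sem·√n`). Hedges' g is reported **without** the
small-sample J correction by default: only the uncorrected convention
reproduces the published effect sizes from the published means, SEMs and
group sizes; the corrected variant sits behind a flag, as does Welch's t.
Exact permutation enumeration is used for the Spearman tonotopy p-value up
to n = 10, a t approximation above.

## Problem sizes and budgets

Defaults used by the tests and the acceptance script: 2.5 s spontaneous
samples, 30 tone repetitions, 11 contralateral levels (5 dB steps,
matching the 5–10 dB stepping of the recording protocol), cohorts of
12 + 12 cells, 10 cohort replicates for the recovery experiment. These
sizes give stable group statistics while keeping a full run in minutes.

## Known limitations

* The spectral cutoff depends on the smoothing bandwidth at the low end of
  multi-second DFTs; the choices above are recorded in the output object,
  and alternatives can be compared via `amplitude_spectrum()` options.
* The interval-to-bin assignment of the regularity analysis is one of
  several defensible readings of per-bin interval statistics; it is
  deliberately isolated.
* The detector's prominence criterion means spikes smaller than ~8 mV
  riding large fast EPSPs are undetectable in principle; with the
  amplitude distributions above this is not limiting.
* Group-mean cutoff values of a synthetic cohort depend on the chosen
  half-width and rate distributions; the analysis claims only the
  qualitative contrast (a ≥3-fold group separation), not the exact
  published group means.
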