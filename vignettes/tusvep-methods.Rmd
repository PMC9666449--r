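---
title: "Methods: quantifying ultrasound neuromodulation of visual evoked potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying ultrasound neuromodulation of visual evoked potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, parameters and numerical choices behind
`tusvep`. The package implements a complete analysis chain for experiments
in which pulsed transcranial focused ultrasound (TUS) is directed at the
lateral geniculate nucleus (LGN) while flash visual evoked potentials
(VEPs) are recorded with a small subdermal electrode montage, together with
MR acoustic radiation force imaging (MR-ARFI) of the focal displacement and
the dose arithmetic of the sonication protocol.

## The experimental schedule the simulator emulates

A session consists of a 5-minute light-only Baseline block followed by
20-minute sonication blocks (two at the LGN, then control blocks at a
non-visual site). Each sonication block is divided into 20 one-minute
sections, and each section into four 15-second conditions: no stimulus,
light-only, TUS-only, and light+TUS. Every condition runs its stimulus at
1 Hz, so a full block contributes 300 light-only trials; equalization
truncates each cell to the first 250 accepted trials. `make_event_table()`
reproduces this schedule exactly; `n_sections` scales block length for
cheaper runs without altering its structure.

## Synthetic EEG: what is modelled, and what is not

`simulate_eeg()` is the package's test bed. It generates, per channel:

* **Evoked response** — two Gaussian-windowed lobes, a negative trough
  ("N70", default −6 µV at 80 ms, SD 10 ms) and a positive peak ("P100",
  default +9 µV at 110 ms), placed on occipital channels at every light
  event. Real large-animal flash VEP morphology is richer; only these two
  quantified features are modelled, and the default latencies sit at the
  centres of the downstream detection windows because anesthesia delays
  the peaks. Amplitudes are placeholders of realistic order (peak-to-peak
  15 µV), not calibrated to any recorded waveform.
* **Suppression** — a per-block multiplicative factor in [0, 1] on the
  evoked amplitude, the ground truth that the VEP stage must recover.
  Side-specific suppression is expressed through per-channel occipital
  gains, which the laterality index recovers.
* **Background** — 1/f (pink) noise, default 5 µV RMS per channel,
  generated by spectral shaping of white noise. Real EEG adds line noise,
  non-stationarities and spatially correlated sources; none are modelled,
  so passing tests demonstrate correctness of the estimators, not
  robustness to every artifact class.
* **Gamma bursts** — Gaussian-envelope bursts (default 40 Hz carrier,
  envelope SD 25 ms) centred at 90 and 280 ms after each light event. With
  the default random-per-trial phase they cancel from the trial average
  while remaining in single trials: the structural premise of the
  non-phase-locked (NPL) analysis. A locked-phase mode moves the same
  power into the phase-locked (PL) part, giving the dissociation its
  control condition.
* **TUS artifact** — broadband noise gated by the 300 ms pulse-train
  envelope on TUS events, attenuated as `exp(-k * distance)` with the
  transducer distance; the exponential law is a modelling choice (the
  phantom observation is only that the artifact shrinks with distance).
* **Blinks** — rare large slow deflections on frontal channels, exercising
  amplitude rejection.

All randomness flows from one seed through a private RNG stream
(`with_rng_seed()`), so identical configurations are bit-identical and the
caller's RNG state is never touched.

## Preprocessing

The pipeline order is fixed: band-pass filter, epoch, amplitude rejection,
trial equalization, and (for TUS-containing conditions only) component
cleaning.

* **Filter**: 2–50 Hz, 4th-order Butterworth applied forward–backward
  (zero phase), because peak latencies are the measurand and a causal
  filter would bias them.
* **Epochs**: 1 s windows from −200 to +800 ms, implemented closed-open
  `[-200, 800)` with 0-based sample indexing so an epoch is exactly 1000
  samples at 1000 Hz and the sample at t = 0 is the onset sample. Events
  without enough record on either side are skipped with a warning, not
  fatal.
* **Amplitude rejection** flags trials exceeding ±100 µV (configurable) on
  any channel; it never mutates voltages, only the mask.
* **Equalization** keeps the chronologically first 250 accepted trials per
  block × condition cell — a deterministic stand-in for an unstated
  selection rule; a seeded random subsample is available via
  `method = "sample"`.
* **Component cleaning**: symmetric FastICA (tanh contrast) on the
  concatenated TUS-condition epochs, with deterministic seeded
  initialization. The supervised rejection procedure is replaced by three
  numeric scores per component: (a) the fraction of 2–50 Hz power in the
  20–40 Hz muscle band (flag above 0.5); (b) a spatial-concentration index
  `max|w| / sum|w|` over mixing weights (flag above 0.8), standing in for
  topographic inspection; (c) the coefficient of variation of per-trial
  band power (flag above 1.0), capturing intermittent artifacts. A
  component whose trial-averaged time course correlates with the
  grand-average evoked response (|r| > 0.6) is never removed — the
  protection rule that keeps genuine evoked activity out of the discard
  pile. All four thresholds are exposed as arguments. Light-only
  conditions are analysed without cleaning, mirroring the original
  artifact-avoidance logic.

## VEP quantification

For each electrode the N70 amplitude is the minimum voltage in the
60–100 ms window and the P100 amplitude the maximum in 90–130 ms (40 ms
windows tolerate anesthesia-induced latency shifts); peak-to-peak is their
difference, ties resolve to the earliest latency, and reported latencies
are asserted to lie inside their windows on every call. Electrode averaging
happens after per-electrode quantification, and normalization divides the
electrode-mean peak-to-peak by the same animal's Baseline block
(average-then-normalize; the per-electrode alternative sits behind
`per_electrode = TRUE`, since the original wording is ambiguous). The
15-point moving average applied to published traces is display-only and
kept out of quantification. The laterality index is the percent reduction
of the ipsilateral occipital mean relative to the contralateral mean.

## Spectral decomposition

Morlet wavelets at 50 linearly spaced centre frequencies from 2 to 55 Hz,
with cycle counts rising linearly from 3 to 10 (log spacing available;
linear is the default since the source material states only the ranges).
Each kernel spans ±3.5 temporal SDs and is discretely normalized to unit
energy. Convolution runs in the frequency domain after reflecting one
maximal wavelet half-support at each epoch edge, so edge ringing does not
leak into the baseline window.

Total power is the trial-average of per-trial squared magnitudes. NPL
power subtracts the trial-averaged evoked response from every trial before
decomposition; PL power is the elementwise difference `total − NPL`, which
makes conservation exact by construction. PL can dip a few ulps negative
through floating-point subtraction; `db_baseline()` clips at zero and
records the clip count. Decibel maps are `10·log10` relative to the
per-frequency mean over −150 to 0 ms, implemented closed-open so the
onset sample never contaminates the pre-stimulus baseline.

## Permutation statistics

Difference maps are dB spectrogram (condition A) minus dB spectrogram
(condition B), each baselined to its own pre-stimulus window. The null
shuffles trial-condition labels (trial-level exchangeability is an
assumption; the permutation unit is not stated in the source), recomputing
the map per permutation; the two-sided pixel p-value uses the add-one
convention `(1 + #{|null| >= |obs|}) / (n_perm + 1)` with 1000 permutations
by default, and no multiple-comparison correction is applied, deliberately.
The permutation stream is attached to a canonical ordering of the pooled
trials so that exchanging the two conditions negates the difference map
and leaves the p-map bit-identical.

Because wavelet smoothing correlates neighbouring pixels, the *average*
rejection rate of a single null map is itself noisy (SD ≈ 0.02 around
0.05 in our measurements) even though every pixelwise p-value is valid by
construction. Calibration checks therefore pool the rejection rate over
five independent null simulations of 200 trials per condition; the pooled
rate sits in [0.03, 0.07].

## MR-ARFI displacement

Displacement encoding follows `D = ΔΦ / (2 γ G τ)` with the proton
gyromagnetic ratio (γ/2π = 42.58 MHz/T) and gradient magnitude 0.04 T/m.
The gradient-lobe duration τ has no defensible default — metres are
meaningless without it — so `encoding_params()` refuses to run when it is
missing; examples use 3 ms. Phase differences are computed through complex
exponentials (`Arg(exp(iΔΦ))`), making results invariant under 2π shifts
of either input. The forward simulator encodes a field into an
opposite-polarity pair plus Gaussian phase noise; the zero-noise round
trip recovers the field to below 1 nm.

The focal maximum is reported with a detectability flag that
operationalizes the exclusion of acquisitions whose focus cannot be
distinguished from noise. Since the statistic is a maximum over `n` ROI
voxels, comparing it against k × (background SD) misfires for any ROI
beyond ~100 voxels: the expected extreme of n Gaussian draws already
exceeds 3 SD, so a pure-noise ROI would almost always be called
detectable. The implemented criterion Bonferroni-corrects the per-voxel
k-sigma rule for the ROI size — with per-voxel tail mass
`a = 2Φ(−k)`, the focus is detectable when
`max > sd · Φ⁻¹(1 − a/(2n))` (≈ 4.5–4.9 SD for typical ROI sizes at
k = 3), which keeps the false-alarm probability of a noise-only ROI
near `a` regardless of its size.

## Dose arithmetic and bioheat

The protocol constructor encodes the pulsing scheme (550 kHz; 1 ms pulses
at 2 ms intervals; 300 ms trains every second), from which the duty cycles
(0.5 within-train, 0.3 train, 0.15 total) and
`I_SPTA = I_SPPA × total duty` follow; with the published pulse-average
intensities of 19.3–63.8 W/cm² these give 2.895–9.57 W/cm² temporal
averages. The plane-wave relation `I = p²/(2ρc)` is provided as a nominal
pressure–intensity mapping only: published pressure and intensity ranges
come from hydrophone calibration and are treated as independent inputs,
because no standard-constant plane-wave mapping reconciles them.

Tissue heating uses the Pennes bioheat equation,
`ρC ∂T/∂t = k∇²T − w_b ρ_b C_b (T − T_a) + Q`, integrated by explicit
finite differences on a regular 3-D grid with insulated (reflected-ghost)
boundaries. The time step defaults to 90% of the stability bound
`1 / (6κ/dx² + w_b ρ_b C_b/(ρC))` and over-large steps are refused with
the bound in the message. Default constants are generic soft-brain values
(k = 0.51 W m⁻¹K⁻¹, ρ = 1046 kg/m³, C = 3630 J kg⁻¹K⁻¹, perfusion
0.0098 s⁻¹, blood 1050 kg/m³ and 3617 J kg⁻¹K⁻¹) and are meant to be
overridden. The solver is free-field: transcranial attenuation and
CT-derived acoustic fields are out of scope, so it is validated against
closed forms — the perfusion-limited steady state `ΔT = Q/(w_b ρ_b C_b)`,
exact conservation of total temperature in insulated source-free runs, the
heat-kernel widening of a Gaussian initial condition, linearity in the
source, and the maximum principle — rather than against any in vivo
temperature estimate. The heat source from an intensity field is
`Q = 2αI`, duty-averaged over the protocol by default.

## Study replica and problem sizes

`run_study()` chains everything per experiment and across a roster of
experiments (default: six sonication experiments with suppression factors
0.35–0.65 and displacement peaks coupled linearly to suppression depth;
five active-sham experiments with factor 1 and a near-zero off-target
focus — the sham arm is intentional here, where in practice it arose from
transducer dislocation). Outputs are tidy CSVs, RDS spectrogram sets, and
a JSON manifest with per-file MD5 checksums that is reproducible at a
fixed seed.

Problem sizes in the shipped drivers and tests are chosen to keep full
runs in minutes: drivers use 2–6 sections per block and 30–60 trials per
cell, while the acceptance checks run the full 250-trial recovery at three
suppression levels and the full-size permutation calibration. Changing
these sizes only trades precision against time; the structure of every
computation is identical at full scale.

## Known limitations

* The generator's evoked template, noise level and burst amplitudes are
  order-of-magnitude realistic but uncalibrated; recovered quantities are
  validated against the generator's ground truth, not against recordings.
* Trial-level permutation exchangeability is assumed; animal-level
  resampling is not implemented.
* No EDF reader is bundled: EEG interchange uses the delimited text matrix
  dialect with a JSON metadata sidecar.
* Wavelet temporal support (±150 ms at 30 Hz) smears any activity
  adjacent to t = 0 into the −150–0 ms baseline window. For an artifact
  or response beginning exactly at onset this biases the whole dB map of
  that condition — visible in the phantom analysis, where the raw-power
  maps show clean containment of the artifact to the 300 ms envelope
  while the dB difference map carries a broadband offset. Conclusions
  about artifact timing should therefore be drawn from raw power.
* The bioheat solver ignores skull heating and acoustic propagation
  entirely; its outputs are free-field estimates for protocol reasoning,
  not safety predictions.
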