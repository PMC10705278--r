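---
title: "Methods: invertible phasor coding, signal processing and decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: invertible phasor coding, signal processing and decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfnavector)
```

## The model

Columnar populations of the fly central complex represent 2-D vectors as
sinusoidal activity profiles across anatomical sectors (*phasors*): the
profile's amplitude encodes vector length and its spatial phase encodes
vector angle. PFNa neurons carry one such phasor per bridge half, phase-locked
to the EPG heading bump, and each phasor can *invert* — shift by 180° —
because single PFNa cells express two spike modes: depolarization-driven
sodium spikes and hyperpolarization-elicited, T-type-channel-mediated 2–6 Hz
calcium spikes.

All angles in the package are degrees in (−180, 180], with 0° directly in
front of the fly, 180° behind, negative to the fly's left. With `H` the
heading relative to a cell's preferred direction and `W` the egocentric
airflow direction (nonzero only during puffs), the three response models are

* `Vm = a0 + aH·cos(H) + aW·cos(W + s·45°)`, with `s = +1` for left-bridge
  and `s = −1` for right-bridge cells;
* sodium-spike rate `r = [bH·cos(H) + bW·cos(W + s·45°)]₊²`;
* 2–6 Hz band power `p = c0 + [cH·cos(H) + cW·cos(W + s·45°)]₋²`.

If the combined synaptic output of a cell is an *unrectified* quadratic
function of its Vm drive — sodium spikes covering the depolarized branch and
calcium spikes the hyperpolarized branch — then the output of a matched
left/right pair after the ±45° bridge→fan-shaped-body anatomical shifts is

`(bH·cos(H−45°) + bW·cos(W+45°))² + (bH·cos(H+45°) + bW·cos(W−45°))²
 = bH² + bW² + 2·bH·bW·cos(W + H)`,

a function of the *allocentric* airflow angle `W + H` alone. The left/right
pairing of heading and airflow shifts is the one for which this identity
holds exactly; it also reproduces the observed laterality (a puff from the
right inverts the left-bridge phasor and vice versa). `pair_output()` and
`closed_form_output()` expose both sides of the identity, and the test suite
verifies their agreement to below 1e−9 over 10⁴ random draws.

## The synthetic experiment

`simulate_experiment()` generates everything downstream stages consume. The
protocol presents 12 airflow directions at 30° increments, 4 s pulses with
5 s intervals, pseudorandomized within each block — the stimulus schedule of
the experiments this package models. Behavior is a wrapped random walk
(white turn-rate noise, default SD 400 deg/s at 80 Hz, chosen so a
10-minute walk occupies every 10° heading bin for ≥ 2 s in ≥ 95% of seeds)
with a two-state moving/standing forward-speed process (~90% moving).

Vm traces are generated at the native 10 kHz: the sum-of-sinusoids mean,
plus (i) 2 ms biphasic ~3 mV sodium-spike waveforms at Poisson times with
the rectified-quadratic rate — only detectability at the soma matters, not
the exact shape; (ii) an amplitude-modulated sinusoid at `osc_freq`
(default 4 Hz, the center of the reported 2–6 Hz range) gated on when the
subthreshold mean drops below the calcium-spike threshold, with variance
equal to the model band power; and (iii) AR(1) colored noise (~20 ms
correlation, default SD 1.5 mV). A single fixed oscillation frequency with
smooth on/off envelopes stands in for what is, in real cells, a frequency
*band*; passing tests therefore show estimator correctness on narrowband
oscillations, not robustness to broadband or drifting rhythms.

Imaging uses the dual-threshold forward model: per bridge glomerulus,
calcium drive `k_na·[Vm − θ_na]₊² + k_ca·[θ_ca − Vm]₊²`, convolved with a
unit-area exponential indicator kernel (`ca_tau` = 1 s) and sampled at the
frame rate with Gaussian noise. The two thresholds are **package defaults**
(−57 and −70 mV), chosen to straddle the resting heading sinusoid
(a0 ± aH = −64 ± 7 mV); no published values exist for them. The gain ratio
`k_na/k_ca = 0.2` makes the decoder's default conversion factor the matched
one. Generator defaults for the response parameters are a0 = −64 mV (the
reported mean baseline), aH = 7 mV (half the reported ~13.7 mV
peak-to-minimum heading modulation), aW = 5 mV, bH = 4, bW = 3
(peak ≈ 49 spikes/s), c0 = 0.5, cH = 2, cW = 1.5 mV². All generators are
pure functions of (parameters, seed).

What the generator deliberately does *not* emulate: multi-frequency or
bursty calcium spikes, sodium spikes riding on calcium spikes, indicator
saturation and bleaching, motion artifacts, and the empirically observed
deficit of sodium spikes for puffs from directly behind (a documented
model–data mismatch in the source experiments; an analysis pipeline must
not special-case it, so the generator omits it by default).

## Signal processing

The processing constants are the protocol values throughout and are
overridable via `default_run_config()` / YAML: 1 kHz downsampling with a
40 ms median filter for subthreshold Vm; 150–1000 Hz band-pass for spike
detection with a 6.66 ms minimum inter-event interval; a unit-area 1 s Hann
kernel for spike rate; 100 Hz downsampling with 4 s Hann windows stepped
20 ms for the 2–6 Hz band power; 600 ms linear-interpolation segments
(starting 550 ms before onset and 50 ms before offset) with 2 s / 10 ms
windows for current-pulse power.

Numerical choices worth knowing:

* The spike-band filter is the squared magnitude response of an order-4
  analog Bessel low-pass prototype transformed to an 8-pole band-pass,
  applied in the frequency domain. This is exactly the zero-phase
  (forward–backward) application of the filter, avoids the numerical
  fragility of an order-8 time-domain transfer function at 10 kHz, and
  keeps detected spike times lag-free. The detection threshold is
  `k·(1.4826·MAD)` of the band-passed trace, `k = 4` by default; detection
  quality claims are property-based (inserted templates, generator
  round-trips), not value-matched.
* Spectral windows are Hann-tapered, mean-removed, one-sided
  power-spectral densities; band power is the mean over bins in [2, 6] Hz,
  timestamped at window centers. The estimator agrees with an independent
  flat-segment periodogram oracle to 1% on pure tones and leaks < 1% from
  20 Hz tones.
* Tuning bins are half-open `[center − w/2, center + w/2)` with centers at
  multiples of the bin width, so 0° and 180° are bin centers. Samples with
  forward speed ≤ 0.5 mm/s are excluded; 10° heading bins require 2 s of
  occupancy, the 18 × 12 conjunctive grid 0.5 s per cell. Conjunctive maps
  use within-puff samples only on the airflow axis, with per-sample
  concurrent heading.
* Phase extraction: the EPG bridge phase is the phase of the period-8
  discrete Fourier component over the 16 EPG-innervated glomeruli; ring
  phases are population-vector averages with a 0.15 strength floor. Phase
  nulling interpolates each 8-glomerulus bridge half to 1/10-glomerulus
  resolution with a *periodic* cubic spline (each half is one 360° cycle;
  rotation requires periodic boundary conditions) and rotates by the
  EPG-determined shift, identically for both halves. Degenerate inputs are
  flagged, never silently defaulted: balanced circular means, all-zero
  frames and sub-floor PVA strengths return explicit undefined/invalid
  flags.
* The "peak" of a phase-nulled profile is its PVA phase by default, with
  argmax available (`profile_peak(method = "argmax")`); the two agree on
  clean single-bump profiles.

## Model fitting

`fit_vm()` is linear least squares (the model is linear in a0, aH, aW) and
matches the closed-form normal-equation solution to machine precision.
`fit_rate()`/`fit_osc()` are multi-start Levenberg–Marquardt fits of the
rectified-quadratic surfaces, with starts covering the four (±, ±) sign
quadrants at a data-derived scale; the positively rectified surface is
invariant under a joint sign flip of (bH, bW), resolved by reporting
bH ≥ 0. Unpopulated grid cells are excluded from every objective, never
imputed. Fits report `r2 = 1 − SSE/SST` over populated cells (NA for
zero-variance data) through `glance()`.

`fit_quadratic_io()` reproduces the combined input–output analysis: rate
and band-power curves are min-max normalized to [0, 1], summed, and fit
with a degree-2 polynomial of the baseline-referenced Vm (Vm minus the
heading-curve minimum).

## Decoding

`decode_allocentric()` decomposes each side's phase-nulled profile by
signed cosine projection at relative angle 0°: a positive amplitude is an
EPG-aligned sodium-spike phasor (phase 0°), a negative one a phase-inverted
calcium-spike phasor (phase 180°) whose magnitude is multiplied by
κ = 0.2 — applied per component, converting calcium-spike signal into
sodium-spike-equivalent units. Side phasors are rotated by their anatomical
shifts (left −45°, right +45°) and summed as sinusoids; the decoded
egocentric direction is the phase of the sum and the allocentric one adds
the heading. With the matched κ the median circular decode error over the
12 protocol directions is ~11° on default synthetic experiments; with
κ = 0 rear and side decodes collapse into the frontal ±45–55° sector, the
read-out expected when only sodium-spike phasors drive the downstream
population.

## Problem sizes and reproducibility

Test and acceptance runs use 1–3 protocol blocks (~2–6 min of simulated
behavior), one or two full-rate Vm traces, and 100 map-level Monte-Carlo
replicates for parameter recovery — sizes chosen so the whole suite runs
in about a minute while every statistical criterion retains a comfortable
margin. The Monte-Carlo noise models mirror the default pipeline: 1 mV
Gaussian noise on Vm maps, Poisson-derived rates at 1 s occupancy per grid
cell, and chi-squared band-power estimates with the degrees of freedom the
spectral estimator actually delivers (≈ 11 independent frequency bins per
4 s window × ≥ 3 independent trials per cell). `run_pipeline()` derives all
stage seeds from the single config seed; rerunning a config byte-identically
reproduces every CSV/JSON artifact, and the config hash excludes output
paths.

## Known limitations

* The decoder's accuracy floor (~10° median error) reflects the 45°
  glomerular quantization, spline interpolation and frame binning, not
  estimator bias; it is far below the 30° protocol spacing but not zero.
* Phase-nulled profiles are only as good as the EPG phase; the package
  propagates undefined-phase frames by exclusion rather than imputation,
  so very dim heading signals shrink the usable data.
* The oscillation detector measures band power, not oscillation count or
  phase; converting between the two requires assumptions the package does
  not make.
* Native I/O is a CSV/JSON directory container (`write_dataset()` /
  `read_dataset()`); large raw traces round-trip exactly but compactness
  was not a goal.
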