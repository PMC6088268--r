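---
title: "Methods: endoscopic laser speckle contrast analysis with especkle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: endoscopic laser speckle contrast analysis with especkle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(especkle)
```

## The measurement problem

When coherent laser light illuminates tissue through an imaging
fiber bundle, backscattered light forms a speckle pattern. Moving red blood
cells decorrelate that pattern within the camera exposure, blurring it, so
the *speckle contrast*

$$K = \frac{\sigma}{\langle I \rangle}$$

computed over a small spatial window drops wherever flow is fast: static,
fully developed speckle has $K \approx 1$; strong blurring drives $K$ toward
0. From the region-averaged contrast over time one can read out cardiac and
respiratory rates (periodic flow and motion modulate $K$), detect a vessel
occlusion (flow stops, contrast steps up), and — with two illumination
wavelengths straddling the hemoglobin near-infrared absorption crossover —
map relative tissue oxygenation. `especkle` implements this whole chain for
endoscopic, fiber-bundle acquisitions, together with a seeded synthetic
acquisition simulator so that every stage can be validated against known
ground truth without animal recordings.

## Contrast model and its assumptions

The package relates contrast to exposure time $T$ and speckle correlation
time $\tau_c$ by the Lorentzian-velocity model

$$K^2(T, \tau_c) = \frac{\tau_c}{2T}\left(1 - e^{-2T/\tau_c}\right),$$

exposed as the pure function `contrast_model()` so an alternative kinetic
model can be swapped in. Assumptions: fully developed speckle (unit
intensity contrast at zero flow), a negative-exponential field correlation
in time (single dominant velocity scale), and no static scattering layer.
$\tau_c$ is inversely proportional to scatterer speed, so "low contrast =
fast flow" is the reading rule for all maps.

The spatial estimator (`contrast_map()`) uses the sample (n−1) standard
deviation over an odd window (default 7×7, configurable 5/7/9 — the usual
trade-off between spatial resolution and estimator variance), reflective
borders so maps align with frames pixel-for-pixel, and flags all-dark
windows as `NaN` rather than erroring. Whether published endoscopic maps
used spatial or temporal contrast is not documented; spatial contrast is
implemented, and a temporal estimator is deliberately out of scope.

## The synthetic acquisition simulator

`simulate_stack()` emulates the two intra-operative recording regimes the
package is designed around (a small-animal high-heart-rate regime at up to
~22 fps and a large-animal dual-wavelength regime at ~1.6–10 fps per
wavelength):

* **Speckle synthesis.** Each frame integrates 10 sub-exposure snapshots of
  a low-pass-filtered complex Gaussian field (speckle grain ≈ 2 px, field
  bandwidth 0.25 cycles/px). Between snapshots the field evolves as an
  AR(1) process with correlation $e^{-\Delta t/\tau_c}$, which reproduces
  the $K(T, \tau_c)$ law up to the known discretization and windowed-
  estimator biases, and gives per-pixel negative-exponential intensities.
* **Physiology.** $1/\tau_c$ is modulated sinusoidally at the cardiac and
  respiratory frequencies (defaults: depths 0.4 and 0.3 — strong pulsatile
  perfusion as seen intra-operatively; baseline $\tau_c$ = 2 ms,
  commensurate with the 0.5–20 ms exposure presets so all presets sit on
  the sensitive part of the $K$ curve). An occlusion window multiplies
  $\tau_c$ by 6 (flow nearly stops; contrast roughly doubles at 20 ms
  exposure, matching the reported step-up).
* **Chromophores.** Mean detected intensity per wavelength follows a
  Beer–Lambert forward model from a $(\Delta C_{HbO_2}, \Delta C_{Hb})$
  trajectory: arterial occlusion ramps $(-0.3, +0.1)$ relative mM
  (oxygen depletion), arteriovenous occlusion $(+0.3, +0.1)$ (venous
  pooling raises oxy- and total hemoglobin — the behavior reported when
  artery and adjacent vein are clamped together). Logistic onset (~0.5 s),
  exponential recovery (5 s) after release.
* **Detector.** Poisson shot noise plus Gaussian read noise (sd 2 DN),
  quantized to 12 bits. Baseline mean intensity defaults to 500 DN: with
  exponential speckle statistics this leaves 8× headroom below the 4095 DN
  ceiling, so tail clipping (which would bias $K$ low) is negligible while
  shot noise remains irrelevant ($1/\sqrt{500} \ll$ speckle contrast).
* **Timing.** Timestamps are nominal frame times plus Gaussian jitter
  (default sd 5% of the frame period, reflecting measured-vs-set frame-rate
  discrepancy), clipped at 45% of a period so they stay strictly
  increasing. Interleaved dual-wavelength acquisition offsets the 830 nm
  stream by half a period.

What the simulator does **not** emulate: tissue heterogeneity (vessel
trees), sample motion other than the modeled periodic modulation, static
scattering layers, polarization, fiber-bundle leaching physics, or
wavelength-dependent speckle grain. Passing recovery tests therefore shows
the *processing chain* is correct and unbiased under the stated statistical
model — not that it is robust to every artifact of real surgical video.
Physical pixel pitch is not modeled; all spatial quantities are in pixels.

## Fiber-bundle artifact removal

The bundle's discrete cores imprint a static hexagonal ("honeycomb")
transmission pattern. `overlay_fiber_pattern()` synthesizes it as three
cosine gratings at 0°/60°/120° with frequency `1/core_spacing`;
`estimate_core_spacing()` finds the dominant non-DC radial frequency of the
time-averaged frame (averaging suppresses speckle ~$1/\sqrt{N}$ but not the
static pattern) and demands the peak annulus stand 6 dB above the median
annulus power, otherwise it reports "no pattern" and filtering is skipped.
`remove_fiber_pattern()` applies a radially symmetric 2-D Butterworth
low-pass $H(f) = 1/(1+(f/f_c)^{2n})$, default order 4 with $f_c$ at half
the detected carrier: steep enough to take ≥ 20 dB off the carrier while
leaving sub-0.02 cycles/px perfusion structure essentially untouched
(< 1 dB), without visible ringing. DC gain is exactly 1, so mean intensity
— the oximetry channel — is preserved. Because any low-pass below the
carrier also removes part of the speckle energy, filtered contrast values
are rescaled relative to unfiltered ones; the guarantee tested is that the
*filtered* series is insensitive to whether the pattern was present, which
is what makes downstream rates and change points pattern-independent.

## Rate extraction

`detrend_series()` removes the least-squares line (the DC level plus slow
drift, e.g. an occlusion ramp). `resample_double()` linearly interpolates
the jittered, possibly nonuniform series onto a uniform grid of $2N-1$
points — double the mean sampling frequency. `power_spectrum()` applies a
Hann taper and returns the one-sided periodogram. `attribute_peaks()`
searches disjoint respiratory (0.1–1 Hz) and cardiac (1–4 Hz) bands —
wide enough for a 220 bpm rabbit heart and a 6 breaths/min slow ventilation
— for local maxima, converts frequency to per-minute rate by an exact ×60,
and quotes ± half a spectral bin as uncertainty.

Numerical choices worth stating:

* **Nyquist bookkeeping.** Interpolation adds no information, so the
  usable Nyquist limit is half the *native* mean acquisition rate, carried
  through resampling. A band extending beyond it is rejected with a classed
  condition (the pipeline reports "aliased/out-of-band" instead of a rate):
  a 3.5 Hz heartbeat recorded at 5 fps must yield *no* cardiac call rather
  than an aliased one.
* **Prominence.** A peak is reported only if its power exceeds 15× the
  median band power. For a single-taper periodogram the bin powers are
  roughly exponential, so the expected max/median ratio of a few hundred
  null bins is ~9–10; the threshold sits safely above that (false-call
  probability ~2% per band) while genuine physiological peaks in the tested
  regimes exceed it by an order of magnitude.
* **Ties.** Candidates within 5% of the band maximum are all listed; the
  highest-frequency one is marked primary (intra-operative spectra often
  show several attributable peaks).

## Oximetry

Oxy- and deoxy-hemoglobin absorptivities cross between 660 and 830 nm:
deoxy-Hb dominates at 660 nm, oxy-Hb at 830 nm. The shipped
`extinction_table()` (per mM·mm: 660 nm — HbO₂ 0.0320, Hb 0.3227; 830 nm —
HbO₂ 0.0974, Hb 0.0693, from the standard compiled hemoglobin
absorptivity tabulation) is validated for exactly that sign structure.
`oxygenation_map()` ratios locally smoothed intensities $I_{660}/I_{830}$ —
a rise in oxygenation raises the ratio; the map is reported as a raw ratio
and color rendering is left to the presentation layer.
`chromophore_deltas()` inverts the modified Beer–Lambert law,
$\Delta OD(\lambda) = -\ln I(\lambda,t)/I(\lambda,\mathrm{ref}) =
L\,[\varepsilon_{HbO_2}\Delta C_{HbO_2} + \varepsilon_{Hb}\Delta C_{Hb}]$,
as an exact 2×2 solve per sample. With the pathlength factor fixed at 1 all
outputs are *relative* units — absolute quantitation would require a
differential pathlength factor that endoscopic geometry does not provide,
and relative changes are what the application needs. The reference sample
defaults to the first frame and should be set to a pre-occlusion frame when
one exists. Detector gain changes cancel exactly (everything is ratioed to
the reference), and intensities — not contrast — feed this channel, since
absorption acts on intensity.

## Occlusion detection

`detect_occlusion()` first suppresses respiratory spikes with a moving
median (width 3× the spike period when a respiratory estimate is supplied,
else 5 s), then exhaustively fits a three-segment piecewise-constant model
(baseline / occluded / released) over all change-point pairs — $O(n^2)$,
trivial at the ~100-sample scale of an occlusion recording. A call requires
the occluded level to exceed baseline by ≥ 3 baseline standard deviations
(of the spike-suppressed series) for ≥ 5 s. If the two-change-point fit
does not contain such a step, a single-step fit is tried instead and, when
valid, reported with the release marked absent — the recording ended while
still clamped. Boundary times are midpoints between bracketing samples, so
accuracy is half a sample interval plus timestamp jitter.

## Problem sizes and test design

Tests and the acceptance script regenerate every input from seeds: no
binary fixtures ship with the package. The rate-recovery runs use 60–120 s
acquisitions at 10–21.4 fps and 64×64 px frames (≈ 580 independent speckle
grains per frame, giving ~3% per-frame contrast noise — ample spectral SNR
at the default modulation depths); the occlusion protocol is 65 s at
1.6 fps per wavelength, exactly the 25 s flow / 25 s clamp / 15 s release
sequence; property suites use 24–128 px frames. A 20-seed recovery study
(30 s, 8 fps, modulation depth 0.25) checks the cardiac estimate lands
within one spectral bin in at least 18 of 20 runs.

One deliberate deviation from a natural-seeming check: asserting that *no*
null-spectrum bin exceeds 5× the median is statistically untenable for a
periodogram with hundreds of bins (the null max/median is ~9); the null
property tested instead bounds the band maximum by an order-statistic
threshold matched to the bin count and verifies that peak attribution stays
silent.

## Known limitations

* Spatial contrast only; no temporal (per-pixel, multi-frame) estimator,
  no motion registration.
* Linear interpolation and linear detrending only (spline resampling and
  higher-order detrending were considered and left out: at 5% timestamp
  jitter they changed recovered rates by less than a tenth of a bin).
* Single occlusion per recording; no streaming detection.
* No absolute oxygen saturation calibration; ratio maps and chromophore
  deltas are relative.
* The honeycomb model is a three-cosine lattice, not a resolved per-core
  image; per-core interpolation/demosaicing is out of scope.
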