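# especkle

Endoscopic laser speckle contrast analysis (eLASCA) of tissue perfusion.

During vascular surgery — the motivating application is monitoring graft
perfusion at anastomotic sites in uterine transplantation — a flexible
fiber-bundle probe delivers coherent 660 nm and 830 nm laser light to the
tissue and relays the backscattered speckle pattern to a 12-bit camera.
Moving red blood cells blur the speckle within the camera exposure, so the
local speckle contrast

    K = sigma / <I>          (standard deviation over mean, small window)

drops where flow is fast. `especkle` turns raw speckle stacks into:

* **perfusion maps** — spatial contrast images `C660`, `C830` (low K = fast
  flow), via the LASCA estimator with the Lorentzian-velocity model
  `K^2(T, tau_c) = (tau_c / 2T) (1 - exp(-2T / tau_c))` linking contrast to
  exposure `T` and speckle correlation time `tau_c`;
* **heart and respiratory rates** — the ROI-averaged contrast series is
  detrended, resampled at double frequency onto a uniform grid, Fourier
  transformed, and band-restricted spectral peaks are attributed as
  `rate = 60 x f` (cardiac 1–4 Hz, respiratory 0.1–1 Hz), with a strict
  native-Nyquist guard against aliased calls;
* **relative oxygenation** — ratiometric `I660 / I830` maps and modified
  Beer–Lambert chromophore changes `(dC_HbO2, dC_Hb, dC_total)` from the
  2×2 extinction-matrix inversion;
* **occlusion calls** — onset and release of a vessel clamp detected as a
  three-segment level shift in the contrast series, robust to periodic
  respiratory spikes;
* **fiber-bundle artifact removal** — a radially symmetric 2-D Butterworth
  low-pass that takes ≥ 20 dB off the honeycomb carrier of the imaging
  bundle while preserving perfusion structure, with automatic carrier
  detection.

A seeded synthetic acquisition simulator (`simulate_stack()`) generates
dual-wavelength 12-bit speckle stacks with known physiological ground truth
(correlation-time modulation, Beer–Lambert intensity forward model,
honeycomb overlay, detector noise, timestamp jitter), so the entire chain
is testable without any recordings.

## Worked example

Simulate a sheep-like intra-operative recording (heart 1.83 Hz, breathing
0.38 Hz, 10 fps, 60 s, 20 ms exposure) and recover the rates:

```r
library(especkle)

cfg <- acquisition_config(exposure_time = 2e-2, nominal_frame_rate = 10,
                          frame_count = 600, wavelengths = 660)
phy <- physiology_params(heart_rate = 109.8, respiratory_rate = 22.8)
sim <- simulate_stack(cfg, phy, seed = 2024)

series <- roi_contrast_series(sim$stacks[["660"]])
spec   <- power_spectrum(resample_double(detrend_series(series)))
est    <- attribute_peaks(spec)
est[est$primary, c("kind", "frequency", "rate", "uncertainty")]
#>          kind frequency   rate uncertainty
#> 5     cardiac    1.8351 110.10      0.5005
#> 1 respiratory    0.3837  23.02      0.5005

mean(series$k)                 # 0.354 — ROI contrast at 20 ms exposure
contrast_model(2e-2, 2e-3)     # 0.224 — ideal-estimator model value
```

The cardiac peak at 1.835 Hz reads 110.1 bpm and the respiratory peak at
0.384 Hz reads 23.0 breaths/min, each ± half a spectral bin (±0.5/min at
60 s); both match the simulated ground truth within one bin. The measured
mean contrast sits above the ideal-model value by the known windowed-
estimator and discrete-integration biases (see the methods vignette).

For recorded data the same chain starts from files:
`read_stack()` (multi-page TIFF + timestamp CSV) → `filter_stack()` /
`auto_filter_spec()` → `contrast_map()` / `roi_contrast_series()` →
rates, `detect_occlusion()`, `pair_frames()` + `chromophore_deltas()`.
`run_pipeline(pipeline_config(...))` executes everything and writes maps,
series, spectra, a JSON report, figures and a hashed manifest;
`inst/cli/especkle.R` wraps the same functions as shell subcommands
(`simulate`, `contrast`, `rates`, `oximetry`, `occlusion`, `pipeline`).

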