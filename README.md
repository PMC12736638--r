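# diffmwi

Differential microwave imaging of weak, temperature-induced dielectric
contrasts in water phantoms.

## What problem this solves

Early, lateralized changes in brain tissue (the motivating case is the
substantia nigra in early Parkinson's disease) are expected to shift the
local dielectric properties by well under a percent. Before such contrasts
can be chased clinically, one needs to know whether a microwave imaging
chain can see them at all. A clean way to find out is a *dynamic phantom*:
a head-sized cylinder of water in which a small tube target changes
temperature — and therefore permittivity — in precisely known 0.1 °C steps,
while a four-antenna array records 4×4 scattering matrices over 0.5–3 GHz.

`diffmwi` implements that feasibility study end to end, for researchers in
biomedical electromagnetic sensing:

* **Dielectrics** — single-Debye model of water,
  `ε(f,T) = ε∞ + (εs − ε∞)/(1 + j2πfτ)`, with pluggable published
  parameterizations, linearity statistics (R²), and per-0.1 °C sensitivity
  tables.
* **Geometry** — paired four-antenna circular array (35°/90° spacing,
  100-mm aperture radius), frequency-dependent phase-center offsets, 1-mm
  circular imaging grid.
* **Synthetic data** — first-order Born forward model with a complex
  background wavenumber, band-limited usable transmission, seeded Gaussian
  noise, the 46-step cooling protocol, and Touchstone `.s4p` I/O.
* **Reconstruction** — differential multi-frequency bi-focusing (MFBF):
  `I(x,y) = Σ_f Σ_Ti Σ_Rj ΔS_TiRj(f)/k² · e^{jkρ_Rj} · e^{jkρ_Ti}`
  with `ΔS = S_background − S_target` and `k = 2πf√εr/c`.
* **Analysis** — localization error, peak-versus-contrast regression,
  detection threshold, contrast conversion, and the thermal budget of the
  cooling experiment.

## Worked example

Dielectric sensitivities and the thermal budget:

```r
library(diffmwi)
sens <- sensitivity_table()
sens
#>    frequency eta_eps eta_sigma
#> 1  500000000  0.0430  0.000153
#> 2 1000000000  0.0424  0.000611
#> 3 1500000000  0.0414  0.00137
#> 4 2000000000  0.0401  0.00242
#> 5 2500000000  0.0383  0.00376
#> 6 3000000000  0.0362  0.00537
```

Each row is the percent change of εr (self-normalized) and of σ (referenced
to εr) per 0.1 °C step of the 26.0–36.5 °C protocol. A 0.4 °C temperature
difference is therefore equivalent to a fraction-of-a-percent dielectric
contrast over the 0.5–2 GHz imaging band:

```r
threshold_to_contrast(0.4, sens)
#>   delta_t eps_percent sigma_percent
#> 1     0.4       0.167       0.00456

thermal_budget()
#> <thermal_budget>
#>   phantom: 3.46 kg, C = 14500 J/degC
#>   target:  0.00785 kg, C = 32.9 J/degC
#>   released heat 148 J -> bulk rise 0.01 degC
#>   h = 5 W/m2K: tau = 5.96 h
#>   h = 10 W/m2K: tau = 2.98 h
```

(The 0.01 °C bulk rise and multi-hour convective time constants confirm the
background stays effectively constant during the 237-s protocol.)

The full synthetic experiment — simulate the cooling series, image every
step against the 40.5 °C background, analyze detection:

```r
arr    <- antenna_array()
grid   <- imaging_grid(100, 1)
scene  <- phantom_scene(inclusion_temperature = 40.5)
acq    <- acquisition_spec(noise_floor_db = -99, seed = 2)
series <- cooling_series(scene, arr, acq)
result <- reconstruct_series(series, arr, grid)
report <- detection_report(result$peaks, true_center = c(-25, 10),
                           sensitivity = sens)
report
#> <detection_report> 45 contrasts
#>   threshold: 0.4 degC (localization tolerance 9 mm)
#>   peak-vs-contrast R^2 = 0.9969
#>   equivalent contrast: 0.17% in eps_r, 0.0046% in sigma
```

At the calibrated −99 dB noise floor the target becomes reliably
localizable from a 0.4 °C contrast (≈0.17 % in εr), and the reconstructed
peak grows linearly with the contrast. Noise-free, the same pipeline
localizes the target to the exact pixel at every step and reaches
R² > 0.999. `autoplot()` methods display the images and the regression;
`tidy()`/`glance()` return the results as tibbles. A YAML-driven interface
(`read_run_config()`, `run_simulate()`, `run_reconstruct()`,
`run_analyze()`) runs the same stages against datasets on disk.

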