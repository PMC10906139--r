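# fkprost

Patient-specific forecasting of organ-confined prostate cancer growth during
active surveillance, from longitudinal diffusion-weighted MRI.

Men on active surveillance are monitored with periodic multiparametric MRI
instead of immediate treatment, and the clinical question is whether — and
when — a tumor is progressing toward higher-risk disease. `fkprost`
implements an imaging-informed biomechanistic pipeline for that question:

1. **ADC → cell density.** The apparent diffusion coefficient (ADC) map
   decreases with increasing cellularity. With the healthy-tissue reference
   ADC<sub>h</sub> and the minimum tumor ADC fixed at
   ADC<sub>min</sub> = 0.25 · ADC<sub>h</sub>, each voxel is mapped to a
   normalized tumor cell density

   N̄ = (ADC<sub>h</sub> − ADC) / (ADC<sub>h</sub> − ADC<sub>min</sub>),

   truncated to [0, 1]. Tumor cores are segmented at 70 % of
   ADC<sub>h</sub> (N̄ ≥ 0.4) and expanded by a 2–4 mm metric margin; a
   hyperbolic-tangent model of the Gleason-score/ADC-ratio relation
   underpins the threshold choice (`fit_gs_adc_model()`).

2. **Growth model.** N̄(x, t) evolves by the Fisher–Kolmogorov
   reaction–diffusion equation on the masked prostate domain Ω,

   ∂N̄/∂t = ∇·(D ∇N̄) + ρ N̄ (1 − N̄),   ∇N̄·n = 0 on ∂Ω,

   with tumor cell diffusivity D (mm²/day) and net proliferation rate ρ
   (1/day). The solver is a masked 7-point finite-volume Laplacian with
   backward-Euler/Newton time stepping (Δt = 1 day) in compiled code.

3. **Calibration.** `fk_fit()` estimates (D, ρ) per patient by bounded
   Gauss–Newton least squares on the relative misfit between simulated and
   measured density maps at the scan times (scan 1 is the initial
   condition; D ∈ [10⁻⁶, 10], ρ ∈ [10⁻⁶, 1]). It returns a classed model
   object with `coef`, `summary`, `predict`, `simulate`, `residuals` and
   `plot` methods.

4. **Agreement metrics and biomarkers.** Tumor volume V_T and total cell
   volume V_N (threshold N̄ ≥ 0.15), Dice overlap, RMSE, Pearson and Lin
   concordance correlation; model-based biomarkers (V_P, V_T, V_N, mean
   density, total tumor index N_T = V_N/V_P, mean proliferation activity
   A_p = ⟨ρN̄(1 − N̄)⟩) feed exact Wilcoxon tests and logistic risk
   classifiers with trapezoidal-AUC ROC analysis.

5. **Synthetic cohorts.** `generate_cohort()` builds fully self-contained
   cohorts (ellipsoidal prostates of 18.5–67.3 cc, three scans at 0.5–2.6
   year intervals, ADC maps inverted from the forward model plus optional
   noise, Gleason-like risk labels tied to proliferation activity), so the
   whole pipeline — including the *global calibration* and
   *fitting–forecasting* study scenarios of `run_scenario()` — runs without
   patient data.

## Worked example

```r
library(fkprost)

sp  <- cohort_spec(n_patients = 1, dim = c(24, 24, 24), spacing = 2.5,
                   prostate_volume_range = c(25, 35),
                   gap_range_years = c(0.8, 1.2), noise_sd = 0, seed = 7)
pat <- generate_cohort(sp)[[1]]
grid <- fk_grid(pat$series$prostate, pat$spacing, pat$dt)

fit <- fk_fit(pat$series, grid)
fit
#> Fisher-Kolmogorov growth model fit
#>   scans fitted : 3 (initial condition from scan 1)
#>   D            : 0.001337 mm^2/day
#>   rho          : 0.0009714 1/day
#>   misfit       : 7.413e-30 after 10 Gauss-Newton iterations (converged)
summary(fit)
#> Per-scan model-data agreement:
#>  time_days v_t_meas v_t_model v_n_meas v_n_model dsc      rmse pcc ccc
#>        302   0.1094    0.1094  0.03610   0.03610   1 1.049e-16   1   1
#>        630   0.1094    0.1094  0.03614   0.03614   1 1.241e-16   1   1
```

The fit recovers the generating parameters of this noiseless synthetic
patient (true D = 0.00134 mm²/day, ρ = 0.000971 1/day) essentially exactly,
and the per-scan panel confirms voxel-level agreement (Dice 1, RMSE ~1e-16).
A personalized forecast one year past the last scan, with its biomarker
panel:

```r
fc <- predict(fit, times = max(pat$series$times) + 365)[[1]]
biomarker_panel(fc, grid, fit$params)
#>   time_days    v_p     v_t     v_n nbar_mean     n_t     a_p
#> 1       995 34.875 0.10938 0.03707   0.33893 0.00106 0.00021
```

i.e. a 34.9 cc prostate carrying a 0.11 cc tumor with mean normalized
density 0.34, total tumor index 0.0011 and mean proliferation activity
2.1e-4 /day at the forecast time.

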