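---
title: "Methods: imaging-informed Fisher-Kolmogorov forecasting of prostate cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imaging-informed Fisher-Kolmogorov forecasting of prostate cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, numerical choices and design decisions
behind `fkprost`, in the spirit of a methods section: what is computed, under
which assumptions, and what the defaults mean.

## From ADC to normalized tumor cell density

Diffusion-weighted MRI yields an apparent diffusion coefficient (ADC) map
whose values fall as cellularity rises. The package treats the conversion as
a fixed linear map between two tissue anchors: the healthy-tissue reference
`adc_h` (the mean ADC over a manually drawn healthy region of the same zone
as the tumor, `estimate_healthy_adc()`) and the minimum ADC observable in a
tumor, fixed at `ratio_min = 0.25` of `adc_h` (the lower asymptote of the
Gleason-score/ADC-ratio sigmoid). The normalized density is

$$\bar N = \frac{ADC_h - ADC}{ADC_h - ADC_{min}},$$

truncated so ADC above `adc_h` gives 0 and below `adc_min` gives 1: negative
cell densities and densities above the tissue carrying capacity are
unphysical. The truncation is applied *wherever* the conversion is
evaluated, whether or not a tumor mask restriction follows; this is the
simpler of the two orderings and the only one consistent with using the map
as an invertible transform in the synthetic-data generator.

Two consequences worth noting: the tumor-core threshold at 70% of `adc_h`
corresponds exactly to $\bar N \ge 0.4$, and the margin-expanded tumor
border (2-4 mm, default 3 mm in `preprocess_scan()`) lands near healthy ADC
values, i.e. $\bar N \lesssim 0.15$ — which is why the tumor-region
threshold used throughout the metrics is `nbar_th = 0.15`.

The Gleason-ADC relation itself is modeled as a hyperbolic tangent on a
continuous 0-10 GS scale (0-2 healthy), with the asymptotes *pinned* at 1
(healthy) and `ratio_min`: only the steepness and midpoint are estimated by
nonlinear least squares (`fit_gs_adc_model()`, via `minpack.lm`). Pinning
reduces the fit to two parameters, which is all the five literature-level
mean points can support. The shipped
`extdata/gs_adc_literature_synthetic.csv` is a synthetic stand-in for those
literature means (the cited per-study values are not redistributable); it is
generated from a plausible sigmoid and exists so the fitting code path is
exercisable, not as a data product.

## The growth model and its solver

Tumor growth is modeled by the normalized Fisher-Kolmogorov equation on the
prostate domain $\Omega$ (the mask from the first scan),

$$\frac{\partial \bar N}{\partial t}
  = \nabla \cdot (D \nabla \bar N) + \rho \bar N (1 - \bar N),
  \qquad \nabla \bar N \cdot \mathbf{n} = 0 \text{ on } \partial\Omega,$$

with two patient-specific parameters: diffusivity $D$ (mm²/day, cell
mobility) and net proliferation rate $\rho$ (1/day, proliferation minus
death against a carrying capacity). Zero-flux boundaries encode
organ-confined disease. Working with the *normalized* density removes the
carrying capacity as a separate parameter — deliberately parsimonious, since
two or three scans per patient cannot identify more.

**Discretization.** Space: a 7-point finite-volume Laplacian on the voxel
grid restricted to the mask; fluxes across faces leaving the mask are simply
omitted, which is the discrete zero-flux condition and makes conservation
exact in exact arithmetic. Time: backward Euler with $\Delta t = 1$ day and
Newton linearization; the final partial step lands exactly on each output
time. The Newton systems are symmetric and diagonally dominant for
$\rho\,\Delta t < 1$, and are solved matrix-free by Jacobi-preconditioned
conjugate gradients in compiled code. This replaces the isogeometric
(NURBS) discretization used in high-fidelity implementations of the same
continuum model; with both schemes consistent, accuracy is anchored on
closed forms rather than on a particular mesh.

**Tolerances.** Newton: relative residual `1e-8`, at most 25 iterations,
with an absolute floor scaled as $10^{-13}\sqrt{n}\,(1+\lVert u\rVert)$ —
below that, the residual is roundoff and iterating further is meaningless.
CG: relative residual `1e-12` (tighter than strictly needed for accuracy;
it buys exact-to-roundoff mass conservation in the $\rho = 0$ limit, which
the tests assert at 1e-10 relative over 1000 steps). After each step the
state is clipped to $[0,1]$ only if the overshoot is below `1e-6`;
anything larger raises an error rather than being silently repaired.

**Verified limits** (see `test-solver.R` / `test-acceptance.R`): spatially
uniform initial data with $D = 0$ reproduce the logistic closed form to
better than $10^{-3}$ over 1000 days at $\Delta t = 1$ (backward Euler's
first-order error is ~2.5e-4 there, so no second-order scheme is needed to
meet the contract); $\rho = 0$ conserves mass; a 1D slab reproduces the
asymptotic travelling-wave speed $2\sqrt{D\rho}$ within 5%. The front-speed
test uses $D = 0.2$, $\rho = 0.2$, $h = 0.125$ mm, $\Delta t = 0.1$ day and
measures the front by regression over $t \in [100, 250]$ days: the front
width $\sqrt{D/\rho}$ must span several voxels and the window must sit past
the initial transient (which decays like $3/(2\lambda t)$), otherwise the
measured speed is biased low regardless of the solver.

## Calibration

`fk_fit()` minimizes the relative least-squares misfit

$$J(D, \rho) = \sum_{i \ge 2}
  \frac{\int_\Omega (\bar N^{mod}(x, t_i) - \bar N^{meas}(x, t_i))^2\,dx}
       {\int_\Omega (\bar N^{meas}(x, t_i))^2\,dx},$$

where scan 1 supplies the initial condition and is never fitted. The
normalizer is the per-scan measured energy over the whole prostate — the
standard relative-$L^2$ choice; integrals are voxel sums times the voxel
volume, so the volume factor cancels inside each term.

Optimization is Gauss-Newton on the stacked, per-scan-normalized residual
vector, in $(\log D, \log \rho)$ coordinates: the admissible boxes
($D \in [10^{-6}, 10]$ mm²/day, $\rho \in [10^{-6}, 1]$ 1/day) span 4-6
decades and the parameters are strictly positive, so log coordinates make
the finite-difference Jacobian step (`1e-3`) meaningful everywhere. Bounds
are enforced by projection, steps by halving line search (Gauss-Newton
needs no trust region here because the line search already guarantees
monotone descent, which the tests assert); convergence is declared at a
relative objective change below `1e-6` or 50 iterations, and
non-convergence is reported as a flag, not an exception. The default
initial guess is $D = 5\times10^{-3}$ mm²/day, $\rho = 2\times10^{-3}$
1/day. `fk_grid_search()` provides the brute-force misfit surface used as
an optimization oracle in the tests.

## Agreement metrics and biomarkers

The tumor region $\Omega_T$ is $\{\bar N \ge 0.15\}$ (inclusive). Global
metrics: $V_T = |\Omega_T|$ and $V_N = \int_{\Omega_T} \bar N\,dx$, in cc;
cohort-level agreement uses Pearson and Lin concordance over patientwise
pairs. Local metrics (RMSE, PCC, CCC) are evaluated over the *union* of the
measured and simulated tumor regions: the union avoids inflating agreement
with shared empty background while covering both footprints; the
correlation moments are population (1/n) moments, under which Lin's
inequality $|CCC| \le |PCC|$ holds identically (asserted to 1e-12 on 1000
random instances). Dice of two empty masks is defined as 1 (perfect
agreement of absence — a case real data never produce but synthetic edge
cases do). A constant field over the support makes PCC undefined; it is
returned as `NaN` with a warning rather than silently dropped.

The biomarker panel at a time point is $V_P$, $V_T$, $V_N$, the mean
density $\bar N_{mean} = V_N / V_T$, the total tumor index
$N_T = V_N / V_P$ (dimensionless; normalizing by organ size matters because
BPH-enlarged prostates carry a lower risk of high-grade disease), and the
mean proliferation activity

$$A_p = \frac{1}{V_T}\int_{\Omega_T} \rho\,\bar N (1 - \bar N)\,dx
  \quad [1/\text{day}],$$

the volume-averaged logistic source term: it peaks at $\bar N = 0.5$ and
vanishes both in empty and in saturated tissue, so it reads as "how actively
is this tumor still proliferating" rather than "how big is it".

**Statistics.** Wilcoxon rank-sum and signed-rank p-values are computed by
exact enumeration of the permutation distribution when the combined sample
(or the number of nonzero paired differences) is at most 12 — enumeration
remains exact under ties, which the classical exact distributions do not
handle — and by the tie-corrected normal approximation otherwise. Logistic
risk classifiers take at most two biomarkers (more would overfit a cohort
of this size); they are fitted by IRLS with step-halving (monotone
log-likelihood), and perfect separation — likely at small n — is detected by
capping the coefficient norm at 30 on internally standardized features and
flagging the fit; predicted probabilities stay well defined and the decision
boundary is preserved. ROC analysis sweeps all observed score thresholds,
integrates by the trapezoidal rule (equal to the Mann-Whitney concordance
on tie-free scores, asserted exactly), and takes the operating point
closest to the (0,1) corner, breaking ties toward higher sensitivity.
Classifiers are trained and evaluated on the same cohort, mirroring the
no-split design of small pilot studies; this is a known limitation, not an
oversight.

## The synthetic cohort: what it emulates, and what it does not

`cohort_spec()` defaults encode the study conditions: 48³ voxels at 1.5 mm
isotropic spacing; ellipsoidal prostates (semi-axis ratios 1.25 : 1 : 0.85)
with volumes uniform on 18.5-67.3 cc; true parameters log-uniform on
$D \in [5.35\times10^{-4}, 5.35\times10^{-3}]$ mm²/day and
$\rho \in [7.8\times10^{-4}, 5.2\times10^{-3}]$ 1/day (the calibrated
ranges of the two study scenarios); three scans with interscan gaps uniform
on 0.5-2.6 years; a focal tumor seeded as a truncated Gaussian (radius
3-6 mm, peak density 0.6-0.9) off-center in the gland; ADC stored as the
ratio to `adc_h` (absolute units cancel in every downstream formula);
additive Gaussian ADC-ratio noise of sd 0.02 truncated to (0, 1.2].
Higher-risk (GS ≥ 3+4-like) labels are assigned when the *true* final-scan
proliferation activity exceeds `ap_cutoff = 4e-4` /day — roughly the cohort
median under the default parameter ranges — so the classifier stage has a
learnable ground truth that is independent of the fitted model.

The generator is deterministic given `seed` and every patient satisfies the
structural invariants (nested masks, densities in [0,1], strictly ordered
times). What it does *not* emulate: real prostate anatomy (zonal structure,
urethra), registration and segmentation error, Rician MRI noise,
scanner/protocol variation, and tumors whose dynamics depart from the
Fisher-Kolmogorov model itself. Passing tests on synthetic cohorts
therefore demonstrate the *internal* consistency of the pipeline
(preprocessing inverts the generator's forward map; calibration recovers
generating parameters; forecasts reproduce model-generated truth), not
clinical accuracy on real imaging.

## Study scenarios and problem sizes

`run_scenario()` drives the two designs: *global calibration* fits all
scans (can the model represent observed growth?) and *fitting-forecasting*
fits scans 1-2 and validates the personalized forecast against scan 3 (can
it predict?). Outputs — per-scan agreement rows, biomarker panels at the
scan times (which stand in for histopathology times), calibration traces,
cohort concordance, the proliferation-activity classifier and per-patient
risk trajectories with the optimal-threshold crossing time — are written as
CSV/JSON when an output directory is given, and runs are deterministic
given the cohort (byte-identical outputs on reruns, asserted in the tests).

Problem sizes in the shipped tests were chosen to keep a full run on one
CPU comfortable: unit tests use 16³-24³ grids with 0.5-1 year gaps; the
acceptance suite runs the default 10-patient 48³ cohort once
(fitting-forecasting, ~10⁴ domain voxels and a few hundred to ~2000 daily
steps per simulation) and reuses those fits for both the
parameter-recovery and forecast-validation checks, and runs the 20×20
grid-search oracle on the patient with the shortest calibration horizon.

## Known limitations

Deterministic point estimates only (no uncertainty quantification or
Bayesian updating); registration across scans is assumed done upstream (all
volumes of a patient share one grid); the solver targets the parameter
regime of slow prostate tumors ($\rho\,\Delta t \ll 1$ at the default
daily step — stiffer regimes need a smaller `dt`); V_T/V_N converge only
first-order in spacing because of the sharp region threshold, so
cross-resolution comparisons should use matched grids; and the risk
classifier inherits every caveat of same-cohort training at n ≈ 10-16.
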