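---
title: "Measuring the pulmonary blood pool with CMR: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the pulmonary blood pool with CMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulmocmr)
```

# The measurement chain

`pulmocmr` derives five physiological quantities from three CMR acquisitions:

| Quantity | Source acquisition | Operator |
|---|---|---|
| PTT (s) | first-pass contrast series, PT + LA ROIs | `compute_ptt()` |
| SV (mL), CO (L/min) | phase-contrast flow in the pulmonary trunk | `cycle_volume()`, `cardiac_output()` |
| PBV (mL) | PTT × CO | `compute_pbv()` |
| Lung volume (mL), PBVI (%) | transverse SSFP stack, planimetry | `planimetric_volume()`, `compute_pbvi()` |
| PBVV (mL), PBVV/SV (%) | flow in the trunk and all pulmonary veins | `compute_pbvv()`, `pbvv_sv_ratio()` |

This vignette explains the underlying models, the numerical choices made
where the methods literature is silent, what the synthetic-data generator
does and does not emulate, and the package's known limitations.

# Transit time by the centroid method

## Model

A small contrast bolus (~2 mL) injected peripherally passes the pulmonary
trunk and, one pulmonary transit later, the left atrium. Each ROI yields a
time–intensity curve; the indicator-dilution view treats each curve (after
baseline removal) as an un-normalised density of tracer arrival times, whose
mean — the curve centroid `t̄ = Σ tᵢ sᵢ / Σ sᵢ` — is the mean arrival time.
The mean transit time between the two sites is the difference of the
centroids, regardless of dispersion: if the LA curve is the PA curve
convolved with a transit-kernel of mean `τ`, then `t̄(LA) − t̄(PA) = τ`
exactly. That convolution identity is why the centroid method is preferred
over peak-to-peak or arrival-time differences, which are biased by bolus
broadening.

The pipeline assumes (i) linearity of signal in concentration over the
observed range (reasonable for a dilute pre-bolus at saturation-recovery
settings), (ii) stationary flow during the ~15 s first pass, and (iii) a
baseline that is constant in time before contrast arrival.

## Numerical choices

* **Quadrature.** The centroid uses rectangle (equal-weight) sampling at the
  frame times; on the uniform grids produced by cine reconstruction the
  weights cancel, and for smooth curves that vanish at the window ends the
  residual error is far below half a frame interval. A trapezoidal option
  (`rule = "trapezoid"`) covers non-uniform grids.
* **Baseline.** `baseline_correct()` subtracts the mean of the first `n_pre`
  (default 5) pre-contrast frames. Negative residuals are clipped to zero by
  default: the centroid is a ratio statistic and noisy near-zero tails
  otherwise destabilise it; `clip_negative = FALSE` restores raw residuals.
* **Recirculation window.** Real curves show a second, recirculated pass.
  The default analysis window (`window_mode = "local_min"`) runs to the first
  local minimum after the peak, found on a 3-point-smoothed copy and only
  below half of peak amplitude — the guard keeps noise dips on the downslope
  from truncating the first pass. `"full"` uses the whole acquisition;
  `"gamma_fit"` fits `s(t) = A ((t−t₀)/β)^α e^{−(t−t₀)/β}` by
  Levenberg–Marquardt and uses the fitted first moment `t₀ + (α+1)β`,
  extrapolating the tail past any recirculation. Whether a given study
  truncated recirculation or used the full window is an acquisition-analysis
  choice, so it is surfaced in `pipeline_config()` rather than hard-coded.
* A negative PTT (LA centroid before PA) is physiologically impossible; it is
  returned with a `negative_ptt` flag, never silently clamped, so swapped ROI
  labels surface in QC output.

# Flow integration and the volume variation

## Stroke volume and cardiac output

`cycle_volume()` integrates the flow curve over one cardiac cycle with a
cyclic trapezoidal rule: the curve is closed by wrapping the first sample one
period forward, so no extrapolation happens at the cycle boundary. `CO = SV ×
HR / 1000` in L/min.

## PBVV

With `Q_a` the pulmonary-trunk inflow and `Q_v` the summed outflow of all
(1–5) pulmonary veins, the stored volume relative to cycle start is
`V(t) = ∫₀ᵗ (Q_a − Q_v) dt`, and `PBVV = max V − min V`. Numerically:

* `net_flow()` subtracts the summed venous curves from the arterial one.
  Curves sharing an identical sampling grid are combined directly; otherwise
  all curves are resampled to a uniform grid (default 128 points/cycle) by
  linear interpolation with periodic boundary handling. Cycle lengths must
  agree within 2% — retrospectively gated reconstructions share the RR
  interval by design, so a larger mismatch indicates inconsistent
  acquisitions and is an error naming the offending vessels.
* `cumulative_volume()` integrates with a running trapezoid. Measured data
  never close exactly (`V(T) ≠ 0`: venous undersampling, background-phase
  error, noise); with `drift_correct = TRUE` (the default) a linear ramp is
  removed so the curve closes, and the removed magnitude is reported as a QC
  metric (`drift_ml`). Drift correction makes PBVV independent of the cycle
  start point; it should be switched off only for noise-free validation work.
  No correction is applied for systematically missed small veins beyond this;
  the drift magnitude is the user's handle on that error.
* `pbvv_sv_ratio()` always normalises by the pulmonary-trunk stroke volume —
  PBVV/SV is defined as the fraction of each right-ventricular stroke volume
  transiently stored in the distensible pulmonary bed, so an aortic SV is the
  wrong denominator even when it was used for CO.

# Planimetric volumetry

`planimetric_volume()` is deliberately simple: masked voxel count × pixel
area × (slice thickness + gap), in mL. Binary masks only — manual planimetry
has no partial-volume weights, and the volumetric error of binary
discretisation is bounded by the volume of the voxels straddling the surface
(the bound `gen_mask_stack()` reports for ellipsoids). Lung masks are taken
as given and are expected to include parenchyma, intrapulmonary vessels and
the end-expiratory air (FRC), excluding the hilar great vessels; the package
does no segmentation. Ventricular EDV/ESV stacks yield `SV = EDV − ESV` and
`EF = 100·SV/EDV`, with `ESV > EDV` flagged (`esv_gt_edv`) but not
suppressed. BSA uses the Mosteller formula.

# Cohort statistics

`unpaired_ttest()` is the pooled-variance Student test by default — when a
study reports only "unpaired t-test" computed in common desktop software, the
pooled test is the historical default — with Welch behind `var_equal =
FALSE`. It accepts raw samples or `n/mean/SD` summary triplets, which makes
published group summaries directly testable; both input forms give
identical results by construction. `pearson_corr()` uses the t transform for
its two-sided p. `interobserver_variability()` uses the pair mean as the
percent-difference denominator, the symmetric convention. Missing covariate
values are dropped pairwise, with the per-metric `n` reported — mirroring
clinical tables where, say, a diffusion-capacity measurement exists for only
23 of 27 patients. No multiple-testing correction is applied anywhere; the
summary table reports raw per-metric p values.

# The synthetic-data generator

The generator exists so that every operator above is testable against known
truth without clinical data. Study conditions are built into its defaults: a
130 ms frame interval for the first-pass series, 35 flow samples per cycle,
50–60 slice lung stacks at 1.4 × 1.4 × 5 mm, a 27-patient / 10-control
cohort with PBVI 16 ± 4 vs 20 ± 5%, PBV 466 ± 87 vs 471 ± 122 mL, PBVV
32 ± 8 vs 33 ± 7 mL, PBVV/SV 45 ± 10 vs 40 ± 6%.

* **Bolus curves** are gamma variates — the standard indicator-dilution
  shape. The LA curve uses the same shape parameter with scale `β·d`
  (dispersion `d = 1.3` by default, emulating transit broadening) and an
  arrival time chosen so the *analytic* centroid difference equals
  `ptt_true` exactly; the sampled, noise-free pipeline must then recover it
  to quadrature precision (≤ dt/2), which the tests assert. Noise is Rician
  on magnitude voxels (σ as a fraction of peak, default experiments use 2%),
  with a Gaussian fallback flag. The dispersion and shape defaults
  (α = 3, β = 1.5 s) are conventions chosen to look like adult first-pass
  curves, not measured facts.
* **Flow sets**: the arterial waveform is a systolic half-sinusoid
  (systole = 30% of the cycle) integrating to `sv_true`; the total venous
  waveform is `(1−d)·Q_a(t) + d·Q_a(t−δ)` with δ = 25% of the cycle. The
  cumulative-excursion of the net flow is linear in the damping `d`, so `d`
  solves in closed form for any `pbvv_true` up to ~0.97·SV; beyond that the
  delay δ is extended numerically (at δ = systolic duration the excursion
  equals SV, the physical ceiling, and `pbvv_true > sv_true` is rejected).
  The sampled venous curves are rescaled by a factor within ~10⁻³ of unity so
  that the *discrete* cyclic-trapezoid cycle volumes of inflow and summed
  outflow agree to machine precision — conservation holds for the curves as
  delivered, not just in the continuous limit. The venous return is split
  among 1–5 veins in fixed proportions, which provably leaves the net flow
  unchanged.
* **Masks**: slab stacks have exactly known volume (count × voxel volume);
  ellipsoid stacks carry their analytic volume and an honest discretisation
  bound (the total volume of surface-straddling voxels).
* **Cohorts** draw each metric independently per group from the stated
  normals. Clinical covariates are patient-only, with missingness emulating
  incomplete workup (DL_CO in 23/27, VC in 25/27, sPAP in 23/27, HRCT in
  24/27; fibrosis prevalence 15/24). The covariate distributions
  (DL_CO 65 ± 18% predicted, VC 85 ± 18% predicted, sPAP 36 ± 14 mmHg) are
  plausible values for an early systemic-sclerosis cohort, chosen once for
  realism — no published per-covariate moments back them.

What the generator does **not** emulate — and therefore what passing tests do
not establish about real data: recirculation of the bolus, respiratory motion
and imperfect breath-holds, background phase error in the velocity maps,
observer variability in manual contours, any correlation structure between
metrics (cohort metrics are drawn independently, so cross-metric correlation
analyses on synthetic cohorts test mechanics, not physiology), and contrast
pharmacokinetics (no T1/relaxivity modelling). Recovery tolerances proven
here (PTT median error ≤ 5% at 2% noise; end-to-end PBVI median error ≤ 7%)
are lower bounds on real-world error, not estimates of it.

# Problem sizes used in validation

The shipped tests and `scripts/acceptance.R` use: 100 first-pass series
(PTT in 4–10 s) for transit-time recovery; 128 samples/cycle for the
closed-form PBVV oracle (`100·sin(2πt)` mL/s ⇒ PBVV = 100/π mL, checked to
0.5%); five flow sets across 1–5 veins for conservation; ellipsoid stacks at
4/2/1 mm in-plane resolution for convergence; 1000 null cohorts at n = 27/10
for type-I calibration (0.05 within its binomial CI) and 10⁴-draw permutation
oracles at n = 10 per group; and 50 full synthetic subjects for end-to-end
PBVI recovery. These sizes make the whole suite run in well under a minute
while leaving the Monte-Carlo margins comfortably away from their
thresholds.

# Known limitations

* ROIs and segmentations are inputs; the package contains no automatic
  PA/LA placement and no lung or ventricular segmentation.
* Flow curves are inputs; velocity-map-to-flow conversion (and its
  background-phase correction) is out of scope.
* NIfTI headers store geometry in single precision, so voxel spacing and
  frame intervals round-trip to ~7 significant digits (voxel data are written
  as float64 and round-trip exactly).
* The PTT analysis assumes a single dominant first pass; severe recirculation
  overlap at very low cardiac output would require the gamma-fit mode.
* `run_cohort()` isolates per-subject failures but makes no attempt at
  imputation; downstream group tests simply see a smaller per-metric `n`.
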