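# pulmocmr

Quantification of the pulmonary blood pool from cardiovascular magnetic
resonance (CMR).

Pulmonary vascular disease — pulmonary arterial hypertension, fibrosis-related
vascular loss — changes how much blood the lung holds and how much the
pulmonary vessels distend with each heartbeat, often before pressures or gas
exchange become abnormal. `pulmocmr` implements a set of non-invasive CMR
measures of exactly those quantities, for imaging scientists and clinical
physiologists analysing first-pass perfusion, phase-contrast flow, and cine
anatomy acquisitions:

* **Pulmonary transit time (PTT)** — the time a contrast bolus takes to travel
  from the pulmonary trunk (PT) to the left atrium (LA). Both first-pass
  time–intensity curves are reduced to their intensity-weighted mean times
  (centroids), and

  `PTT = t̄(LA) − t̄(PA)`,  with  `t̄ = Σ tᵢ sᵢ / Σ sᵢ`.

* **Pulmonary blood volume (PBV)** — the indicator-dilution (Stewart–Hamilton)
  estimate `PBV = PTT × CO`, with cardiac output `CO = SV × HR` from the cycle
  integral of the phase-contrast flow curve in the pulmonary trunk or aorta.

* **PBV indexed to lung volume (PBVI)** — `PBVI = 100 × PBV / V_lung` (%),
  with the lung volume from slice-by-slice planimetry of a transverse SSFP
  stack (masked voxels × voxel volume).

* **Pulmonary blood volume variation (PBVV)** — the peak-to-trough excursion
  of `V(t) = ∫₀ᵗ (Q_PT − Σ Q_veins) dt`, the blood volume transiently stored
  in the pulmonary circulation during one cardiac cycle (arterial inflow minus
  the summed outflow of up to five pulmonary veins). `PBVV/SV` (%) is a global
  index of pulmonary vascular distensibility (the Windkessel effect).

* **Ventricular volumetry** — planimetric EDV/ESV/SV/EF for LV and RV, indexed
  to body surface area by the Mosteller formula `BSA = √(h·w/3600)`.

* **Cohort statistics** — pooled (or Welch) unpaired t tests accepting raw
  samples *or* published `n / mean / SD` summary triplets, Pearson
  correlation, interobserver variability (percent difference of the pair
  mean), and per-metric group summary tables with pairwise-complete handling
  of missing covariates.

Every stage is validated against a synthetic-data generator with analytic
ground truth: gamma-variate bolus passages with an exactly known centroid
difference and Rician magnitude noise, pulsatile arterial/venous flow sets
with exactly conserved cycle volumes and a prescribed PBVV, mask stacks of
known analytic volume, and two-group cohorts drawn from stated means/SDs.

## Worked example

A complete synthetic subject — first-pass series, flow set, lung and
ventricular masks — analysed by the full pipeline:

```r
library(pulmocmr)

bundle <- gen_subject_bundle(seed = 42, ptt_true = 7, sv_true = 70,
                             hr_bpm = 70, pbvv_true = 32,
                             lung_volume_ml = 3500)
record <- run_subject(bundle)
record
#> <subject record> synthetic_01 (patient)
#>   PTT 6.9 s | SV 69.8 mL | CO 4.9 L/min
#>   PBV 563.7 mL | lung 3500.0 mL | PBVI 16.1 % | PBVV 31.3 mL | PBVV/SV 44.8 %
```

The recovered values sit on top of the ground truth: the true PTT is 7 s, the
true SV 70 mL, so the true PBV is `7 × 4.9 L/min × 1000/60 = 571 mL` and the
true PBVI `100 × 571/3500 = 16.3 %`; the pipeline returns 16.1 % from noisy
images and flow curves (2 % voxel noise, 2 mL/s flow noise).

Group statistics work directly from published summaries — for example, PBVI
in 27 patients (16 ± 4 %) versus 10 controls (20 ± 5 %):

```r
tt <- unpaired_ttest(list(n = 27, mean = 16, sd = 4),
                     list(n = 10, mean = 20, sd = 5))
sprintf("t = %.2f, df = %d, p = %.4f", tt$t, tt$df, tt$p)
#> "t = -2.52, df = 35, p = 0.0163"
```

so the patients' lower PBVI is significant at the 5 % level. A full synthetic
cohort with the same design:

```r
cohort <- gen_cohort(cohort_spec(seed = 1))
summarize_groups(cohort, c("pbvi_pct", "pbv_ml", "pbvv_sv_pct"))
#>       metric  group1 n1 mean1   sd1  group2 n2 mean2    sd2      t df      p
#>     pbvi_pct patient 27  16.6  3.66 control 10  18.9   4.20 -1.662 35 0.1055
#>       pbv_ml patient 27 490.7 73.80 control 10 481.7 144.56  0.251 35 0.8033
#>  pbvv_sv_pct patient 27  43.4  6.70 control 10  38.0   7.35  2.140 35 0.0394
```

(single draws at n = 27/10 scatter around the generating means — the power of
this design for a 16-vs-20 PBVI separation is about 0.7).

## Command line

A thin CLI over the same functions lives at `inst/cli/pulmocmr.R`:

```sh
Rscript inst/cli/pulmocmr.R simulate --out subj01 --seed 3 --ptt 6.5
Rscript inst/cli/pulmocmr.R subject  --bundle subj01 --out record.json
Rscript inst/cli/pulmocmr.R ptt      --pa pa.csv --la la.csv
Rscript inst/cli/pulmocmr.R flow     --arterial a.csv --venous v1.csv,v2.csv --hr 70
Rscript inst/cli/pulmocmr.R volume   --mask lung.nii --label lung
Rscript inst/cli/pulmocmr.R cohort-stats --cohort cohort.csv --metrics pbvi_pct,pbvv_sv_pct
```

Formats: NIfTI for image series and masks, CSV for flow/intensity curves and
cohort tables (`time_s,flow_ml_s` / `time_s,intensity_au` with labelled
comment headers), JSON for records, metrics and ground truth, YAML for the
pipeline configuration.

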