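# hfpefcmr

Contrast-free discrimination of heart failure with preserved ejection
fraction (HFpEF) is hard in obese and diabetic patients, because the
comorbidities themselves blur the imaging and biomarker signal. `hfpefcmr`
implements, as a tested R pipeline, the quantitative analysis chain used to
compare obese controls, obese T2DM patients, and obese HFpEF + T2DM
patients with cardiac magnetic resonance (CMR) and serum biomarkers:

* **Myocardial perfusion** — myocardial blood flow (MBF) from dual-bolus
  first-pass curves by Fermi model-constrained deconvolution. The tissue
  curve is modelled as the convolution of the (rescaled) arterial input
  function with a Fermi impulse response

  `R(t) = A / (exp((t − μ)/k) + 1)`,

  fitted by Levenberg–Marquardt least squares; MBF is the initial value
  `R(0)` and the myocardial perfusion reserve is `MPR = MBF_stress /
  MBF_rest`.
* **Diffuse fibrosis** — extracellular volume fraction from native and
  post-contrast T1 with hematocrit:

  `ECV = (1 − HCT) · (1/T1_myo_post − 1/T1_myo_native) /
  (1/T1_blood_post − 1/T1_blood_native)`.
* **Left atrial mechanics** — biplane area–length volumes
  (`V = 8/(3π)·A_2ch·A_4ch/L`) and phasic strain with the LV end-diastolic
  reference: reservoir = peak strain, booster = strain at the
  pre-atrial-contraction frame, conduit = reservoir − booster.
* **Cohort statistics** — one-way ANOVA with Tukey–Kramer post hoc tests,
  Pearson chi-squared, Pearson correlation (with log transform for skewed
  biomarkers), univariable and age/sex/BMI-adjusted logistic regression
  with Wald CIs and separation detection, ROC analysis with DeLong CIs and
  Youden-index operating points, ICC(2,1) test–retest reliability with
  Cicchetti bands, and an arrhythmia-exclusion sensitivity analysis.

Because the study's raw curves and contours are not public, a first-class
synthetic-data module generates every input from known ground truth —
gamma-variate bolus curves, T1 panels, LA length/area trajectories, and
group-structured cohorts with day-1/day-8 replicates — so each analysis
stage is validated by round-trip recovery.

## Worked example

```r
library(hfpefcmr)

# dual-bolus perfusion study with known flows, quantified by deconvolution
study <- synth_perfusion_study(
  rest   = tissue_gen_params(true_mbf = 1.0),
  stress = tissue_gen_params(true_mbf = 2.3),
  aif    = aif_params(onset_time = 10, amplitude = 1),
  seed   = 42)
res <- quantify_perfusion(study)
#> rest MBF   1.000 mL/g/min
#> stress MBF 2.300 mL/g/min
#> MPR        2.30

# ECV from a T1 panel
compute_ecv(t1_panel(t1_myo_native = 1200, t1_myo_post = 500,
                     t1_blood_native = 1800, t1_blood_post = 350,
                     hct = 0.42))
#> ECV 29.4 %

# LA phasic mechanics from a synthetic trajectory
la <- analyze_la_trajectory(
  synth_la_trajectory(reservoir_pct = 25, booster_pct = 12,
                      ref_length = 62))
#> LA reservoir/conduit/booster  25.0 / 13.0 / 12.0 %
#> LA volume min/max  49 / 96 mL

# cohort statistics on a study-conditions cohort (6 / 16 / 13 subjects)
cohort <- synth_cohort(study_group_specs(), study_retest_specs(), seed = 1)
subj <- average_across_visits(cohort)
subj$hfpef <- as.integer(subj$group == "hfpef_t2dm")

fit_logistic(subj, "hfpef", "la_max_volume")
#> LA max volume OR 1.04 (95% CI 1.01-1.08), p = 0.016

roc_analysis(subj$la_max_volume, subj$hfpef)
#> AUC 0.74 (0.57-0.92), Youden threshold 98 mL, sens 0.46 spec 0.95

d1 <- cohort[cohort$visit_day == 1, ]
d8 <- cohort[cohort$visit_day == 8, ]
d8 <- d8[match(d1$subject_id, d8$subject_id), ]
icc2(d1$mpr, d8$mpr)
#> MPR ICC(2,1) 0.93 (95% CI 0.87-0.96), excellent
```

The odds ratio per mL of LA maximum volume, the AUC of its ROC curve, and
the excellent perfusion-reserve reliability are single-cohort draws of the
quantities the study reports; `run_pipeline(pipeline_config(seed = 1),
out_dir = "report")` composes all stages end to end and writes the
characteristics, findings, regression, ROC and reliability tables plus a
machine-readable `results.json`.

A thin command-line front end over the same functions is installed at
`inst/cli/hfpefcmr.R` (`pipeline`, `synth`, `perfusion`, `ecv`, `la`,
`stats` subcommands).

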