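# lai — the Liver Aging Index in R

`lai` constructs and validates a **liver-specific biological age**, the
Liver Aging Index (LAI), from 13 routine noninvasive biomarkers: three
clinical measures (BMI, systolic and diastolic blood pressure), eight blood
biomarkers (glucose, total cholesterol, triglycerides, HDL-C, LDL-C, ALT,
AST, GGT), and two transient-elastography measures (fat attenuation
parameter, liver stiffness). It is aimed at epidemiologists and
hepatologists who want a mortality-anchored ("second generation") aging
clock for the liver in cohorts of adults aged 45–95, and at methodologists
who want the full construction reproducible and testable end to end.

## The model

Construction is a two-step procedure on a training cohort:

1. **Per-category LRE risk scores.** The biomarkers are grouped into four
   categories (clinical / metabolic / liver-enzyme / imaging). Within each
   category an elastic-net Cox regression is fitted with the liver-related
   event (LRE: hepatocellular carcinoma, variceal bleeding, ascites, hepatic
   failure or encephalopathy) as outcome, the penalty chosen by seeded
   10-fold cross-validation. Each subject gets four centered linear-predictor
   scores `s_c = β_c'z − m_c`.

2. **Cox–Gompertz mortality models.** On the *age* timescale with left
   truncation at entry, two Gompertz proportional-hazards models are fitted
   by maximum likelihood:
   a *null* model `h0(u) = exp(b0_s + γ_s u)` (chronological age and sex
   only) and a *full* model adding the risk scores,
   `h_liver(u) = exp(b0*_s + γ*_s u + β's)`. The null slope defines the
   sex-specific **mortality-rate doubling time**, `MRDT_s = ln 2 / γ_s`.
   Each subject's **liver aging acceleration** is the hazard ratio between
   the two models at their own age, converted into years of population
   aging:

   ```
   LAA = MRDT_s · log2( h_liver(CA) / h0(CA) )        [years]
   LAI = CA + LAA
   ```

   One hazard doubling equals one MRDT of acceleration. Subjects above the
   training-cohort LAA third quartile are classed *accelerated*, below the
   first quartile *decelerated*; validation cohorts always reuse the
   training thresholds.

A simplified five-marker variant (LAI-5: ALT, AST, GGT, FAP, LSM), fitted
fully stratified by sex, is available via `lai_feature_spec("lai5")`.

Because the cohorts this kind of index is built on are not freely
redistributable, the package ships a first-class synthetic cohort generator
(`simulate_cohort()`) with age-trending, correlated biomarkers, a latent
liver-aging factor, and closed-form Gompertz event sampling, so the entire
pipeline is runnable and testable offline.

## Worked example

```r
library(lai)
sim   <- simulate_cohort(sim_config(n = 10000, seed = 42))
model <- fit_lai(sim$cohort, seed = 1)
model
#> Liver Aging Index model (lai13)
#>   trained on n = 10000 ( 2468 deaths, 507 LREs )
#>   [ pooled ] MRDT: female=7.58 yr, male=7.59 yr
#>   training LAA mean -0.130 yr (SD 2.91); quartiles Q1=-2.08 Q3=1.86

valid <- simulate_cohort(sim_config(n = 3000, seed = 43))$cohort
head(predict(model, valid), 4)
#>   subject_id      age    sex        laa      lai        class
#> 1    S000001 60.71927 female -0.7003213 60.01894 intermediate
#> 2    S000002 84.19827   male  2.1967439 86.39501  accelerated
#> 3    S000003 54.47776 female -0.5662559 53.91151 intermediate
#> 4    S000004 64.89103   male  1.5541926 66.44522 intermediate

evaluate_lai(model, valid)
#> Liver Aging Index evaluation (n = 3000 )
#>   agreement with CA: r = 0.952, RMSE = 2.95 yr, MAE = 2.31 yr
#>   death (757 events): AUROC LAI 0.752 [0.732, 0.772] vs CA 0.740 (DeLong p = 0.0012); HR/SD 1.31 [1.22, 1.41]; log-rank chi2 = 43.7 (p = 3.76e-11)
#>   lre   (138 events): AUROC LAI 0.687 [0.644, 0.730] vs CA 0.630 (DeLong p = 9.03e-13); HR/SD 2.31 [1.94, 2.75]; log-rank chi2 = 58.2 (p = 2.34e-14)
#>   lrm   (27 events):  AUROC LAI 0.769 [0.681, 0.856] vs CA 0.742 (DeLong p = 0.0416); HR/SD 2.04 [1.38, 3.01]; log-rank chi2 = 8.2 (p = 0.0042)
```

Reading the output: the fitted null model says mortality doubles roughly
every 7.6 years; the index stays tightly aligned with chronological age
(r = 0.95, MAE ≈ 2.3 years) while discriminating mortality better than age
alone (paired DeLong p < 0.05); each standard deviation of liver aging
acceleration carries a 31% higher adjusted mortality hazard and a
2.3-fold LRE hazard; and the accelerated vs decelerated quartile classes
separate cleanly on Kaplan–Meier curves.

The same pipeline is scriptable from a shell:

```sh
exec/lai simulate --out cohort.csv --n 10000 --seed 42
exec/lai fit      --train cohort.csv --out bundle.json --seed 1
exec/lai apply    --bundle bundle.json --cohort cohort.csv --out scores.csv
exec/lai evaluate --bundle bundle.json --cohort cohort.csv --out report.json
```

Fitted models serialize to versioned JSON bundles
(`write_lai_bundle()` / `read_lai_bundle()`) that round-trip losslessly.

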