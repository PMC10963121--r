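# nawmstrata

Quantifies subtle FLAIR signal-intensity changes in **normal-appearing
white matter (NAWM)** in relation to **leukoaraiosis** burden, for
neuroimaging researchers studying cerebral small-vessel disease.
Leukoaraiosis (LKA) — white matter conspicuously hyperintense on FLAIR —
marks small-vessel disease, but damage is thought to extend into white
matter that still looks normal. If tissue free water accumulates
diffusely, NAWM FLAIR intensity should rise with lesion burden, and not
only next to visible lesions. This package implements the measurement
chain and statistics needed to test that, together with a synthetic
phantom cohort generator with known ground truth that all validations
run on.

## What it computes

Per subject (volumes in a common atlas space):

* **Calibration** — the LKA threshold is the splenium ROI sample mean
  + 6 SD (8–10 ROIs of 1 mm diameter); the CSF exclusion floor is the
  maximum over 6–8 ventricular CSF ROIs.
* **Masks** — white matter from a probability map (≥ 0.95, two erosions
  + one dilation, 6-connectivity); LKA by thresholding within a
  supplied outline; NAWM = (WM − LKA) minus sub-CSF voxels. For
  unilateral infarcts only the contralateral hemisphere is analysed and
  the LKA volume (LKA_V, cm³) is doubled.
* **Distance strata** — with D₀ the LKA mask and D_k its k-th recursive
  2D 8-connected dilation, stratum k = (D_k − D_{k−1}) ∩ NAWM,
  k = 1..5: the NAWM voxels at in-slice Chebyshev distance k from
  lesion borders.
* **NAWM_M** — mean FLAIR intensity per stratum, normalized to the
  splenium mean (dimensionless).

Per cohort: LKA_V quartiles (nearest-rank, ties low), one-way ANOVA of
NAWM_M across strata, univariate covariate screening (t/Wilcoxon,
Pearson/Spearman chosen by a Shapiro–Wilk check), and linear mixed
models with the **strata as the clustering variable**:

    nawm_m ~ lka_quartile + age_decades + hypertension + (1 | stratum)          # random intercepts
    nawm_m ~ lka_quartile + age_decades + hypertension + (1 + lka_quartile | stratum)  # + random slopes

fitted by REML for reporting, compared by ML AIC and a χ²₂
likelihood-ratio test, with Wald 95% CIs (estimate ± 1.96 SE), plus
per-quartile voxel maps of LKA frequency and mean normalized NAWM
intensity.

## Worked example

```r
library(nawmstrata)
cfg <- phantomConfig(seed = 11L)     # calibrated default synthetic cohort
report <- runCohort(cfg, nSubjects = 100)
report
```

```
CohortReport: 100 subjects analysed, 0 excluded; ANOVA F = 13.0 (p = 4.73e-10)
Model comparison (ML): AIC intercepts -2269.2 vs slopes -2265.3; LRT 0.093 on 2 df, p = 0.954
-- REML random intercepts --
Linear mixed model (REML) with random intercepts
  (Intercept)                    1.0613 (SE 0.0083, 95% CI 1.0450 to 1.0775)
  lka_quartile                   0.0215 (SE 0.0012, 95% CI 0.0191 to 0.0238)
  age_decades                    0.0090 (SE 0.0008, 95% CI 0.0074 to 0.0105)
  hypertension                  -0.0029 (SE 0.0024, 95% CI -0.0076 to 0.0017)
  logLik 1119.10, AIC -2226.2
-- REML random intercepts + slopes --
Linear mixed model (REML) with random intercepts and random slopes [boundary fit]
  (Intercept)                    1.0613 (SE 0.0086, 95% CI 1.0444 to 1.0781)
  lka_quartile                   0.0215 (SE 0.0012, 95% CI 0.0191 to 0.0239)
  ...
```

Reading this: each LKA_V quartile step raises mean normalized NAWM
intensity by ≈ 0.02 (the generator injects 0.025; measured-quartile
label noise from hemisphere doubling attenuates image-cohort estimates
slightly), each decade of age by ≈ 0.009, and hypertension has no
resolvable effect. The stratum means fall strictly with distance from
lesions (here 1.192, 1.182, 1.172, 1.162, 1.153 for strata 1–5), the
random-slopes model agrees with the random-intercepts model to well
within one SE, and the LRT finds no slope heterogeneity — the boundary
(singular) fit flag is expected with only five clusters. The
`[boundary fit]` message, exclusion log, tables, JSON summary and voxel
maps are all part of `writeCohortReport(report, dir)`.

A command-line wrapper is included:

```sh
Rscript inst/scripts/nawm_pipeline.R simulate --n 100 --out cohort/ --seed 7
Rscript inst/scripts/nawm_pipeline.R run-all  --n 100 --out results/ --seed 7
```

See `vignettes/nawm-distance-strata.Rmd` for the full methods account
(conventions, phantom design, numerical choices, limitations).

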