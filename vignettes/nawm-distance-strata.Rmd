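---
title: "Distance-stratified NAWM FLAIR intensity analysis: methods"
author: "nawmstrata authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-stratified NAWM FLAIR intensity analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nawmstrata)
```

## The scientific question

Leukoaraiosis (LKA) — conspicuous white-matter hyperintensity on FLAIR
MRI — is the visible face of cerebral small-vessel disease, but tissue
damage is thought to extend into white matter that still *looks* normal.
If free water accumulates diffusely in normal-appearing white matter
(NAWM), its FLAIR signal should be subtly elevated, more so in subjects
with a larger lesion burden, and the elevation should not be confined to
the voxels that happen to border visible lesions.

`nawmstrata` implements the full quantitative chain needed to test this:
calibrated lesion segmentation, conservative white-matter masking, NAWM
strata at increasing voxel distance from lesion borders,
splenium-normalized intensity metrics, and mixed-model inference over a
cohort. Because clinical cohorts of this kind are generally not shareable,
the package also ships a synthetic phantom cohort generator with known
ground truth, which is what every validation in the package runs on.

## Segmentation model

Per subject the pipeline consumes a FLAIR-like volume in a common atlas
space, a white-matter probability map, small ROI masks for the splenium
of the corpus callosum and the anterior horns of the lateral ventricles,
a generous outline containing all candidate lesions (the stand-in for a
human rater's outline), and covariates (age, hypertension, infarct
laterality).

**Calibration.** Two thresholds are derived from reference ROIs of 1 mm
diameter: the LKA threshold is the splenium sample mean plus 6 sample
standard deviations (denominator $n-1$; radiology software convention —
the choice is configuration, not inference), from 8–10 splenium ROIs;
the CSF exclusion floor is the maximum over 6–8 ventricular ROIs. An ROI
value is the mean of the voxels whose centres fall inside the
world-space sphere; on the default anisotropic clinical voxels
(0.75 × 0.75 × 3.5 mm) a 1-mm sphere contains exactly one voxel centre,
which is accepted and documented rather than interpolated. ROI placement
is seeded-uniform within the supplied mask with a non-overlap
constraint; explicit world-mm centres can be supplied to reproduce rater
behaviour. `oracleThresholds()` instead takes a known reference
mean/SD/CSF maximum — used for validation against phantom ground truth.

**Masks.** White matter: probability ≥ 0.95 (inclusive), restricted to
the supratentorial mask, then two erosions and one dilation with the
face-connectivity (6-neighbour) element — the most conservative 3D
choice on 3.5-mm slices, keeping mostly central white matter. LKA:
voxels of the outline with intensity ≥ LKA threshold and not below the
CSF floor. NAWM: (WM − LKA) minus voxels below the CSF floor. All
intensity thresholds keep a voxel at equality; "below X is excluded" is
read as strict `<`. Because both thresholds are derived from the same
image, every mask is invariant under global intensity rescaling.

**Hemisphere exclusion.** For subjects with a unilateral infarct only
the contralateral hemisphere is analysed and the single-hemisphere LKA
volume is doubled. Hemisphere membership is the sign of the world
x-coordinate of the voxel centre (a supplied label map can override);
exact-midline voxels belong to neither side.

## Distance strata

Strata are defined *only* through dilation counts: with $D_0$ the LKA
mask and $D_k$ its $k$-th recursive 2D 8-connected dilation, stratum
$k$ is $(D_k \setminus D_{k-1}) \cap \mathrm{NAWM}$, $k = 1..5$ —
equivalently the NAWM voxels at in-slice Chebyshev distance $k$ from
the nearest lesion voxel in the same slice. The 2D rule avoids vertical
partial-volume contamination across thick slices; no Euclidean or
geodesic distance transform is involved, and the tests hold the
implementation to an independent Chebyshev-distance oracle exactly.

Morphology border conventions are explicit and shared with the
brute-force test oracles: dilation ignores out-of-grid neighbours;
erosion counts them as background, so border voxels always erode. A
consequence worth stating: the textbook duality
$\mathrm{erode}(M) = \overline{\mathrm{dilate}(\overline{M})}$ holds on
this finite grid only when the complement is extended into a one-voxel
pad; the tests assert exactly that padded form.

## Metrics and models

NAWM intensity is normalized by the splenium reference mean, giving the
dimensionless NAWM~M~; per subject, the mean normalized intensity is
computed in each non-empty stratum (empty strata yield no row — a zero
would bias the models) plus a descriptive full-NAWM value. LKA volume
(cm³, count × voxel volume) is converted to cohort quartiles with
nearest-rank cut-points and ties going low; labels depend only on ranks.
Quartiles are computed on the analysis cohort after exclusions.

The cohort models mirror a standard reporting layout:

* one-way ANOVA of NAWM~M~ across the five strata (subjects as
  replicates, as printed — not a repeated-measures ANOVA; with shared
  subject effects the p-values are conservative);
* univariate screening of covariates against subject-level NAWM~M~
  (t-test vs Wilcoxon for binary covariates, Pearson vs Spearman for
  quantitative ones, switched by a per-group Shapiro–Wilk check at
  α = 0.05, configurable);
* linear mixed models `nawm_m ~ lka_quartile + age_decades +
  hypertension` with the *strata* as the clustering variable: random
  intercepts, or random intercepts plus random slopes on the quartile
  term. The quartile enters as a numeric 1–4 regressor (one "per
  quartile increase" coefficient; coding 1–4 rather than 0–3 shifts
  only the intercept); age enters as age/10 so the coefficient reads
  per decade.

Inference is Wald (estimate ± 1.96 SE) — appropriate at these cohort
sizes and stated so results are reproducible; no Satterthwaite
correction. Model comparison fits both models by ML and refers
$2\,\Delta\log L$ to $\chi^2_2$ (slope variance + intercept–slope
covariance); at the variance boundary this is conservative. Reported
models are REML refits; REML log-likelihoods are never compared across
models. With only five clusters the random-effect variances are weakly
identified: singular (boundary) fits are flagged and messaged, not
hidden, and the structure is reproduced as designed rather than
"fixed". The descriptive full-NAWM row is not entered as a sixth
cluster, since it contains the strata and would double-count voxels.

## The phantom generator

`phantomConfig()` / `generateSubject()` build a minimal atlas-space
anatomy in which every downstream mask operation is non-trivial: an
in-plane elliptical brain with a rim excluded from white matter, paired
ventricular CSF ellipsoids near the grid centre, a posterior midline
splenium block, and random ellipsoidal lesions confined to the WM
compartment with a periventricular placement bias. Intensities are
arbitrary units; only ratios to the splenium mean are meaningful.

NAWM voxel intensities follow a closed form (`phantomNawmM()`):

$$ I = \mathrm{wmBase} + s\,\big(\beta_q\,\mathrm{level} +
   \delta\,(6-d)_+ + \beta_a\,(\mathrm{age}/10 - 6.8)\big) + \epsilon $$

with $s$ the splenium mean, $d$ the in-slice Chebyshev distance to the
nearest lesion (capped at 5), and $\epsilon$ Gaussian noise. Defaults
are the package's reference conditions: a NAWM/splenium ratio near
1.15, $\beta_q = 0.025$ per burden quartile, $\delta = 0.01$ per voxel
of proximity, $\beta_a = 0.011$ per decade, ages Normal(68, 16)
correlated 0.45 with burden through a Gaussian copula, 68% hypertension
prevalence, and unilateral infarcts in 55% of subjects (31% left, 24%
right; posterior-fossa infarcts count as "none" for hemisphere
exclusion).

Design choices that matter for interpretation:

* **Two random streams per subject** (geometry vs noise), so noise can
  be toggled without moving the anatomy. The splenium texture and CSF
  variability live on the noise stream and vanish with `noiseSd = 0`:
  a "noise-free" phantom is exactly piecewise constant, which is what
  makes bit-exact recovery testable.
* **Burden bands.** Each burden level 1–4 draws a target total lesion
  volume from one of four disjoint bands; lesions are added until the
  union reaches the target, so realized volumes land within a band
  whose gaps exceed the largest single lesion. Empirical LKA-volume
  quartiles of a balanced cohort therefore reproduce the intended
  levels (hemisphere doubling adds label noise near boundaries, a
  genuine property of the doubling rule, visible as mild attenuation
  of fitted quartile effects on image cohorts).
* **Lesion brightness** is set far above the splenium mean + 6 SD, so
  segmentation with correctly calibrated thresholds always captures
  lesions; conversely the bright NAWM halo inside the generous outline
  *can* cross an under-estimated ROI threshold — real threshold
  contamination of stratum 1, which the 2D-distance design exists to
  expose, not a bug.
* With ROI calibration on a noise-free phantom the sampled splenium SD
  is 0 and the threshold collapses to the splenium mean, so exact-
  recovery validations use `calibration = "oracle"` (the generator's
  known mean/SD), and infarct-free subjects (hemisphere exclusion
  rebuilds strata from one-sided LKA while the generator's proximity
  field sees all lesions, shifting stratum values near the midline by
  construction).

What the phantom does **not** emulate: realistic anatomy, bias fields,
registration error, scanner physics, non-uniformity correction. Passing
tests demonstrate correctness of the measurement chain and calibration
of the statistics under the stated generative model — not performance
on real MRI.

A second, table-level simulator (`simulateStratumTable()`) draws
subject × stratum observation rows directly from the mixed-model
generative structure. It exists because parameter-recovery, coverage and
power studies need hundreds of replicated cohorts, where rendering
volumes adds cost but no information: the image pipeline is validated
end-to-end separately, and the two meet in the closed form above. Its
default residual SD of 0.075 was chosen analytically so that at
100 subjects × 5 strata the Wald SE of the quartile effect is ≈ 0.003
(`SE = σ /(\sqrt{n}\,\mathrm{sd}(q)\sqrt{1-R^2})`), the reference
reporting scale.

## Numerical and degenerate-input conventions

* Quartiles: nearest-rank percentiles, ties low; all-identical volumes
  are a warned degeneracy (all labelled 1). Fewer than 4 subjects is an
  error; cohorts require ≥ 8 survivors.
* Empty masks: an empty outline is a valid lesion-free subject; an
  empty WM mask after morphology is a warning and the subject is
  excluded from the cohort with a logged reason; an empty stratum emits
  no observation row.
* Mixed models: lme4 with its default optimizer; the advisory post-hoc
  gradient warnings are muffled (hard optimizer failure still raises),
  singular fits are flagged via `isSingular`. The LRT statistic is
  clipped at 0 within optimizer tolerance.
* Determinism: every stochastic step (ROI placement, lesion geometry,
  noise, covariates) is seeded through one integer mixing function;
  identical seeds give bit-identical masks and byte-identical JSON
  summaries.

## Problem sizes used in the shipped validations

The test-suite and the acceptance script validate on 16 × 16 × 8 random
masks (100 replicates) for morphology parity, 36 × 42 × 8 phantoms for
per-subject pipeline properties, one 48 × 56 × 12 default cohort of 100
subjects end-to-end, and 200 replicated table-level cohorts
(100 × 5 rows) for recovery, coverage, LRT and ANOVA calibration. These
sizes were chosen as the smallest at which every geometric feature
(rings, hemispheres, periventricular shells) and every statistical
property (SE ≈ 0.003 scale) is non-trivially exercised.

## Known limitations

* The strata metric is in-slice Chebyshev distance; no 3D or geodesic
  variant is provided, by design.
* Clustering on five strata leaves random-effect variances weakly
  identified; the package reproduces that structure faithfully and
  flags boundary fits rather than re-parameterizing.
* Lesion counts/shapes in the generator are stand-ins, not estimates of
  any population; no public data exist to fit them.
* The univariate screen's normality rule (Shapiro–Wilk at 0.05) is one
  reasonable operationalization of "as appropriate"; it is exposed as a
  parameter rather than asserted as the only choice.

## A minimal session

```{r example, eval = FALSE}
cfg <- phantomConfig(seed = 11L)
report <- runCohort(cfg, nSubjects = 100)
report                      # ANOVA, model comparison
fixedEffects(report@lmmIntercepts)
randomEffects(report@lmmSlopes)
writeCohortReport(report, "cohort_out")
```
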