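#' @import methods
NULL

#' BrainVolume: a 3D scalar image in atlas space
#'
#' Dense 3D scalar grid with a 4x4 voxel-to-world affine (RAS+ convention;
#' +x = subject right) and voxel dimensions in mm. Used for FLAIR-like
#' intensity volumes and tissue probability maps.
#'
#' @slot data 3D numeric array of voxel values.
#' @slot affine 4x4 numeric voxel-to-world transform. Maps 1-based voxel
#'   indices (i, j, k) to world mm via \code{affine \%*\% c(i, j, k, 1)}.
#' @slot voxelDims numeric length-3, voxel edge lengths in mm.
#' @export
setClass("BrainVolume",
  representation(data = "array", affine = "matrix", voxelDims = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (length(dim(object@data)) != 3L)
      msgs <- c(msgs, "data must be a 3D array")
    if (!all(dim(object@affine) == c(4L, 4L)))
      msgs <- c(msgs, "affine must be 4x4")
    if (length(object@voxelDims) != 3L || any(object@voxelDims <= 0))
      msgs <- c(msgs, "voxelDims must be 3 positive lengths (mm)")
    if (length(msgs)) msgs else TRUE
  }
)

#' BrainMask: a binary region sharing a BrainVolume's geometry
#'
#' @slot data 3D logical array.
#' @export
setClass("BrainMask", contains = "BrainVolume",
  validity = function(object) {
    if (!is.logical(object@data)) "mask data must be logical" else TRUE
  }
)

#' StructuringElement: neighbour offsets for binary morphology
#'
#' Two conventions are supported: \code{in_plane_8}, the 8 in-slice
#' neighbours (all offsets with |di|, |dj| <= 1, dk = 0, excluding the
#' centre), used for the 2D recursive dilations that define the NAWM
#' distance strata; and \code{cross_3d_6}, the 6 face neighbours, used for
#' the conservative white-matter mask erosion/dilation.
#'
#' @slot kind character, one of \code{"in_plane_8"}, \code{"cross_3d_6"}.
#' @slot offsets integer matrix (n x 3) of neighbour offsets.
#' @export
setClass("StructuringElement",
  representation(kind = "character", offsets = "matrix"),
  validity = function(object) {
    if (!object@kind %in% c("in_plane_8", "cross_3d_6"))
      return("kind must be 'in_plane_8' or 'cross_3d_6'")
    if (ncol(object@offsets) != 3L) return("offsets must be n x 3")
    TRUE
  }
)

#' ROISample: intensities sampled from small spherical ROIs
#'
#' Holds the per-ROI mean intensities obtained from 1-mm-diameter regions
#' of interest placed within a reference structure (splenium of the corpus
#' callosum, or anterior horn of the lateral ventricles).
#'
#' @slot values numeric, one mean intensity per ROI (arbitrary units).
#' @slot source character, \code{"splenium"} or \code{"ventricle"}.
#' @slot diameterMm numeric ROI diameter in mm (default 1).
#' @slot centresMm numeric matrix (n x 3) of ROI centres in world mm.
#' @export
setClass("ROISample",
  representation(values = "numeric", source = "character",
                 diameterMm = "numeric", centresMm = "matrix"),
  validity = function(object) {
    n <- length(object@values)
    if (n == 0L) return("values must be non-empty")
    if (!object@source %in% c("splenium", "ventricle"))
      return("source must be 'splenium' or 'ventricle'")
    rng <- if (object@source == "splenium") c(8L, 10L) else c(6L, 8L)
    if (n < rng[1] || n > rng[2])
      return(sprintf("%s samples use %d-%d ROIs, got %d",
                     object@source, rng[1], rng[2], n))
    TRUE
  }
)

#' CalibrationThresholds: the two intensity thresholds driving segmentation
#'
#' The leukoaraiosis threshold is the splenium ROI mean plus 6 standard
#' deviations (sample SD, denominator n-1); the CSF exclusion floor is the
#' maximum of the ventricular CSF ROI sample.
#'
#' @slot spleniumMean numeric, splenium reference mean intensity (a.u.).
#' @slot spleniumSd numeric, splenium reference SD (a.u.).
#' @slot lkaThreshold numeric, spleniumMean + 6 * spleniumSd.
#' @slot csfMax numeric, maximum ventricular CSF intensity (a.u.).
#' @export
setClass("CalibrationThresholds",
  representation(spleniumMean = "numeric", spleniumSd = "numeric",
                 lkaThreshold = "numeric", csfMax = "numeric"),
  validity = function(object) {
    if (!isTRUE(all.equal(object@lkaThreshold,
                          object@spleniumMean + 6 * object@spleniumSd)))
      return("lkaThreshold must equal spleniumMean + 6 * spleniumSd")
    TRUE
  }
)

#' SegmentationResult: per-subject leukoaraiosis / WM / NAWM masks
#'
#' @slot lkaMask BinaryMask of leukoaraiosis.
#' @slot wmMask conservative white-matter mask.
#' @slot nawmMask normal-appearing white matter (WM minus LKA minus
#'   sub-CSF voxels).
#' @slot lkaVolumeCm3 numeric, total leukoaraiosis volume in cm^3 (doubled
#'   when measured from a single hemisphere).
#' @slot hemisphereExcluded character, \code{"none"}, \code{"left"} or
#'   \code{"right"}: the side removed from analysis (the infarct side).
#' @slot thresholds CalibrationThresholds used.
#' @export
setClass("SegmentationResult",
  representation(lkaMask = "BrainMask", wmMask = "BrainMask",
                 nawmMask = "BrainMask", lkaVolumeCm3 = "numeric",
                 hemisphereExcluded = "character",
                 thresholds = "CalibrationThresholds"),
  validity = function(object) {
    msgs <- character()
    if (any(object@lkaMask@data & object@nawmMask@data))
      msgs <- c(msgs, "LKA and NAWM masks must be disjoint")
    if (any(object@nawmMask@data & !object@wmMask@data))
      msgs <- c(msgs, "NAWM must be a subset of the WM mask")
    if (!object@hemisphereExcluded %in% c("none", "left", "right"))
      msgs <- c(msgs, "hemisphereExcluded must be none/left/right")
    if (length(msgs)) msgs else TRUE
  }
)

#' StrataSet: NAWM strata at increasing in-slice voxel distance from LKA
#'
#' Stratum k holds the NAWM voxels whose in-slice Chebyshev (8-connected)
#' distance to the nearest leukoaraiosis voxel in the same slice equals k,
#' built by k recursive 2D dilations of the LKA mask.
#'
#' @slot strata list of BrainMask, index k = voxel distance.
#' @slot fullNawm BrainMask, the full NAWM region.
#' @export
setClass("StrataSet",
  representation(strata = "list", fullNawm = "BrainMask"),
  validity = function(object) {
    if (!all(vapply(object@strata, is, logical(1), class2 = "BrainMask")))
      return("strata must all be BrainMask")
    TRUE
  }
)

#' PhantomConfig: parameters of the synthetic atlas-space cohort generator
#'
#' Defines the phantom geometry (grid, anisotropic clinical voxels), the
#' compartment intensities in arbitrary units (only ratios to the splenium
#' mean are meaningful), the injected effects (diffuse NAWM elevation per
#' leukoaraiosis burden quartile, proximity elevation decaying with voxel
#' distance from lesions, age effect per decade), lesion placement, noise,
#' and the cohort covariate model.
#'
#' @slot gridShape integer length-3 grid dimensions (voxels).
#' @slot voxelDimsMm numeric length-3 voxel size, default 0.75 x 0.75 x 3.5.
#' @slot wmBaseIntensity numeric baseline WM intensity (a.u.).
#' @slot spleniumIntensityMean numeric splenium mean (a.u.).
#' @slot spleniumIntensitySd numeric splenium texture SD (a.u.).
#' @slot csfIntensityMax numeric upper bound of CSF intensity (a.u.).
#' @slot lesionIntensity numeric lesion intensity (a.u.), must exceed
#'   spleniumIntensityMean + 6 * spleniumIntensitySd.
#' @slot lesionCountRange integer length-2, allowed lesions per subject.
#' @slot lesionRadiusRangeMm numeric length-2 in-plane semi-axis range, mm.
#' @slot burdenBandsCm3 4 x 2 matrix of disjoint target lesion-volume bands
#'   (cm^3) for burden levels 1-4.
#' @slot burdenEffectPerQuartile numeric, NAWM elevation per burden level in
#'   splenium-normalized units.
#' @slot distanceDecayPerVoxel numeric >= 0, extra normalized elevation per
#'   voxel of proximity to lesions (applies at in-slice distance 1..5).
#' @slot noiseSd numeric additive Gaussian noise SD (a.u.); 0 gives an
#'   exactly piecewise-constant phantom.
#' @slot ageEffectPerDecade numeric NAWM elevation per decade of age
#'   (normalized units), centred at age 68.
#' @slot ageBurdenCorrelation numeric in [0, 1), Gaussian-copula weight
#'   linking age to burden level.
#' @slot hypertensionPrevalence numeric in [0, 1].
#' @slot infarctSideProbs named numeric (none/left/right) summing to 1.
#' @slot periventricularBias numeric in [0, 1], probability a lesion is
#'   seeded in the periventricular shell.
#' @slot seed integer cohort-level seed.
#' @export
setClass("PhantomConfig",
  representation(gridShape = "integer", voxelDimsMm = "numeric",
    wmBaseIntensity = "numeric", spleniumIntensityMean = "numeric",
    spleniumIntensitySd = "numeric", csfIntensityMax = "numeric",
    lesionIntensity = "numeric", lesionCountRange = "integer",
    lesionRadiusRangeMm = "numeric", burdenBandsCm3 = "matrix",
    burdenEffectPerQuartile = "numeric", distanceDecayPerVoxel = "numeric",
    noiseSd = "numeric", ageEffectPerDecade = "numeric",
    ageBurdenCorrelation = "numeric", hypertensionPrevalence = "numeric",
    infarctSideProbs = "numeric", periventricularBias = "numeric",
    seed = "integer"),
  validity = function(object) {
    msgs <- character()
    if (object@csfIntensityMax >= object@wmBaseIntensity)
      msgs <- c(msgs, "csfIntensityMax must be below wmBaseIntensity")
    if (object@lesionIntensity <=
        object@spleniumIntensityMean + 6 * object@spleniumIntensitySd)
      msgs <- c(msgs, "lesionIntensity must exceed splenium mean + 6 SD")
    if (object@lesionCountRange[1] > object@lesionCountRange[2] ||
        object@lesionRadiusRangeMm[1] > object@lesionRadiusRangeMm[2])
      msgs <- c(msgs, "ranges must be non-empty (lo <= hi)")
    if (object@distanceDecayPerVoxel < 0)
      msgs <- c(msgs, "distanceDecayPerVoxel must be >= 0")
    if (!all(dim(object@burdenBandsCm3) == c(4L, 2L)) ||
        any(diff(as.vector(t(object@burdenBandsCm3))) <= 0))
      msgs <- c(msgs, "burdenBandsCm3 must be 4 increasing disjoint bands")
    if (abs(sum(object@infarctSideProbs) - 1) > 1e-8)
      msgs <- c(msgs, "infarctSideProbs must sum to 1")
    if (length(msgs)) msgs else TRUE
  }
)

#' SubjectBundle: one phantom subject's volumes, masks and covariates
#'
#' @slot flair BrainVolume, FLAIR-like intensity volume.
#' @slot wmProbability BrainVolume in [0, 1], WM probability map.
#' @slot spleniumMask BrainMask for splenium ROI sampling.
#' @slot ventricleMask BrainMask for ventricular CSF ROI sampling.
#' @slot outlineMask BrainMask, generous outline containing all lesions
#'   (stands in for the manual rater's outline).
#' @slot supratentorialMask BrainMask restricting analysis to
#'   supratentorial slices.
#' @slot hemisphereMap 3D integer array: -1 left, +1 right, 0 midline.
#' @slot truthLesionMask BrainMask, ground-truth lesions.
#' @slot covariates data.frame with subject_id, age, hypertension,
#'   infarct_side, truth_burden_level, seed.
#' @export
setClass("SubjectBundle",
  representation(flair = "BrainVolume", wmProbability = "BrainVolume",
    spleniumMask = "BrainMask", ventricleMask = "BrainMask",
    outlineMask = "BrainMask", supratentorialMask = "BrainMask",
    hemisphereMap = "array", truthLesionMask = "BrainMask",
    covariates = "data.frame"),
  validity = function(object) {
    msgs <- character()
    if (any(object@truthLesionMask@data & !object@outlineMask@data))
      msgs <- c(msgs, "truth lesions must lie within the outline mask")
    if (any(object@spleniumMask@data & object@ventricleMask@data))
      msgs <- c(msgs, "splenium and ventricle masks must be disjoint")
    if (length(msgs)) msgs else TRUE
  }
)

#' LMMResult: a fitted linear mixed model of NAWM intensity
#'
#' Fixed effects with Wald standard errors and 95\% confidence intervals
#' (estimate +/- 1.96 SE), per-stratum random-effect estimates (conditional
#' modes), variance components, log-likelihood and AIC.
#'
#' @slot fixedEffects data.frame: term, estimate, se, ci_lo, ci_hi.
#' @slot randomEffects data.frame: stratum, intercept deviation, combined
#'   intercept, and (when present) slope deviation and combined slope.
#' @slot varianceComponents data.frame from \code{lme4::VarCorr}.
#' @slot logLik numeric.
#' @slot aic numeric, 2k - 2 logLik.
#' @slot method character, "ML" or "REML".
#' @slot hasRandomSlopes logical.
#' @slot singular logical, TRUE for a boundary (singular) fit.
#' @slot fit the underlying \code{merMod} object.
#' @export
setClass("LMMResult",
  representation(fixedEffects = "data.frame", randomEffects = "data.frame",
    varianceComponents = "data.frame", logLik = "numeric", aic = "numeric",
    method = "character", hasRandomSlopes = "logical",
    singular = "logical", fit = "ANY"))

#' ModelComparison: random-intercepts vs random-slopes model comparison
#'
#' Both models are fitted by maximum likelihood on identical rows; the
#' likelihood-ratio statistic is referred to a chi-squared distribution
#' with 2 degrees of freedom (slope variance + intercept-slope covariance),
#' which is conservative at the variance boundary. REML refits are carried
#' for reporting.
#'
#' @slot aicIntercepts numeric, ML AIC of the random-intercepts model.
#' @slot aicSlopes numeric, ML AIC of the random-slopes model.
#' @slot lrtStatistic numeric.
#' @slot lrtDf integer.
#' @slot lrtP numeric.
#' @slot remlIntercepts LMMResult (REML refit).
#' @slot remlSlopes LMMResult (REML refit).
#' @export
setClass("ModelComparison",
  representation(aicIntercepts = "numeric", aicSlopes = "numeric",
    lrtStatistic = "numeric", lrtDf = "integer", lrtP = "numeric",
    remlIntercepts = "LMMResult", remlSlopes = "LMMResult"))

#' CohortReport: cohort-level analysis outputs
#'
#' @slot subjectTable data.frame, one row per analysed subject.
#' @slot stratumTable data.frame, one row per subject x non-empty stratum.
#' @slot anova list with F, p, df for the stratum ANOVA.
#' @slot univariate data.frame of univariate screening results.
#' @slot lmmIntercepts LMMResult (REML, random intercepts).
#' @slot lmmSlopes LMMResult (REML, random intercepts + slopes).
#' @slot comparison ModelComparison.
#' @slot lkaFrequencyMaps list (by quartile) of integer voxel count arrays.
#' @slot nawmMeanMaps list (by quartile) of mean normalized-intensity
#'   arrays (NA where no subject contributes).
#' @slot exclusions data.frame: subject_id, reason.
#' @export
setClass("CohortReport",
  representation(subjectTable = "data.frame", stratumTable = "data.frame",
    anova = "list", univariate = "data.frame",
    lmmIntercepts = "LMMResult", lmmSlopes = "LMMResult",
    comparison = "ModelComparison", lkaFrequencyMaps = "list",
    nawmMeanMaps = "list", exclusions = "data.frame"))
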