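# Synthetic atlas-space phantom cohort generator.
#
# The phantom is a minimal geometry that makes every downstream mask
# operation non-trivial: an in-plane elliptical brain with a grey-matter
# rim, paired ventricular CSF ellipsoids near the grid centre, a posterior
# midline splenium block, and random ellipsoidal lesions confined to the
# white-matter compartment with a configurable periventricular placement
# bias. Intensities are arbitrary units; only ratios to the splenium mean
# are meaningful.
#
# Two independent random streams are used per subject: a geometry stream
# (lesion placement) and a noise stream (voxel noise and CSF/splenium
# texture), so noise can be toggled without changing anatomy. With
# noiseSd = 0 the phantom is exactly piecewise constant.

#' Construct a PhantomConfig
#'
#' Defaults emulate the study conditions the analysis assumes: anisotropic
#' 0.75 x 0.75 x 3.5 mm clinical FLAIR voxels; an NAWM-to-splenium
#' intensity ratio near 1.15; a diffuse NAWM elevation of 0.025 normalized
#' units per leukoaraiosis burden quartile and 0.011 per decade of age; a
#' mild proximity elevation decaying with in-slice voxel distance from
#' lesions; ages Normal(68, 16) positively correlated with burden; 68%
#' hypertension prevalence; and unilateral infarcts in 55% of subjects
#' (31% left, 24% right).
#'
#' @param gridShape integer length-3, default \code{c(48, 56, 12)}.
#' @param voxelDimsMm numeric length-3, default \code{c(0.75, 0.75, 3.5)}.
#' @param wmBaseIntensity baseline WM intensity, a.u. (default 108).
#' @param spleniumIntensityMean splenium mean, a.u. (default 100).
#' @param spleniumIntensitySd splenium texture SD, a.u. (default 6).
#' @param csfIntensityMax CSF intensity ceiling, a.u. (default 40).
#' @param lesionIntensity lesion intensity, a.u. (default 190; must exceed
#'   splenium mean + 6 SD by construction).
#' @param lesionCountRange allowed lesions per subject (default 1-120).
#' @param lesionRadiusRangeMm in-plane semi-axis range (default 1.5-3 mm).
#' @param burdenBandsCm3 disjoint target lesion-volume bands per burden
#'   level, cm^3.
#' @param burdenEffectPerQuartile normalized NAWM elevation per burden
#'   level (default 0.025).
#' @param distanceDecayPerVoxel extra normalized elevation per voxel of
#'   proximity to lesions, applied at in-slice distance d = 1..5 as
#'   (6 - d) x this value (default 0.01).
#' @param noiseSd additive Gaussian noise SD, a.u. (default 2).
#' @param ageEffectPerDecade normalized NAWM elevation per decade of age,
#'   centred at 68 years (default 0.011).
#' @param ageBurdenCorrelation Gaussian-copula weight in [0, 1) linking
#'   age to burden level (default 0.45).
#' @param hypertensionPrevalence default 0.68.
#' @param infarctSideProbs named probabilities for none/left/right
#'   (default 0.45/0.31/0.24).
#' @param periventricularBias probability a lesion seeds in the
#'   periventricular shell (default 0.6).
#' @param seed cohort-level integer seed.
#' @return a \linkS4class{PhantomConfig}
#' @export
phantomConfig <- function(gridShape = c(48L, 56L, 12L),
    voxelDimsMm = c(0.75, 0.75, 3.5),
    wmBaseIntensity = 108, spleniumIntensityMean = 100,
    spleniumIntensitySd = 6, csfIntensityMax = 40, lesionIntensity = 190,
    lesionCountRange = c(1L, 120L), lesionRadiusRangeMm = c(1.5, 3.0),
    burdenBandsCm3 = matrix(c(0.15, 0.45, 0.70, 1.00,
                              1.30, 1.70, 2.10, 2.60),
                            nrow = 4, ncol = 2, byrow = TRUE),
    burdenEffectPerQuartile = 0.025, distanceDecayPerVoxel = 0.01,
    noiseSd = 2, ageEffectPerDecade = 0.011, ageBurdenCorrelation = 0.45,
    hypertensionPrevalence = 0.68,
    infarctSideProbs = c(none = 0.45, left = 0.31, right = 0.24),
    periventricularBias = 0.6, seed = 1L) {
  new("PhantomConfig", gridShape = as.integer(gridShape),
      voxelDimsMm = as.numeric(voxelDimsMm),
      wmBaseIntensity = wmBaseIntensity,
      spleniumIntensityMean = spleniumIntensityMean,
      spleniumIntensitySd = spleniumIntensitySd,
      csfIntensityMax = csfIntensityMax, lesionIntensity = lesionIntensity,
      lesionCountRange = as.integer(lesionCountRange),
      lesionRadiusRangeMm = as.numeric(lesionRadiusRangeMm),
      burdenBandsCm3 = burdenBandsCm3,
      burdenEffectPerQuartile = burdenEffectPerQuartile,
      distanceDecayPerVoxel = distanceDecayPerVoxel, noiseSd = noiseSd,
      ageEffectPerDecade = ageEffectPerDecade,
      ageBurdenCorrelation = ageBurdenCorrelation,
      hypertensionPrevalence = hypertensionPrevalence,
      infarctSideProbs = infarctSideProbs,
      periventricularBias = periventricularBias, seed = as.integer(seed))
}

# Deterministic anatomical compartments (no randomness).
phantomGeometry <- function(config) {
  d <- config@gridShape
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  i <- slice.index(array(0, d), 1)
  j <- slice.index(array(0, d), 2)
  k <- slice.index(array(0, d), 3)
  brain <- ((i - cx) / (0.46 * d[1]))^2 + ((j - cy) / (0.46 * d[2]))^2 <= 1
  supra <- k >= 2L
  el8 <- structuringElement("in_plane_8")
  tmp <- brainMask(brain, voxelDims = config@voxelDimsMm)
  interior <- erodeMask(erodeMask(tmp, el8), el8)@data
  rim <- brain & !interior
  zmid <- max(2L, floor(d[3] / 2) - 1L)
  zv <- k >= zmid & k <= min(d[3] - 1L, zmid + 3L)
  vent <- rep(FALSE, length(i)); dim(vent) <- d
  for (sgn in c(-1, 1)) {
    vcx <- cx + sgn * 6
    vent <- vent |
      (((i - vcx) / 2.8)^2 + ((j - (cy + 5)) / 5.5)^2 <= 1 & zv)
  }
  splenium <- abs(i - cx) <= 3 & j >= cy - 15 & j <= cy - 9 & zv
  vent <- vent & !splenium
  core <- brainMask(vent | splenium, voxelDims = config@voxelDimsMm)
  margin <- dilateMask(core, structuringElement("cross_3d_6"))@data &
    !(vent | splenium)
  wmComp <- interior & supra & !vent & !splenium & !margin
  prob <- array(0, d)
  prob[rim | margin] <- 0.5
  prob[wmComp] <- 0.97
  list(brain = brain, rim = rim, vent = vent, splenium = splenium,
       margin = margin, wmComp = wmComp, supra = supra, prob = prob)
}

# Place random ellipsoidal lesions until the union volume enters the
# burden band. Geometry-stream RNG must be active when called.
placeLesions <- function(config, geom) {
  d <- config@gridShape
  vd <- config@voxelDimsMm
  voxCm3 <- prod(vd) / 1000
  band <- config@burdenBandsCm3[, , drop = TRUE]
  wmCore <- erodeMask(brainMask(geom$wmComp, voxelDims = vd),
                      structuringElement("in_plane_8"))@data
  shell <- dilateMask(dilateMask(
    dilateMask(dilateMask(brainMask(geom$vent, voxelDims = vd)),
               structuringElement("in_plane_8")),
    structuringElement("in_plane_8")), structuringElement("in_plane_8"))@data
  shell <- shell & wmCore
  coreIdx <- which(wmCore, arr.ind = TRUE)
  shellIdx <- which(shell, arr.ind = TRUE)
  if (nrow(coreIdx) < 10L)
    stop(sprintf(
      "grid %s too small: white-matter core has only %d voxels for lesion placement",
      paste(d, collapse = "x"), nrow(coreIdx)))
  i <- slice.index(array(0, d), 1)
  j <- slice.index(array(0, d), 2)
  k <- slice.index(array(0, d), 3)
  function(level) {
    lo <- config@burdenBandsCm3[level, 1]
    hi <- config@burdenBandsCm3[level, 2]
    target <- stats::runif(1, lo, hi)
    lesion <- array(FALSE, d)
    count <- 0L
    attempts <- 0L
    # add lesions until the union volume reaches the drawn target; the
    # realized volume lands in [target, target + one lesion), and the
    # inter-band gaps exceed the largest single lesion, so levels stay
    # strictly ordered
    while (sum(lesion) * voxCm3 < target) {
      attempts <- attempts + 1L
      if (attempts > 2000L || count >= config@lesionCountRange[2])
        stop(sprintf(
          "cannot reach burden band [%.2f, %.2f] cm^3 for level %d within %d lesions: grid or WM compartment too small",
          lo, hi, level, config@lesionCountRange[2]))
      pool <- if (nrow(shellIdx) > 0 &&
                  stats::runif(1) < config@periventricularBias)
        shellIdx else coreIdx
      ctr <- pool[sample.int(nrow(pool), 1L), ]
      ab <- stats::runif(2, config@lesionRadiusRangeMm[1],
                         config@lesionRadiusRangeMm[2]) / vd[1:2]
      cz <- stats::runif(1, 0.52 * vd[3], 1.2 * vd[3]) / vd[3]
      ell <- ((i - ctr[1]) / ab[1])^2 + ((j - ctr[2]) / ab[2])^2 +
        ((k - ctr[3]) / cz)^2 <= 1
      add <- ell & geom$wmComp
      if (!any(add)) next
      lesion <- lesion | add
      count <- count + 1L
    }
    lesion
  }
}

# In-slice proximity weight to the lesion mask: (6 - d) for Chebyshev
# distance d = 1..5 in the same slice, 0 beyond (and 0 on lesions).
lesionProximity <- function(lesionArr, voxelDims) {
  prox <- array(0, dim(lesionArr))
  el <- structuringElement("in_plane_8")
  prev <- brainMask(lesionArr, voxelDims = voxelDims)
  for (dist in 1:5) {
    cur <- dilateMask(prev, el)
    prox[cur@data & !prev@data] <- 6 - dist
    prev <- cur
  }
  prox
}

#' Closed-form normalized NAWM intensity of a noise-free phantom
#'
#' The value every NAWM voxel of stratum \code{k} takes when
#' \code{noiseSd = 0}: wmBase/spleniumMean + burdenEffect x level +
#' distanceDecay x (6 - k) + ageEffect x (age/10 - 6.8). \code{k = Inf}
#' (or any k > 5) gives the value beyond the five proximity strata.
#'
#' @param config a PhantomConfig
#' @param burdenLevel burden level 1-4
#' @param age age in years
#' @param k stratum index (in-slice voxel distance from lesions)
#' @return numeric normalized intensity
#' @export
phantomNawmM <- function(config, burdenLevel, age, k) {
  prox <- pmax(0, 6 - k)
  config@wmBaseIntensity / config@spleniumIntensityMean +
    config@burdenEffectPerQuartile * burdenLevel +
    config@distanceDecayPerVoxel * prox +
    config@ageEffectPerDecade * (age / 10 - 6.8)
}

#' Generate one phantom subject
#'
#' Deterministic given \code{(config@@seed, subjectSeed)}. Lesion total
#' volume is drawn from the disjoint band mapped to \code{burdenLevel},
#' so empirical LKA_V quartiles of a balanced cohort reproduce the
#' intended levels. NAWM voxel intensities follow the closed form of
#' \code{\link{phantomNawmM}} plus Gaussian noise.
#'
#' @param config a PhantomConfig
#' @param subjectSeed integer per-subject seed
#' @param burdenLevel integer 1-4
#' @return a \linkS4class{SubjectBundle}
#' @export
generateSubject <- function(config, subjectSeed, burdenLevel) {
  stopifnot(burdenLevel %in% 1:4)
  validObject(config)
  d <- config@gridShape
  vd <- config@voxelDimsMm
  geom <- phantomGeometry(config)
  geomSeed <- mixSeed(config@seed, subjectSeed, 1)
  noiseSeed <- mixSeed(config@seed, subjectSeed, 2)

  lesion <- withSeed(geomSeed, placeLesions(config, geom)(burdenLevel))

  cov <- drawSubjectCovariates(config, subjectSeed, burdenLevel)

  prox <- lesionProximity(lesion, vd)
  spl <- config@spleniumIntensityMean
  vol <- array(0, d)
  vol[geom$rim | geom$margin] <- 0.82 * config@wmBaseIntensity
  nawmVal <- config@wmBaseIntensity +
    spl * (config@burdenEffectPerQuartile * burdenLevel +
           config@ageEffectPerDecade * (cov$age / 10 - 6.8))
  wmIdx <- geom$wmComp & !lesion
  vol[wmIdx] <- nawmVal + spl * config@distanceDecayPerVoxel * prox[wmIdx]
  vol[lesion] <- config@lesionIntensity

  nBrain <- sum(geom$brain)
  tex <- withSeed(noiseSeed, {
    if (config@noiseSd > 0) {
      list(spl = stats::rnorm(sum(geom$splenium), 0, 1),
           csf = stats::runif(sum(geom$vent), 0.4, 0.9),
           noise = stats::rnorm(nBrain, 0, config@noiseSd))
    } else NULL
  })
  if (is.null(tex)) {
    vol[geom$splenium] <- spl
    vol[geom$vent] <- 0.7 * config@csfIntensityMax
  } else {
    vol[geom$splenium] <- spl + config@spleniumIntensitySd * tex$spl
    vol[geom$vent] <- config@csfIntensityMax * tex$csf
    vol[geom$brain] <- vol[geom$brain] + tex$noise
  }

  flair <- brainVolume(vol, voxelDims = vd)
  asMask <- function(a) brainMask(a, geometryFrom = flair)
  truth <- asMask(lesion)
  outline <- dilateMask(dilateMask(truth))
  covariates <- data.frame(
    subject_id = sprintf("S%07d", subjectSeed %% 10000000L),
    age = cov$age, hypertension = cov$htn, infarct_side = cov$side,
    truth_burden_level = as.integer(burdenLevel),
    seed = as.integer(subjectSeed), stringsAsFactors = FALSE)
  new("SubjectBundle", flair = flair,
      wmProbability = brainVolume(geom$prob, voxelDims = vd),
      spleniumMask = asMask(geom$splenium), ventricleMask = asMask(geom$vent),
      outlineMask = outline, supratentorialMask = asMask(geom$supra),
      hemisphereMap = hemisphereLabels(flair), truthLesionMask = truth,
      covariates = covariates)
}

#' Generate a balanced phantom cohort
#'
#' Burden levels 1-4 are assigned in balanced rotation (n = 8 gives
#' exactly 2 subjects per level); ages follow Normal(68, 16) with a
#' Gaussian-copula correlation to burden.
#'
#' @param config a PhantomConfig
#' @param nSubjects number of subjects (>= 8 so quartiles are
#'   non-degenerate)
#' @return list with \code{subjects} (list of SubjectBundle) and
#'   \code{covariates} (data.frame)
#' @export
generateCohort <- function(config, nSubjects) {
  if (nSubjects < 8L)
    stop("a cohort needs at least 8 subjects for non-degenerate quartiles")
  plan <- cohortPlan(config, nSubjects)
  subjects <- lapply(seq_len(nSubjects), function(s)
    generateSubject(config, plan$subjectSeeds[s], plan$levels[s]))
  covariates <- do.call(rbind, lapply(subjects, slot, "covariates"))
  list(subjects = subjects, covariates = covariates)
}

# Covariate model: age Normal(68, 16) linked to burden by a Gaussian
# copula (burden standardized over the balanced 1..4 design), Bernoulli
# hypertension, categorical infarct side. Deterministic given
# (config@seed, subjectSeed).
drawSubjectCovariates <- function(config, subjectSeed, burdenLevel) {
  withSeed(mixSeed(config@seed, subjectSeed, 3), {
    w <- config@ageBurdenCorrelation
    zb <- (burdenLevel - 2.5) / sqrt(1.25)
    age <- 68 + 16 * (w * zb + sqrt(1 - w^2) * stats::rnorm(1))
    age <- min(max(age, 20), 100)
    htn <- stats::rbinom(1, 1, config@hypertensionPrevalence)
    side <- sample(names(config@infarctSideProbs), 1,
                   prob = config@infarctSideProbs)
    list(age = age, htn = htn, side = side)
  })
}

# Balanced level assignment and per-subject seeds for a cohort.
cohortPlan <- function(config, nSubjects) {
  levels <- rep_len(1:4, nSubjects)
  subjectSeeds <- withSeed(mixSeed(config@seed, 424243),
                           sample.int(9999999L, nSubjects))
  list(levels = levels, subjectSeeds = subjectSeeds)
}

#' Write a subject bundle to NIfTI files plus a covariate row
#'
#' Writes flair.nii.gz, wm_probability.nii.gz and the 0/1 integer masks
#' (splenium, ventricles, outline, supratentorial, truth lesions) under
#' \code{dir/<subject_id>/}.
#'
#' @param bundle a SubjectBundle
#' @param dir output directory (created if needed)
#' @return the subject directory, invisibly
#' @export
writeSubjectBundle <- function(bundle, dir) {
  sdir <- file.path(dir, bundle@covariates$subject_id[1])
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  writeVolume(bundle@flair, file.path(sdir, "flair.nii.gz"))
  writeVolume(bundle@wmProbability, file.path(sdir, "wm_probability.nii.gz"))
  writeVolume(bundle@spleniumMask, file.path(sdir, "splenium_mask.nii.gz"))
  writeVolume(bundle@ventricleMask, file.path(sdir, "ventricle_mask.nii.gz"))
  writeVolume(bundle@outlineMask, file.path(sdir, "outline_mask.nii.gz"))
  writeVolume(bundle@supratentorialMask,
              file.path(sdir, "supratentorial_mask.nii.gz"))
  writeVolume(bundle@truthLesionMask,
              file.path(sdir, "truth_lesion_mask.nii.gz"))
  invisible(sdir)
}

#' Simulate a phantom cohort to disk
#'
#' Writes per-subject NIfTI files and a cohort covariates CSV
#' (subject_id, age, hypertension, infarct_side, truth_burden_level,
#' seed).
#'
#' @param config a PhantomConfig
#' @param nSubjects cohort size (>= 8)
#' @param dir output directory
#' @return path of the covariates CSV, invisibly
#' @export
simulateCohortToDisk <- function(config, nSubjects, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  plan <- cohortPlan(config, nSubjects)
  covs <- vector("list", nSubjects)
  for (s in seq_len(nSubjects)) {
    b <- generateSubject(config, plan$subjectSeeds[s], plan$levels[s])
    writeSubjectBundle(b, dir)
    covs[[s]] <- b@covariates
  }
  path <- file.path(dir, "covariates.csv")
  utils::write.csv(do.call(rbind, covs), path, row.names = FALSE)
  invisible(path)
}
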