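# Subject-level orchestration and cohort-level analysis.

#' Process one subject end-to-end
#'
#' Runs the full per-subject chain: threshold calibration (ROI sampling,
#' or the generator's known values in \code{"oracle"} mode), conservative
#' WM masking, leukoaraiosis segmentation, NAWM construction, hemisphere
#' exclusion with volume doubling, distance strata, and splenium-normalized
#' stratum metrics. Deterministic given \code{seed}.
#'
#' @param bundle a SubjectBundle
#' @param seed integer seed for ROI placement
#' @param calibration \code{"roi"} (sample reference ROIs from the image)
#'   or \code{"oracle"} (use the phantom generator's known splenium
#'   mean/SD and CSF ceiling from \code{config}; for validation studies)
#' @param config PhantomConfig, required for \code{calibration = "oracle"}
#' @param nSpleniumRois number of splenium ROIs (8-10, default 10)
#' @param nVentricleRois number of ventricular ROIs (6-8, default 8)
#' @param nStrata number of distance strata (default 5)
#' @return list with \code{segmentation} (SegmentationResult),
#'   \code{strata} (StrataSet), \code{rows} (stratum metric data.frame)
#' @export
runSubject <- function(bundle, seed = 1L, calibration = c("roi", "oracle"),
                       config = NULL, nSpleniumRois = 10L,
                       nVentricleRois = 8L, nStrata = 5L) {
  calibration <- match.arg(calibration)
  cov <- bundle@covariates
  sid <- cov$subject_id[1]
  thr <- if (calibration == "oracle") {
    if (is.null(config))
      stop("oracle calibration needs the PhantomConfig")
    oracleThresholds(config@spleniumIntensityMean,
                     config@spleniumIntensitySd, config@csfIntensityMax)
  } else {
    roiSeed <- mixSeed(seed, sum(utf8ToInt(sid)))
    spl <- sampleROIs(bundle@flair, bundle@spleniumMask, nSpleniumRois,
                      "splenium", seed = mixSeed(roiSeed, 1))
    vent <- sampleROIs(bundle@flair, bundle@ventricleMask, nVentricleRois,
                       "ventricle", seed = mixSeed(roiSeed, 2))
    calibrationThresholds(spl, vent)
  }
  wm <- wmMaskFromProbability(bundle@wmProbability,
                              bundle@supratentorialMask)
  lka <- segmentLKA(bundle@flair, bundle@outlineMask, thr)
  nawm <- buildNAWM(wm, lka, bundle@flair, thr)
  seg <- segmentationResult(lka, wm, nawm, thr)
  seg <- applyHemisphereExclusion(seg, bundle@hemisphereMap,
                                  cov$infarct_side[1])
  strata <- buildStrata(seg@lkaMask, seg@nawmMask, nStrata)
  rows <- subjectStratumRows(sid, bundle@flair, strata, thr,
                             age = cov$age[1],
                             hypertension = cov$hypertension[1],
                             lkaVolumeCm3 = seg@lkaVolumeCm3)
  list(segmentation = seg, strata = strata, rows = rows)
}

#' Voxel maps of leukoaraiosis frequency and mean NAWM intensity
#'
#' Per LKA_V quartile: the voxelwise count of subjects whose
#' leukoaraiosis mask covers the voxel, and the voxelwise mean of
#' splenium-normalized intensity over subjects' NAWM masks (NA where no
#' subject contributes).
#'
#' @param lkaMasks list of 3D logical arrays (shared atlas geometry)
#' @param nawmMasks list of 3D logical arrays
#' @param normVolumes list of 3D numeric arrays (normalized intensities)
#' @param quartiles integer vector of per-subject quartile labels
#' @param geometry a BrainVolume/BrainMask supplying voxel dims and affine
#' @return list with \code{lkaFrequency} and \code{nawmMean}, each a list
#'   of BrainVolume indexed \code{"Q1"}..\code{"Q4"}
#' @export
buildVoxelMaps <- function(lkaMasks, nawmMasks, normVolumes, quartiles,
                           geometry) {
  d <- dim(lkaMasks[[1]])
  for (m in c(lkaMasks, nawmMasks, normVolumes))
    if (!identical(dim(m), d))
      stop("voxel maps need all subjects in shared atlas geometry")
  freq <- means <- list()
  for (q in 1:4) {
    idx <- which(quartiles == q)
    f <- array(0, d); s <- array(0, d); n <- array(0, d)
    for (i in idx) {
      f <- f + lkaMasks[[i]]
      s <- s + normVolumes[[i]] * nawmMasks[[i]]
      n <- n + nawmMasks[[i]]
    }
    mm <- s / n
    mm[n == 0] <- NA_real_
    key <- paste0("Q", q)
    freq[[key]] <- brainVolume(f, voxelDims = geometry@voxelDims,
                               affine = geometry@affine)
    means[[key]] <- brainVolume(mm, voxelDims = geometry@voxelDims,
                                affine = geometry@affine)
  }
  list(lkaFrequency = freq, nawmMean = means)
}

#' Run the full cohort analysis on a synthetic cohort
#'
#' Generates subjects one at a time from \code{config}, processes each
#' with \code{\link{runSubject}} (failed or empty subjects are excluded
#' with a logged reason; the run continues), assigns LKA_V quartiles on
#' the survivors, and performs the cohort statistics: stratum ANOVA,
#' univariate screening, the random-intercepts and random-slopes mixed
#' models with their comparison, and the per-quartile voxel maps.
#'
#' @param config a PhantomConfig
#' @param nSubjects cohort size (>= 8 survivors required)
#' @param calibration \code{"roi"} (default) or \code{"oracle"}, see
#'   \code{\link{runSubject}}
#' @param outDir optional directory; when given, tables, the JSON summary
#'   and the voxel maps are written there
#' @return a \linkS4class{CohortReport}
#' @export
runCohort <- function(config, nSubjects = 100, calibration = "roi",
                      outDir = NULL) {
  plan <- cohortPlan(config, nSubjects)
  subjRows <- list(); stratRows <- list(); excl <- list()
  lkaA <- list(); nawmA <- list(); normA <- list()
  geometry <- NULL
  for (s in seq_len(nSubjects)) {
    sid <- sprintf("S%07d", plan$subjectSeeds[s] %% 10000000L)
    bundle <- tryCatch(
      generateSubject(config, plan$subjectSeeds[s], plan$levels[s]),
      error = function(e) e)
    if (inherits(bundle, "error")) {
      excl[[sid]] <- data.frame(subject_id = sid,
                                reason = conditionMessage(bundle))
      next
    }
    res <- tryCatch(
      runSubject(bundle, seed = config@seed, calibration = calibration,
                 config = config),
      error = function(e) e)
    if (inherits(res, "error")) {
      excl[[sid]] <- data.frame(subject_id = sid,
                                reason = conditionMessage(res))
      next
    }
    if (is.null(res$rows) || !any(res$rows$stratum != "full")) {
      excl[[sid]] <- data.frame(
        subject_id = sid,
        reason = "no non-empty NAWM stratum after segmentation")
      next
    }
    if (voxelCount(res$segmentation@wmMask) == 0L) {
      excl[[sid]] <- data.frame(subject_id = sid,
                                reason = "empty white-matter mask")
      next
    }
    cv <- bundle@covariates
    subjRows[[sid]] <- data.frame(
      subject_id = sid, age = cv$age, hypertension = cv$hypertension,
      infarct_side = cv$infarct_side,
      truth_burden_level = cv$truth_burden_level,
      lka_volume_cm3 = res$segmentation@lkaVolumeCm3,
      nawm_m = res$rows$nawm_m[res$rows$stratum == "full"][1],
      stringsAsFactors = FALSE)
    stratRows[[sid]] <- res$rows
    thrMean <- res$segmentation@thresholds@spleniumMean
    lkaA[[sid]] <- res$segmentation@lkaMask@data
    nawmA[[sid]] <- res$segmentation@nawmMask@data
    normA[[sid]] <- bundle@flair@data / thrMean
    if (is.null(geometry)) geometry <- bundle@flair
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(subject_id = character(), reason = character())
  rownames(exclusions) <- NULL
  if (length(subjRows) < 8L)
    stop(sprintf(
      "only %d subjects survived exclusions (need >= 8); reasons: %s",
      length(subjRows), paste(exclusions$reason, collapse = "; ")))
  subjectTable <- do.call(rbind, subjRows); rownames(subjectTable) <- NULL
  subjectTable$lka_quartile <- assignQuartiles(subjectTable$lka_volume_cm3)
  stratumTable <- do.call(rbind, stratRows); rownames(stratumTable) <- NULL
  stratumTable$lka_quartile <- subjectTable$lka_quartile[
    match(stratumTable$subject_id, subjectTable$subject_id)]
  anova <- strataAnova(stratumTable)
  univ <- univariateScreen(subjectTable)
  comparison <- compareModels(stratumTable)
  maps <- buildVoxelMaps(lkaA, nawmA, normA, subjectTable$lka_quartile,
                         geometry)
  report <- new("CohortReport", subjectTable = subjectTable,
                stratumTable = stratumTable, anova = anova,
                univariate = univ,
                lmmIntercepts = comparison@remlIntercepts,
                lmmSlopes = comparison@remlSlopes,
                comparison = comparison,
                lkaFrequencyMaps = maps$lkaFrequency,
                nawmMeanMaps = maps$nawmMean, exclusions = exclusions)
  if (!is.null(outDir)) writeCohortReport(report, outDir)
  report
}

setMethod("show", "CohortReport", function(object) {
  cat(sprintf(
    "CohortReport: %d subjects analysed, %d excluded; ANOVA F = %.1f (p = %.3g)\n",
    nrow(object@subjectTable), nrow(object@exclusions),
    object@anova$F, object@anova$p))
  show(object@comparison)
})

#' Machine-readable summary of a CohortReport
#' @param report a CohortReport
#' @return a list ready for JSON serialization
#' @export
cohortSummary <- function(report) {
  fe <- function(m) {
    f <- m@fixedEffects
    stats::setNames(lapply(seq_len(nrow(f)), function(i)
      list(estimate = f$estimate[i], se = f$se[i],
           ci = c(f$ci_lo[i], f$ci_hi[i]))), f$term)
  }
  cmp <- report@comparison
  list(
    n_subjects = nrow(report@subjectTable),
    n_excluded = nrow(report@exclusions),
    anova = report@anova[c("F", "p")],
    fixed_effects_random_intercepts = fe(report@lmmIntercepts),
    fixed_effects_random_slopes = fe(report@lmmSlopes),
    random_effects = report@lmmSlopes@randomEffects,
    aic_ml = c(intercepts = cmp@aicIntercepts, slopes = cmp@aicSlopes),
    lrt = list(statistic = cmp@lrtStatistic, df = cmp@lrtDf, p = cmp@lrtP),
    stratum_means = as.list(tapply(
      report@stratumTable$nawm_m[report@stratumTable$stratum != "full"],
      report@stratumTable$stratum[report@stratumTable$stratum != "full"],
      mean)))
}

#' Write cohort tables, JSON summary and voxel maps
#'
#' @param report a CohortReport
#' @param dir output directory (created if needed)
#' @param writeMaps logical, also write the per-quartile NIfTI maps
#' @return \code{dir}, invisibly
#' @export
writeCohortReport <- function(report, dir, writeMaps = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report@subjectTable,
                   file.path(dir, "subject_table.csv"), row.names = FALSE)
  utils::write.csv(report@stratumTable,
                   file.path(dir, "stratum_table.csv"), row.names = FALSE)
  utils::write.csv(report@exclusions,
                   file.path(dir, "exclusions.csv"), row.names = FALSE)
  utils::write.csv(report@univariate,
                   file.path(dir, "univariate.csv"), row.names = FALSE)
  jsonlite::write_json(cohortSummary(report),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(reportText(report), file.path(dir, "report.txt"))
  if (writeMaps) {
    for (q in names(report@lkaFrequencyMaps)) {
      writeVolume(report@lkaFrequencyMaps[[q]],
                  file.path(dir, sprintf("lka_frequency_%s.nii.gz", q)))
      m <- report@nawmMeanMaps[[q]]
      m@data[is.na(m@data)] <- 0
      writeVolume(m, file.path(dir, sprintf("nawm_mean_%s.nii.gz", q)))
    }
  }
  invisible(dir)
}

#' Human-readable cohort report text
#' @param report a CohortReport
#' @return character vector of report lines
#' @export
reportText <- function(report) {
  fmt <- function(m, title) {
    f <- m@fixedEffects
    c(title, sprintf("  %-28s %8.3f  SE %.3f  95%% CI %.3f to %.3f",
                     f$term, f$estimate, f$se, f$ci_lo, f$ci_hi))
  }
  re <- report@lmmSlopes@randomEffects
  cmp <- report@comparison
  c(sprintf("Cohort: %d subjects analysed, %d excluded",
            nrow(report@subjectTable), nrow(report@exclusions)),
    sprintf("Stratum ANOVA: F = %.1f, p = %.3g", report@anova$F,
            report@anova$p),
    "",
    fmt(report@lmmIntercepts,
        "Linear mixed model with random intercepts (REML)"),
    "",
    fmt(report@lmmSlopes,
        "Linear mixed model with random intercepts and random slopes (REML)"),
    "Random effects (per-stratum estimates)",
    sprintf("  stratum %-3s intercept %7.3f  quartile slope %7.4f",
            re$stratum, re$intercept, re$slope),
    "",
    sprintf("AIC (ML): intercepts %.1f, slopes %.1f; LRT %.3f on %d df, p = %.3g",
            cmp@aicIntercepts, cmp@aicSlopes, cmp@lrtStatistic, cmp@lrtDf,
            cmp@lrtP))
}

#' Write per-subject segmentation outputs
#'
#' Writes lka/wm/nawm masks, the strata label volume and a JSON sidecar
#' with thresholds, volumes, stratum voxel counts and the exclusion flag.
#'
#' @param result output of \code{\link{runSubject}}
#' @param subjectId subject identifier
#' @param dir output directory
#' @return the subject directory, invisibly
#' @export
writeSubjectOutputs <- function(result, subjectId, dir) {
  sdir <- file.path(dir, subjectId)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  seg <- result$segmentation
  writeVolume(seg@lkaMask, file.path(sdir, "lka.nii.gz"))
  writeVolume(seg@wmMask, file.path(sdir, "wm.nii.gz"))
  writeVolume(seg@nawmMask, file.path(sdir, "nawm.nii.gz"))
  writeVolume(strataLabelVolume(result$strata),
              file.path(sdir, "strata.nii.gz"))
  thr <- seg@thresholds
  sidecar <- list(
    subject_id = subjectId,
    thresholds = list(splenium_mean = thr@spleniumMean,
                      splenium_sd = thr@spleniumSd,
                      lka_threshold = thr@lkaThreshold,
                      csf_max = thr@csfMax),
    lka_volume_cm3 = seg@lkaVolumeCm3,
    hemisphere_excluded = seg@hemisphereExcluded,
    voxel_counts = list(
      lka = voxelCount(seg@lkaMask), wm = voxelCount(seg@wmMask),
      nawm = voxelCount(seg@nawmMask),
      strata = vapply(result$strata@strata, voxelCount, integer(1))))
  jsonlite::write_json(sidecar, file.path(sdir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sdir)
}
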