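# Splenium normalization, masked intensity means and LKA_V quartiles.

#' Normalize a volume to the splenium mean intensity
#'
#' Raw FLAIR intensities are arbitrary units; dividing by the splenium
#' reference mean yields the dimensionless normalized intensity on which
#' NAWM_M is defined (global intensity scaling cancels).
#'
#' @param flair a BrainVolume
#' @param spleniumMean positive reference mean (a.u.)
#' @return a BrainVolume of normalized intensities
#' @export
normalizeToSplenium <- function(flair, spleniumMean) {
  if (!is.finite(spleniumMean) || spleniumMean <= 0)
    stop("splenium mean must be positive")
  brainVolume(flair@data / spleniumMean, voxelDims = flair@voxelDims,
              affine = flair@affine)
}

#' Mean intensity over a mask
#'
#' @param volume a BrainVolume
#' @param mask a BrainMask sharing its geometry
#' @return the arithmetic mean over masked voxels, or \code{NA_real_}
#'   (with a message) for an empty mask -- the caller emits no observation
#'   row in that case
#' @export
meanMaskedIntensity <- function(volume, mask) {
  stopIfGeometryMismatch(volume, mask, "volume and mask")
  if (!any(mask@data)) {
    message("empty mask: no intensity observation emitted")
    return(NA_real_)
  }
  mean(volume@data[mask@data])
}

#' Assign LKA_V quartile labels (nearest-rank cut-points, ties low)
#'
#' Cut-points are the 25th/50th/75th percentiles under the nearest-rank
#' definition (the ceiling(p n)-th order statistic); a value <= Q1 maps to
#' quartile 1, <= Q2 to 2, <= Q3 to 3, else 4. Labels depend only on
#' ranks, so any monotone transform of the volumes yields the same labels.
#'
#' @param volumes numeric vector of leukoaraiosis volumes (>= 4 values)
#' @return integer vector of quartile labels 1-4
#' @examples
#' assignQuartiles(1:8)  # 1 1 2 2 3 3 4 4
#' @export
assignQuartiles <- function(volumes) {
  n <- length(volumes)
  if (n < 4L) stop("quartiles need at least 4 subjects")
  s <- sort(volumes)
  cuts <- s[ceiling(c(0.25, 0.5, 0.75) * n)]
  q <- 1L + (volumes > cuts[1]) + (volumes > cuts[2]) + (volumes > cuts[3])
  if (length(unique(volumes)) == 1L)
    warning("all volumes identical: degenerate quartiles (all labelled 1)")
  as.integer(q)
}

#' Per-stratum NAWM_M rows for one subject
#'
#' Computes the mean splenium-normalized FLAIR intensity within each
#' non-empty NAWM stratum, plus a descriptive \code{"full"} NAWM row
#' (reported but not entered in the mixed models, whose observation unit
#' is subject x stratum).
#'
#' @param subjectId character subject identifier
#' @param flair raw FLAIR BrainVolume
#' @param strataSet a StrataSet
#' @param thresholds CalibrationThresholds (supplies the splenium mean)
#' @param age age in years
#' @param hypertension 0/1
#' @param lkaVolumeCm3 total leukoaraiosis volume (cm^3)
#' @return data.frame with columns subject_id, stratum (character: "1".."5",
#'   "full"), nawm_m, lka_volume_cm3, age_decades, hypertension; empty
#'   strata contribute no row
#' @export
subjectStratumRows <- function(subjectId, flair, strataSet, thresholds,
                               age, hypertension, lkaVolumeCm3) {
  norm <- normalizeToSplenium(flair, thresholds@spleniumMean)
  rows <- list()
  for (k in seq_len(nStrata(strataSet))) {
    m <- getStratum(strataSet, k)
    if (!any(m@data)) next
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = subjectId, stratum = as.character(k),
      nawm_m = mean(norm@data[m@data]),
      lka_volume_cm3 = lkaVolumeCm3,
      age_decades = age / 10, hypertension = as.integer(hypertension),
      stringsAsFactors = FALSE)
  }
  if (any(strataSet@fullNawm@data)) {
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = subjectId, stratum = "full",
      nawm_m = mean(norm@data[strataSet@fullNawm@data]),
      lka_volume_cm3 = lkaVolumeCm3,
      age_decades = age / 10, hypertension = as.integer(hypertension),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
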