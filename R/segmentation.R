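# Leukoaraiosis, white-matter and NAWM segmentation.
#
# Threshold conventions: an intensity threshold keeps a voxel when its
# value is >= the threshold; "voxels below the CSF maximum are excluded"
# is read as strict <, so a voxel exactly at the CSF maximum survives.

#' Conservative white-matter mask from a probabilistic tissue map
#'
#' Thresholds the WM probability map at \code{threshold} (inclusive),
#' restricts to the supratentorial region, then applies two erosions and
#' one dilation with the given structuring element, yielding a mask of
#' mostly central white matter (juxtacortical WM removed).
#'
#' @param prob a BrainVolume with values in [0, 1]
#' @param supratentorialMask a BrainMask restricting to supratentorial WM
#' @param threshold probability cut-off, default 0.95
#' @param element StructuringElement for the morphology (default the 3D
#'   6-neighbour cross, the most conservative choice on thick slices)
#' @return a BrainMask (empty, with a warning, if morphology removes
#'   everything; such subjects are dropped downstream)
#' @export
wmMaskFromProbability <- function(prob, supratentorialMask,
                                  threshold = 0.95,
                                  element = structuringElement("cross_3d_6")) {
  if (min(prob@data) < 0 || max(prob@data) > 1)
    stop("probability map values must lie in [0, 1]")
  stopIfGeometryMismatch(prob, supratentorialMask,
                         "probability map and supratentorial mask")
  m <- brainMask(prob@data >= threshold, geometryFrom = prob)
  m <- maskAlgebra(m, supratentorialMask, "intersection")
  m <- dilateMask(erodeMask(erodeMask(m, element), element), element)
  if (!any(m@data))
    warning("white-matter mask empty after thresholding and morphology")
  m
}

#' Segment leukoaraiosis by calibrated thresholding within an outline
#'
#' Keeps the voxels of the (manually drawn or supplied) outline whose
#' intensity reaches the leukoaraiosis threshold (splenium mean + 6 SD)
#' and is not below the CSF exclusion floor.
#'
#' @param flair a BrainVolume (FLAIR-like intensities)
#' @param outline a BrainMask containing all candidate lesion regions; an
#'   empty outline is valid (subjects may have no lesions)
#' @param thresholds a CalibrationThresholds computed from the same volume
#' @return the leukoaraiosis BrainMask
#' @export
segmentLKA <- function(flair, outline, thresholds) {
  stopIfGeometryMismatch(flair, outline, "FLAIR and outline")
  keep <- outline@data &
    flair@data >= thresholds@lkaThreshold &
    flair@data >= thresholds@csfMax
  brainMask(keep, geometryFrom = flair)
}

#' Build the NAWM mask
#'
#' NAWM = (white matter minus leukoaraiosis) minus voxels with intensity
#' strictly below the CSF exclusion floor (removes CSF contamination from
#' minor co-registration errors).
#'
#' @param wm white-matter BrainMask
#' @param lka leukoaraiosis BrainMask
#' @param flair the FLAIR BrainVolume
#' @param thresholds CalibrationThresholds providing the CSF floor
#' @return the NAWM BrainMask
#' @export
buildNAWM <- function(wm, lka, flair, thresholds) {
  stopIfGeometryMismatch(wm, lka, "WM and LKA masks")
  stopIfGeometryMismatch(wm, flair, "WM mask and FLAIR")
  keep <- wm@data & !lka@data & flair@data >= thresholds@csfMax
  brainMask(keep, geometryFrom = wm)
}

#' Assemble a SegmentationResult (no hemisphere exclusion yet)
#'
#' @param lka,wm,nawm the three masks
#' @param thresholds the CalibrationThresholds used
#' @return a \linkS4class{SegmentationResult} with
#'   \code{hemisphereExcluded = "none"} and LKA_V = voxel count x voxel
#'   volume in cm^3
#' @export
segmentationResult <- function(lka, wm, nawm, thresholds) {
  new("SegmentationResult", lkaMask = lka, wmMask = wm, nawmMask = nawm,
      lkaVolumeCm3 = maskVolumeCm3(lka), hemisphereExcluded = "none",
      thresholds = thresholds)
}

#' Exclude the infarct hemisphere and double the single-hemisphere volume
#'
#' For subjects with a unilateral infarct, only the contralateral
#' hemisphere is analysed: the LKA and NAWM masks are intersected with
#' the unaffected side and the total leukoaraiosis volume measured there
#' is doubled. With \code{infarctSide = "none"} the result is returned
#' unchanged (volume not doubled).
#'
#' @param seg a SegmentationResult
#' @param hemisphereMap 3D integer array (-1 left, +1 right, 0 midline),
#'   e.g. from \code{\link{hemisphereLabels}}
#' @param infarctSide \code{"none"}, \code{"left"} or \code{"right"}
#' @return the updated \linkS4class{SegmentationResult}
#' @export
applyHemisphereExclusion <- function(seg, hemisphereMap, infarctSide) {
  if (!infarctSide %in% c("none", "left", "right"))
    stop(sprintf("unknown infarct side '%s' (expected none/left/right)",
                 infarctSide))
  if (infarctSide == "none") return(seg)
  keepLabel <- if (infarctSide == "left") 1L else -1L
  keep <- hemisphereMap == keepLabel
  lka <- brainMask(seg@lkaMask@data & keep, geometryFrom = seg@lkaMask)
  nawm <- brainMask(seg@nawmMask@data & keep, geometryFrom = seg@nawmMask)
  wm <- brainMask(seg@wmMask@data & keep, geometryFrom = seg@wmMask)
  new("SegmentationResult", lkaMask = lka, wmMask = wm, nawmMask = nawm,
      lkaVolumeCm3 = 2 * maskVolumeCm3(lka),
      hemisphereExcluded = infarctSide, thresholds = seg@thresholds)
}

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf(
    "SegmentationResult: LKA %d vox (LKA_V %.4g cm^3%s), WM %d vox, NAWM %d vox\n",
    voxelCount(object@lkaMask), object@lkaVolumeCm3,
    if (object@hemisphereExcluded != "none")
      sprintf(", %s hemisphere excluded, volume doubled",
              object@hemisphereExcluded) else "",
    voxelCount(object@wmMask), voxelCount(object@nawmMask)))
})
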