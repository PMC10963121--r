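#' Extract the voxel data array
#' @param x a BrainVolume or BrainMask
#' @return the underlying 3D array
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Voxel dimensions in mm
#' @param x a BrainVolume or BrainMask
#' @return numeric length-3
#' @export
setGeneric("voxelDims", function(x) standardGeneric("voxelDims"))

#' Voxel-to-world affine
#' @param x a BrainVolume or BrainMask
#' @return 4x4 numeric matrix
#' @export
setGeneric("voxelAffine", function(x) standardGeneric("voxelAffine"))

#' Number of true voxels in a mask
#' @param x a BrainMask
#' @return integer count
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))

#' Mask volume in cm^3 (voxel count times voxel volume)
#' @param x a BrainMask
#' @return numeric volume in cm^3
#' @export
setGeneric("maskVolumeCm3", function(x) standardGeneric("maskVolumeCm3"))

#' Leukoaraiosis threshold: reference mean + 6 SD
#'
#' The leukoaraiosis signal threshold is defined as 6 standard deviations
#' above the mean of the splenium reference sample (sample SD, denominator
#' n - 1).
#'
#' @param x an ROISample or a numeric vector of ROI values
#' @return numeric threshold (a.u.)
#' @export
setGeneric("lkaThreshold", function(x) standardGeneric("lkaThreshold"))

#' CSF exclusion threshold: maximum of the ventricular sample
#'
#' Voxels below the maximum signal intensity observed in ventricular CSF
#' are excluded from the leukoaraiosis and NAWM masks.
#'
#' @param x an ROISample or a numeric vector of ROI values
#' @return numeric threshold (a.u.)
#' @export
setGeneric("csfExclusionThreshold",
           function(x) standardGeneric("csfExclusionThreshold"))

#' Retrieve one NAWM stratum mask
#' @param x a StrataSet
#' @param k stratum index (voxel distance), 1-based
#' @return a BrainMask
#' @export
setGeneric("getStratum", function(x, k) standardGeneric("getStratum"))

#' Number of strata in a StrataSet
#' @param x a StrataSet
#' @return integer
#' @export
setGeneric("nStrata", function(x) standardGeneric("nStrata"))

#' Fixed-effect table of a fitted mixed model
#' @param x an LMMResult
#' @return data.frame with estimate, se and Wald 95\% CI per term
#' @export
setGeneric("fixedEffects", function(x) standardGeneric("fixedEffects"))

#' Per-stratum random-effect estimates of a fitted mixed model
#' @param x an LMMResult
#' @return data.frame of conditional modes (deviations and combined values)
#' @export
setGeneric("randomEffects", function(x) standardGeneric("randomEffects"))
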