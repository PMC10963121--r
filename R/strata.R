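# NAWM distance strata by recursive 2D 8-connected dilation.
#
# With D0 = LKA and D_k = dilate(D_{k-1}, in_plane_8), stratum k is
# (D_k - D_{k-1}) intersected with NAWM: the NAWM voxels whose in-slice
# Chebyshev distance to the nearest leukoaraiosis voxel in the same slice
# equals k. Dilations never cross slices, which avoids vertical
# partial-volume contamination across thick slices.

#' Build NAWM strata at increasing voxel distance from leukoaraiosis
#'
#' @param lka leukoaraiosis BrainMask
#' @param nawm NAWM BrainMask (must be disjoint from \code{lka})
#' @param nStrata number of strata (default 5)
#' @return a \linkS4class{StrataSet}; strata with no lesion in reach are
#'   empty masks (retained, but downstream metrics emit no row for them)
#' @examples
#' lka <- brainMask(array(FALSE, c(15, 15, 1)))
#' lka@data[8, 8, 1] <- TRUE
#' nawm <- brainMask(!lka@data, geometryFrom = lka)
#' vapply(buildStrata(lka, nawm)@strata, voxelCount, integer(1))
#' # 8 16 24 32 40: concentric in-slice square rings
#' @export
buildStrata <- function(lka, nawm, nStrata = 5L) {
  stopIfGeometryMismatch(lka, nawm, "LKA and NAWM masks")
  if (any(lka@data & nawm@data))
    stop("LKA and NAWM masks overlap; they must be disjoint")
  el <- structuringElement("in_plane_8")
  strata <- vector("list", nStrata)
  prev <- lka
  for (k in seq_len(nStrata)) {
    cur <- dilateMask(prev, el)
    ring <- brainMask(cur@data & !prev@data & nawm@data, geometryFrom = lka)
    strata[[k]] <- ring
    prev <- cur
  }
  new("StrataSet", strata = strata, fullNawm = nawm)
}

#' @rdname getStratum
#' @export
setMethod("getStratum", "StrataSet", function(x, k) x@strata[[k]])

#' @rdname nStrata
#' @export
setMethod("nStrata", "StrataSet", function(x) length(x@strata))

setMethod("show", "StrataSet", function(object) {
  counts <- vapply(object@strata, voxelCount, integer(1))
  cat(sprintf("StrataSet: %d strata, voxel counts %s; full NAWM %d vox\n",
              length(counts), paste(counts, collapse = ", "),
              voxelCount(object@fullNawm)))
})

#' Encode a StrataSet as a single label volume
#'
#' @param x a StrataSet
#' @return a BrainVolume with 0 outside all strata and k on stratum k
#' @export
strataLabelVolume <- function(x) {
  lab <- array(0, dim(x@fullNawm@data))
  for (k in seq_along(x@strata)) lab[x@strata[[k]]@data] <- k
  brainVolume(lab, voxelDims = x@fullNawm@voxelDims,
              affine = x@fullNawm@affine)
}
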