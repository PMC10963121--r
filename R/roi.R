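# Reference-structure ROI sampling and the two calibration thresholds.
#
# An ROI is a 1-mm-diameter world-space sphere; its value is the mean of
# the voxels whose centres fall inside the sphere. With the default
# anisotropic clinical voxels (0.75 x 0.75 x 3.5 mm) a 1-mm sphere covers
# exactly the single containing voxel, which is accepted: the ROI value is
# that voxel's intensity.

# Integer voxel offsets whose centres lie within radius r (mm) of a voxel
# centre. Always contains the zero offset.
sphereOffsets <- function(voxelDims, diameterMm) {
  r <- diameterMm / 2
  reach <- pmax(0L, as.integer(floor(r / voxelDims)))
  g <- as.matrix(expand.grid(di = -reach[1]:reach[1],
                             dj = -reach[2]:reach[2],
                             dk = -reach[3]:reach[3]))
  dd <- sweep(g, 2, voxelDims, `*`)
  keep <- sqrt(rowSums(dd^2)) <= r + 1e-12
  out <- g[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

roiValueAt <- function(volume, centreIdx, offsets) {
  d <- dim(volume@data)
  pts <- sweep(offsets, 2, as.integer(centreIdx), `+`)
  ok <- pts[, 1] >= 1 & pts[, 1] <= d[1] &
        pts[, 2] >= 1 & pts[, 2] <= d[2] &
        pts[, 3] >= 1 & pts[, 3] <= d[3]
  mean(volume@data[pts[ok, , drop = FALSE]])
}

#' Sample spherical ROIs within a reference region
#'
#' Places \code{nRois} non-overlapping spherical ROIs (world-space
#' diameter \code{diameterMm}) at uniformly drawn voxel centres within
#' \code{regionMask}; each sphere must fit entirely inside the region.
#' Non-overlap requires pairwise centre distances of at least one
#' diameter. Deterministic given \code{seed}.
#'
#' @param volume a BrainVolume to sample intensities from
#' @param regionMask a BrainMask delimiting the reference structure
#' @param nRois number of ROIs (splenium convention: 8-10; ventricle: 6-8)
#' @param source \code{"splenium"} or \code{"ventricle"}
#' @param diameterMm ROI diameter in mm (default 1)
#' @param seed integer RNG seed for centre placement
#' @return an \linkS4class{ROISample}
#' @export
sampleROIs <- function(volume, regionMask, nRois, source, diameterMm = 1,
                       seed = 1L) {
  stopIfGeometryMismatch(volume, regionMask, "volume and region mask")
  if (!any(regionMask@data))
    stop(sprintf("%s region mask is empty", source))
  offs <- sphereOffsets(volume@voxelDims, diameterMm)
  # eligible centres: sphere fits inside the region
  elig <- regionMask@data
  for (r in seq_len(nrow(offs))) {
    d <- offs[r, ]
    if (all(d == 0L)) next
    elig <- elig & shiftLogical(regionMask@data, -d)
  }
  cand <- which(elig, arr.ind = TRUE)
  if (nrow(cand) < nRois)
    stop(sprintf("%s region too small: %d eligible centres for %d ROIs",
                 source, nrow(cand), nRois))
  centres <- withSeed(seed, {
    ord <- sample.int(nrow(cand))
    pick <- matrix(0L, 0, 3)
    w <- cand %*% diag(volume@voxelDims)  # world-scaled for distances
    for (i in ord) {
      if (nrow(pick) == 0L) ok <- TRUE
      else {
        pw <- pick %*% diag(volume@voxelDims)
        dist2 <- rowSums(sweep(pw, 2, w[i, ], `-`)^2)
        ok <- all(dist2 >= diameterMm^2 - 1e-12)
      }
      if (ok) pick <- rbind(pick, cand[i, , drop = FALSE])
      if (nrow(pick) == nRois) break
    }
    pick
  })
  if (nrow(centres) < nRois)
    stop(sprintf(
      "%s region too small to place %d non-overlapping %.3g-mm ROIs",
      source, nRois, diameterMm))
  vals <- vapply(seq_len(nRois),
                 function(i) roiValueAt(volume, centres[i, ], offs),
                 numeric(1))
  new("ROISample", values = vals, source = source, diameterMm = diameterMm,
      centresMm = worldCoords(volume, centres))
}

#' Sample ROIs at explicit world-space centres
#'
#' Manual mode reproducing rater-placed ROIs: centres are given in world
#' mm and snapped to the nearest voxel centre.
#'
#' @param volume a BrainVolume
#' @param centresMm numeric matrix (n x 3) of world-mm centres
#' @param source \code{"splenium"} or \code{"ventricle"}
#' @param diameterMm ROI diameter in mm
#' @return an \linkS4class{ROISample}
#' @export
sampleROIsAt <- function(volume, centresMm, source, diameterMm = 1) {
  offs <- sphereOffsets(volume@voxelDims, diameterMm)
  inv <- solve(volume@affine)
  idx <- round(cbind(centresMm, 1) %*% t(inv))[, 1:3, drop = FALSE]
  vals <- vapply(seq_len(nrow(idx)),
                 function(i) roiValueAt(volume, idx[i, ], offs),
                 numeric(1))
  new("ROISample", values = vals, source = source, diameterMm = diameterMm,
      centresMm = worldCoords(volume, idx))
}

#' @rdname lkaThreshold
#' @export
setMethod("lkaThreshold", "numeric", function(x) {
  if (length(x) < 2L)
    stop("lkaThreshold needs at least 2 ROI values (SD undefined)")
  mean(x) + 6 * stats::sd(x)
})

#' @rdname lkaThreshold
#' @export
setMethod("lkaThreshold", "ROISample", function(x) lkaThreshold(x@values))

#' @rdname csfExclusionThreshold
#' @export
setMethod("csfExclusionThreshold", "numeric", function(x) {
  if (length(x) == 0L) stop("empty CSF ROI sample")
  max(x)
})

#' @rdname csfExclusionThreshold
#' @export
setMethod("csfExclusionThreshold", "ROISample",
          function(x) csfExclusionThreshold(x@values))

#' Assemble calibration thresholds from the two reference samples
#'
#' @param splenium an ROISample from the splenium (or numeric values)
#' @param ventricle an ROISample from ventricular CSF (or numeric values)
#' @return a \linkS4class{CalibrationThresholds}
#' @examples
#' calibrationThresholds(c(99, 100, 101, 100, 99, 101, 100, 100),
#'                       c(20, 25, 30, 22, 28, 26))
#' @export
calibrationThresholds <- function(splenium, ventricle) {
  sv <- if (is(splenium, "ROISample")) splenium@values else splenium
  vv <- if (is(ventricle, "ROISample")) ventricle@values else ventricle
  if (length(sv) < 2L)
    stop("splenium sample needs at least 2 values")
  new("CalibrationThresholds",
      spleniumMean = mean(sv), spleniumSd = stats::sd(sv),
      lkaThreshold = mean(sv) + 6 * stats::sd(sv),
      csfMax = csfExclusionThreshold(vv))
}

#' Calibration thresholds taken as known (oracle) values
#'
#' Builds \linkS4class{CalibrationThresholds} directly from a known
#' reference mean/SD and CSF maximum, e.g. a phantom generator's ground
#' truth, bypassing ROI sampling.
#'
#' @param spleniumMean,spleniumSd known splenium reference mean and SD
#' @param csfMax known CSF intensity maximum
#' @return a \linkS4class{CalibrationThresholds}
#' @export
oracleThresholds <- function(spleniumMean, spleniumSd, csfMax) {
  new("CalibrationThresholds",
      spleniumMean = spleniumMean, spleniumSd = spleniumSd,
      lkaThreshold = spleniumMean + 6 * spleniumSd, csfMax = csfMax)
}

setMethod("show", "CalibrationThresholds", function(object) {
  cat(sprintf(
    "CalibrationThresholds: splenium %.4g +/- %.4g, LKA >= %.4g, CSF < %.4g\n",
    object@spleniumMean, object@spleniumSd, object@lkaThreshold,
    object@csfMax))
})
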