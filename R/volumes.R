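# Constructors, accessors and geometry helpers for BrainVolume/BrainMask.

#' Create a BrainVolume
#'
#' If no affine is given, a diagonal RAS+ affine is built from the voxel
#' dimensions with the world origin at the grid centre, so that the x = 0
#' plane is the inter-hemispheric midline.
#'
#' @param data 3D numeric array.
#' @param voxelDims numeric length-3 voxel size in mm
#'   (default \code{c(0.75, 0.75, 3.5)}, anisotropic clinical FLAIR slices).
#' @param affine optional 4x4 voxel-to-world matrix (1-based indices).
#' @return a \linkS4class{BrainVolume}
#' @examples
#' v <- brainVolume(array(1, dim = c(4, 4, 2)))
#' voxelDims(v)
#' @export
brainVolume <- function(data, voxelDims = c(0.75, 0.75, 3.5), affine = NULL) {
  data <- as.array(data)
  storage.mode(data) <- "double"
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (is.null(affine)) affine <- centredAffine(dim(data), voxelDims)
  new("BrainVolume", data = data, affine = affine,
      voxelDims = as.numeric(voxelDims))
}

#' Create a BrainMask
#'
#' @param data 3D array, coerced to logical (non-zero = inside).
#' @param voxelDims numeric length-3 voxel size in mm.
#' @param affine optional 4x4 voxel-to-world matrix.
#' @param geometryFrom optional BrainVolume/BrainMask whose geometry
#'   (voxel dims and affine) is copied.
#' @return a \linkS4class{BrainMask}
#' @export
brainMask <- function(data, voxelDims = c(0.75, 0.75, 3.5), affine = NULL,
                      geometryFrom = NULL) {
  data <- as.array(data)
  storage.mode(data) <- "logical"
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (!is.null(geometryFrom)) {
    voxelDims <- geometryFrom@voxelDims
    affine <- geometryFrom@affine
  }
  if (is.null(affine)) affine <- centredAffine(dim(data), voxelDims)
  new("BrainMask", data = data, affine = affine,
      voxelDims = as.numeric(voxelDims))
}

# Diagonal RAS+ affine with the world origin at the grid centre:
# world = voxelDims * (index - (dim + 1) / 2), 1-based indices.
centredAffine <- function(gridShape, voxelDims) {
  aff <- diag(c(voxelDims, 1))
  aff[1:3, 4] <- -voxelDims * (gridShape + 1) / 2
  aff
}

#' @rdname voxelData
#' @export
setMethod("voxelData", "BrainVolume", function(x) x@data)

#' @rdname voxelDims
#' @export
setMethod("voxelDims", "BrainVolume", function(x) x@voxelDims)

#' @rdname voxelAffine
#' @export
setMethod("voxelAffine", "BrainVolume", function(x) x@affine)

#' @rdname voxelCount
#' @export
setMethod("voxelCount", "BrainMask", function(x) sum(x@data))

#' @rdname maskVolumeCm3
#' @export
setMethod("maskVolumeCm3", "BrainMask", function(x)
  sum(x@data) * prod(x@voxelDims) / 1000)

setMethod("dim", "BrainVolume", function(x) dim(x@data))

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("BrainVolume %d x %d x %d, voxels %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@voxelDims[1], object@voxelDims[2],
              object@voxelDims[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "BrainMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("BrainMask %d x %d x %d, %d voxels in mask (%.4g cm^3)\n",
              d[1], d[2], d[3], sum(object@data), maskVolumeCm3(object)))
})

#' Do two volumes share grid shape, voxel dims and affine?
#' @param a,b BrainVolume or BrainMask objects
#' @param tol numeric tolerance on affine/voxel-dim comparison
#' @return logical
#' @export
sameGeometry <- function(a, b, tol = 1e-8) {
  identical(dim(a@data), dim(b@data)) &&
    max(abs(a@affine - b@affine)) <= tol &&
    max(abs(a@voxelDims - b@voxelDims)) <= tol
}

stopIfGeometryMismatch <- function(a, b, what = "inputs") {
  if (!sameGeometry(a, b))
    stop(sprintf(
      "%s have mismatched geometry: shapes %s vs %s, voxel dims %s vs %s",
      what, paste(dim(a@data), collapse = "x"),
      paste(dim(b@data), collapse = "x"),
      paste(signif(a@voxelDims, 4), collapse = "x"),
      paste(signif(b@voxelDims, 4), collapse = "x")))
  invisible(TRUE)
}

#' World coordinates (mm) of voxel indices
#' @param x a BrainVolume or BrainMask
#' @param idx integer matrix (n x 3) of 1-based voxel indices
#' @return numeric matrix (n x 3) of world mm coordinates
#' @export
worldCoords <- function(x, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  h <- cbind(idx, 1) %*% t(x@affine)
  h[, 1:3, drop = FALSE]
}

#' Hemisphere labels from world x-coordinates
#'
#' Labels each voxel by the sign of the world x-coordinate of its centre
#' in atlas space (RAS+: +x = right): -1 left, +1 right, 0 for voxels
#' exactly on the midline plane, which are excluded from both hemispheres.
#'
#' @param x a BrainVolume or BrainMask providing the geometry
#' @return 3D integer array of labels
#' @export
hemisphereLabels <- function(x) {
  d <- dim(x@data)
  i <- seq_len(d[1])
  wx <- x@affine[1, 1] * i + x@affine[1, 4]
  lab <- as.integer(sign(wx))
  array(rep(lab, times = d[2] * d[3]), dim = d)
}

#' Write a volume or mask to a NIfTI file
#'
#' Masks are written as 0/1 integer volumes. The affine is stored in both
#' the sform and qform.
#'
#' @param x a BrainVolume or BrainMask
#' @param path output file path (.nii or .nii.gz)
#' @return the path, invisibly
#' @export
writeVolume <- function(x, path) {
  dat <- x@data
  if (is.logical(dat)) storage.mode(dat) <- "integer"
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- x@voxelDims
  # RNifti xforms map 0-based indices; shift the 1-based translation
  aff <- x@affine
  aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1:3] %*% rep(1, 3)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as a BrainVolume or BrainMask
#'
#' @param path NIfTI file path
#' @param mask logical; if TRUE return a BrainMask (non-zero voxels)
#' @return a BrainVolume or BrainMask
#' @export
readVolume <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(aff), 4, 4)
  aff[1:3, 4] <- aff[1:3, 4] - aff[1:3, 1:3] %*% rep(1, 3)
  vd <- RNifti::pixdim(img)[1:3]
  dat <- array(as.numeric(img), dim = dim(img))
  if (mask) brainMask(dat != 0, voxelDims = vd, affine = aff)
  else brainVolume(dat, voxelDims = vd, affine = aff)
}
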