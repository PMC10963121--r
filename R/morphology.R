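# Binary-mask morphology with explicit connectivity and border conventions.
#
# Conventions (shared with the brute-force oracles in the test suite):
#  - dilation: a voxel is set if it is set in the input or any
#    element-neighbour is set; neighbours outside the grid are ignored.
#  - erosion: a voxel survives iff it and all element-neighbours are set;
#    neighbours outside the grid count as unset, so border voxels erode.

#' Create a structuring element
#'
#' @param kind \code{"in_plane_8"} (the 8 in-slice neighbours, used for the
#'   2D recursive dilations defining the NAWM distance strata) or
#'   \code{"cross_3d_6"} (the 6 face neighbours, used for the conservative
#'   WM-mask erosions/dilation).
#' @return a \linkS4class{StructuringElement}
#' @examples
#' structuringElement("in_plane_8")
#' @export
structuringElement <- function(kind = c("in_plane_8", "cross_3d_6")) {
  kind <- match.arg(kind)
  offsets <- switch(kind,
    in_plane_8 = {
      g <- expand.grid(di = -1:1, dj = -1:1, dk = 0L)
      as.matrix(g[!(g$di == 0 & g$dj == 0), ])
    },
    cross_3d_6 = matrix(c(-1, 0, 0,  1, 0, 0,  0, -1, 0,
                           0, 1, 0,  0, 0, -1, 0, 0, 1),
                        ncol = 3, byrow = TRUE))
  storage.mode(offsets) <- "integer"
  dimnames(offsets) <- NULL
  new("StructuringElement", kind = kind, offsets = offsets)
}

# Shift a logical array by integer offset d, filling exposed planes FALSE.
shiftLogical <- function(g, d) {
  dm <- dim(g)
  out <- array(FALSE, dm)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    n <- dm[ax]
    if (abs(d[ax]) >= n) return(out)
    if (d[ax] >= 0) {
      dst[[ax]] <- (1L + d[ax]):n
      src[[ax]] <- 1L:(n - d[ax])
    } else {
      dst[[ax]] <- 1L:(n + d[ax])
      src[[ax]] <- (1L - d[ax]):n
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    g[src[[1]], src[[2]], src[[3]]]
  out
}

#' Dilate a binary mask
#'
#' @param mask a BrainMask
#' @param element a StructuringElement (default the 2D 8-neighbour kernel)
#' @return the dilated BrainMask
#' @examples
#' m <- brainMask(array(FALSE, c(5, 5, 3)))
#' m@data[3, 3, 2] <- TRUE
#' voxelCount(dilateMask(m))  # 9: a 3x3 in-slice square
#' @export
dilateMask <- function(mask, element = structuringElement("in_plane_8")) {
  g <- mask@data
  out <- g
  for (r in seq_len(nrow(element@offsets)))
    out <- out | shiftLogical(g, element@offsets[r, ])
  brainMask(out, geometryFrom = mask)
}

#' Erode a binary mask
#'
#' Out-of-grid neighbours count as background, so voxels on the relevant
#' grid borders are always removed.
#'
#' @inheritParams dilateMask
#' @return the eroded BrainMask
#' @export
erodeMask <- function(mask, element = structuringElement("in_plane_8")) {
  g <- mask@data
  out <- g
  for (r in seq_len(nrow(element@offsets))) {
    d <- element@offsets[r, ]
    # voxel v needs neighbour v + d set; that value arrives at v when the
    # grid is shifted by -d
    out <- out & shiftLogical(g, -d)
  }
  brainMask(out, geometryFrom = mask)
}

#' Voxelwise set algebra on two masks of identical geometry
#'
#' @param a,b BrainMask objects sharing geometry
#' @param op \code{"difference"} (a minus b), \code{"intersection"} or
#'   \code{"union"}
#' @return a BrainMask
#' @export
maskAlgebra <- function(a, b, op = c("difference", "intersection", "union")) {
  op <- match.arg(op)
  stopIfGeometryMismatch(a, b, "mask operands")
  out <- switch(op,
    difference   = a@data & !b@data,
    intersection = a@data & b@data,
    union        = a@data | b@data)
  brainMask(out, geometryFrom = a)
}

#' Complement of a mask
#' @param mask a BrainMask
#' @return a BrainMask with membership inverted
#' @export
maskComplement <- function(mask) brainMask(!mask@data, geometryFrom = mask)
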