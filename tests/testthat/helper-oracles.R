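# Independent brute-force oracles and fixture builders shared by the
# tests. These deliberately use naive per-voxel loops, not the package's
# array-shift implementation.

elementOffsets <- function(kind) {
  if (kind == "in_plane_8") {
    offs <- expand.grid(di = -1:1, dj = -1:1, dk = 0)
    as.matrix(offs[!(offs$di == 0 & offs$dj == 0), ])
  } else {
    matrix(c(-1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1),
           ncol = 3, byrow = TRUE)
  }
}

# Per-voxel neighbour scan; out-of-grid neighbours ignored (dilate) or
# counted as background (erode).
bruteMorph <- function(g, kind, op) {
  d <- dim(g)
  offs <- elementOffsets(kind)
  nr <- nrow(offs)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    val <- g[i, j, k]
    if (op == "dilate") {
      if (!val) for (r in seq_len(nr)) {
        pi <- i + offs[r, 1]; pj <- j + offs[r, 2]; pk <- k + offs[r, 3]
        if (pi >= 1 && pi <= d[1] && pj >= 1 && pj <= d[2] &&
            pk >= 1 && pk <= d[3] && g[pi, pj, pk]) { val <- TRUE; break }
      }
    } else {
      # out-of-grid neighbours count as background
      if (val) for (r in seq_len(nr)) {
        pi <- i + offs[r, 1]; pj <- j + offs[r, 2]; pk <- k + offs[r, 3]
        if (pi < 1 || pi > d[1] || pj < 1 || pj > d[2] ||
            pk < 1 || pk > d[3] || !g[pi, pj, pk]) { val <- FALSE; break }
      }
    }
    out[i, j, k] <- val
  }
  out
}

# In-slice Chebyshev distance from every voxel to the nearest LKA voxel
# in the same slice (Inf if the slice has none).
chebyshevStrata <- function(lkaArr, nawmArr, nStrata = 5) {
  d <- dim(lkaArr)
  strata <- lapply(seq_len(nStrata), function(k) array(FALSE, d))
  for (k in seq_len(d[3])) {
    les <- which(lkaArr[, , k], arr.ind = TRUE)
    if (nrow(les) == 0) next
    tgt <- which(nawmArr[, , k], arr.ind = TRUE)
    for (t in seq_len(nrow(tgt))) {
      dist <- min(pmax(abs(les[, 1] - tgt[t, 1]), abs(les[, 2] - tgt[t, 2])))
      if (dist >= 1 && dist <= nStrata)
        strata[[dist]][tgt[t, 1], tgt[t, 2], k] <- TRUE
    }
  }
  strata
}

# Erosion-by-duality oracle: erode(M) = complement(dilate(complement(M)))
# evaluated on a one-voxel padded domain, where the padding belongs to the
# complement. This reproduces the border convention that out-of-grid
# neighbours count as background for erosion.
dualErode <- function(m, el) {
  d <- dim(m@data)
  pad <- array(TRUE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- !m@data
  pd <- dilateMask(brainMask(pad), el)@data
  !pd[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}

randomMaskArray <- function(dims, p = 0.3) {
  array(runif(prod(dims)) < p, dim = dims)
}

# Small phantom configuration for fast pipeline tests.
smallPhantomConfig <- function(...) {
  args <- list(gridShape = c(36L, 42L, 8L),
               burdenBandsCm3 = matrix(c(0.08, 0.2, 0.35, 0.5,
                                         0.65, 0.8, 0.95, 1.15),
                                       nrow = 4, byrow = TRUE))
  do.call(phantomConfig, utils::modifyList(args, list(...)))
}

quartileEffectRow <- function(fit) {
  fe <- fixedEffects(fit)
  fe[fe$term == "lka_quartile", ]
}
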