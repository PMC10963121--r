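test_that("threshold arithmetic: mean + 6 SD with sample (n-1) SD", {
  x <- c(95, 100, 105, 100, 95, 105, 100, 100)
  expect_equal(lkaThreshold(x), mean(x) + 6 * sd(x))
  # hand-computed: mean 100, SD 5
  y <- c(95, 105, 95, 105, 95, 105, 95, 105)
  expect_equal(mean(y), 100)
  expect_equal(sd(y), 5 * sqrt(8 / 7), tolerance = 1e-12)
  expect_equal(lkaThreshold(c(97, 103, 100, 100)), 100 + 6 * sd(c(97, 103, 100, 100)))
  # zero variance: threshold equals the common value
  expect_equal(lkaThreshold(rep(7.5, 9)), 7.5)
  # two-point sample, hand arithmetic: mean 0.82, sd 0.02828427
  expect_equal(lkaThreshold(c(0.80, 0.84)), 0.82 + 6 * 0.04 / sqrt(2),
               tolerance = 1e-9)
  expect_equal(lkaThreshold(c(0.80, 0.84)), 0.9897056, tolerance = 1e-6)
  expect_error(lkaThreshold(5), "at least 2")
})

test_that("CSF exclusion threshold is the sample maximum and monotone", {
  expect_equal(csfExclusionThreshold(c(0.1, 0.2, 0.15)), 0.2)
  expect_equal(csfExclusionThreshold(0.3), 0.3)
  expect_error(csfExclusionThreshold(numeric(0)), "empty")
  set.seed(1)
  v <- runif(8)
  for (i in seq_along(v)) {
    v2 <- v; v2[i] <- v2[i] + 0.5
    expect_gte(csfExclusionThreshold(v2), csfExclusionThreshold(v))
  }
})

test_that("the 6-SD rule is affine-equivariant", {
  set.seed(4)
  v <- rnorm(10, 100, 5)
  a <- 2.7; b <- 13
  expect_equal(lkaThreshold(a * v), a * lkaThreshold(v))
  expect_equal(lkaThreshold(a * v + b), a * lkaThreshold(v) + b)
})

test_that("ROI sampling: constant field, determinism, single-voxel ROIs", {
  arr <- array(5.0, c(20, 20, 4))
  vol <- brainVolume(arr)
  region <- brainMask(array(FALSE, c(20, 20, 4)), geometryFrom = vol)
  region@data[5:16, 5:16, 2:3] <- TRUE
  s1 <- sampleROIs(vol, region, 10, "splenium", seed = 9)
  expect_true(all(s1@values == 5.0))
  s2 <- sampleROIs(vol, region, 10, "splenium", seed = 9)
  expect_identical(s1@centresMm, s2@centresMm)
  expect_identical(s1@values, s2@values)

  # 1-mm sphere on 0.75 x 0.75 x 3.5 mm voxels covers only the containing
  # voxel: the geometric oracle is the set of voxel centres within 0.5 mm
  offs <- nawmstrata:::sphereOffsets(c(0.75, 0.75, 3.5), 1.0)
  expect_identical(offs, matrix(0L, 1, 3))
  arr2 <- array(rnorm(20 * 20 * 4), c(20, 20, 4))
  vol2 <- brainVolume(arr2)
  s3 <- sampleROIs(vol2, region, 8, "splenium", seed = 21)
  inv <- solve(voxelAffine(vol2))
  idx <- round(cbind(s3@centresMm, 1) %*% t(inv))[, 1:3]
  expect_equal(s3@values, arr2[idx], tolerance = 1e-12)

  # planted maximum recovered through explicit centre placement
  arr3 <- array(0.1, c(20, 20, 4)); arr3[10, 10, 2] <- 0.9
  vol3 <- brainVolume(arr3)
  sm <- sampleROIsAt(vol3, worldCoords(vol3, rbind(c(10, 10, 2),
                                                   c(6, 6, 2),
                                                   c(14, 6, 3),
                                                   c(6, 14, 3),
                                                   c(14, 14, 2),
                                                   c(8, 12, 3))),
                     "ventricle")
  expect_equal(csfExclusionThreshold(sm), 0.9)
})

test_that("ROI placement failures name the region", {
  vol <- brainVolume(array(1, c(6, 6, 2)))
  tiny <- brainMask(array(FALSE, c(6, 6, 2)), geometryFrom = vol)
  tiny@data[3, 3, 1] <- TRUE
  expect_error(sampleROIs(vol, tiny, 8, "splenium", seed = 1), "splenium")
  empty <- brainMask(array(FALSE, c(6, 6, 2)), geometryFrom = vol)
  expect_error(sampleROIs(vol, empty, 6, "ventricle", seed = 1),
               "ventricle")
})

test_that("ROI sample sizes follow the source conventions", {
  expect_error(new("ROISample", values = rnorm(12), source = "splenium",
                   diameterMm = 1, centresMm = matrix(0, 12, 3)),
               "8-10")
  expect_error(new("ROISample", values = rnorm(3), source = "ventricle",
                   diameterMm = 1, centresMm = matrix(0, 3, 3)),
               "6-8")
})

test_that("calibrationThresholds assembles both thresholds consistently", {
  thr <- calibrationThresholds(c(99, 101, 100, 98, 102, 100, 99, 101),
                               c(20, 35, 30, 22, 28, 26))
  expect_equal(thr@lkaThreshold, thr@spleniumMean + 6 * thr@spleniumSd)
  expect_equal(thr@csfMax, 35)
  expect_equal(oracleThresholds(100, 5, 40)@lkaThreshold, 130)
  expect_equal(oracleThresholds(100, 5, 40)@csfMax, 40)
})
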