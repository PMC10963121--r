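test_that("WM probability threshold is inclusive and morphology shrinks", {
  arr <- array(0, c(7, 7, 7))
  arr[2, 2, 2] <- 0.94; arr[3, 3, 3] <- 0.95; arr[4, 4, 4] <- 0.96
  prob <- brainVolume(arr)
  supra <- brainMask(array(TRUE, c(7, 7, 7)), geometryFrom = prob)
  pass <- prob@data >= 0.95
  expect_identical(sum(pass), 2L)

  # solid probability-1 cube: erode x2 shrinks to a 3x3x3 core, and the
  # face-connectivity dilation re-grows it into the 81-voxel cross-solid
  # (Minkowski sum of the core with the 6-cross), per the brute-force
  # morphology oracle
  cube <- array(0, c(9, 9, 9)); cube[2:8, 2:8, 2:8] <- 1
  wm <- wmMaskFromProbability(brainVolume(cube),
                              brainMask(array(TRUE, c(9, 9, 9))))
  expected <- bruteMorph(bruteMorph(bruteMorph(cube >= 0.95,
    "cross_3d_6", "erode"), "cross_3d_6", "erode"), "cross_3d_6", "dilate")
  core <- array(FALSE, c(9, 9, 9)); core[4:6, 4:6, 4:6] <- TRUE
  expect_identical(bruteMorph(bruteMorph(cube >= 0.95, "cross_3d_6",
                                         "erode"), "cross_3d_6", "erode"),
                   core)
  expect_identical(wm@data, expected)
  expect_equal(sum(wm@data), 81L)

  expect_warning(
    wmMaskFromProbability(brainVolume(array(0, c(5, 5, 5))),
                          brainMask(array(TRUE, c(5, 5, 5)))),
    "empty")
  expect_error(
    wmMaskFromProbability(brainVolume(array(2, c(3, 3, 3))),
                          brainMask(array(TRUE, c(3, 3, 3)))),
    "\\[0, 1\\]")
})

test_that("LKA segmentation equals a brute-force voxel filter", {
  vals <- matrix(c(0.5, 1.2, 0.9, 1.4,
                   1.3, 0.2, 1.1, 0.7,
                   1.5, 1.0, 0.3, 1.2,
                   0.8, 1.3, 1.4, 0.1), 4, 4)
  flair <- brainVolume(array(vals, c(4, 4, 1)))
  outline <- brainMask(array(TRUE, c(4, 4, 1)), geometryFrom = flair)
  outline@data[1, , 1] <- FALSE
  thr <- oracleThresholds(1.0, 0.03, 0.4)  # lka >= 1.18, csf floor 0.4
  got <- segmentLKA(flair, outline, thr)
  brute <- array(FALSE, c(4, 4, 1))
  for (i in 1:4) for (j in 1:4)
    brute[i, j, 1] <- outline@data[i, j, 1] &&
      vals[i, j] >= 1.18 && vals[i, j] >= 0.4
  expect_identical(got@data, brute)
  # empty outline is valid: no lesions
  expect_equal(voxelCount(segmentLKA(flair,
    brainMask(array(FALSE, c(4, 4, 1)), geometryFrom = flair), thr)), 0L)
})

test_that("NAWM = (WM - LKA) minus sub-CSF voxels, matching set algebra", {
  set.seed(10)
  arr <- array(runif(6 * 6 * 3, 0, 2), c(6, 6, 3))
  flair <- brainVolume(arr)
  wm <- brainMask(randomMaskArray(c(6, 6, 3), 0.7), geometryFrom = flair)
  lka <- brainMask(randomMaskArray(c(6, 6, 3), 0.2), geometryFrom = flair)
  thr <- oracleThresholds(1.0, 0.05, 0.6)
  got <- buildNAWM(wm, lka, flair, thr)
  expect_identical(got@data, wm@data & !lka@data & arr >= 0.6)
  # lka = wm gives empty NAWM; lka empty gives wm minus sub-CSF
  expect_equal(voxelCount(buildNAWM(wm, wm, flair, thr)), 0L)
  none <- brainMask(array(FALSE, c(6, 6, 3)), geometryFrom = flair)
  expect_identical(buildNAWM(wm, none, flair, thr)@data,
                   wm@data & arr >= 0.6)
})

test_that("hemisphere exclusion doubles the single-hemisphere LKA volume", {
  d <- c(20, 10, 5)
  flair <- brainVolume(array(1, d))
  hemi <- hemisphereLabels(flair)
  thr <- oracleThresholds(1, 0, 0)
  # 1000 LKA voxels at 0.75 x 0.75 x 3.5 mm: 1.96875 cm^3, not doubled
  lka <- brainMask(array(TRUE, d), geometryFrom = flair)
  expect_equal(voxelCount(lka), 1000L)
  wm <- brainMask(array(TRUE, d), geometryFrom = flair)
  nawm <- brainMask(array(FALSE, d), geometryFrom = flair)
  seg <- segmentationResult(lka, wm, nawm, thr)
  expect_equal(seg@lkaVolumeCm3, 1.96875)
  segN <- applyHemisphereExclusion(seg, hemi, "none")
  expect_equal(segN@lkaVolumeCm3, seg@lkaVolumeCm3)

  # 500 left-hemisphere voxels, right infarct: volume = 2 x left volume
  lkaL <- brainMask(array(FALSE, d), geometryFrom = flair)
  lkaL@data[1:10, 1:10, 1:5] <- TRUE
  expect_equal(voxelCount(lkaL), 500L)
  segL <- segmentationResult(lkaL, wm,
    brainMask(array(FALSE, d), geometryFrom = flair), thr)
  segR <- applyHemisphereExclusion(segL, hemi, "right")
  expect_equal(segR@lkaVolumeCm3, 2 * 500 * 0.00196875)
  expect_equal(segR@lkaVolumeCm3, 1.96875)
  expect_equal(voxelCount(segR@lkaMask), 500L)
  expect_false(any(segR@nawmMask@data[11:20, , ]))
  expect_error(applyHemisphereExclusion(seg, hemi, "bilateral"), "unknown")
})

test_that("mirrored lesions: doubled one-sided volume equals bilateral", {
  d <- c(16, 12, 3)
  flair <- brainVolume(array(1, d))
  hemi <- hemisphereLabels(flair)
  lka <- array(FALSE, d)
  lka[3:5, 4:8, 2] <- TRUE          # left-hemisphere block
  lka[16 - (2:4), 4:8, 2] <- TRUE   # mirrored on the right
  m <- brainMask(lka, geometryFrom = flair)
  wm <- brainMask(array(TRUE, d), geometryFrom = flair)
  seg <- segmentationResult(m, wm,
    brainMask(wm@data & !lka, geometryFrom = flair),
    oracleThresholds(1, 0, 0))
  bilateral <- seg@lkaVolumeCm3
  segEx <- applyHemisphereExclusion(seg, hemi, "left")
  expect_equal(segEx@lkaVolumeCm3, bilateral)
})

test_that("all masks are invariant under global intensity scaling", {
  cfg <- smallPhantomConfig(seed = 31L)
  b <- generateSubject(cfg, 77L, 3L)
  run1 <- runSubject(b, seed = 5)
  b2 <- b
  b2@flair <- brainVolume(b@flair@data * 3.7, voxelDims = voxelDims(b@flair),
                          affine = voxelAffine(b@flair))
  run2 <- runSubject(b2, seed = 5)
  expect_identical(run1$segmentation@lkaMask@data,
                   run2$segmentation@lkaMask@data)
  expect_identical(run1$segmentation@nawmMask@data,
                   run2$segmentation@nawmMask@data)
  expect_equal(run2$segmentation@thresholds@lkaThreshold,
               3.7 * run1$segmentation@thresholds@lkaThreshold)
  # splenium-normalized metrics cancel the scale too
  expect_equal(run1$rows$nawm_m, run2$rows$nawm_m, tolerance = 1e-12)
})

test_that("segmentation invariants hold on noisy pipeline runs", {
  cfg <- smallPhantomConfig(seed = 13L)
  for (ss in c(5L, 6L)) {
    b <- generateSubject(cfg, ss, 4L)
    seg <- runSubject(b, seed = 2)$segmentation
    expect_equal(voxelCount(maskAlgebra(seg@lkaMask, seg@nawmMask,
                                        "intersection")), 0L)
    expect_true(all(seg@nawmMask@data <= seg@wmMask@data))
    expect_true(all(b@flair@data[seg@nawmMask@data] >=
                      seg@thresholds@csfMax))
    expect_true(all(b@flair@data[seg@lkaMask@data] >=
                      seg@thresholds@csfMax))
    if (seg@hemisphereExcluded != "none") {
      gone <- if (seg@hemisphereExcluded == "left") -1L else 1L
      expect_false(any(seg@lkaMask@data[b@hemisphereMap == gone]))
      expect_false(any(seg@nawmMask@data[b@hemisphereMap == gone]))
    }
  }
})
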