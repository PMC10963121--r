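test_that("degenerate generator: all NAWM voxels exactly the WM base", {
  cfg <- smallPhantomConfig(noiseSd = 0, burdenEffectPerQuartile = 0,
                            distanceDecayPerVoxel = 0,
                            ageEffectPerDecade = 0, seed = 2L)
  b <- generateSubject(cfg, 10L, 3L)
  wmComp <- nawmstrata:::phantomGeometry(cfg)$wmComp
  nawmVox <- b@flair@data[wmComp & !b@truthLesionMask@data]
  expect_true(all(nawmVox == cfg@wmBaseIntensity))
})

test_that("identical seeds give bit-identical bundles", {
  cfg <- smallPhantomConfig(seed = 3L)
  a <- generateSubject(cfg, 21L, 2L)
  b <- generateSubject(cfg, 21L, 2L)
  expect_identical(a@flair@data, b@flair@data)
  expect_identical(a@truthLesionMask@data, b@truthLesionMask@data)
  expect_identical(a@covariates, b@covariates)
  c2 <- generateSubject(cfg, 22L, 2L)
  expect_false(identical(a@flair@data, c2@flair@data))
})

test_that("higher burden levels produce strictly larger lesion volumes", {
  cfg <- smallPhantomConfig(seed = 6L)
  v1 <- vapply(1:12, function(s)
    maskVolumeCm3(generateSubject(cfg, s, 1L)@truthLesionMask), numeric(1))
  v4 <- vapply(1:12, function(s)
    maskVolumeCm3(generateSubject(cfg, 100L + s, 4L)@truthLesionMask),
    numeric(1))
  expect_gt(mean(v4), mean(v1))
  # disjoint bands make even the extremes ordered
  expect_gt(min(v4), max(v1))
  expect_true(all(v1 >= cfg@burdenBandsCm3[1, 1]))
  expect_true(all(v4 >= cfg@burdenBandsCm3[4, 1]))
})

test_that("bundle invariants: lesions above threshold, masks consistent", {
  cfg <- smallPhantomConfig(seed = 14L)
  for (lev in c(1L, 4L)) {
    b <- generateSubject(cfg, 30L + lev, lev)
    expect_true(all(b@truthLesionMask@data <= b@outlineMask@data))
    expect_false(any(b@spleniumMask@data & b@ventricleMask@data))
    # generated lesion voxels exceed the generator's splenium mean + 6 SD
    lesionVox <- b@flair@data[b@truthLesionMask@data]
    expect_true(all(lesionVox > cfg@spleniumIntensityMean +
                      6 * cfg@spleniumIntensitySd))
    expect_true(validObject(b))
  }
})

test_that("noise-free segmentation recovers ground truth exactly (Dice 1)", {
  cfg <- smallPhantomConfig(noiseSd = 0, seed = 9L,
                            infarctSideProbs = c(none = 1, left = 0,
                                                 right = 0))
  for (lev in 1:4) {
    b <- generateSubject(cfg, 50L + lev, lev)
    res <- runSubject(b, calibration = "oracle", config = cfg)
    expect_identical(res$segmentation@lkaMask@data, b@truthLesionMask@data)
  }
})

test_that("injected NAWM_M slope across levels equals the burden effect", {
  # with zero noise and no distance decay, per-stratum NAWM_M is linear
  # in the burden level with slope exactly burdenEffectPerQuartile
  cfg <- smallPhantomConfig(noiseSd = 0, distanceDecayPerVoxel = 0,
                            ageEffectPerDecade = 0, seed = 4L,
                            infarctSideProbs = c(none = 1, left = 0,
                                                 right = 0))
  m <- vapply(1:4, function(lev) {
    b <- generateSubject(cfg, 70L + lev, lev)
    res <- runSubject(b, calibration = "oracle", config = cfg)
    res$rows$nawm_m[res$rows$stratum == "3"]
  }, numeric(1))
  expect_equal(diff(m), rep(cfg@burdenEffectPerQuartile, 3),
               tolerance = 1e-9)
})

test_that("cohorts are balanced and covariates follow the stated model", {
  cfg <- smallPhantomConfig(seed = 12L)
  plan <- nawmstrata:::cohortPlan(cfg, 8)
  expect_equal(as.vector(table(plan$levels)), rep(2L, 4))

  # covariate model at scale: ages Normal(68, 16), copula correlation
  levels <- rep_len(1:4, 600)
  covs <- lapply(seq_along(levels), function(s)
    nawmstrata:::drawSubjectCovariates(cfg, 100000L + s, levels[s]))
  ages <- vapply(covs, `[[`, numeric(1), "age")
  expect_lt(abs(mean(ages) - 68), 3)
  expect_gt(cor(ages, levels), 0.25)
  htn <- vapply(covs, `[[`, numeric(1), "htn")
  expect_lt(abs(mean(htn) - cfg@hypertensionPrevalence), 0.08)

  # zero copula weight decouples age from burden
  cfg0 <- smallPhantomConfig(seed = 12L, ageBurdenCorrelation = 0)
  ages0 <- vapply(seq_along(levels), function(s)
    nawmstrata:::drawSubjectCovariates(cfg0, 200000L + s,
                                       levels[s])$age, numeric(1))
  expect_lt(abs(cor(ages0, levels)), 0.1)
})

test_that("generateCohort validates size and returns matching covariates", {
  cfg <- smallPhantomConfig(seed = 18L)
  expect_error(generateCohort(cfg, 7), "at least 8")
  ch <- generateCohort(cfg, 8)
  expect_length(ch$subjects, 8)
  expect_equal(nrow(ch$covariates), 8)
  expect_equal(sort(unique(ch$covariates$truth_burden_level)), 1:4)
})

test_that("impossible lesion targets fail naming the constraint", {
  cfg <- smallPhantomConfig(seed = 2L,
    burdenBandsCm3 = matrix(c(0.08, 0.2, 0.35, 0.5, 0.65, 0.8, 50, 51),
                            nrow = 4, byrow = TRUE),
    lesionCountRange = c(1L, 40L))
  expect_error(generateSubject(cfg, 1L, 4L), "burden band")
})

test_that("phantom config YAML round-trips", {
  cfg <- smallPhantomConfig(seed = 77L, noiseSd = 1.5)
  f <- tempfile(fileext = ".yaml")
  phantomConfigToYaml(cfg, f)
  cfg2 <- phantomConfigFromYaml(f)
  for (sl in slotNames("PhantomConfig"))
    expect_equal(slot(cfg2, sl), slot(cfg, sl), tolerance = 1e-12,
                 label = sl)
  writeLines(c("gridShape: [10, 10, 4]", "bogusKey: 3"), f)
  expect_error(phantomConfigFromYaml(f), "bogusKey")
})
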