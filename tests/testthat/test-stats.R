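test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(2)
  tab <- data.frame(
    stratum = rep(c("1", "2"), each = 15),
    nawm_m = c(rnorm(15, 1.15, 0.05), rnorm(15, 1.18, 0.05)))
  a <- strataAnova(tab)
  tt <- t.test(nawm_m ~ stratum, data = tab, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA under equal group means is null-calibrated", {
  set.seed(31)
  base <- rnorm(20, 0, 0.04)
  tab <- data.frame(stratum = rep(as.character(1:5), each = 20),
                    nawm_m = 1.15 + rep(base, 5)[sample(100)])
  a <- strataAnova(tab)
  # permutation oracle for the p-value
  obs <- a$F
  perm <- replicate(400, {
    t2 <- tab; t2$stratum <- sample(t2$stratum)
    strataAnova(t2)$F
  })
  pPerm <- mean(perm >= obs)
  expect_gt(a$p, 0.01)
  expect_lt(abs(a$p - pPerm), 0.12)
  expect_error(strataAnova(data.frame(stratum = "1", nawm_m = 1)),
               ">= 2 strata")
})

test_that("univariate screen chooses tests by type and normality", {
  set.seed(12)
  n <- 60
  x <- rnorm(n, 50, 8)
  df <- data.frame(nawm_m = 1 + 0.01 * x, age = x,
                   hypertension = rep(0:1, each = n / 2),
                   lka_volume_cm3 = exp(x / 10))
  res <- univariateScreen(df, c(age = "quantitative",
                                hypertension = "binary",
                                lka_volume_cm3 = "quantitative"))
  ageRow <- res[res$covariate == "age", ]
  expect_equal(ageRow$test, "pearson")
  expect_equal(ageRow$statistic, 1, tolerance = 1e-9)
  # monotone nonlinear association: Spearman rho = 1, Pearson would be < 1
  lkaRow <- res[res$covariate == "lka_volume_cm3", ]
  expect_equal(lkaRow$test, "spearman")
  expect_equal(lkaRow$statistic, 1, tolerance = 1e-9)
  expect_lt(cor(df$lka_volume_cm3, df$nawm_m), 1)
  expect_true(res[res$covariate == "hypertension", "test"] %in%
                c("t", "wilcoxon"))

  expect_message(
    res2 <- univariateScreen(cbind(df, one = 1),
                             c(one = "binary", age = "quantitative")),
    "single level")
  expect_false("one" %in% res2$covariate)
})

test_that("null covariates give approximately uniform p-values", {
  set.seed(77)
  ps <- replicate(300, {
    df <- data.frame(nawm_m = rnorm(24, 1.15, 0.06),
                     grp = rep(0:1, each = 12))
    univariateScreen(df, c(grp = "binary"))$p
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("mixed model recovers exactly constructed fixed effects", {
  tab <- simulateStratumTable(nSubjects = 40, intercept = 1.0,
    quartileEffect = 0.025, ageEffectPerDecade = 0.011,
    hypertensionEffect = 0.006, stratumInterceptSd = 0,
    residualSd = 1e-8, seed = 3)
  fit <- suppressMessages(fitLMM(tab, randomSlopes = FALSE))
  fe <- fixedEffects(fit)
  expect_equal(fe$estimate[fe$term == "(Intercept)"], 1.0, tolerance = 1e-6)
  expect_equal(fe$estimate[fe$term == "lka_quartile"], 0.025,
               tolerance = 1e-6)
  expect_equal(fe$estimate[fe$term == "age_decades"], 0.011,
               tolerance = 1e-6)
  expect_equal(fe$estimate[fe$term == "hypertension"], 0.006,
               tolerance = 1e-6)
  expect_equal(fe$ci_lo, fe$estimate - 1.96 * fe$se, tolerance = 1e-12)
  expect_equal(fit@aic, 2 * 6 - 2 * fit@logLik, tolerance = 1e-8)
})

test_that("slope-homogeneous data: both models agree within 1 SE", {
  tab <- simulateStratumTable(nSubjects = 100, residualSd = 0.075,
                              stratumSlopeSd = 0, seed = 41)
  fI <- suppressMessages(fitLMM(tab, FALSE))
  fS <- suppressMessages(fitLMM(tab, TRUE))
  qi <- quartileEffectRow(fI); qs <- quartileEffectRow(fS)
  expect_lt(abs(qi$estimate - qs$estimate), qi$se)
  expect_false(fI@hasRandomSlopes)
  expect_true(fS@hasRandomSlopes)
})

test_that("conditional-mode slopes track injected per-stratum slopes", {
  # per-stratum quartile slopes shaped like the reference pattern
  # noise small relative to the 0.001 slope gaps, so conditional modes
  # (shrunken but monotone) must preserve the ranks
  trueSlopes <- c(0.014, 0.024, 0.027, 0.028, 0.029)
  hits <- vapply(1:8, function(r) {
    tab <- simulateStratumTable(nSubjects = 100, quartileEffect = 0.025,
      stratumSlopes = trueSlopes - 0.025, residualSd = 0.003,
      seed = 500 + r)
    fit <- suppressMessages(fitLMM(tab, randomSlopes = TRUE))
    re <- randomEffects(fit)
    sl <- re$slope[order(as.integer(re$stratum))]
    identical(rank(sl), rank(trueSlopes))  # Spearman rho exactly 1
  }, logical(1))
  expect_true(all(hits))
})

test_that("ML log-likelihood of the wider model dominates the nested one", {
  for (s in 1:4) {
    tab <- simulateStratumTable(nSubjects = 60, stratumSlopeSd = 0.005,
                                residualSd = 0.05, seed = 600 + s)
    mI <- suppressMessages(fitLMM(tab, FALSE, "ML"))
    mS <- suppressMessages(fitLMM(tab, TRUE, "ML"))
    expect_gte(mS@logLik, mI@logLik - 1e-6)
  }
})

test_that("fixed effects are invariant to stratum relabeling", {
  tab <- simulateStratumTable(nSubjects = 50, seed = 15)
  fit1 <- suppressMessages(fitLMM(tab, FALSE))
  relab <- tab
  relab$stratum <- factor(letters[as.integer(as.character(tab$stratum))])
  fit2 <- suppressMessages(fitLMM(relab, FALSE))
  expect_equal(fixedEffects(fit1)$estimate, fixedEffects(fit2)$estimate,
               tolerance = 1e-8)
})

test_that("model comparison: trivial equality and REML guard", {
  tab <- simulateStratumTable(nSubjects = 40, stratumSlopeSd = 0.01,
                              residualSd = 0.05, seed = 9)
  cmp <- suppressMessages(compareModels(tab))
  expect_gte(cmp@lrtStatistic, 0)
  expect_identical(cmp@lrtDf, 2L)
  expect_equal(cmp@lrtP,
               pchisq(cmp@lrtStatistic, 2, lower.tail = FALSE))
  expect_equal(cmp@remlIntercepts@method, "REML")
  expect_equal(cmp@remlSlopes@method, "REML")
  # the same model fitted twice has identical AIC and zero LRT
  m1 <- suppressMessages(fitLMM(tab, FALSE, "ML"))
  m2 <- suppressMessages(fitLMM(tab, FALSE, "ML"))
  expect_equal(m1@aic, m2@aic, tolerance = 1e-10)
  expect_equal(2 * (m1@logLik - m2@logLik), 0, tolerance = 1e-10)
})
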