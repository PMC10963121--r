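# Table-level cohort simulator: draws subject x stratum observation rows
# directly from the mixed-model generative structure the image pipeline
# produces, for parameter-recovery, coverage and power studies at scales
# where rendering full image volumes would add nothing.

#' Simulate a subject-by-stratum analysis table
#'
#' Generates \code{nSubjects x nStrata} rows from
#' \deqn{nawm_m = \beta_0 + b_0(s) + (\beta_q + b_1(s)) q + \beta_a
#'   age_{dec} + \beta_h htn + \epsilon}
#' with balanced quartiles q = 1..4, ages Normal(68, 16) correlated with
#' quartile through a Gaussian copula, Bernoulli hypertension, stratum
#' random intercepts \eqn{b_0} and optional random slopes \eqn{b_1}, and
#' i.i.d. Gaussian residuals. Defaults follow the package's reference
#' scale: \eqn{\beta_0} = 1.026, \eqn{\beta_q} = 0.025, \eqn{\beta_a} =
#' 0.011/decade, \eqn{\beta_h} = 0.006, stratum-intercept SD 0.07, and
#' residual SD 0.075, which yields a Wald SE near 0.003 for the quartile
#' effect at n = 100 x 5 rows.
#'
#' @param nSubjects number of subjects (default 100)
#' @param intercept fixed intercept
#' @param quartileEffect fixed effect per quartile step
#' @param ageEffectPerDecade fixed effect per decade of age
#' @param hypertensionEffect fixed effect of hypertension
#' @param stratumInterceptSd SD of stratum random intercepts
#' @param stratumSlopeSd SD of stratum random slopes (0 = slope-homogeneous)
#' @param stratumIntercepts optional explicit intercept deviations (length
#'   \code{nStrata}), overriding the random draw
#' @param stratumSlopes optional explicit slope deviations, overriding the
#'   random draw
#' @param residualSd residual SD
#' @param nStrata number of strata (default 5)
#' @param ageBurdenCorrelation copula weight in [0, 1)
#' @param hypertensionPrevalence Bernoulli probability
#' @param seed integer seed
#' @return data.frame with subject_id, stratum (factor), lka_quartile,
#'   age_decades, hypertension, nawm_m; the drawn random effects are
#'   attached as attribute \code{"truth"}
#' @export
simulateStratumTable <- function(nSubjects = 100, intercept = 1.026,
    quartileEffect = 0.025, ageEffectPerDecade = 0.011,
    hypertensionEffect = 0.006, stratumInterceptSd = 0.07,
    stratumSlopeSd = 0, residualSd = 0.075, nStrata = 5,
    stratumIntercepts = NULL, stratumSlopes = NULL,
    ageBurdenCorrelation = 0.45, hypertensionPrevalence = 0.68,
    seed = 1L) {
  if (nSubjects < 8L) stop("need at least 8 subjects")
  withSeed(seed, {
    q <- sample(rep_len(1:4, nSubjects))
    w <- ageBurdenCorrelation
    zb <- (q - mean(1:4)) / stats::sd(rep(1:4, 25))
    age <- 68 + 16 * (w * zb + sqrt(1 - w^2) * stats::rnorm(nSubjects))
    htn <- stats::rbinom(nSubjects, 1, hypertensionPrevalence)
    b0 <- if (!is.null(stratumIntercepts)) stratumIntercepts
      else stats::rnorm(nStrata, 0, stratumInterceptSd)
    b1 <- if (!is.null(stratumSlopes)) stratumSlopes
      else if (stratumSlopeSd > 0)
        stats::rnorm(nStrata, 0, stratumSlopeSd) else rep(0, nStrata)
    tab <- expand.grid(subject = seq_len(nSubjects),
                       stratum = seq_len(nStrata))
    s <- tab$stratum
    y <- intercept + b0[s] + (quartileEffect + b1[s]) * q[tab$subject] +
      ageEffectPerDecade * age[tab$subject] / 10 +
      hypertensionEffect * htn[tab$subject] +
      stats::rnorm(nrow(tab), 0, residualSd)
    out <- data.frame(
      subject_id = sprintf("S%04d", tab$subject),
      stratum = factor(s, levels = seq_len(nStrata)),
      lka_quartile = q[tab$subject],
      age_decades = age[tab$subject] / 10,
      hypertension = htn[tab$subject],
      nawm_m = y, stringsAsFactors = FALSE)
    attr(out, "truth") <- list(
      intercept = intercept, quartileEffect = quartileEffect,
      ageEffectPerDecade = ageEffectPerDecade,
      hypertensionEffect = hypertensionEffect, b0 = b0, b1 = b1)
    out
  })
}
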