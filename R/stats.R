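# Cohort-level statistics: stratum ANOVA, univariate screening, and
# linear mixed models with the NAWM strata as the clustering variable.
#
# Modelling conventions: the observation unit is subject x stratum (the
# five distance strata only; the descriptive "full NAWM" value is not a
# sixth cluster). The LKA_V quartile enters as a numeric 1-4 regressor,
# age as age/10 so coefficients read per 10-year increase. Fixed-effect
# inference is Wald (estimate +/- 1.96 SE); the random-slopes vs
# random-intercepts comparison uses ML fits, AIC and a chi-squared(2)
# likelihood-ratio test (slope variance + intercept-slope covariance),
# conservative at the variance boundary. Reported models are REML refits.

modelRows <- function(table) {
  tab <- table[table$stratum != "full", , drop = FALSE]
  tab$stratum <- factor(as.character(tab$stratum))
  tab
}

#' One-way ANOVA of NAWM_M across NAWM strata
#'
#' Fixed-effects one-way ANOVA with subjects as replicates, testing
#' whether mean normalized NAWM intensity differs between the five
#' distance strata.
#'
#' @param table data.frame with columns \code{stratum} and \code{nawm_m}
#'   (rows with stratum \code{"full"} are ignored)
#' @return list with \code{F}, \code{p}, \code{dfBetween}, \code{dfWithin}
#' @export
strataAnova <- function(table) {
  tab <- modelRows(table)
  counts <- table(tab$stratum)
  if (length(counts) < 2L || any(counts < 2L))
    stop("ANOVA needs >= 2 strata with >= 2 observations each")
  a <- stats::anova(stats::lm(nawm_m ~ stratum, data = tab))
  list(F = a[1, "F value"], p = a[1, "Pr(>F)"],
       dfBetween = a[1, "Df"], dfWithin = a[2, "Df"])
}

#' Univariate screening of covariates against subject-level NAWM_M
#'
#' Binary covariates: two-sample t-test when both groups pass the
#' Shapiro-Wilk normality check at \code{alpha}, otherwise Wilcoxon
#' rank-sum. Quantitative covariates: Pearson correlation when both
#' variables pass, otherwise Spearman. Covariates with a single observed
#' level are skipped with a message (mirroring the exclusion of sparse
#' covariates from multivariable models).
#'
#' @param subjectTable data.frame with one row per subject, a
#'   \code{nawm_m} column and the covariate columns
#' @param covariates named character vector mapping covariate column name
#'   to type, \code{"binary"} or \code{"quantitative"}
#' @param alpha Shapiro-Wilk significance level (default 0.05)
#' @return data.frame: covariate, type, test, statistic, p
#' @export
univariateScreen <- function(subjectTable,
    covariates = c(hypertension = "binary", age = "quantitative",
                   lka_volume_cm3 = "quantitative"),
    alpha = 0.05) {
  y <- subjectTable$nawm_m
  normalOk <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 3L || length(unique(v)) == 1L) return(FALSE)
    if (length(v) > 5000L) v <- v[seq_len(5000L)]
    stats::shapiro.test(v)$p.value > alpha
  }
  rows <- list()
  for (nm in names(covariates)) {
    x <- subjectTable[[nm]]
    type <- covariates[[nm]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      message(sprintf("covariate '%s' has a single level: skipped", nm))
      next
    }
    if (type == "binary") {
      g <- split(y, x)
      if (length(g) != 2L) {
        message(sprintf("covariate '%s' is not two-level: skipped", nm))
        next
      }
      if (all(vapply(g, normalOk, logical(1)))) {
        tst <- stats::t.test(g[[1]], g[[2]])
        rows[[nm]] <- data.frame(covariate = nm, type = type, test = "t",
                                 statistic = unname(tst$statistic),
                                 p = tst$p.value)
      } else {
        tst <- stats::wilcox.test(g[[1]], g[[2]], exact = FALSE)
        rows[[nm]] <- data.frame(covariate = nm, type = type,
                                 test = "wilcoxon",
                                 statistic = unname(tst$statistic),
                                 p = tst$p.value)
      }
    } else {
      meth <- if (normalOk(x) && normalOk(y)) "pearson" else "spearman"
      tst <- suppressWarnings(
        stats::cor.test(x, y, method = meth, exact = FALSE))
      rows[[nm]] <- data.frame(covariate = nm, type = type, test = meth,
                               statistic = unname(tst$estimate),
                               p = tst$p.value)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(covariate = character(), type = character(),
                      test = character(), statistic = numeric(),
                      p = numeric())
  rownames(out) <- NULL
  out
}

#' Fit the NAWM_M linear mixed model
#'
#' Fits \code{nawm_m ~ lka_quartile + age_decades + hypertension} with the
#' NAWM strata as the clustering variable: random intercepts, or random
#' intercepts plus random slopes on the quartile term. With only five
#' strata the random-effect variances are weakly identified; singular
#' (boundary) fits are flagged, not silenced.
#'
#' @param table subject x stratum data.frame with columns \code{nawm_m},
#'   \code{lka_quartile}, \code{age_decades}, \code{hypertension},
#'   \code{stratum} (\code{"full"} rows are dropped)
#' @param randomSlopes logical, include per-stratum random slopes on the
#'   quartile term
#' @param method \code{"REML"} (reporting) or \code{"ML"} (model
#'   comparison)
#' @return an \linkS4class{LMMResult}
#' @export
fitLMM <- function(table, randomSlopes = FALSE, method = c("REML", "ML")) {
  method <- match.arg(method)
  tab <- modelRows(table)
  if (nlevels(tab$stratum) < 2L)
    stop("mixed model needs >= 2 stratum clusters")
  form <- if (randomSlopes)
    nawm_m ~ lka_quartile + age_decades + hypertension +
      (1 + lka_quartile | stratum)
  else
    nawm_m ~ lka_quartile + age_decades + hypertension + (1 | stratum)
  fit <- withCallingHandlers(
    lme4::lmer(form, data = tab, REML = (method == "REML")),
    warning = function(w) {
      # lme4's post-hoc gradient check is advisory; the hard failure case
      # (optimizer error) is handled below
      invokeRestart("muffleWarning")
    })
  if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0)
    stop("mixed model optimizer failed (code ", fit@optinfo$conv$opt,
         "): ", paste(unlist(fit@optinfo$conv$lme4$messages),
                      collapse = "; "))
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  if (length(msgs))
    message("mixed model convergence check: ",
            paste(msgs, collapse = "; "))
  singular <- lme4::isSingular(fit)
  if (singular)
    message("boundary (singular) random-effects fit: variance estimate ",
            "at zero; expected with few stratum clusters")
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  fe <- data.frame(term = names(est), estimate = unname(est),
                   se = unname(se),
                   ci_lo = unname(est - 1.96 * se),
                   ci_hi = unname(est + 1.96 * se),
                   stringsAsFactors = FALSE)
  re <- lme4::ranef(fit)$stratum
  red <- data.frame(stratum = rownames(re),
                    intercept_dev = re[["(Intercept)"]],
                    intercept = est[["(Intercept)"]] + re[["(Intercept)"]],
                    stringsAsFactors = FALSE)
  if (randomSlopes) {
    red$slope_dev <- re[["lka_quartile"]]
    red$slope <- est[["lka_quartile"]] + re[["lka_quartile"]]
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  new("LMMResult", fixedEffects = fe, randomEffects = red,
      varianceComponents = vc,
      logLik = as.numeric(stats::logLik(fit)),
      aic = stats::AIC(fit), method = method,
      hasRandomSlopes = randomSlopes, singular = singular, fit = fit)
}

#' @rdname fixedEffects
#' @export
setMethod("fixedEffects", "LMMResult", function(x) x@fixedEffects)

#' @rdname randomEffects
#' @export
setMethod("randomEffects", "LMMResult", function(x) x@randomEffects)

setMethod("show", "LMMResult", function(object) {
  cat(sprintf("Linear mixed model (%s) with random intercepts%s%s\n",
              object@method,
              if (object@hasRandomSlopes) " and random slopes" else "",
              if (object@singular) " [boundary fit]" else ""))
  fe <- object@fixedEffects
  for (i in seq_len(nrow(fe)))
    cat(sprintf("  %-28s %8.4f (SE %.4f, 95%% CI %.4f to %.4f)\n",
                fe$term[i], fe$estimate[i], fe$se[i], fe$ci_lo[i],
                fe$ci_hi[i]))
  cat(sprintf("  logLik %.2f, AIC %.1f\n", object@logLik, object@aic))
})

#' Compare random-intercepts and random-slopes models
#'
#' Both models are fitted by maximum likelihood on identical rows; AICs
#' are compared and the likelihood-ratio statistic
#' \code{2 (logLik_slopes - logLik_intercepts)} is referred to a
#' chi-squared distribution with 2 degrees of freedom. REML refits of
#' both models are attached for reporting; REML log-likelihoods are never
#' compared.
#'
#' @param table subject x stratum data.frame (see \code{\link{fitLMM}})
#' @return a \linkS4class{ModelComparison}
#' @export
compareModels <- function(table) {
  mlI <- fitLMM(table, randomSlopes = FALSE, method = "ML")
  mlS <- fitLMM(table, randomSlopes = TRUE, method = "ML")
  stat <- 2 * (mlS@logLik - mlI@logLik)
  if (stat < -1e-6)
    warning("random-slopes ML log-likelihood below nested model: ",
            "optimizer tolerance exceeded")
  stat <- max(stat, 0)
  new("ModelComparison",
      aicIntercepts = mlI@aic, aicSlopes = mlS@aic,
      lrtStatistic = stat, lrtDf = 2L,
      lrtP = stats::pchisq(stat, df = 2, lower.tail = FALSE),
      remlIntercepts = fitLMM(table, FALSE, "REML"),
      remlSlopes = fitLMM(table, TRUE, "REML"))
}

setMethod("show", "ModelComparison", function(object) {
  cat(sprintf(
    "Model comparison (ML): AIC intercepts %.1f vs slopes %.1f; LRT %.3f on %d df, p = %.3g\n",
    object@aicIntercepts, object@aicSlopes, object@lrtStatistic,
    object@lrtDf, object@lrtP))
  cat("-- REML random intercepts --\n"); show(object@remlIntercepts)
  cat("-- REML random intercepts + slopes --\n"); show(object@remlSlopes)
})
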