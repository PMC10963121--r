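# YAML serialization of PhantomConfig.

#' Read a PhantomConfig from a YAML file
#'
#' Unknown keys are rejected; missing keys take the package defaults.
#' The \code{burdenBandsCm3} entry, when present, is a list of 4
#' two-element numeric vectors.
#'
#' @param path YAML file path
#' @return a \linkS4class{PhantomConfig}
#' @export
phantomConfigFromYaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(phantomConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown phantom config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$burdenBandsCm3))
    raw$burdenBandsCm3 <- do.call(rbind, lapply(raw$burdenBandsCm3,
                                                as.numeric))
  if (!is.null(raw$infarctSideProbs))
    raw$infarctSideProbs <- unlist(raw$infarctSideProbs)
  do.call(phantomConfig, raw)
}

#' Write a PhantomConfig to a YAML file
#'
#' @param config a PhantomConfig
#' @param path output YAML path
#' @return \code{path}, invisibly
#' @export
phantomConfigToYaml <- function(config, path) {
  lst <- list(
    gridShape = config@gridShape, voxelDimsMm = config@voxelDimsMm,
    wmBaseIntensity = config@wmBaseIntensity,
    spleniumIntensityMean = config@spleniumIntensityMean,
    spleniumIntensitySd = config@spleniumIntensitySd,
    csfIntensityMax = config@csfIntensityMax,
    lesionIntensity = config@lesionIntensity,
    lesionCountRange = config@lesionCountRange,
    lesionRadiusRangeMm = config@lesionRadiusRangeMm,
    burdenBandsCm3 = lapply(seq_len(4), function(i)
      config@burdenBandsCm3[i, ]),
    burdenEffectPerQuartile = config@burdenEffectPerQuartile,
    distanceDecayPerVoxel = config@distanceDecayPerVoxel,
    noiseSd = config@noiseSd,
    ageEffectPerDecade = config@ageEffectPerDecade,
    ageBurdenCorrelation = config@ageBurdenCorrelation,
    hypertensionPrevalence = config@hypertensionPrevalence,
    infarctSideProbs = as.list(config@infarctSideProbs),
    periventricularBias = config@periventricularBias,
    seed = config@seed)
  yaml::write_yaml(lst, path)
  invisible(path)
}
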