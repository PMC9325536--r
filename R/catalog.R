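#' The voxel-wise feature catalog
#'
#' Five feature families computed inside each sliding window: 18 first-order
#' statistics, 24 gray-level co-occurrence (GLCM), 14 gray-level dependence
#' (GLDM), 16 gray-level run-length (GLRLM) and 5 neighbouring gray-tone
#' difference (NGTDM) features - 77 per modality. First-order intensity
#' statistics use the raw voxel values; histogram statistics (Entropy,
#' Uniformity) and all texture families use the discretized gray levels.
#'
#' @param families character subset of
#'   `c("FIRSTORDER", "GLCM", "GLDM", "GLRLM", "NGTDM")`.
#' @return A tibble with columns `family`, `feature`, `column` (position in
#'   the 77-column engine output).
#' @export
feature_catalog <- function(families = c("FIRSTORDER", "GLCM", "GLDM",
                                         "GLRLM", "NGTDM")) {
  families <- match.arg(families, several.ok = TRUE,
                        choices = c("FIRSTORDER", "GLCM", "GLDM", "GLRLM",
                                    "NGTDM"))
  cat_all <- tibble(
    family = rep(c("FIRSTORDER", "GLCM", "GLDM", "GLRLM", "NGTDM"),
                 times = c(18, 24, 14, 16, 5)),
    feature = c(
      # first-order (18)
      "Energy", "TotalEnergy", "Entropy", "Minimum", "Percentile10",
      "Percentile90", "Maximum", "Mean", "Median", "InterquartileRange",
      "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
      "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity",
      # GLCM (24)
      "Autocorrelation", "ClusterProminence", "ClusterShade",
      "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
      "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
      "Imc1", "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
      "JointEntropy", "MaximumProbability", "MCC", "SumAverage",
      "SumEntropy", "SumSquares",
      # GLDM (14)
      "SmallDependenceEmphasis", "LargeDependenceEmphasis",
      "GrayLevelNonUniformity", "DependenceNonUniformity",
      "DependenceNonUniformityNormalized", "GrayLevelVariance",
      "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
      "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
      "SmallDependenceHighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis",
      "LargeDependenceHighGrayLevelEmphasis",
      # GLRLM (16)
      "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage",
      "GrayLevelVariance", "RunVariance", "RunEntropy",
      "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
      "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
      "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis",
      # NGTDM (5)
      "Coarseness", "Contrast", "Busyness", "Complexity", "Strength"
    ),
    column = 1:77
  )
  dplyr::filter(cat_all, .data$family %in% families)
}

catalog_names <- function(catalog = feature_catalog()) {
  paste(catalog$family, catalog$feature, sep = "_")
}
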