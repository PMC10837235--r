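# First-order (intensity histogram) features.
#
# All statistics are population versions (moments divided by N), matching
# the usual radiomics definitions. Entropy and Uniformity are computed on
# the discretized in-mask histogram using the same discretization settings
# as the texture families. Skewness and Kurtosis of a constant signal are
# defined as 0 (degenerate convention); Kurtosis is the non-excess version
# (Gaussian data gives about 3).

first_order_names <- function() {
  c("Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
    "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
    "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
    "RootMeanSquared", "StandardDeviation", "Skewness", "Kurtosis",
    "Variance", "Uniformity")
}

#' Extract the 19 first-order features
#'
#' @param volume 3-D numeric array.
#' @param mask a `subregion_mask` with at least one voxel.
#' @param disc discretization settings from [discretization_settings()],
#'   used for the histogram-based Entropy and Uniformity.
#' @return Named numeric vector of length 19.
#' @export
extract_first_order <- function(volume, mask,
                                disc = discretization_settings()) {
  x <- volume[mask$voxels]
  n <- length(x)
  if (n == 0) stop_hab("empty mask in first-order extraction")
  qs <- as.numeric(stats::quantile(x, c(0.10, 0.25, 0.75, 0.90),
                                   names = FALSE))
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  robust <- x[x >= qs[1] & x <= qs[4]]
  lv <- discretize_values(x, disc)
  p <- tabulate(lv) / n
  p <- p[p > 0]
  voxvol <- prod(mask$spacing)
  c(
    Energy = sum(x^2),
    TotalEnergy = voxvol * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = qs[1],
    `90Percentile` = qs[4],
    Maximum = max(x),
    Mean = mu,
    Median = stats::median(x),
    InterquartileRange = qs[3] - qs[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(robust)) mean(abs(robust - mean(robust))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    StandardDeviation = sqrt(m2),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2)
  )
}
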