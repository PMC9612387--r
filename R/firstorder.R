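#' First-order (intensity) radiomic features
#'
#' The 18 standard first-order features computed from the raw in-mask
#' intensities (entropy and uniformity from the discretized histogram, total
#' energy scaled by voxel volume). Percentiles use linear interpolation
#' (quantile type 7). Skewness and kurtosis use population moments; kurtosis
#' is not excess-corrected. For a constant region skewness and kurtosis are
#' returned as 0 and flagged degenerate.
#'
#' @param image 3D numeric array.
#' @param mask Logical 3D array.
#' @param config A [discretization_config()] for the histogram features.
#' @param voxel_size_mm Length-3 voxel size in mm (total energy scaling).
#' @return Named numeric vector of 18 features (`firstorder_*`), with
#'   attribute `degenerate` naming flagged features.
#' @export
first_order_features <- function(image, mask,
                                 config = discretization_config(),
                                 voxel_size_mm = c(1, 1, 1)) {
  mask <- mask > 0
  if (!sum(mask)) stop("mask is empty")
  x <- image[mask]
  n <- length(x)
  vol <- prod(voxel_size_mm)
  lev <- discretize(image, mask, config)
  p <- tabulate(lev[mask], attr(lev, "n_levels")) / n
  pp <- p[p > 0]

  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- unname(stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), type = 7))
  robust <- x[x >= q[1] & x <= q[4]]
  degenerate <- character(0)
  if (m2 > 0) {
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2
  } else {
    skew <- 0
    kurt <- 0
    degenerate <- c("firstorder_Skewness", "firstorder_Kurtosis")
  }
  out <- c(
    firstorder_Energy = sum(x^2),
    firstorder_TotalEnergy = vol * sum(x^2),
    firstorder_Entropy = -sum(pp * log2(pp)),
    firstorder_Minimum = min(x),
    firstorder_10Percentile = q[1],
    firstorder_90Percentile = q[4],
    firstorder_Maximum = max(x),
    firstorder_Mean = mu,
    firstorder_Median = stats::median(x),
    firstorder_InterquartileRange = q[3] - q[2],
    firstorder_Range = max(x) - min(x),
    firstorder_MeanAbsoluteDeviation = mean(abs(x - mu)),
    firstorder_RobustMeanAbsoluteDeviation =
      mean(abs(robust - mean(robust))),
    firstorder_RootMeanSquared = sqrt(mean(x^2)),
    firstorder_Skewness = skew,
    firstorder_Kurtosis = kurt,
    firstorder_Variance = m2,
    firstorder_Uniformity = sum(pp^2)
  )
  attr(out, "degenerate") <- degenerate
  out
}
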