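#' First-order (histogram) features of the in-ROI values
#'
#' Computes the fifteen first-order statistics used throughout the pipeline:
#' minimum, 5th/10th/25th percentiles, median, 75th/90th percentiles,
#' maximum, mean, sum, standard deviation (sample SD), skewness and excess
#' kurtosis (standardized 3rd/4th central moments; 0 by convention for a
#' constant ROI), energy (\eqn{\sum x^2}) and entropy
#' (\eqn{-\sum p \log_2 p} over the `nBins`-level min-max discretized
#' histogram). Percentiles use linear interpolation.
#'
#' @param values numeric vector of in-ROI values (>= 1 value, no NA), or a
#'   numeric matrix plus `mask`.
#' @param mask optional logical matrix when `values` is a matrix.
#' @param nBins histogram bin count for the entropy term.
#' @return named numeric vector of 15 features.
#' @examples
#' firstOrderFeatures(1:10)[c("p10", "median", "sum")]
#' @export
firstOrderFeatures <- function(values, mask = NULL, nBins = 32L) {
  if (is.matrix(values)) {
    if (is.null(mask)) stop("mask is required for matrix input")
    values <- values[mask]
  }
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("first-order features need at least one value")
  q <- stats::quantile(values, c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90),
                       names = FALSE, type = 7)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  skew <- if (m2 > 0) mean((values - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((values - mu)^4) / m2^2 - 3 else 0
  # histogram entropy over the discretized levels
  lev <- if (max(values) > min(values)) {
    pmin(1L + floor(nBins * (values - min(values)) /
                      (max(values) - min(values))), nBins)
  } else rep(1L, n)
  p <- tabulate(lev, nBins) / n
  p <- p[p > 0]
  c(minimum = min(values), p5 = q[1], p10 = q[2], p25 = q[3], median = q[4],
    p75 = q[5], p90 = q[6], maximum = max(values), mean = mu,
    sum = sum(values), sd = if (n > 1) stats::sd(values) else 0,
    skewness = skew, kurtosis = kurt, energy = sum(values^2),
    entropy = -sum(p * log2(p)))
}
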