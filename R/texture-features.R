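# Scalar features from the texture matrices. Conventions fixed across the
# package: counts are summed over directions and features computed once from
# the aggregate; entropies use log base 2 with 0*log(0) = 0; degenerate
# denominators give the documented conventions (GLCM correlation 0 when a
# marginal SD is 0; NGLDM busyness 0 when its denominator is 0).

.GLCM_NAMES <- c("glcm_homogeneity", "glcm_energy", "glcm_correlation",
                 "glcm_contrast", "glcm_entropy", "glcm_dissimilarity")
.GLRLM_NAMES <- c("SRE", "LRE", "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE",
                  "LRHGE", "GLNUr", "RLNU", "RP")
.GLZSM_NAMES <- c("SZE", "LZE", "LGZE", "HGZE", "SZLGE", "SZHGE", "LZLGE",
                  "LZHGE", "GLNUz", "ZLNU", "ZP")
.NGLDM_NAMES <- c("coarseness", "ngldm_contrast", "busyness")

.naFeatures <- function(nm) stats::setNames(rep(NA_real_, length(nm)), nm)

#' Features of a gray-level co-occurrence matrix
#'
#' Normalizes the aggregated pair counts to probabilities \eqn{p(i,j)} and
#' computes homogeneity \eqn{\sum p/(1+|i-j|)}, energy \eqn{\sum p^2},
#' correlation \eqn{\sum (i-\mu_i)(j-\mu_j) p / (\sigma_i \sigma_j)}
#' (0 when a marginal SD is 0), contrast \eqn{\sum p (i-j)^2}, entropy
#' \eqn{-\sum p \log_2 p} and dissimilarity \eqn{\sum p |i-j|}.
#'
#' @param counts matrix from [computeGlcm()].
#' @return named numeric vector of 6 features; all NA when the matrix holds
#'   no pair (feature set not computable for the lesion).
#' @export
glcmFeatures <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(.naFeatures(.GLCM_NAMES))
  p <- counts / tot
  nB <- nrow(p)
  i <- row(p); j <- col(p)
  pi_ <- rowSums(p)
  mu_i <- sum(seq_len(nB) * pi_)
  sd_i <- sqrt(sum((seq_len(nB) - mu_i)^2 * pi_))
  # symmetric matrix: both marginals coincide
  corr <- if (sd_i > 0) sum((i - mu_i) * (j - mu_i) * p) / (sd_i * sd_i) else 0
  pNz <- p[p > 0]
  stats::setNames(c(
    sum(p / (1 + abs(i - j))),
    sum(p^2),
    corr,
    sum(p * (i - j)^2),
    -sum(pNz * log2(pNz)),
    sum(p * abs(i - j))
  ), .GLCM_NAMES)
}

# Shared emphasis formulas for run-length and zone-size matrices: `counts`
# indexed by (level i, size l), `nTotal` the normalizing voxel mass for the
# percentage feature (voxels x directions for runs, voxels for zones).
.rlzsFeatures <- function(counts, nTotal, names) {
  nTot <- sum(counts)
  if (nTot == 0) return(.naFeatures(names))
  i <- row(counts); l <- col(counts)
  f <- function(w) sum(counts * w) / nTot
  stats::setNames(c(
    f(1 / l^2), f(l^2), f(1 / i^2), f(i^2),
    f(1 / (i^2 * l^2)), f(i^2 / l^2), f(l^2 / i^2), f(i^2 * l^2),
    sum(rowSums(counts)^2) / nTot,
    sum(colSums(counts)^2) / nTot,
    nTot / nTotal
  ), names)
}

#' Features of a gray-level run-length matrix
#'
#' Standard Galloway run-length statistics: short/long-run emphases (SRE,
#' LRE), low/high gray-level run emphases (LGRE, HGRE), the four joint forms
#' (SRLGE, SRHGE, LRLGE, LRHGE), the two non-uniformities (GLNUr over
#' levels, RLNU over lengths) and run percentage
#' RP = (number of runs) / (masked voxels x directions).
#'
#' @param counts matrix from [computeGlrlm()].
#' @param nVoxels masked voxel count of the ROI.
#' @param nDirections directions aggregated into `counts` (default: read
#'   from the matrix attribute, falling back to 4).
#' @return named numeric vector of 11 features.
#' @export
glrlmFeatures <- function(counts, nVoxels,
                          nDirections = attr(counts, "nDirections") %||% 4L) {
  .rlzsFeatures(counts, nVoxels * nDirections, .GLRLM_NAMES)
}

#' Features of a gray-level zone-size matrix
#'
#' Zone-size analogues of the run-length statistics, with zone size in place
#' of run length and ZP = (number of zones) / (masked voxels).
#'
#' @param counts matrix from [computeGlzsm()].
#' @param nVoxels masked voxel count of the ROI.
#' @return named numeric vector of 11 features.
#' @export
glzsmFeatures <- function(counts, nVoxels) {
  .rlzsFeatures(counts, nVoxels, .GLZSM_NAMES)
}

#' Features of the neighborhood gray-level difference vectors
#'
#' Amadasun-King coarseness \eqn{1/(\epsilon + \sum p(i) s(i))} with
#' \eqn{\epsilon = 10^{-12}}, contrast
#' \eqn{[\frac{1}{N_g(N_g-1)}\sum_i\sum_j p_i p_j (i-j)^2]
#'   [\frac{1}{n}\sum_i s(i)]} (0 when fewer than two levels are present)
#' and busyness \eqn{\sum p(i) s(i) / \sum_{i,j} |i p_i - j p_j|} over level
#' pairs with \eqn{p > 0} (0 when the denominator is 0).
#'
#' @param ngldm list from [computeNgldm()].
#' @return named numeric vector of 3 features; all NA when no voxel has an
#'   in-mask neighbor.
#' @export
ngldmFeatures <- function(ngldm) {
  p <- ngldm$p; s <- ngldm$s; n <- ngldm$nEligible
  if (n == 0L) return(.naFeatures(.NGLDM_NAMES))
  eps <- 1e-12
  ps <- sum(p * s)
  lv <- which(p > 0)
  ng <- length(lv)
  contrast <- if (ng >= 2) {
    sum(outer(p[lv], p[lv]) * outer(lv, lv, "-")^2) / (ng * (ng - 1)) *
      (sum(s) / n)
  } else 0
  ip <- lv * p[lv]
  denom <- sum(abs(outer(ip, ip, "-")))
  busy <- if (denom > 0) ps / denom else 0
  stats::setNames(c(1 / (eps + ps), contrast, busy), .NGLDM_NAMES)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' All 46 features of one masked value grid
#'
#' First-order (15), GLCM (6), GLRLM (11), GLZSM (11) and NGLDM (3) features
#' of a single base image (an ADC map or one b-value's DWI grid) restricted
#' to the ROI. NA voxels inside the mask (invalid ADC voxels) are excluded
#' before discretization.
#'
#' @param values numeric matrix or an [AdcMap-class].
#' @param mask logical matrix (defaults to the map's mask).
#' @param nBins gray levels for discretization (8, 16 or 32).
#' @return named numeric vector of 46 features.
#' @export
textureFeatureVector <- function(values, mask = NULL, nBins = 32L) {
  if (is(values, "AdcMap")) {
    if (is.null(mask)) mask <- values@mask
    values <- values@values
  }
  d <- discretizeRoi(values, mask, nBins)
  nVox <- sum(d$mask)
  c(firstOrderFeatures(values[d$mask], nBins = nBins),
    glcmFeatures(computeGlcm(d)),
    glrlmFeatures(computeGlrlm(d), nVox),
    glzsmFeatures(computeGlzsm(d), nVox),
    ngldmFeatures(computeNgldm(d)))
}
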