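#' Spearman rank correlation of a feature with grade group
#'
#' Rho is the Pearson correlation of midranks (ties allowed). The two-sided
#' p-value uses the t-approximation with n - 2 degrees of freedom,
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}}; for small samples
#' (`exact = TRUE`, n <= 8) an exact permutation p-value over all orderings
#' is available. The 95\% CI uses the Fisher z transform,
#' \eqn{\tanh(\mathrm{atanh}\,\rho \pm 1.96/\sqrt{n-3})}.
#'
#' @param x numeric feature values (n >= 5).
#' @param gg ordinal grade groups (integers 1..5), same length.
#' @param exact use the exact permutation p-value (only for n <= 8).
#' @return an object of class `SpearmanResult`: list with `rho`, `p_value`,
#'   `ci_low`, `ci_high`, `n`, `computable`. A constant feature or constant
#'   grade group makes rho undefined (`computable = FALSE`, NA values).
#' @export
spearmanVsGG <- function(x, gg, exact = FALSE) {
  keep <- !is.na(x) & !is.na(gg)
  x <- x[keep]; gg <- gg[keep]
  n <- length(x)
  if (n < 5L) stop("Spearman screening needs n >= 5")
  out <- list(rho = NA_real_, p_value = NA_real_, ci_low = NA_real_,
              ci_high = NA_real_, n = n, computable = FALSE)
  class(out) <- "SpearmanResult"
  if (stats::sd(x) == 0 || stats::sd(gg) == 0) return(out)
  rho <- stats::cor(x, gg, method = "spearman")
  p <- if (exact) {
    if (n > 8L) stop("exact permutation p-value supported only for n <= 8")
    rx <- rank(x); rg <- rank(gg)
    perms <- .allPermutations(n)
    rhos <- apply(perms, 1L, function(idx) stats::cor(rx[idx], rg))
    mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    2 * stats::pt(-abs(tt), n - 2)
  }
  ci <- if (abs(rho) >= 1) c(rho, rho) else
    tanh(atanh(rho) + c(-1.96, 1.96) / sqrt(n - 3))
  out$rho <- rho; out$p_value <- min(p, 1); out$ci_low <- ci[1]
  out$ci_high <- ci[2]; out$computable <- TRUE
  out
}

# All permutations of 1..n as rows (n <= 8).
.allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

#' @export
print.SpearmanResult <- function(x, ...) {
  if (!x$computable) cat("SpearmanResult: not computable (constant input)\n")
  else cat(sprintf("SpearmanResult: rho = %.3f [%.3f, %.3f], p = %.3g, n = %d\n",
                   x$rho, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}

#' ROC AUC for grade group 1-2 versus 3-5
#'
#' Binarizes grade group at <= 2 versus >= 3 and computes the area under the
#' ROC curve as the normalized Mann-Whitney U statistic with midrank tie
#' handling: the probability (plus half the tie probability) that a GG 3-5
#' lesion scores above a GG 1-2 lesion. The `orientation` sign (typically the
#' sign of the pooled Spearman rho) multiplies the feature so that the
#' reported AUC is >= 0.5 whenever the monotone trend holds; it is recorded
#' in the result.
#'
#' @param x numeric feature values.
#' @param gg grade groups 1..5.
#' @param orientation +1 or -1 score orientation.
#' @return list with `auc`, `orientation`, `n_low`, `n_high`, `computable`.
#' @export
rocAucGG <- function(x, gg, orientation = 1) {
  keep <- !is.na(x) & !is.na(gg)
  x <- x[keep] * orientation
  high <- gg[keep] >= 3
  n1 <- sum(high); n0 <- sum(!high)
  if (n1 == 0L || n0 == 0L)
    return(list(auc = NA_real_, orientation = orientation, n_low = n0,
                n_high = n1, computable = FALSE))
  r <- rank(x)
  auc <- (sum(r[high]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(auc = auc, orientation = orientation, n_low = n0, n_high = n1,
       computable = TRUE)
}

#' Test-retest intraclass correlation, ICC(A,1)
#'
#' Two-way model, single measurement, absolute agreement (McGraw-Wong
#' ICC(A,1)), computed from the two-way ANOVA mean squares of a
#' subjects-by-examinations table:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with the F-based 95\% confidence interval of McGraw and Wong.
#'
#' @param first,second paired feature values of the two examinations
#'   (n >= 5 pairs).
#' @return an object of class `IccResult`: list with `icc`, `ci_low`,
#'   `ci_high`, `model` (`"two-way, single measure, absolute agreement"`),
#'   `n`, `computable` (FALSE when total variance is zero).
#' @export
iccTestRetest <- function(first, second) {
  keep <- !is.na(first) & !is.na(second)
  first <- first[keep]; second <- second[keep]
  n <- length(first)
  if (n < 5L) stop("ICC needs at least 5 paired observations")
  out <- list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              model = "two-way, single measure, absolute agreement",
              n = n, computable = FALSE)
  class(out) <- "IccResult"
  x <- cbind(first, second)
  k <- 2L
  grand <- mean(x)
  if (sum((x - grand)^2) == 0) return(out)
  rowM <- rowMeans(x); colM <- colMeans(x)
  msr <- k * sum((rowM - grand)^2) / (n - 1)
  msc <- n * sum((colM - grand)^2) / (k - 1)
  mse <- sum((x - outer(rowM, rep(1, k)) -
                outer(rep(1, n), colM) + grand)^2) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  icc <- (msr - mse) / denom
  if (mse <= 0 && msc <= mse) {
    ci <- c(1, 1)
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(0.975, n - 1, v)
    fu <- stats::qf(0.975, v, n - 1)
    ci <- c(n * (msr - fl * mse) /
              (fl * (k * msc + (k * n - k - n) * mse) + n * msr),
            n * (fu * msr - mse) /
              (k * msc + (k * n - k - n) * mse + n * fu * msr))
  }
  out$icc <- icc; out$ci_low <- ci[1]; out$ci_high <- ci[2]
  out$computable <- TRUE
  out
}

#' @export
print.IccResult <- function(x, ...) {
  if (!x$computable) cat("IccResult: not computable (zero total variance)\n")
  else cat(sprintf("IccResult (%s): %.3f [%.3f, %.3f], n = %d\n",
                   x$model, x$icc, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Bland-Altman analysis on percentage differences
#'
#' Per pair, the percentage difference
#' \eqn{100 (x_1 - x_2) / ((x_1 + x_2)/2)} normalizes differences by the pair
#' mean so features of different magnitudes are comparable. Reports the bias
#' (mean), the SD of the differences and the 95\% limits of agreement
#' `bias +/- 1.96 sd`. Pairs with a zero mean are flagged and dropped; at
#' least one valid pair is required.
#'
#' @param first,second paired feature values of the two examinations.
#' @return an object of class `BlandAltmanPct`: list with `bias_pct`,
#'   `sd_pct`, `loa_low_pct`, `loa_high_pct`, `n`, `n_flagged`.
#' @export
blandAltmanPct <- function(first, second) {
  keep <- !is.na(first) & !is.na(second)
  first <- first[keep]; second <- second[keep]
  pm <- (first + second) / 2
  ok <- pm != 0
  if (!any(ok)) stop("Bland-Altman analysis needs at least one pair with a non-zero mean")
  pct <- 100 * (first[ok] - second[ok]) / pm[ok]
  bias <- mean(pct)
  s <- if (sum(ok) > 1) stats::sd(pct) else 0
  structure(list(bias_pct = bias, sd_pct = s,
                 loa_low_pct = bias - 1.96 * s, loa_high_pct = bias + 1.96 * s,
                 n = sum(ok), n_flagged = sum(!ok)),
            class = "BlandAltmanPct")
}

#' @export
print.BlandAltmanPct <- function(x, ...) {
  cat(sprintf("Bland-Altman (%%): bias %.2f, SD %.2f, 95%% LOA [%.2f, %.2f], n = %d%s\n",
              x$bias_pct, x$sd_pct, x$loa_low_pct, x$loa_high_pct, x$n,
              if (x$n_flagged > 0) sprintf(" (%d zero-mean pairs dropped)",
                                           x$n_flagged) else ""))
  invisible(x)
}
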