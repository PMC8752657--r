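# Independent exhaustive-enumeration references for the texture features and
# rank statistics. These are deliberately slow, loop-based implementations
# structured differently from the package code paths they check.

oracleGlcm <- function(bins, mask) {
  nB <- max(bins[mask])
  counts <- matrix(0, nB, nB)
  nr <- nrow(bins); nc <- ncol(bins)
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    for (o in offs) {
      r2 <- r + o[1]; c2 <- c + o[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && mask[r2, c2]) {
        i <- bins[r, c]; j <- bins[r2, c2]
        counts[i, j] <- counts[i, j] + 1
        counts[j, i] <- counts[j, i] + 1
      }
    }
  }
  counts
}

oracleGlcmFeatures <- function(bins, mask, nB) {
  counts <- matrix(0, nB, nB)
  cc <- oracleGlcm(bins, mask)
  counts[seq_len(nrow(cc)), seq_len(ncol(cc))] <- cc
  p <- counts / sum(counts)
  hom <- en <- con <- dis <- ent <- 0
  for (i in 1:nB) for (j in 1:nB) {
    hom <- hom + p[i, j] / (1 + abs(i - j))
    en <- en + p[i, j]^2
    con <- con + p[i, j] * (i - j)^2
    dis <- dis + p[i, j] * abs(i - j)
    if (p[i, j] > 0) ent <- ent - p[i, j] * log2(p[i, j])
  }
  mu_i <- sum(rowSums(p) * (1:nB)); mu_j <- sum(colSums(p) * (1:nB))
  sd_i <- sqrt(sum(rowSums(p) * ((1:nB) - mu_i)^2))
  sd_j <- sqrt(sum(colSums(p) * ((1:nB) - mu_j)^2))
  corr <- 0
  if (sd_i * sd_j > 0) {
    for (i in 1:nB) for (j in 1:nB)
      corr <- corr + (i - mu_i) * (j - mu_j) * p[i, j] / (sd_i * sd_j)
  }
  c(glcm_homogeneity = hom, glcm_energy = en, glcm_correlation = corr,
    glcm_contrast = con, glcm_entropy = ent, glcm_dissimilarity = dis)
}

# walk every line of every direction voxel by voxel
oracleRuns <- function(bins, mask) {
  nr <- nrow(bins); nc <- ncol(bins)
  lineRuns <- function(cells) {
    out <- list()
    cur <- NA; len <- 0
    for (k in seq_len(nrow(cells))) {
      r <- cells[k, 1]; c <- cells[k, 2]
      v <- if (r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c])
        bins[r, c] else NA
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1
      } else {
        if (!is.na(cur)) out[[length(out) + 1]] <- c(cur, len)
        cur <- v; len <- 1
      }
    }
    if (!is.na(cur)) out[[length(out) + 1]] <- c(cur, len)
    out
  }
  runs <- list()
  for (r in 1:nr) runs <- c(runs, lineRuns(cbind(r, 1:nc)))     # horizontal
  for (c in 1:nc) runs <- c(runs, lineRuns(cbind(1:nr, c)))     # vertical
  for (s in (1 - nc):(nr - 1)) {                                # down-right
    cells <- cbind(s + 1:nc, 1:nc)
    runs <- c(runs, lineRuns(cells[cells[, 1] >= 1 & cells[, 1] <= nr, ,
                                   drop = FALSE]))
  }
  for (s in 2:(nr + nc)) {                                      # down-left
    cells <- cbind(s - nc:1, nc:1)
    runs <- c(runs, lineRuns(cells[cells[, 1] >= 1 & cells[, 1] <= nr, ,
                                   drop = FALSE]))
  }
  do.call(rbind, runs)
}

oracleRlzsFeatures <- function(tab, nTotal) {
  # tab: matrix with columns (level, size); returns the 11 emphasis values
  nTot <- nrow(tab)
  i <- tab[, 1]; l <- tab[, 2]
  c(sum(1 / l^2), sum(l^2), sum(1 / i^2), sum(i^2),
    sum(1 / (i^2 * l^2)), sum(i^2 / l^2), sum(l^2 / i^2), sum(i^2 * l^2),
    sum(tapply(rep(1, nTot), i, sum)^2),
    sum(tapply(rep(1, nTot), l, sum)^2),
    NA) / nTot -> out
  out[11] <- nTot / nTotal
  out
}

oracleGlrlmFeatures <- function(bins, mask) {
  runs <- oracleRuns(bins, mask)
  stats::setNames(oracleRlzsFeatures(runs, sum(mask) * 4),
                  c("SRE", "LRE", "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE",
                    "LRHGE", "GLNUr", "RLNU", "RP"))
}

# flood-fill zones, 8-connected
oracleZones <- function(bins, mask) {
  nr <- nrow(bins); nc <- ncol(bins)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (r in 1:nr) for (c in 1:nc) {
    if (!mask[r, c] || seen[r, c]) next
    lev <- bins[r, c]
    stack <- list(c(r, c)); seen[r, c] <- TRUE; size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- p[1] + dr; c2 <- p[2] + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] && !seen[r2, c2] && bins[r2, c2] == lev) {
          seen[r2, c2] <- TRUE
          stack[[length(stack) + 1]] <- c(r2, c2)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(lev, size)
  }
  do.call(rbind, zones)
}

oracleGlzsmFeatures <- function(bins, mask) {
  zones <- oracleZones(bins, mask)
  stats::setNames(oracleRlzsFeatures(zones, sum(mask)),
                  c("SZE", "LZE", "LGZE", "HGZE", "SZLGE", "SZHGE", "LZLGE",
                    "LZHGE", "GLNUz", "ZLNU", "ZP"))
}

oracleNgldmFeatures <- function(bins, mask, nB) {
  nr <- nrow(bins); nc <- ncol(bins)
  s <- numeric(nB); cnt <- numeric(nB); nE <- 0
  for (r in 1:nr) for (c in 1:nc) {
    if (!mask[r, c]) next
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && mask[r2, c2])
        nb <- c(nb, bins[r2, c2])
    }
    if (length(nb) == 0) next
    nE <- nE + 1
    i <- bins[r, c]
    cnt[i] <- cnt[i] + 1
    s[i] <- s[i] + abs(i - mean(nb))
  }
  if (nE == 0) return(c(coarseness = NA, ngldm_contrast = NA, busyness = NA))
  p <- cnt / nE
  ps <- sum(p * s)
  lv <- which(p > 0); ng <- length(lv)
  contrast <- 0
  if (ng >= 2) {
    acc <- 0
    for (i in lv) for (j in lv) acc <- acc + p[i] * p[j] * (i - j)^2
    contrast <- acc / (ng * (ng - 1)) * sum(s) / nE
  }
  denom <- 0
  for (i in lv) for (j in lv) denom <- denom + abs(i * p[i] - j * p[j])
  busy <- if (denom > 0) ps / denom else 0
  c(coarseness = 1 / (1e-12 + ps), ngldm_contrast = contrast, busyness = busy)
}

# midrank Spearman from first principles
oracleSpearmanRho <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- sum(v < v[i]) + (1 + sum(v == v[i])) / 2
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# concordant / tied pair counting
oracleAuc <- function(x, isHigh) {
  xs <- x[isHigh]; xn <- x[!isHigh]
  tot <- 0
  for (a in xs) for (b in xn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(xs) * length(xn))
}

# ICC(A,1) from aov()-derived mean squares (independent ANOVA route)
oracleIccA1 <- function(first, second) {
  n <- length(first)
  d <- data.frame(score = c(first, second),
                  subj = factor(rep(seq_len(n), 2)),
                  exam = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(score ~ subj + exam, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 / n * (msc - mse))
}

# random connected-ish masked grid with levels in 1..nB
randomMaskedGrid <- function(n, nB, pMask = 0.8) {
  mask <- matrix(stats::runif(n * n) < pMask, n, n)
  if (!any(mask)) mask[sample(n * n, 1)] <- TRUE
  bins <- matrix(sample.int(nB, n * n, replace = TRUE), n, n)
  bins[!mask] <- 0L
  list(bins = bins, mask = mask,
       d = structure(list(bins = bins, mask = mask, nBins = nB,
                          sourceMin = 0, sourceMax = 1),
                     class = "DiscretizedRoi"))
}
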