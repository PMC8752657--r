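# Texture matrix construction on discretized 2D ROIs. All four families
# operate on a `DiscretizedRoi` (levels 1..nBins inside the effective mask,
# 0 outside) and follow the standard radiomics constructions: Haralick
# co-occurrence, Galloway run-length, Thibault zone-size and Amadasun-King
# neighborhood gray-tone difference.

# The four 2D directions (0, 45, 90, 135 degrees) at distance 1, as
# (delta_row, delta_col) steps.
.DIRECTIONS4 <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))

#' Gray-level co-occurrence matrix
#'
#' Counts pairs of in-mask voxels at distance 1 along the four 2D directions
#' (0, 45, 90, 135 degrees), both orderings, so the matrix is symmetric;
#' counts are summed over directions. Only pairs with both voxels inside the
#' (effective) mask contribute.
#'
#' @param d a `DiscretizedRoi` from [discretizeRoi()].
#' @param directions list of `(delta_row, delta_col)` steps (default: the
#'   standard four).
#' @return an `nBins x nBins` matrix of raw pair counts.
#' @export
computeGlcm <- function(d, directions = .DIRECTIONS4) {
  nB <- d$nBins
  counts <- matrix(0, nB, nB)
  for (dd in directions) {
    binsS <- .shiftGrid(d$bins, dd[1], dd[2], 0L)
    maskS <- .shiftGrid(d$mask, dd[1], dd[2], FALSE)
    valid <- d$mask & maskS
    if (!any(valid)) next
    i <- binsS[valid]; j <- d$bins[valid]
    counts <- counts +
      matrix(tabulate((j - 1L) * nB + i, nB * nB), nB, nB) +
      matrix(tabulate((i - 1L) * nB + j, nB * nB), nB, nB)
  }
  counts
}

# Maximal same-level runs along `directions`, broken by mask boundaries.
# Returns a data.frame(level, length) with one row per run.
.enumerateRuns <- function(d, directions = .DIRECTIONS4) {
  lev <- matrix(NA_integer_, nrow(d$bins), ncol(d$bins))
  lev[d$mask] <- d$bins[d$mask]
  lines <- list()
  for (dd in directions) {
    key <- if (identical(dd, c(0L, 1L))) {
      rbind(t(lev), NA_integer_)            # rows, left to right
    } else if (identical(dd, c(1L, 0L))) {
      rbind(lev, NA_integer_)               # columns, top to bottom
    } else if (identical(dd, c(1L, 1L))) {
      grp <- split(lev, col(lev) - row(lev))
      unlist(lapply(grp, function(v) c(v, NA_integer_)), use.names = FALSE)
    } else if (identical(dd, c(1L, -1L))) {
      grp <- split(lev, col(lev) + row(lev))
      unlist(lapply(grp, function(v) c(v, NA_integer_)), use.names = FALSE)
    } else stop("unsupported run direction (", dd[1], ", ", dd[2], ")")
    lines[[length(lines) + 1L]] <- as.vector(key)
  }
  r <- rle(unlist(lines, use.names = FALSE))
  keep <- !is.na(r$values)
  data.frame(level = r$values[keep], length = r$lengths[keep])
}

#' Gray-level run-length matrix
#'
#' Counts maximal runs of equal level along the four 2D directions (runs are
#' broken by mask boundaries), summed over directions.
#'
#' @inheritParams computeGlcm
#' @return an `nBins x max_run_length` count matrix; attribute `nDirections`
#'   records how many directions were aggregated.
#' @export
computeGlrlm <- function(d, directions = .DIRECTIONS4) {
  runs <- .enumerateRuns(d, directions)
  nB <- d$nBins
  maxLen <- max(runs$length)
  counts <- matrix(tabulate((runs$length - 1L) * nB + runs$level, nB * maxLen),
                   nB, maxLen)
  attr(counts, "nDirections") <- length(directions)
  counts
}

#' Gray-level zone-size matrix
#'
#' Zones are 8-connected components of equal level within the mask; the
#' matrix counts zones by level and size.
#'
#' @param d a `DiscretizedRoi` from [discretizeRoi()].
#' @return an `nBins x max_zone_size` count matrix.
#' @export
computeGlzsm <- function(d) {
  lab <- .labelZones(d$bins, d$mask)
  inZone <- lab[d$mask]
  sizes <- tabulate(inZone)
  levelOf <- d$bins[d$mask][match(seq_along(sizes), inZone)]
  nB <- d$nBins
  maxSize <- max(sizes)
  matrix(tabulate((sizes - 1L) * nB + levelOf, nB * maxSize), nB, maxSize)
}

#' Neighborhood gray-level difference vectors
#'
#' Amadasun-King construction: for every in-mask voxel with at least one
#' in-mask 8-neighbor, the neighborhood average \eqn{A} is the mean level of
#' its in-mask neighbors; \eqn{s(i)} accumulates \eqn{|i - A|} over eligible
#' voxels of level \eqn{i}, and \eqn{p(i)} is the fraction of eligible voxels
#' at level \eqn{i}.
#'
#' @param d a `DiscretizedRoi` from [discretizeRoi()].
#' @return list with `p` (level probabilities), `s` (difference sums), both
#'   length `nBins`, and `nEligible`.
#' @export
computeNgldm <- function(d) {
  lev <- matrix(0, nrow(d$bins), ncol(d$bins))
  lev[d$mask] <- d$bins[d$mask]
  nbSum <- matrix(0, nrow(lev), ncol(lev))
  nbCnt <- matrix(0L, nrow(lev), ncol(lev))
  for (dd in .NEIGH8) {
    nbSum <- nbSum + .shiftGrid(lev, dd[1], dd[2], 0)
    nbCnt <- nbCnt + .shiftGrid(d$mask, dd[1], dd[2], FALSE)
  }
  eligible <- d$mask & nbCnt > 0L
  nE <- sum(eligible)
  nB <- d$nBins
  p <- numeric(nB); s <- numeric(nB)
  if (nE > 0L) {
    levE <- d$bins[eligible]
    a <- nbSum[eligible] / nbCnt[eligible]
    dif <- abs(levE - a)
    p <- tabulate(levE, nB) / nE
    agg <- rowsum(dif, levE)
    s[as.integer(rownames(agg))] <- agg[, 1]
  }
  list(p = p, s = s, nEligible = nE)
}
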