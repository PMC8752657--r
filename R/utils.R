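# Internal helpers: seeded RNG scoping, grid shifting, connected-component
# labelling and Gaussian random fields. All grids are row-major 2D matrices,
# mask TRUE = inside ROI.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards, so generator functions are pure in (args, seed).
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a master seed and integer context tags, staying
# below 2^31 (all arithmetic exact in doubles).
.deriveSeed <- function(seed, ...) {
  m <- 2147483629
  s <- as.numeric(seed) %% m
  for (k in c(...)) s <- (s * 48271 + as.numeric(k) * 8191 + 1) %% m
  as.integer(s)
}

# Shift a matrix by (dr, dc), filling vacated cells.
.shiftGrid <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr); cs <- seq_len(nc)
  rdst <- rs[rs + dr >= 1 & rs + dr <= nr] + dr
  cdst <- cs[cs + dc >= 1 & cs + dc <= nc] + dc
  if (length(rdst) && length(cdst))
    out[rdst, cdst] <- m[rdst - dr, cdst - dc]
  out
}

.NEIGH8 <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))

# Label 8-connected components of constant `lev` within `mask` by iterative
# minimum-label propagation. Returns an integer matrix: 0 outside the mask,
# otherwise a component id in 1..n_components.
.labelZones <- function(lev, mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- which(mask)
  key <- matrix(NA_real_, nr, nc)
  key[mask] <- as.numeric(lev[mask])
  repeat {
    new <- lab
    for (d in .NEIGH8) {
      nbLab <- .shiftGrid(lab, d[1], d[2], 0L)
      nbKey <- .shiftGrid(key, d[1], d[2], NA_real_)
      ok <- mask & !is.na(nbKey) & !is.na(key) & nbKey == key &
        nbLab > 0L & nbLab < new
      new[ok] <- nbLab[ok]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[mask]))
  lab[mask] <- match(lab[mask], ids)
  lab
}

.countComponents <- function(mask) {
  if (!any(mask)) return(0L)
  max(.labelZones(matrix(1L, nrow(mask), ncol(mask)), mask))
}

# Keep only the largest 8-connected component of a mask.
.largestComponent <- function(mask) {
  lab <- .labelZones(matrix(1L, nrow(mask), ncol(mask)), mask)
  if (max(lab) <= 1L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# Bounding-box extent (rows, cols) of a mask.
.maskExtent <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  c(diff(range(w[, 1])) + 1L, diff(range(w[, 2])) + 1L)
}

.maskBoundingBox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  list(rows = range(w[, 1]), cols = range(w[, 2]))
}

# Zero-mean, unit-variance Gaussian random field with isotropic Gaussian
# correlation of length `corrLen` voxels (white noise convolved with a
# Gaussian kernel; edge effects avoided by padding). Consumes the current RNG.
.gaussianField <- function(nr, nc, corrLen) {
  if (corrLen <= 0) return(matrix(stats::rnorm(nr * nc), nr, nc))
  h <- max(1L, ceiling(3 * corrLen))
  k <- stats::dnorm(seq(-h, h), sd = corrLen)
  w <- matrix(stats::rnorm((nr + 2 * h) * (nc + 2 * h)), nr + 2 * h, nc + 2 * h)
  a <- matrix(0, nr, nr + 2 * h)
  for (i in seq_len(nr)) a[i, i:(i + 2 * h)] <- k
  b <- matrix(0, nc, nc + 2 * h)
  for (j in seq_len(nc)) b[j, j:(j + 2 * h)] <- k
  (a %*% w %*% t(b)) / sum(k^2)
}
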