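# Small programmatic fixtures.

# Build an acquisition with exact monoexponential signals S0 * exp(-b * D)
# (D in 1e-3 mm^2/s units); dGrid may be a scalar or matrix.
makeMonoexpAcq <- function(dGrid, mask, s0 = 100, lesionId = "fx",
                           zone = "PZ", gradeGroup = 2L, examIndex = 1L) {
  if (!is.matrix(dGrid)) dGrid <- matrix(dGrid, nrow(mask), ncol(mask))
  signals <- lapply(c(0, 100, 1000, 1500), function(b)
    s0 * exp(-b * dGrid * 1e-3))
  names(signals) <- c("0", "100", "1000", "1500")
  new("LesionAcquisition", lesionId = lesionId, zone = zone,
      gradeGroup = as.integer(gradeGroup), examIndex = as.integer(examIndex),
      signals = signals, mask = mask, voxelSize = 1.0)
}

# Build an acquisition directly from four signal grids.
makeAcq <- function(b0, b100, b1000, b1500, mask, lesionId = "fx",
                    zone = "PZ", gradeGroup = 2L, examIndex = 1L) {
  new("LesionAcquisition", lesionId = lesionId, zone = zone,
      gradeGroup = as.integer(gradeGroup), examIndex = as.integer(examIndex),
      signals = list("0" = b0, "100" = b100, "1000" = b1000, "1500" = b1500),
      mask = mask, voxelSize = 1.0)
}

# A blocky connected mask of exactly `n` voxels on an r x c grid, filled
# row-major from the top-left so it stays 8-connected.
blockMask <- function(n, r, c) {
  m <- matrix(FALSE, r, c)
  m[order(row(m) * 1000 + col(m))[seq_len(n)]] <- TRUE
  m
}
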