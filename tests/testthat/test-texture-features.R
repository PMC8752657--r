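test_that("first-order features match direct computation", {
  f <- firstOrderFeatures(1:10)
  expect_equal(unname(f["p10"]), 1.9)
  expect_equal(unname(f["median"]), 5.5)
  expect_equal(unname(f["sum"]), 55)
  f2 <- firstOrderFeatures(c(0, 0, 0, 10))
  expect_equal(unname(f2["mean"]), 2.5)
  expect_equal(unname(f2["energy"]), 100)
  const <- firstOrderFeatures(rep(3, 20))
  expect_equal(unname(const[c("sd", "skewness", "kurtosis", "entropy")]),
               c(0, 0, 0, 0))
  expect_error(firstOrderFeatures(numeric(0)), "at least one value")
})

test_that("discretization maps endpoints and interior per the floor rule", {
  m <- matrix(c(0, 1, 0.5, 0.5), 2, 2)
  d <- discretizeRoi(m, matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2), 32)
  expect_identical(sort(d$bins[d$mask]), c(1L, 32L))
  d2 <- discretizeRoi(matrix(c(0, 0.5, 1, 0), 2, 2),
                      matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2), 2)
  expect_identical(d2$bins[d2$mask], c(1L, 2L, 2L))  # 0.5 -> 1 + floor(1.0)
  const <- discretizeRoi(matrix(7, 3, 3), matrix(TRUE, 3, 3), 8)
  expect_true(all(const$bins[const$mask] == 1L))
  expect_true(all(const$bins[!const$mask] == 0L))
})

test_that("GLCM features equal brute-force pair enumeration", {
  bins <- matrix(c(1L, 1L, 2L, 2L), 2, 2)  # [[1,2],[1,2]] row-wise
  mask <- matrix(TRUE, 2, 2)
  d <- structure(list(bins = bins, mask = mask, nBins = 2L,
                      sourceMin = 0, sourceMax = 1), class = "DiscretizedRoi")
  got <- glcmFeatures(computeGlcm(d))
  want <- oracleGlcmFeatures(bins, mask, 2L)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("constant ROI collapses the GLCM to a single cell", {
  d <- discretizeRoi(matrix(4, 4, 4), matrix(TRUE, 4, 4), 32)
  f <- glcmFeatures(computeGlcm(d))
  expect_equal(unname(f["glcm_homogeneity"]), 1)
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_energy"]), 1)
  expect_equal(unname(f["glcm_entropy"]), 0)
  expect_equal(unname(f["glcm_correlation"]), 0)  # zero marginal SD convention
})

test_that("run-length features match hand-enumerated runs", {
  # single row (1,1,2), horizontal direction only: runs (1,len2),(2,len1)
  d <- structure(list(bins = matrix(c(1L, 1L, 2L), 1, 3),
                      mask = matrix(TRUE, 1, 3), nBins = 2L,
                      sourceMin = 0, sourceMax = 1), class = "DiscretizedRoi")
  counts <- computeGlrlm(d, directions = list(c(0L, 1L)))
  f <- glrlmFeatures(counts, nVoxels = 3L, nDirections = 1L)
  expect_equal(unname(f["SRE"]), 0.625)        # (1/2)(1/4 + 1/1)
  expect_equal(unname(f["RP"]), 2 / 3)
  # constant 3x3, one direction: three runs of length 3 -> LRE = 9
  dc <- discretizeRoi(matrix(1, 3, 3), matrix(TRUE, 3, 3), 8)
  fc <- glrlmFeatures(computeGlrlm(dc, directions = list(c(0L, 1L))),
                      nVoxels = 9L, nDirections = 1L)
  expect_equal(unname(fc["LRE"]), 9)
})

test_that("zone-size features match connected-component enumeration", {
  bins <- matrix(c(1L, 1L, 1L, 2L), 2, 2)  # zones: level1 size 3, level2 size 1
  mask <- matrix(TRUE, 2, 2)
  d <- structure(list(bins = bins, mask = mask, nBins = 2L,
                      sourceMin = 0, sourceMax = 1), class = "DiscretizedRoi")
  f <- glzsmFeatures(computeGlzsm(d), nVoxels = 4L)
  expect_equal(unname(f["ZP"]), 0.5)
  # constant ROI of n voxels: one zone, LZE = n^2, ZP = 1/n
  n <- 12
  dc <- discretizeRoi(matrix(1, 4, 4), blockMask(n, 4, 4), 8)
  fc <- glzsmFeatures(computeGlzsm(dc), nVoxels = n)
  expect_equal(unname(fc["LZE"]), n^2)
  expect_equal(unname(fc["ZP"]), 1 / n)
})

test_that("neighborhood difference features match hand evaluation", {
  # 3x3 ring of level 1 with center level 2
  bins <- matrix(1L, 3, 3); bins[2, 2] <- 2L
  mask <- matrix(TRUE, 3, 3)
  d <- structure(list(bins = bins, mask = mask, nBins = 2L,
                      sourceMin = 0, sourceMax = 1), class = "DiscretizedRoi")
  ng <- computeNgldm(d)
  expect_equal(ng$p, c(8 / 9, 1 / 9))
  expect_equal(ng$s, c(4 * (1 / 3) + 4 * (1 / 5), 1))  # corners 1/3, edges 1/5
  got <- ngldmFeatures(ng)
  want <- oracleNgldmFeatures(bins, mask, 2L)
  expect_equal(got, want, tolerance = 1e-12)
  # constant ROI: coarseness hits 1/eps, busyness 0 by convention
  dc <- discretizeRoi(matrix(1, 3, 3), mask, 8)
  fc <- ngldmFeatures(computeNgldm(dc))
  expect_equal(unname(fc["busyness"]), 0)
  expect_equal(unname(fc["coarseness"]), 1e12)
})

test_that("higher-order families agree with exhaustive oracles on random grids", {
  set.seed(31)
  for (rep in 1:20) {
    nB <- sample(c(2L, 8L, 32L), 1)
    g <- randomMaskedGrid(sample(4:8, 1), nB)
    nVox <- sum(g$mask)
    expect_equal(glcmFeatures(computeGlcm(g$d)),
                 oracleGlcmFeatures(g$bins, g$mask, nB), tolerance = 1e-10)
    expect_equal(glrlmFeatures(computeGlrlm(g$d), nVox),
                 oracleGlrlmFeatures(g$bins, g$mask), tolerance = 1e-10)
    expect_equal(glzsmFeatures(computeGlzsm(g$d), nVox),
                 oracleGlzsmFeatures(g$bins, g$mask), tolerance = 1e-10)
    expect_equal(ngldmFeatures(computeNgldm(g$d)),
                 oracleNgldmFeatures(g$bins, g$mask, nB), tolerance = 1e-10)
  }
})

test_that("first-order features ignore spatial arrangement; texture does not", {
  set.seed(5)
  mask <- matrix(TRUE, 6, 6)
  v <- matrix(runif(36), 6, 6)
  perm <- matrix(sample(v), 6, 6)
  expect_equal(firstOrderFeatures(v, mask), firstOrderFeatures(perm, mask))
  # fixed counterexample: a smooth ramp vs its shuffle
  ramp <- matrix(rep(1:6, each = 6), 6, 6)
  set.seed(9)
  shuf <- matrix(sample(ramp), 6, 6)
  fr <- glcmFeatures(computeGlcm(discretizeRoi(ramp, mask, 8)))
  fs <- glcmFeatures(computeGlcm(discretizeRoi(shuf, mask, 8)))
  expect_gt(abs(fr["glcm_contrast"] - fs["glcm_contrast"]), 1e-6)
})

test_that("a full feature vector has the 46 named features, deterministically", {
  cfg <- syntheticCohortConfig()
  tr <- generateLesionTruth(cfg, "PZ", 3L, seed = 21)
  acq <- simulateAcquisition(tr, cfg, 1L, seed = 21)
  fv <- textureFeatureVector(computeAdc(acq, c(100, 1500)))
  expect_length(fv, 46L)
  expect_false(anyDuplicated(names(fv)) > 0)
  expect_true(all(c("p5", "p10", "glcm_energy", "SRE", "SZE", "busyness")
                  %in% names(fv)))
  expect_identical(fv, textureFeatureVector(computeAdc(acq, c(100, 1500))))
})

test_that("per-lesion extraction yields 8 base images x 2 exams at any bin count", {
  cfg <- syntheticCohortConfig(nLesionsPZ = 1L, nLesionsTZ = 0L, seed = 3L)
  les <- generateCohort(cfg)[[1]]
  for (nb in c(8L, 16L, 32L)) {
    ft <- extractLesionFeatures(les$exam1, les$exam2, nBins = nb)
    expect_identical(nrow(ft), 16L * 46L)
    expect_identical(unique(ft$n_bins), nb)
    expect_length(unique(ft$base_image), 8L)
  }
})
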