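test_that("configuration invariants are enforced", {
  expect_error(syntheticCohortConfig(ggDistributionPZ = c(0.5, 0.5, 0, 0, 0.1)),
               "summing to 1")
  expect_error(syntheticCohortConfig(lesionAreaRange = c(40, 271)), "50")
  expect_error(syntheticCohortConfig(perfusionFractionF = 1), "perfusionFractionF")
  expect_error(syntheticCohortConfig(ricianSigma = -1), "ricianSigma")
  expect_error(syntheticCohortConfig(pseudoDiffusionDstar = 0.5),
               "pseudoDiffusionDstar")
  expect_error(syntheticCohortConfig(gridSize = 8L), "impossible geometry")
  expect_s4_class(syntheticCohortConfig(), "SyntheticCohortConfig")
})

test_that("generated ROI masks respect area range, extent and connectivity", {
  cfg <- syntheticCohortConfig()
  for (s in 1:25) {
    tr <- generateLesionTruth(cfg, if (s %% 2) "PZ" else "TZ",
                              1L + s %% 5L, seed = s)
    a <- sum(tr@mask)
    expect_gte(a, 58)
    expect_lte(a, 271)
    expect_true(all(DWItexture:::.maskExtent(tr@mask) >= 4L))
    expect_identical(DWItexture:::.countComponents(tr@mask), 1L)
    expect_true(all(tr@diffusionField[tr@mask] > 0))
  }
})

test_that("PZ lesion-mean diffusivity tracks the programmed level trend", {
  cfg <- syntheticCohortConfig(adcMeanInterceptPZ = 1.10, adcSlopePZ = -0.08)
  means <- vapply(1:100, function(s)
    mean(maskedValues(generateLesionTruth(cfg, "PZ", 5L, seed = 1000 + s))),
    1.0)
  # closed-form target 1.10 - 0.08 * 5 = 0.70
  expect_gt(mean(means), 0.60)
  expect_lt(mean(means), 0.80)
})

test_that("TZ diffusivity mean is flat across grade groups", {
  cfg <- syntheticCohortConfig()
  mByGg <- vapply(c(1L, 5L), function(gg) {
    mean(vapply(1:40, function(s)
      mean(maskedValues(generateLesionTruth(cfg, "TZ", gg, seed = 2000 + s))),
      1.0))
  }, 1.0)
  expect_lt(abs(mByGg[1] - mByGg[2]), 0.03)
  expect_lt(abs(mByGg[1] - cfg@adcMeanTZ), 0.05)
})

test_that("noiseless IVIM signal follows the bi-exponential closed form", {
  cfg <- syntheticCohortConfig(ricianSigma = 0, perfusionFractionF = 0.1,
                               pseudoDiffusionDstar = 10)
  mask <- blockMask(60, 10, 10)
  tr <- new("LesionTruth", lesionId = "t", zone = "PZ", gradeGroup = 3L,
            diffusionField = matrix(1.0, 10, 10),
            s0Field = matrix(100, 10, 10), mask = mask)
  acq <- simulateAcquisition(tr, cfg, 1L, seed = 1)
  expect_equal(signalGrid(acq, 0)[1, 1] / 100, 1.0, tolerance = 1e-12)
  expect_equal(signalGrid(acq, 100)[1, 1] / 100,
               0.1 * exp(-1) + 0.9 * exp(-0.1), tolerance = 1e-12)
})

test_that("with no noise and no perfusion the decay is exactly monoexponential", {
  cfg <- syntheticCohortConfig(ricianSigma = 0, perfusionFractionF = 0)
  tr <- generateLesionTruth(cfg, "PZ", 2L, seed = 3)
  acq <- simulateAcquisition(tr, cfg, 1L, seed = 3)
  for (b in c(100, 1000, 1500)) {
    expect_equal(signalGrid(acq, b),
                 tr@s0Field * exp(-b * tr@diffusionField * 1e-3),
                 tolerance = 1e-14)
  }
})

test_that("acquisition simulation is deterministic in its seed", {
  cfg <- syntheticCohortConfig()
  tr <- generateLesionTruth(cfg, "TZ", 4L, seed = 8)
  a1 <- simulateAcquisition(tr, cfg, 1L, seed = 42)
  a2 <- simulateAcquisition(tr, cfg, 1L, seed = 42)
  expect_identical(a1@signals, a2@signals)
  a3 <- simulateAcquisition(tr, cfg, 1L, seed = 43)
  expect_false(identical(a1@signals, a3@signals))
})

test_that("retest mask jitter 0 reuses the exam-1 mask; jitter perturbs it", {
  cfg0 <- syntheticCohortConfig(retestMaskJitter = 0L)
  tr <- generateLesionTruth(cfg0, "PZ", 2L, seed = 5)
  e2 <- simulateAcquisition(tr, cfg0, 2L, seed = 5)
  expect_identical(e2@mask, tr@mask)
  cfg1 <- syntheticCohortConfig(retestMaskJitter = 1L)
  e2j <- simulateAcquisition(tr, cfg1, 2L, seed = 5)
  expect_false(identical(e2j@mask, tr@mask))
  expect_identical(DWItexture:::.countComponents(e2j@mask), 1L)
  expect_gte(sum(e2j@mask), 50)
})

test_that("cohort generation is reproducible and respects composition", {
  cfg <- syntheticCohortConfig(nLesionsPZ = 4L, nLesionsTZ = 3L, seed = 11L)
  coh1 <- generateCohort(cfg)
  coh2 <- generateCohort(cfg)
  expect_length(coh1, 7L)
  expect_identical(
    lapply(coh1, function(l) l$exam1@signals),
    lapply(coh2, function(l) l$exam1@signals))
  expect_identical(vapply(coh1, function(l) l$exam1@zone, ""),
                   c(rep("PZ", 4), rep("TZ", 3)))
  # degenerate grade-group distribution
  cfgD <- syntheticCohortConfig(nLesionsPZ = 5L, nLesionsTZ = 0L,
                                ggDistributionPZ = c(0, 1, 0, 0, 0),
                                ggDistributionTZ = c(0, 1, 0, 0, 0),
                                seed = 2L)
  expect_true(all(vapply(generateCohort(cfgD),
                         function(l) l$exam1@gradeGroup, 1L) == 2L))
})

test_that("generator functions leave the caller's RNG state untouched", {
  cfg <- syntheticCohortConfig(nLesionsPZ = 1L, nLesionsTZ = 0L)
  set.seed(123)
  before <- .Random.seed
  invisible(generateCohort(cfg))
  expect_identical(.Random.seed, before)
})

test_that("YAML configuration round-trips through the constructor", {
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  writeLines(c("nLesionsPZ: 3", "nLesionsTZ: 2", "ricianSigma: 1.5",
               "seed: 9"), path)
  cfg <- cohortConfigFromYaml(path)
  expect_identical(cfg@nLesionsPZ, 3L)
  expect_equal(cfg@ricianSigma, 1.5)
  writeLines("noSuchKnob: 1", path)
  expect_error(cohortConfigFromYaml(path), "unknown configuration key")
})
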