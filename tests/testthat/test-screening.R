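# A small reusable image cohort for cascade tests; features are injected so
# the tests isolate the screening logic from texture extraction.
localCohort <- local({
  cache <- NULL
  function(n = 20L) {
    if (is.null(cache)) {
      cfg <- syntheticCohortConfig(
        nLesionsPZ = n, nLesionsTZ = 0L,
        ggDistributionPZ = c(0.1, 0.3, 0.3, 0.2, 0.1),
        ggDistributionTZ = c(0.1, 0.3, 0.3, 0.2, 0.1), seed = 77L)
      cache <<- generateCohort(cfg)
    }
    cache
  }
})

injectFeatures <- function(cohort, values1, values2, feature = "prog",
                           base = "ADC(100,1500)") {
  ids <- vapply(cohort, function(l) l$exam1@lesionId, "")
  rbind(
    data.frame(lesion_id = ids, exam = 1L, base_image = base,
               feature = feature, value = values1, stringsAsFactors = FALSE),
    data.frame(lesion_id = ids, exam = 2L, base_image = base,
               feature = feature, value = values2, stringsAsFactors = FALSE))
}

cohortGG <- function(cohort) vapply(cohort, function(l) l$exam1@gradeGroup, 1L)

test_that("classification bands assign shared endpoints to the upper band", {
  expect_identical(classifyStrength(-0.45), "moderate")
  expect_identical(classifyStrength(0.7), "strong")
  expect_identical(classifyStrength(0.95), "very strong")
  expect_identical(classifyStrength(0.1), "none")
  expect_identical(classifyAuc(0.85), "excellent")
  expect_identical(classifyAuc(c(0.7, 0.9, 0.65)),
                   c("acceptable", "outstanding", "none"))
  expect_identical(classifyIcc(0.75), "good")
  expect_identical(classifyIcc(c(0.5, 0.9, 1)),
                   c("moderate", "excellent", "excellent"))
  expect_identical(classifyIcc(NA_real_), NA_character_)
})

test_that("only the feature with a dual-exam programmed trend reaches stage 2", {
  coh <- localCohort()
  gg <- cohortGG(coh)
  set.seed(101)
  feats <- rbind(
    injectFeatures(coh, gg + rnorm(20, 0, 0.1), gg + rnorm(20, 0, 0.1), "prog"),
    injectFeatures(coh, gg + rnorm(20, 0, 0.1), rnorm(20), "halfsig"),
    injectFeatures(coh, rnorm(20), rnorm(20), "null"))
  rep <- runZoneAnalysis(coh, "PZ", pipelineConfig(), features = feats)
  expect_identical(rep$feature[rep$advanced], "prog")
  prog <- rep[rep$feature == "prog", ]
  expect_true(prog$selected)
  expect_gt(prog$auc_first, 0.9)
  expect_gt(prog$icc, 0.9)
  half <- rep[rep$feature == "halfsig", ]
  expect_false(half$advanced)   # dual-exam rule: p_second too large
  expect_true(is.na(half$auc_first))
})

test_that("a Bland-Altman SD above the threshold excludes the feature", {
  coh <- localCohort()
  gg <- cohortGG(coh)
  set.seed(103)
  # a zero-crossing feature (like skewness): pair means near 0 blow up the
  # percentage differences even though the GG trend is strong at both exams
  v1 <- gg - 2.5 + rnorm(20, 0, 0.2)
  v2 <- gg - 2.5 + rnorm(20, 0, 0.6)
  feats <- injectFeatures(coh, v1, v2, "wild")
  rep <- runZoneAnalysis(coh, "PZ", pipelineConfig(), features = feats)
  r <- rep[rep$feature == "wild", ]
  expect_true(r$advanced)
  expect_gt(r$ba_sd_pct, 300)
  expect_true(r$excluded_by_ba)
  expect_false(r$selected)
})

test_that("selection is monotone in alpha", {
  coh <- localCohort()
  gg <- cohortGG(coh)
  set.seed(107)
  feats <- do.call(rbind, lapply(1:8, function(k)
    injectFeatures(coh, gg * (k / 8) + rnorm(20, 0, 1),
                   gg * (k / 8) + rnorm(20, 0, 1), paste0("f", k))))
  sel <- function(a) {
    r <- runZoneAnalysis(coh, "PZ", pipelineConfig(alpha = a), features = feats)
    r$feature[r$selected]
  }
  expect_true(all(sel(0.01) %in% sel(0.05)))
  expect_true(all(sel(0.05) %in% sel(0.20)))
})

test_that("null features pass the dual-exam gate at well below twice alpha", {
  coh <- localCohort()
  nFeat <- 100
  rates <- vapply(1:50, function(s) {
    set.seed(500 + s)
    subj <- rnorm(20)
    feats <- do.call(rbind, lapply(seq_len(nFeat), function(k) {
      base <- rnorm(20, subj, 1)   # exam-correlated but GG-independent
      injectFeatures(coh, base + rnorm(20, 0, 0.5),
                     base + rnorm(20, 0, 0.5), paste0("n", k))
    }))
    r <- runZoneAnalysis(coh, "PZ", pipelineConfig(), features = feats)
    mean(r$advanced)
  }, 1.0)
  expect_lte(mean(rates), 2 * 0.05)
})

test_that("zone analysis enforces its preconditions", {
  coh <- localCohort()
  expect_error(runZoneAnalysis(coh, "TZ", pipelineConfig()), "fewer than 5")
  cfg1 <- syntheticCohortConfig(nLesionsPZ = 6L, nLesionsTZ = 0L,
                                ggDistributionPZ = c(0, 1, 0, 0, 0),
                                ggDistributionTZ = c(0, 1, 0, 0, 0), seed = 5L)
  oneGG <- generateCohort(cfg1)
  expect_error(runZoneAnalysis(oneGG, "PZ", pipelineConfig()),
               "single grade group")
})

test_that("screening reports are deterministic and state empty selections", {
  coh <- localCohort()
  gg <- cohortGG(coh)
  set.seed(113)
  feats <- injectFeatures(coh, rnorm(20), rnorm(20), "null")
  rep <- runZoneAnalysis(coh, "PZ", pipelineConfig(), features = feats)
  d <- tempfile(); dir.create(d)
  on.exit(unlink(d, recursive = TRUE))
  p1 <- writeScreeningReport(rep, file.path(d, "a"))
  p2 <- writeScreeningReport(rep, file.path(d, "b"))
  expect_identical(readLines(p1[1]), readLines(p2[1]))
  expect_true("no feature selected" %in% readLines(p1[3]))
})

test_that("the full study bundles QC and per-zone reports across bin settings", {
  cfg <- syntheticCohortConfig(nLesionsPZ = 6L, nLesionsTZ = 6L,
                               ggDistributionPZ = c(0, .4, .4, .2, 0),
                               ggDistributionTZ = c(0, .4, .4, .2, 0),
                               seed = 19L)
  coh <- generateCohort(cfg)
  cfgP <- pipelineConfig(nBins = c(8L, 32L), bPairs = list(c(100, 1500)),
                         dwiBs = 100)
  bundle <- runFullStudy(coh, cfgP)
  expect_s3_class(bundle, "StudyBundle")
  expect_setequal(names(bundle$reports),
                  c("PZ_bins8", "TZ_bins8", "PZ_bins32", "TZ_bins32"))
  s <- attr(bundle$qc, "summary")
  expect_identical(s$n_lesions, 12L)
  expect_identical(s$n_passed + s$n_excluded, 12L)
  # each report covers 2 base images x 46 features
  expect_identical(nrow(bundle$reports$PZ_bins32), 2L * 46L)
  d <- tempfile()
  on.exit(unlink(d, recursive = TRUE), add = TRUE)
  writeStudyBundle(bundle, d)
  expect_true(file.exists(file.path(d, "qc.csv")))
  expect_true(file.exists(file.path(d, "PZ_bins32.csv")))
})
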