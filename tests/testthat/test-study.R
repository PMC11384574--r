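# Channel-pair sampling and end-to-end study orchestration.

test_that("channel-pair sampling is uniform over valid unordered pairs", {
  forced <- sampleChannelPairs(2, 3, seed = 1)
  expect_identical(dim(forced), c(3L, 2L))
  expect_true(all(forced[, 1] == 1 & forced[, 2] == 2))

  big <- sampleChannelPairs(128, 5000, seed = 2)
  expect_identical(nrow(big), 5000L)
  expect_true(all(big[, 1] < big[, 2]))
  expect_true(all(big >= 1 & big <= 128))
  expect_identical(big, sampleChannelPairs(128, 5000, seed = 2))

  # with replacement beyond C(n,2); full support is reached
  many <- sampleChannelPairs(5, 500, seed = 3)
  expect_identical(nrow(unique(many)), 10L)
  expect_true(all(many[, 1] < many[, 2]))

  excl <- sampleChannelPairs(6, 50, seed = 4, exclude = c(2, 5))
  expect_false(any(excl %in% c(2, 5)))
  expect_error(sampleChannelPairs(1, 5, seed = 1), "at least 2")
})

test_that("a planted condition effect is recovered with positive direction", {
  delta <- canonicalBands()[["delta"]]
  cfg <- studyConfig(bands = list(delta = delta),
                     estimator = estimatorConfig(windowS = 120),
                     nPairs = 8, nSubjects = 2,
                     lagBins = data.frame(lowerS = 0, upperS = 1),
                     conditions = c("low", "high"),
                     durationS = 480, trialsPerBin = 8, seed = 42)
  input <- list(
    low = syntheticCondition(modulatorFreq = 0.02, couplingStrength = 0),
    high = syntheticCondition(modulatorFreq = 0.02, couplingStrength = 0.9))
  res <- runStudy(cfg, input, threshold = mscReferenceThreshold())
  cmp <- res@comparisons
  expect_identical(cmp$direction, 1)
  expect_lt(cmp$pAdjusted, 0.01)
  # pooled bookkeeping: samples per bin = nSubjects * trialsPerBin
  expect_identical(lengths(mscSamples(res@lagScans$low$delta)),
                   2L * 8L)
})

test_that("swapping condition labels flips direction and preserves p-values", {
  delta <- canonicalBands()[["delta"]]
  mkConfig <- function(conds) studyConfig(
    bands = list(delta = delta), estimator = estimatorConfig(windowS = 120),
    nPairs = 6, nSubjects = 1, lagBins = data.frame(lowerS = 0, upperS = 1),
    conditions = conds, durationS = 480, trialsPerBin = 6, seed = 7)
  input <- list(
    a = syntheticCondition(couplingStrength = 0),
    b = syntheticCondition(couplingStrength = 0.9))
  fwd <- runStudy(mkConfig(c("a", "b")), input,
                  threshold = mscReferenceThreshold())
  rev <- runStudy(mkConfig(c("b", "a")), input,
                  threshold = mscReferenceThreshold())
  expect_identical(fwd@comparisons$direction, -rev@comparisons$direction)
  expect_equal(fwd@comparisons$pValue, rev@comparisons$pValue,
               tolerance = 1e-12)
})

test_that("a study re-run from its provenance is bit-identical", {
  delta <- canonicalBands()[["delta"]]
  cfg <- studyConfig(bands = list(delta = delta),
                     estimator = estimatorConfig(windowS = 120),
                     nPairs = 3, nSubjects = 2,
                     lagBins = lagBins(0, 30, 15),
                     conditions = c("x", "y"),
                     durationS = 480, trialsPerBin = 3, seed = 99)
  input <- list(x = syntheticCondition(couplingStrength = 0),
                y = syntheticCondition(couplingStrength = 0.5))
  r1 <- runStudy(cfg, input, threshold = 0.054)
  r2 <- runStudy(r1@config, r1@provenance$input, threshold = 0.054)
  expect_identical(r1@lagScans, r2@lagScans)
  expect_identical(r1@comparisons, r2@comparisons)
})

test_that("EDF-backed studies run the same pipeline as synthetic ones", {
  dir <- tempfile("edfstudy")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  fs <- 256
  paths <- vapply(1:2, function(s) {
    chans <- lapply(1:3, function(k)
      generatePinkNoise(fs * 480, samplingRate = fs, seed = 100 * s + k,
                        label = paste0("C", k)))
    p <- file.path(dir, paste0("subj", s, ".edf"))
    writeEDF(chans, p)
    p
  }, "")
  delta <- canonicalBands()[["delta"]]
  cfg <- studyConfig(bands = list(delta = delta),
                     estimator = estimatorConfig(windowS = 120),
                     nPairs = 3, nSubjects = 2,
                     lagBins = data.frame(lowerS = 0, upperS = 1),
                     conditions = c("rec", "synth"),
                     durationS = 480, trialsPerBin = 3, seed = 31)
  input <- list(rec = paths,
                synth = syntheticCondition(couplingStrength = 0))
  res <- runStudy(cfg, input, threshold = 0.054)
  expect_s4_class(res, "StudyResult")
  expect_identical(names(res@lagScans), c("rec", "synth"))
  # both conditions are null here: no significant difference expected
  expect_gt(res@comparisons$pAdjusted, 0.01)
})
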