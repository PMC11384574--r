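# Circular lag imposition, lag scanning, and condition comparison.

test_that("circular envelope shifts form a group: identity, periodicity, inverse", {
  set.seed(3)
  env <- asEnvelope(stats::rexp(360))
  expect_identical(circularShiftEnvelope(env, 0), env)
  expect_identical(envelopeValues(circularShiftEnvelope(env, 360)),
                   envelopeValues(env))
  once <- circularShiftEnvelope(env, 40)
  back <- circularShiftEnvelope(once, 360 - 40)
  expect_identical(envelopeValues(back), envelopeValues(env))
  # the shift convention: output[t] = input[(t - lag) mod L]
  expect_identical(envelopeValues(once)[41], envelopeValues(env)[1])
  expect_error(circularShiftEnvelope(env, 2.5), "integer")
  expect_error(circularShiftEnvelope(env, -3), "non-negative")
})

test_that("a degenerate [0,1) bin reproduces the unshifted pipeline bit-exactly", {
  cfg <- estimatorConfig(windowS = 60)
  set.seed(19)
  pairs <- lapply(1:5, function(i)
    list(asEnvelope(stats::rexp(300)), asEnvelope(stats::rexp(300))))
  scan <- runLagScan(pairs, bins = data.frame(lowerS = 0, upperS = 1),
                     trialsPerBin = 5, config = cfg, seed = 8)
  # bit-exact against the same estimation path without any shift
  pc <- iscoh:::.wosaPrecomp(300L, cfg, 1)
  fast <- vapply(pairs, function(p)
    iscoh:::.wosaInfraslowPair(envelopeValues(p[[1]]),
                               envelopeValues(p[[2]]), pc), 0)
  expect_identical(sort(mscSamples(scan)[[1]]), sort(fast))
  # and equal to the public spectrum route to numerical precision
  direct <- vapply(pairs, function(p)
    infraslowMSC(wosaMSC(p[[1]], p[[2]], cfg), cfg), 0)
  expect_equal(sort(mscSamples(scan)[[1]]), sort(direct),
               tolerance = 1e-12)
})

test_that("lag scans are seed-deterministic and refuse over-wrapping bins", {
  cfg <- estimatorConfig(windowS = 60)
  set.seed(23)
  pairs <- lapply(1:3, function(i)
    list(asEnvelope(stats::rexp(300)), asEnvelope(stats::rexp(300))))
  bins <- lagBins(0, 60, 15)
  a <- runLagScan(pairs, bins, trialsPerBin = 10, config = cfg, seed = 4)
  b <- runLagScan(pairs, bins, trialsPerBin = 10, config = cfg, seed = 4)
  expect_identical(a, b)
  expect_error(runLagScan(pairs, lagBins(0, 360, 15), trialsPerBin = 2,
                          config = cfg, seed = 1), "wrap")
})

test_that("independent pairs give a lag-invariant MSC distribution", {
  cfg <- estimatorConfig(windowS = 90)
  pairs <- lapply(1:60, function(i) {
    pr <- iscoh:::.pinkPair(256 * 450, 256, 0, 7000 + i)
    ps <- iscoh:::.perSecondPSDPair(pr[[1]], pr[[2]], 256L)
    rows <- iscoh:::.bandRows(canonicalBands()[["delta"]], 256)
    list(asEnvelope(colSums(ps[[1]][rows, ])),
         asEnvelope(colSums(ps[[2]][rows, ])))
  })
  bins <- data.frame(lowerS = c(0, 150, 285), upperS = c(15, 165, 300))
  # one trial per pair per bin keeps the within-bin samples independent,
  # which the KS comparison requires
  scan <- runLagScan(pairs, bins, trialsPerBin = 60, config = cfg,
                     seed = 12)
  s <- mscSamples(scan)
  expect_gt(suppressWarnings(stats::ks.test(s[[1]], s[[2]]))$p.value, 0.01)
  expect_gt(suppressWarnings(stats::ks.test(s[[1]], s[[3]]))$p.value, 0.01)
  expect_gt(suppressWarnings(stats::ks.test(s[[2]], s[[3]]))$p.value, 0.01)
})

test_that("threshold crossing reports the first bin whose mean falls below", {
  cfg <- estimatorConfig(windowS = 60)
  scan <- new("LagScanResult",
              bins = lagBins(0, 60, 15),
              samples = list(c(0.5, 0.6), c(0.2, 0.3), c(0.01, 0.02),
                             c(0.5, 0.6)),
              meanCurve = c(0.55, 0.25, 0.015, 0.55),
              threshold = 0.054, thresholdCrossingS = 30, config = cfg)
  expect_identical(scan@thresholdCrossingS, 30)
  validObject(scan)
})

test_that("rank-sum comparison matches small-sample enumeration and direction conventions", {
  # {1,2} vs {3,4}: statistic at its extreme, exact two-sided p = 2/6
  r <- compareConditions(c(1, 2), c(3, 4))
  expect_identical(r$statistic, 0)
  expect_equal(r$pValue, 1 / 3, tolerance = 1e-12)
  expect_identical(r$direction, 1)
  # identical collections: p (and adjusted p) 1, direction 0
  set.seed(9)
  x <- stats::rexp(50)
  r2 <- compareConditions(x, x)
  expect_equal(r2$pAdjusted, 1)
  expect_identical(r2$direction, 0)
  # a planted location shift is detected after Bonferroni adjustment
  set.seed(10)
  a <- stats::rbeta(400, 2, 50)
  b <- a + 0.05
  r3 <- compareConditions(a, b, nComparisons = 5)
  expect_lt(r3$pAdjusted, 0.01)
  expect_identical(r3$direction, 1)
  expect_identical(compareConditions(b, a)$direction, -1)
  expect_error(compareConditions(numeric(), a), "at least 2")
})
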