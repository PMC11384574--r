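# WOSA MSC estimation and the infraslow scalar summary.

test_that("window counting follows floor((L - w)/step) + 1", {
  expect_identical(countWindows(3600, estimatorConfig(180, 0.5)), 39L)
  expect_identical(countWindows(3600, estimatorConfig(360, 0.5)), 19L)
  expect_identical(countWindows(3600, estimatorConfig(720, 0.5)), 9L)
  expect_identical(countWindows(3600, estimatorConfig(1800, 0.5)), 3L)
  expect_identical(countWindows(3600, estimatorConfig(180, 0.25)), 26L)
  expect_identical(countWindows(180, estimatorConfig(180, 0.5)), 1L)
  expect_error(countWindows(100, estimatorConfig(180)), "longer")
})

test_that("self-coherence is 1 at every frequency with nonzero auto-spectrum", {
  set.seed(5)
  env <- asEnvelope(stats::rexp(400))
  sp <- wosaMSC(env, env, estimatorConfig(windowS = 100))
  v <- mscValues(sp)
  expect_equal(v[is.finite(v)], rep(1, sum(is.finite(v))), tolerance = 1e-12)
  # DC bin is 0/0 under mean deletion
  expect_true(is.nan(v[1]))
})

test_that("a shared spectral line dominates its bin and matches the direct DFT oracle", {
  t <- 0:599
  set.seed(21)
  base <- 1 + 0.5 * sin(2 * pi * 0.05 * t)
  x <- asEnvelope(base + stats::rnorm(600, sd = 0.01))
  y <- asEnvelope(base + stats::rnorm(600, sd = 0.01))
  cfg <- estimatorConfig(windowS = 180)
  sp <- wosaMSC(x, y, cfg)
  k <- which(abs(frequencies(sp) - 0.05) < 1e-12)
  expect_gt(mscValues(sp)[k], 0.99)
  ora <- directWosaMSC(envelopeValues(x), envelopeValues(y), 180)
  expect_equal(mscValues(sp), ora$msc, tolerance = 1e-10)
  expect_identical(nWindows(sp), ora$n)
})

test_that("estimator matches the brute-force DFT oracle across configurations", {
  set.seed(31)
  for (case in list(
    list(L = 64, w = 16, ov = 0.5, taper = "hann", md = TRUE),
    list(L = 64, w = 32, ov = 0.5, taper = "boxcar", md = TRUE),
    list(L = 60, w = 20, ov = 0, taper = "hann", md = FALSE),
    list(L = 64, w = 17, ov = 0.25, taper = "hamming", md = TRUE),
    list(L = 48, w = 16, ov = 0.75, taper = "hann", md = TRUE))) {
    x <- stats::rexp(case$L)
    y <- stats::rexp(case$L)
    cfg <- estimatorConfig(windowS = case$w, overlapFraction = case$ov,
                           taper = case$taper, meanDeletion = case$md)
    sp <- wosaMSC(asEnvelope(x), asEnvelope(y), cfg)
    ora <- directWosaMSC(x, y, case$w, case$ov, case$taper, case$md)
    expect_equal(mscValues(sp), ora$msc, tolerance = 1e-10,
                 info = paste("w", case$w, "ov", case$ov, case$taper))
    expect_equal(frequencies(sp), ora$frequencies, tolerance = 1e-12)
  }
})

test_that("MSC is symmetric, scale-invariant and bounded in [0, 1]", {
  set.seed(41)
  cfg <- estimatorConfig(windowS = 50)
  for (i in 1:10) {
    x <- asEnvelope(stats::rexp(200) + (i %% 3 == 0))
    y <- asEnvelope(stats::rexp(200))
    a <- mscValues(wosaMSC(x, y, cfg))
    b <- mscValues(wosaMSC(y, x, cfg))
    expect_equal(a, b, tolerance = 1e-12)
    ys <- asEnvelope(envelopeValues(y) * 37.5)
    expect_equal(a, mscValues(wosaMSC(x, ys, cfg)), tolerance = 1e-10)
    fin <- a[is.finite(a)]
    expect_true(all(fin >= 0 & fin <= 1))
  }
})

test_that("single-segment and mismatched inputs are rejected", {
  x <- asEnvelope(stats::rexp(180))
  expect_error(wosaMSC(x, x, estimatorConfig(windowS = 180)), "2 windows")
  y <- asEnvelope(stats::rexp(100))
  expect_error(wosaMSC(x, y, estimatorConfig(windowS = 50)), "length")
})

test_that("infraslow average uses bins strictly between DC and the cutoff", {
  # 3-min windows: qualifying bins are k = 1..26 (26/180 < 0.15, 27/180 = 0.15)
  freqs <- (0:90) / 180
  sel <- freqs > 0 & freqs < 0.15
  expect_identical(sum(sel), 26L)
  vals <- rep(0, 91)
  vals[sel] <- 1   # unit MSC exactly on the qualifying bins
  vals[1] <- NaN
  sp <- new("MSCSpectrum", frequencies = freqs, mscValues = vals,
            nWindows = 39L)
  expect_equal(infraslowMSC(sp), 1)
  sp2 <- new("MSCSpectrum", frequencies = freqs,
             mscValues = c(NaN, rep(0.5, 90)), nWindows = 39L)
  expect_equal(infraslowMSC(sp2), 0.5)
  # too-coarse grid: no bins below the cutoff
  sp3 <- new("MSCSpectrum", frequencies = c(0, 0.2, 0.4),
             mscValues = c(NaN, 0.5, 0.5), nWindows = 3L)
  expect_error(infraslowMSC(sp3), "no frequency bins")
})

test_that("null per-bin MSC approaches 1/K for K independent white segments", {
  set.seed(53)
  w <- 40L
  cfg <- estimatorConfig(windowS = w, overlapFraction = 0,
                         taper = "boxcar", meanDeletion = TRUE)
  for (K in c(3L, 9L, 19L, 39L)) {
    L <- K * w
    m <- mean(replicate(24, {
      sp <- wosaMSC(asEnvelope(stats::rexp(L)), asEnvelope(stats::rexp(L)),
                    cfg)
      mean(mscValues(sp)[-1])
    }))
    expect_equal(m, 1 / K, tolerance = 0.2)
  }
})

test_that("the packed calibration fast path equals the public estimator route", {
  set.seed(61)
  cfg <- estimatorConfig(windowS = 60)
  for (i in 1:5) {
    ex <- stats::rexp(600)
    ey <- stats::rexp(600)
    pub <- infraslowMSC(wosaMSC(asEnvelope(ex), asEnvelope(ey), cfg), cfg)
    pc <- iscoh:::.wosaPrecomp(600L, cfg, 1)
    expect_equal(iscoh:::.wosaInfraslowPair(ex, ey, pc), pub,
                 tolerance = 1e-12)
  }
})
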