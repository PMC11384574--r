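# WOSA magnitude-squared coherence of band-power envelopes, and its
# infraslow scalar summary.

#' Construct a WOSA estimator configuration
#'
#' @param windowS segment length in seconds (default 180, i.e. 3 min).
#' @param overlapFraction overlap fraction in `[0, 1)` (default 0.5).
#' @param taper taper name: `"hann"` (default), `"hamming"` or `"boxcar"`.
#' @param meanDeletion subtract each segment's own mean before tapering
#'   (default TRUE); this zeroes the DC bin.
#' @param infraslowCutoffHz infraslow cutoff in Hz (default 0.15; strict
#'   inequality, DC excluded).
#' @return An [EstimatorConfig-class].
#' @examples
#' estimatorConfig()                 # the calibrated default
#' estimatorConfig(windowS = 360)    # 6-min windows
#' @export
estimatorConfig <- function(windowS = 180, overlapFraction = 0.5,
                            taper = "hann", meanDeletion = TRUE,
                            infraslowCutoffHz = 0.15) {
  new("EstimatorConfig", windowS = windowS,
      overlapFraction = overlapFraction, taper = taper,
      meanDeletion = meanDeletion, infraslowCutoffHz = infraslowCutoffHz)
}

# Segmentation geometry shared by countWindows() and the estimators.
.segmentGeometry <- function(L, config, resolutionS = 1) {
  w <- config@windowS / resolutionS
  if (abs(w - round(w)) > 1e-9)
    stop("'windowS' must be an integer number of envelope bins")
  w <- as.integer(round(w))
  if (w < 2) stop("'windowS' must span at least 2 envelope bins")
  if (w > L) stop("window (", w, " bins) longer than the series (", L, ")")
  step <- max(1L, as.integer(round(w * (1 - config@overlapFraction))))
  n <- as.integer((L - w) %/% step + 1L)
  list(w = w, step = step, n = n,
       starts = (seq_len(n) - 1L) * step)
}

#' Number of WOSA windows over a series
#'
#' `n = floor((L - w) / step) + 1` with `w` the window length and
#' `step = round(w * (1 - overlapFraction))` in envelope bins; trailing
#' samples that do not fill a window are dropped.
#'
#' @param seriesLength series length in envelope bins.
#' @param config an [EstimatorConfig-class].
#' @param resolutionS envelope bin width in seconds (default 1).
#' @return Integer window count.
#' @examples
#' countWindows(3600, estimatorConfig())                  # 39
#' countWindows(3600, estimatorConfig(windowS = 1800))    # 3
#' @export
countWindows <- function(seriesLength, config = estimatorConfig(),
                         resolutionS = 1) {
  .segmentGeometry(seriesLength, config, resolutionS)$n
}

# Tapered, mean-deleted segment DFT matrix (w x n) of a numeric series.
.segmentFFT <- function(v, geom, taper, meanDeletion) {
  segs <- matrix(v[rep(geom$starts, each = geom$w) + seq_len(geom$w)],
                 nrow = geom$w)
  if (meanDeletion)
    segs <- segs - rep(colMeans(segs), each = geom$w)
  stats::mvfft(segs * taper)
}

#' WOSA magnitude-squared coherence spectrum of two envelopes
#'
#' Splits both envelopes into `n` overlapping segments, optionally deletes
#' each segment's mean, tapers, transforms, and averages the segment cross-
#' and auto-spectra before forming the squared coherence
#' \deqn{\mathrm{MSC}(f) = \frac{|\sum_i S_{xy}^{(i)}(f)|^2}
#'   {\sum_i S_{xx}^{(i)}(f)\,\sum_i S_{yy}^{(i)}(f)},}
#' bounded in `[0, 1]` by the Cauchy-Schwarz inequality. At least two
#' segments are required — a single-segment MSC is identically 1 and
#' meaningless. Segments are not zero-padded, so the frequency grid is
#' `k / windowS` Hz exactly.
#'
#' @param x,y [BandPowerEnvelope-class] objects of equal length and
#'   resolution.
#' @param config an [EstimatorConfig-class].
#' @return An [MSCSpectrum-class] over the one-sided grid
#'   `k / windowS`, `k = 0 ... floor(w/2)`. Bins with vanishing averaged
#'   auto-spectra (the DC bin under mean deletion) are `NaN`.
#' @examples
#' sig <- generatePinkNoise(256 * 900, samplingRate = 256, seed = 1)
#' env <- bandPowerSeries(sig, canonicalBands()[["delta"]])
#' sp <- wosaMSC(env, env, estimatorConfig())  # self-coherence: all 1
#' range(mscValues(sp)[-1])
#' @seealso [infraslowMSC()], [countWindows()]
#' @export
wosaMSC <- function(x, y, config = estimatorConfig()) {
  stopifnot(is(x, "BandPowerEnvelope"), is(y, "BandPowerEnvelope"))
  if (length(x@values) != length(y@values))
    stop("envelopes have different lengths (", length(x@values), " vs ",
         length(y@values), ")")
  if (x@resolutionS != y@resolutionS)
    stop("envelopes have different resolutions")
  res <- x@resolutionS
  L <- length(x@values)
  geom <- .segmentGeometry(L, config, res)
  if (geom$n < 2)
    stop("fewer than 2 windows (got ", geom$n,
         "): single-segment MSC is identically 1 and meaningless")
  taper <- .taperWindow(config@taper, geom$w)
  FX <- .segmentFFT(x@values, geom, taper, config@meanDeletion)
  FY <- .segmentFFT(y@values, geom, taper, config@meanDeletion)
  half <- geom$w %/% 2L
  rows <- seq_len(half + 1L)
  FX <- FX[rows, , drop = FALSE]
  FY <- FY[rows, , drop = FALSE]
  Sxy <- rowSums(FX * Conj(FY))
  Sxx <- rowSums(Mod(FX)^2)
  Syy <- rowSums(Mod(FY)^2)
  denom <- Sxx * Syy
  msc <- rep(NaN, length(rows))
  ok <- denom > 0
  if (config@meanDeletion) ok[1] <- FALSE  # DC is analytically 0/0
  msc[ok] <- Mod(Sxy[ok])^2 / denom[ok]
  msc[ok] <- pmin(pmax(msc[ok], 0), 1)  # clip 1e-12-level rounding
  new("MSCSpectrum",
      frequencies = (rows - 1L) / (geom$w * res),
      mscValues = msc, nWindows = geom$n)
}

#' Collapse an MSC spectrum to the scalar infraslow MSC
#'
#' The unweighted mean of the MSC values over bins with
#' `0 < f < infraslowCutoffHz` — DC is excluded (it is 0/0 under mean
#' deletion) and the inequality at the cutoff is strict. With the default
#' 180-s windows and 0.15 Hz cutoff the qualifying bins are
#' `k/180` for `k = 1 ... 26`.
#'
#' @param x an [MSCSpectrum-class].
#' @param config an [EstimatorConfig-class] supplying the cutoff, or a
#'   single number interpreted as the cutoff in Hz.
#' @return A single number in `[0, 1]`.
#' @examples
#' sp <- new("MSCSpectrum", frequencies = (0:90) / 180,
#'           mscValues = c(NaN, rep(0.5, 90)), nWindows = 39L)
#' infraslowMSC(sp)  # 0.5
#' @seealso [wosaMSC()]
#' @export
infraslowMSC <- function(x, config = estimatorConfig()) {
  stopifnot(is(x, "MSCSpectrum"))
  cutoff <- if (is(config, "EstimatorConfig")) config@infraslowCutoffHz
            else .assertScalarNumber(config, "config")
  sel <- x@frequencies > 0 & x@frequencies < cutoff
  if (!any(sel))
    stop("no frequency bins strictly between 0 and the cutoff (", cutoff,
         " Hz); use longer windows or a higher cutoff")
  mean(x@mscValues[sel])
}

# Fast internal path used by calibration and lag scanning: infraslow MSC of
# two numeric envelope series, with the pair packed into one complex FFT per
# segment block. pc comes from .wosaPrecomp(). Bitwise equivalence with the
# public wosaMSC()+infraslowMSC() route is covered by tests.
.wosaPrecomp <- function(L, config, resolutionS = 1) {
  geom <- .segmentGeometry(L, config, resolutionS)
  if (geom$n < 2)
    stop("fewer than 2 windows (got ", geom$n,
         "): single-segment MSC is identically 1 and meaningless")
  w <- geom$w
  ks <- seq_len(w %/% 2L)
  sel <- ks[ks / (w * resolutionS) < config@infraslowCutoffHz]
  if (!length(sel))
    stop("no frequency bins strictly between 0 and the cutoff (",
         config@infraslowCutoffHz, " Hz)")
  list(geom = geom,
       idx = rep(geom$starts, each = w) + seq_len(w),
       taper = .taperWindow(config@taper, w),
       meanDeletion = config@meanDeletion,
       sel = sel + 1L,          # 1-based row of bin k
       selConj = w - sel + 1L)  # 1-based row of bin w - k
}

.wosaInfraslowPair <- function(ex, ey, pc) {
  w <- pc$geom$w
  z <- matrix(complex(real = ex[pc$idx], imaginary = ey[pc$idx]), nrow = w)
  if (pc$meanDeletion)
    z <- z - rep(colMeans(z), each = w)
  Z <- stats::mvfft(z * pc$taper)
  A <- Z[pc$sel, , drop = FALSE]
  B <- Conj(Z[pc$selConj, , drop = FALSE])
  X <- (A + B) / 2
  Y <- (A - B) / 2i
  Sxy <- rowSums(X * Conj(Y))
  Sxx <- rowSums(Re(X)^2 + Im(X)^2)
  Syy <- rowSums(Re(Y)^2 + Im(Y)^2)
  mean(pmin((Re(Sxy)^2 + Im(Sxy)^2) / (Sxx * Syy), 1))
}
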