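# Band-power envelope extraction: per-second periodograms summed over the
# canonical EEG bands.

#' Construct a band definition
#'
#' @param name band name.
#' @param fLow,fHigh band edges in Hz; the band is the half-open interval
#'   `[fLow, fHigh)`.
#' @return A [BandDefinition-class].
#' @examples
#' bandDefinition("slow-gamma", 30, 50)
#' @export
bandDefinition <- function(name, fLow, fHigh) {
  new("BandDefinition", name = name, fLow = fLow, fHigh = fHigh)
}

#' The five canonical EEG bands
#'
#' Delta `[0.5, 4)`, theta `[4, 8)`, alpha `[8, 13)`, beta `[13, 25)` and
#' gamma `[25, 55)` Hz. Half-open intervals: each shared edge belongs to the
#' upper band only, so no frequency bin is counted twice.
#'
#' @return A named list of [BandDefinition-class] objects.
#' @examples
#' canonicalBands()[["delta"]]
#' @export
canonicalBands <- function() {
  list(delta = bandDefinition("delta", 0.5, 4),
       theta = bandDefinition("theta", 4, 8),
       alpha = bandDefinition("alpha", 8, 13),
       beta  = bandDefinition("beta", 13, 25),
       gamma = bandDefinition("gamma", 25, 55))
}

# One-sided, folded per-second periodogram matrix of a real signal.
# Rows index frequency 0, 1, ..., floor(fs/2) Hz (1-s segments give 1-Hz
# bins); columns index whole seconds; a partial trailing second is dropped.
# The folding doubles all bins except DC and (for even fs) Nyquist, so the
# column sums equal the per-second mean square (Parseval).
.perSecondPSD <- function(x, fs) {
  nsec <- floor(length(x) / fs)
  if (nsec < 1) stop("signal shorter than one second")
  m <- matrix(x[seq_len(nsec * fs)], nrow = fs)
  Z <- stats::mvfft(m)
  half <- floor(fs / 2)
  P <- Mod(Z[seq_len(half + 1L), , drop = FALSE])^2 / fs^2
  if (half >= 2) {
    up <- if (fs %% 2 == 0) half else half + 1L
    P[2:up, ] <- 2 * P[2:up, ]
  }
  P
}

# Same, for a pair of real signals packed into one complex FFT. When
# maxRow is given only rows 1..maxRow of the folded periodogram matrices
# are returned (the calibration loop only needs bins up to the highest
# band edge).
.perSecondPSDPair <- function(x, y, fs, maxRow = NULL) {
  nsec <- floor(length(x) / fs)
  if (nsec < 1) stop("signal shorter than one second")
  keep <- seq_len(nsec * fs)
  m <- matrix(complex(real = x[keep], imaginary = y[keep]), nrow = fs)
  Z <- stats::mvfft(m)
  half <- floor(fs / 2)
  top <- if (is.null(maxRow)) half + 1L else min(half + 1L, maxRow)
  rows <- seq_len(top)
  conjRows <- c(1L, fs + 2L - rows[-1])
  Zc <- Conj(Z[conjRows, , drop = FALSE])
  Z <- Z[rows, , drop = FALSE]
  X <- (Z + Zc) / 2
  Y <- (Z - Zc) / 2i
  fold <- function(P) {
    up <- if (fs %% 2 == 0) min(top, half) else top
    if (up >= 2) P[2:up, ] <- 2 * P[2:up, ]
    P
  }
  list(fold((Re(X)^2 + Im(X)^2) / fs^2),
       fold((Re(Y)^2 + Im(Y)^2) / fs^2))
}

# Row indices of the per-second PSD matrix falling in [fLow, fHigh).
# Bin k (1-based row k) has frequency (k-1)/resolution Hz.
.bandRows <- function(band, fs, resolutionS = 1) {
  freq <- (seq_len(floor(fs * resolutionS / 2) + 1L) - 1L) / resolutionS
  which(freq >= band@fLow & freq < band@fHigh)
}

.checkBandNyquist <- function(band, fs) {
  if (band@fHigh > fs / 2)
    stop("band \"", band@name, "\" exceeds the Nyquist frequency (",
         fs / 2, " Hz)")
}

#' Per-second band-power time series of a channel
#'
#' Computes the power spectral density of each non-overlapping 1-s segment
#' (plain untapered periodogram, no detrending within the second) and sums it
#' over the frequency bins in `[fLow, fHigh)`, producing one non-negative
#' power value per full second; a partial trailing second is dropped. The
#' periodogram is normalized so that its sum over all bins from 0 to Nyquist
#' equals the segment's mean square (Parseval).
#'
#' @param signal a [ChannelSignal-class] of duration >= 1 s.
#' @param band a [BandDefinition-class]; must not exceed the Nyquist range.
#' @param resolutionS envelope bin width in seconds (default 1).
#' @return A [BandPowerEnvelope-class] with `floor(duration)` values.
#' @examples
#' sig <- generatePinkNoise(256 * 10, samplingRate = 256, seed = 1)
#' env <- bandPowerSeries(sig, canonicalBands()[["delta"]])
#' length(envelopeValues(env))  # 10
#' @seealso [allBandPowers()], [wosaMSC()]
#' @export
bandPowerSeries <- function(signal, band, resolutionS = 1) {
  stopifnot(is(signal, "ChannelSignal"), is(band, "BandDefinition"))
  fs <- signal@samplingRate
  .checkBandNyquist(band, fs)
  nseg <- fs * resolutionS
  if (abs(nseg - round(nseg)) > 1e-9)
    stop("samplingRate * resolutionS must be an integer")
  if (length(signal@samples) < nseg)
    stop("signal shorter than one envelope bin (", resolutionS, " s)")
  P <- .perSecondPSD(signal@samples, as.integer(round(nseg)))
  rows <- .bandRows(band, fs, resolutionS)
  vals <- if (length(rows)) .colSumsSafe(P, rows) else
    numeric(ncol(P))
  new("BandPowerEnvelope", values = vals, resolutionS = resolutionS,
      band = band, sourceLabel = signal@label)
}

.colSumsSafe <- function(P, rows) {
  if (length(rows) == 1L) P[rows, ] else colSums(P[rows, , drop = FALSE])
}

#' Band-power envelopes for several bands in one pass
#'
#' Computes the per-second periodogram once and sums it over each requested
#' band, so joint extraction is bitwise identical to (and cheaper than)
#' separate [bandPowerSeries()] calls.
#'
#' @param signal a [ChannelSignal-class].
#' @param bands non-empty list of [BandDefinition-class] objects (default:
#'   the five canonical bands).
#' @param resolutionS envelope bin width in seconds (default 1).
#' @return A named list of [BandPowerEnvelope-class], one per band.
#' @examples
#' sig <- generatePinkNoise(256 * 8, samplingRate = 256, seed = 1)
#' envs <- allBandPowers(sig)
#' names(envs)
#' @export
allBandPowers <- function(signal, bands = canonicalBands(), resolutionS = 1) {
  stopifnot(is(signal, "ChannelSignal"))
  if (!length(bands)) stop("'bands' must be a non-empty list")
  if (is(bands, "BandDefinition")) bands <- list(bands)
  for (b in bands) {
    stopifnot(is(b, "BandDefinition"))
    .checkBandNyquist(b, signal@samplingRate)
  }
  fs <- signal@samplingRate
  nseg <- fs * resolutionS
  if (abs(nseg - round(nseg)) > 1e-9)
    stop("samplingRate * resolutionS must be an integer")
  P <- .perSecondPSD(signal@samples, as.integer(round(nseg)))
  out <- lapply(bands, function(b) {
    rows <- .bandRows(b, fs, resolutionS)
    vals <- if (length(rows)) .colSumsSafe(P, rows) else numeric(ncol(P))
    new("BandPowerEnvelope", values = vals, resolutionS = resolutionS,
        band = b, sourceLabel = signal@label)
  })
  if (is.null(names(out)))
    names(out) <- vapply(bands, function(b) b@name, "")
  out
}
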