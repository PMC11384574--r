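# Synthetic signal generation: pink-noise surrogates and coupled pairs.
#
# Pink noise is synthesized in the frequency domain: complex Gaussian
# coefficients scaled by 1/sqrt(f) (DC zeroed), inverse transform, then an
# exact rescale to the target mean power. Two statistically independent real
# channels are obtained from ONE complex inverse FFT by reading its real and
# imaginary parts (the Hermitian and anti-Hermitian parts of a non-symmetric
# Gaussian spectrum are independent), which halves the cost of generating
# surrogate pairs.

# Spectral amplitude profile of the pink synthesis (cacheable across
# trials: it depends only on the geometry).
.pinkAmplitude <- function(n, samplingRate) {
  amp <- numeric(n)
  f <- .foldedFrequencies(n, samplingRate)
  amp[f > 0] <- 1 / sqrt(f[f > 0])
  amp
}

# Generate a pair of independent pink-noise channels from one seed.
.pinkPair <- function(nSamples, samplingRate, powerDb = 0, seed,
                      amp = NULL) {
  n <- as.integer(nSamples)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  if (is.null(amp)) amp <- .pinkAmplitude(n, samplingRate)
  z <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) * amp
  w <- stats::fft(z, inverse = TRUE)
  target <- 10^(powerDb / 10)
  x <- Re(w)
  y <- Im(w)
  list(x * sqrt(target / mean(x^2)), y * sqrt(target / mean(y^2)))
}

#' Generate a seeded pink-noise (1/f) surrogate channel
#'
#' Synthesizes a channel whose power spectral density is proportional to
#' `1/f` for `f > 0` — the canonical surrogate for intracranial EEG, whose
#' spectrum it matches well. Synthesis is done in the frequency domain
#' (spectral amplitudes proportional to `1/sqrt(f)`, DC set to zero, i.i.d.
#' uniform phases via complex Gaussian coefficients, inverse real transform),
#' then the realization is rescaled so its mean power equals exactly
#' `10^(powerDb / 10)`; "0 dB" therefore means unit variance. The DC
#' component is exactly zero, so the signal has exactly zero mean.
#'
#' @param nSamples integer number of samples (>= 2).
#' @param samplingRate sampling rate in Hz (default 256).
#' @param powerDb target mean power in decibels relative to 1 (default 0,
#'   i.e. unit variance).
#' @param seed integer seed; identical seeds give bit-identical signals,
#'   distinct seeds give statistically independent ones.
#' @param label channel label.
#' @return A [ChannelSignal-class].
#' @examples
#' sig <- generatePinkNoise(2^14, samplingRate = 256, seed = 42)
#' mean(samples(sig)^2)  # 1 (0 dB)
#' @seealso [generateCoupledPair()], [calibrateEstimator()]
#' @export
generatePinkNoise <- function(nSamples, samplingRate = 256, powerDb = 0,
                              seed, label = "pink") {
  if (missing(seed)) stop("'seed' is required: reproducibility is mandatory")
  .assertScalarNumber(nSamples, "nSamples")
  if (nSamples < 2) stop("'nSamples' must be >= 2")
  .assertScalarNumber(samplingRate, "samplingRate")
  if (samplingRate <= 0) stop("'samplingRate' must be positive")
  x <- .pinkPair(nSamples, samplingRate, powerDb, seed)[[1]]
  new("ChannelSignal", samples = x, samplingRate = samplingRate,
      label = label)
}

# Band-limited Gaussian noise (flat spectral amplitude inside [fLow, fHigh),
# zero outside), unit variance, synthesized in the frequency domain.
.bandNoise <- function(n, samplingRate, fLow, fHigh) {
  f <- .foldedFrequencies(n, samplingRate)
  amp <- as.numeric(f >= fLow & f < fHigh & f > 0)
  if (!any(amp > 0)) stop("modulator band contains no frequency bins")
  z <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) * amp
  m <- Re(stats::fft(z, inverse = TRUE))
  m / stats::sd(m)
}

#' Generate a channel pair with a shared infraslow envelope modulator
#'
#' Builds two pink-noise carriers whose instantaneous amplitude in one
#' canonical band is multiplied by `1 + couplingStrength * m(t)`, where
#' `m(t)` is a shared zero-mean infraslow modulator; the second channel's
#' modulator is delayed circularly by `imposedLagS`. This is the
#' parameter-recovery fixture for the whole pipeline: the imposed coupling
#' strength and lag are ground truth that downstream estimates must recover.
#'
#' The modulation is applied by splitting each carrier into its zero-phase
#' band-limited component (frequency-domain mask over `[fLow, fHigh)`) and
#' the out-of-band residue, scaling only the in-band component, and adding
#' the residue back — coupling is therefore confined to `carrierBand`.
#' With `couplingStrength = 0` the carriers are returned untouched: two
#' independent pink-noise channels.
#'
#' Two modulators are available. `"sine"` (the default) is a sinusoid at
#' `modulatorFreq` with a random initial phase shared by both channels; its
#' envelope second spectrum is a single analyzable line. Note that a
#' deterministic sinusoid yields WOSA coherence that is *invariant* under
#' circular lag (a lag only rotates the cross-spectrum phase, identically in
#' every segment), so lag-decay experiments must use `"bandnoise"`: a
#' band-limited Gaussian modulator (flat over `modulatorBand`, default
#' one octave around `modulatorFreq`, i.e. `[0.5, 1.5] * modulatorFreq`)
#' whose finite coherence time makes the estimated coherence decay with
#' imposed lag, as genuinely stochastic infraslow oscillations do.
#'
#' @param durationS signal duration in seconds.
#' @param samplingRate sampling rate in Hz (default 256).
#' @param modulatorFreq modulator frequency in Hz; must be positive and
#'   below the infraslow cutoff (modulation at or above the cutoff would be
#'   invisible to the infraslow average).
#' @param couplingStrength modulation depth shared by both channels, in
#'   `[0, 1]`.
#' @param imposedLagS circular delay (seconds) of channel 2's modulator.
#' @param carrierBand a [BandDefinition-class]; the band carrying the
#'   coupling (default delta).
#' @param modulatorType `"sine"` or `"bandnoise"` (see Details).
#' @param modulatorBand length-2 numeric band (Hz) for the `"bandnoise"`
#'   modulator; default `c(0.5, 1.5) * modulatorFreq`.
#' @param infraslowCutoffHz cutoff against which `modulatorFreq` is
#'   validated (default 0.15).
#' @param seed integer master seed (carrier and modulator streams derive
#'   from it).
#' @return A list of two [ChannelSignal-class] objects.
#' @examples
#' pair <- generateCoupledPair(600, modulatorFreq = 0.02,
#'                             couplingStrength = 0.8, seed = 7)
#' duration(pair[[1]])
#' @seealso [generatePinkNoise()], [runLagScan()]
#' @export
generateCoupledPair <- function(durationS, samplingRate = 256,
                                modulatorFreq, couplingStrength,
                                imposedLagS = 0,
                                carrierBand = canonicalBands()[["delta"]],
                                modulatorType = c("sine", "bandnoise"),
                                modulatorBand = NULL,
                                infraslowCutoffHz = 0.15, seed) {
  if (missing(seed)) stop("'seed' is required: reproducibility is mandatory")
  modulatorType <- match.arg(modulatorType)
  .assertScalarNumber(modulatorFreq, "modulatorFreq")
  .assertScalarNumber(couplingStrength, "couplingStrength")
  if (modulatorFreq <= 0) stop("'modulatorFreq' must be positive")
  if (modulatorFreq >= infraslowCutoffHz)
    stop("'modulatorFreq' must be below the infraslow cutoff (",
         infraslowCutoffHz, " Hz): faster modulation is invisible to the ",
         "infraslow average")
  if (modulatorFreq >= 0.5)
    stop("'modulatorFreq' must be below 0.5 Hz, the Nyquist frequency of ",
         "the 1-s envelope resolution")
  if (couplingStrength < 0 || couplingStrength > 1)
    stop("'couplingStrength' must lie in [0, 1]")
  if (durationS * modulatorFreq < 3)
    stop("need at least 3 modulator cycles: durationS * modulatorFreq >= 3")
  n <- as.integer(round(durationS * samplingRate))
  seeds <- .spawnSeeds(seed, 2L)
  carriers <- .pinkPair(n, samplingRate, 0, seeds[1])
  mk <- function(x, lab) new("ChannelSignal", samples = x,
                             samplingRate = samplingRate, label = lab)
  if (couplingStrength == 0)
    return(list(mk(carriers[[1]], "coupled-1"), mk(carriers[[2]], "coupled-2")))

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seeds[2])
  t <- (seq_len(n) - 1) / samplingRate
  if (modulatorType == "sine") {
    phi <- stats::runif(1, 0, 2 * pi)
    m1 <- sin(2 * pi * modulatorFreq * t + phi)
    m2 <- sin(2 * pi * modulatorFreq * (t - imposedLagS) + phi)
  } else {
    if (is.null(modulatorBand))
      modulatorBand <- c(0.5, 1.5) * modulatorFreq
    m1 <- .bandNoise(n, samplingRate, modulatorBand[1], modulatorBand[2]) /
      sqrt(2)  # RMS 1/sqrt(2), matching the unit-amplitude sinusoid
    lagSamp <- as.integer(round(imposedLagS * samplingRate)) %% n
    m2 <- if (lagSamp == 0) m1 else
      c(m1[(n - lagSamp + 1):n], m1[1:(n - lagSamp)])
  }
  x1 <- .modulateBand(carriers[[1]], samplingRate, carrierBand,
                      couplingStrength * m1)
  x2 <- .modulateBand(carriers[[2]], samplingRate, carrierBand,
                      couplingStrength * m2)
  list(mk(x1, "coupled-1"), mk(x2, "coupled-2"))
}

# Multiply the zero-phase band-limited component of x by (1 + g) and add the
# out-of-band residue back: x + B * g, with B the in-band component.
.modulateBand <- function(x, samplingRate, band, g) {
  n <- length(x)
  f <- .foldedFrequencies(n, samplingRate)
  mask <- as.numeric(f >= band@fLow & f < band@fHigh)
  B <- Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
  x + B * g
}
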