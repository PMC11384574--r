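#' @import methods
NULL

#' BandDefinition: a canonical frequency band
#'
#' A half-open frequency interval `[fLow, fHigh)` in Hz with a name. The
#' half-open convention means a shared band edge (e.g. 4 Hz between delta and
#' theta) is counted in the upper band only, so no periodogram bin is ever
#' summed into two adjacent bands.
#'
#' @slot name character band name (e.g. `"delta"`).
#' @slot fLow numeric lower edge in Hz (inclusive).
#' @slot fHigh numeric upper edge in Hz (exclusive).
#'
#' @seealso [canonicalBands()], [bandDefinition()]
#' @export
setClass("BandDefinition",
  representation(name = "character", fLow = "numeric", fHigh = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "'name' must be a single non-empty string")
    if (length(object@fLow) != 1L || length(object@fHigh) != 1L ||
        !is.finite(object@fLow) || !is.finite(object@fHigh))
      msg <- c(msg, "'fLow' and 'fHigh' must be single finite numbers")
    else if (object@fLow < 0 || object@fLow >= object@fHigh)
      msg <- c(msg, "need 0 <= fLow < fHigh")
    if (length(msg)) msg else TRUE
  })

#' ChannelSignal: a uniformly sampled voltage (or surrogate) trace
#'
#' The raw unit of analysis: one channel's samples together with its sampling
#' rate and a label. Duration in seconds is `length(samples) / samplingRate`.
#'
#' @slot samples numeric vector of finite sample values (arbitrary units).
#' @slot samplingRate numeric sampling rate in Hz.
#' @slot label character channel identifier.
#'
#' @seealso [generatePinkNoise()], [generateCoupledPair()], [readRecording()]
#' @export
setClass("ChannelSignal",
  representation(samples = "numeric", samplingRate = "numeric",
                 label = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@samples) < 1L)
      msg <- c(msg, "'samples' must be non-empty")
    if (anyNA(object@samples) || !all(is.finite(object@samples)))
      msg <- c(msg, "all samples must be finite")
    if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
        object@samplingRate <= 0)
      msg <- c(msg, "'samplingRate' must be a single positive number")
    if (length(object@label) != 1L)
      msg <- c(msg, "'label' must be a single string")
    if (length(msg)) msg else TRUE
  })

#' BandPowerEnvelope: per-second band power of one channel in one band
#'
#' The slow time course ("envelope") of power in one canonical band at a fixed
#' temporal resolution (1 s by default). These are the series on which
#' infraslow coherence is computed.
#'
#' @slot values numeric vector of non-negative, finite per-bin powers
#'   (signal-units squared per time bin).
#' @slot resolutionS numeric bin width in seconds (1 by default).
#' @slot band a [BandDefinition-class].
#' @slot sourceLabel character label of the source channel.
#'
#' @seealso [bandPowerSeries()], [allBandPowers()]
#' @export
setClass("BandPowerEnvelope",
  representation(values = "numeric", resolutionS = "numeric",
                 band = "BandDefinition", sourceLabel = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@values) < 1L)
      msg <- c(msg, "'values' must be non-empty")
    if (anyNA(object@values) || !all(is.finite(object@values)) ||
        any(object@values < 0))
      msg <- c(msg, "all envelope values must be finite and >= 0")
    if (length(object@resolutionS) != 1L || !is.finite(object@resolutionS) ||
        object@resolutionS <= 0)
      msg <- c(msg, "'resolutionS' must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' EstimatorConfig: WOSA coherence estimator configuration
#'
#' Parameters of the Welch overlapped-segment-averaging (WOSA) magnitude-
#' squared-coherence estimator applied to band-power envelopes, plus the
#' infraslow cutoff used to collapse the MSC spectrum to a scalar.
#'
#' Defaults are the calibrated operating point: 180-s (3-min) windows, 50%
#' overlap, Hann taper, per-segment mean deletion, 0.15 Hz infraslow cutoff.
#'
#' @slot windowS numeric segment length in seconds.
#' @slot overlapFraction numeric overlap fraction in `[0, 1)`.
#' @slot taper character taper name: `"hann"`, `"hamming"` or `"boxcar"`.
#' @slot meanDeletion logical; subtract each segment's own mean before
#'   tapering and transforming (zeroes the DC bin).
#' @slot infraslowCutoffHz numeric cutoff in Hz; the scalar infraslow MSC is
#'   the unweighted mean of MSC bins with `0 < f < infraslowCutoffHz`.
#'
#' @seealso [estimatorConfig()], [wosaMSC()], [infraslowMSC()]
#' @export
setClass("EstimatorConfig",
  representation(windowS = "numeric", overlapFraction = "numeric",
                 taper = "character", meanDeletion = "logical",
                 infraslowCutoffHz = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@windowS) != 1L || !is.finite(object@windowS) ||
        object@windowS <= 0)
      msg <- c(msg, "'windowS' must be a single positive number")
    if (length(object@overlapFraction) != 1L ||
        !is.finite(object@overlapFraction) ||
        object@overlapFraction < 0 || object@overlapFraction >= 1)
      msg <- c(msg, "'overlapFraction' must lie in [0, 1)")
    if (length(object@taper) != 1L ||
        !object@taper %in% c("hann", "hamming", "boxcar"))
      msg <- c(msg, "'taper' must be one of \"hann\", \"hamming\", \"boxcar\"")
    if (length(object@meanDeletion) != 1L || is.na(object@meanDeletion))
      msg <- c(msg, "'meanDeletion' must be TRUE or FALSE")
    if (length(object@infraslowCutoffHz) != 1L ||
        !is.finite(object@infraslowCutoffHz) || object@infraslowCutoffHz <= 0)
      msg <- c(msg, "'infraslowCutoffHz' must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' MSCSpectrum: frequency-indexed magnitude-squared coherence
#'
#' One-sided squared coherence of an envelope pair on the WOSA frequency grid
#' `k / windowS` for `k = 0 ... floor(w/2)`. Values are bounded in `[0, 1]`
#' by the Cauchy-Schwarz inequality; bins whose averaged auto-spectra vanish
#' (the DC bin under mean deletion) are `NaN`.
#'
#' @slot frequencies numeric frequency grid in Hz.
#' @slot mscValues numeric squared coherence per frequency.
#' @slot nWindows integer number of (overlapping) segments averaged.
#'
#' @seealso [wosaMSC()], [infraslowMSC()]
#' @export
setClass("MSCSpectrum",
  representation(frequencies = "numeric", mscValues = "numeric",
                 nWindows = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@frequencies) != length(object@mscValues))
      msg <- c(msg, "'frequencies' and 'mscValues' lengths differ")
    v <- object@mscValues[is.finite(object@mscValues)]
    if (length(v) && (any(v < 0) || any(v > 1)))
      msg <- c(msg, "finite MSC values must lie in [0, 1]")
    if (length(object@nWindows) != 1L || object@nWindows < 1L)
      msg <- c(msg, "'nWindows' must be a single positive integer")
    if (length(msg)) msg else TRUE
  })

#' CalibrationResult: null distribution summary of the infraslow MSC
#'
#' Summary of the infraslow MSC over independent surrogate (pink-noise) pairs
#' under one estimator configuration and band: mean, SD, maximum, and the
#' mean + 3 SD significance threshold.
#'
#' @slot nTrials integer number of surrogate pairs.
#' @slot config the [EstimatorConfig-class] used.
#' @slot band the [BandDefinition-class] of the envelopes.
#' @slot nullMean,nullSd,nullMax numeric summary statistics of the null.
#' @slot threshold numeric `nullMean + 3 * nullSd`.
#' @slot samples numeric per-trial infraslow MSC values (possibly empty when
#'   not stored).
#'
#' @seealso [calibrateEstimator()], [significanceThreshold()]
#' @export
setClass("CalibrationResult",
  representation(nTrials = "integer", config = "EstimatorConfig",
                 band = "BandDefinition", nullMean = "numeric",
                 nullSd = "numeric", nullMax = "numeric",
                 threshold = "numeric", samples = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@nTrials) != 1L || object@nTrials < 1L)
      msg <- c(msg, "'nTrials' must be a single positive integer")
    if (!(object@nullMean >= 0 && object@nullMean <= object@nullMax &&
          object@nullMax <= 1))
      msg <- c(msg, "need 0 <= nullMean <= nullMax <= 1")
    if (object@nullSd < 0)
      msg <- c(msg, "'nullSd' must be >= 0")
    if (object@threshold < object@nullMean)
      msg <- c(msg, "'threshold' must be >= nullMean")
    if (length(object@samples) &&
        length(object@samples) != object@nTrials)
      msg <- c(msg, "'samples', when stored, must have one value per trial")
    if (length(msg)) msg else TRUE
  })

#' LagScanResult: infraslow MSC binned by imposed circular lag
#'
#' Per-bin collections of infraslow MSC values obtained by circularly
#' shifting the second envelope of each sampled pair by a random lag drawn
#' within the bin, plus the per-bin mean curve and the first bin whose mean
#' falls below the significance threshold.
#'
#' @slot bins data.frame with columns `lowerS` (inclusive) and `upperS`
#'   (exclusive), in seconds.
#' @slot samples list of numeric vectors, one per bin.
#' @slot meanCurve numeric per-bin mean infraslow MSC.
#' @slot threshold numeric threshold used for the crossing (NA when none
#'   supplied).
#' @slot thresholdCrossingS numeric `lowerS` of the first bin whose mean is
#'   below `threshold` (NA when never crossed or no threshold given).
#' @slot config the [EstimatorConfig-class] used.
#'
#' @seealso [runLagScan()], [lagBins()]
#' @export
setClass("LagScanResult",
  representation(bins = "data.frame", samples = "list", meanCurve = "numeric",
                 threshold = "numeric", thresholdCrossingS = "numeric",
                 config = "EstimatorConfig"),
  validity = function(object) {
    msg <- character()
    nb <- nrow(object@bins)
    if (!all(c("lowerS", "upperS") %in% names(object@bins)))
      msg <- c(msg, "'bins' needs columns lowerS and upperS")
    if (length(object@samples) != nb || length(object@meanCurve) != nb)
      msg <- c(msg, "'samples' and 'meanCurve' must have one entry per bin")
    v <- unlist(object@samples, use.names = FALSE)
    if (length(v) && (any(!is.finite(v)) || any(v < 0) || any(v > 1)))
      msg <- c(msg, "all stored MSC values must be finite and in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' StudyConfig: configuration of an end-to-end study run
#'
#' Bundles every parameter of a multi-subject, multi-condition analysis:
#' bands, estimator configuration, number of channel pairs per subject, lag
#' bins, subject count, condition labels and the master seed. The defaults
#' mirror a 22-subject study with 5,000 sampled contact pairs per subject,
#' hour-long 256 Hz recordings, and 15-s lag bins through 300 s.
#'
#' @slot bands list of [BandDefinition-class] objects.
#' @slot estimator an [EstimatorConfig-class].
#' @slot nPairs integer channel (or synthetic) pairs per subject.
#' @slot lagBins data.frame of lag bins (see [lagBins()]).
#' @slot nSubjects integer number of subjects / synthetic ensembles.
#' @slot conditions character vector of unique condition labels.
#' @slot durationS,samplingRate numeric recording duration (s) and rate (Hz).
#' @slot trialsPerBin integer lag-scan trials per bin (defaults to `nPairs`).
#' @slot seed integer master seed; all sub-streams derive from it.
#'
#' @seealso [studyConfig()], [runStudy()]
#' @export
setClass("StudyConfig",
  representation(bands = "list", estimator = "EstimatorConfig",
                 nPairs = "integer", lagBins = "data.frame",
                 nSubjects = "integer", conditions = "character",
                 durationS = "numeric", samplingRate = "numeric",
                 trialsPerBin = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!length(object@bands) ||
        !all(vapply(object@bands, is, TRUE, "BandDefinition")))
      msg <- c(msg, "'bands' must be a non-empty list of BandDefinition")
    if (object@nPairs < 1L) msg <- c(msg, "'nPairs' must be >= 1")
    if (object@nSubjects < 1L) msg <- c(msg, "'nSubjects' must be >= 1")
    if (!length(object@conditions) || anyDuplicated(object@conditions))
      msg <- c(msg, "'conditions' must be non-empty and unique")
    if (length(msg)) msg else TRUE
  })

#' StudyResult: aggregated output of a study run
#'
#' Per-condition, per-band lag-scan results pooled across subjects, the
#' pairwise condition comparisons (Bonferroni-adjusted Wilcoxon rank-sum
#' tests per band), and full provenance (configuration, seeds, package
#' version) sufficient to reproduce the run bit-for-bit.
#'
#' @slot lagScans nested list: `lagScans[[condition]][[band]]` is a pooled
#'   [LagScanResult-class].
#' @slot comparisons data.frame of per-band condition comparisons.
#' @slot threshold numeric significance threshold used.
#' @slot config the [StudyConfig-class] of the run.
#' @slot provenance list recording the input specification, seeds and
#'   package version.
#'
#' @seealso [runStudy()]
#' @export
setClass("StudyResult",
  representation(lagScans = "list", comparisons = "data.frame",
                 threshold = "numeric", config = "StudyConfig",
                 provenance = "list"))
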