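#' Accessors for iscoh classes
#'
#' Small accessor generics so user code never reaches into slots:
#' `samples()`, `samplingRate()`, `duration()` and `signalLabel()` for
#' [ChannelSignal-class]; `envelopeValues()`, `envelopeResolution()` and
#' `bandOf()` for [BandPowerEnvelope-class]; `frequencies()`, `mscValues()`
#' and `nWindows()` for [MSCSpectrum-class]; `nullMean()`, `nullSd()`,
#' `nullMax()` and `nullSamples()` for [CalibrationResult-class];
#' `lagBinsOf()`, `mscSamples()` and `meanCurve()` for
#' [LagScanResult-class].
#'
#' @param x an iscoh object.
#' @return The corresponding slot value.
#' @name accessors
#' @aliases samples samplingRate duration signalLabel envelopeValues
#'   envelopeResolution bandOf frequencies mscValues nWindows nullMean
#'   nullSd nullMax nullSamples lagBinsOf mscSamples meanCurve
#' @examples
#' sig <- generatePinkNoise(1024, samplingRate = 256, seed = 1)
#' samplingRate(sig)
#' duration(sig)
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @rdname accessors
#' @export
setGeneric("signalLabel", function(x) standardGeneric("signalLabel"))
#' @rdname accessors
#' @export
setGeneric("envelopeValues", function(x) standardGeneric("envelopeValues"))
#' @rdname accessors
#' @export
setGeneric("envelopeResolution",
           function(x) standardGeneric("envelopeResolution"))
#' @rdname accessors
#' @export
setGeneric("bandOf", function(x) standardGeneric("bandOf"))
#' @rdname accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))
#' @rdname accessors
#' @export
setGeneric("mscValues", function(x) standardGeneric("mscValues"))
#' @rdname accessors
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))
#' @rdname accessors
#' @export
setGeneric("nullMean", function(x) standardGeneric("nullMean"))
#' @rdname accessors
#' @export
setGeneric("nullSd", function(x) standardGeneric("nullSd"))
#' @rdname accessors
#' @export
setGeneric("nullMax", function(x) standardGeneric("nullMax"))
#' @rdname accessors
#' @export
setGeneric("nullSamples", function(x) standardGeneric("nullSamples"))
#' @rdname accessors
#' @export
setGeneric("lagBinsOf", function(x) standardGeneric("lagBinsOf"))
#' @rdname accessors
#' @export
setGeneric("mscSamples", function(x) standardGeneric("mscSamples"))
#' @rdname accessors
#' @export
setGeneric("meanCurve", function(x) standardGeneric("meanCurve"))

#' @rdname accessors
setMethod("samples", "ChannelSignal", function(x) x@samples)
#' @rdname accessors
setMethod("samplingRate", "ChannelSignal", function(x) x@samplingRate)
#' @rdname accessors
setMethod("duration", "ChannelSignal",
          function(x) length(x@samples) / x@samplingRate)
#' @rdname accessors
setMethod("signalLabel", "ChannelSignal", function(x) x@label)

#' @rdname accessors
setMethod("envelopeValues", "BandPowerEnvelope", function(x) x@values)
#' @rdname accessors
setMethod("envelopeResolution", "BandPowerEnvelope",
          function(x) x@resolutionS)
#' @rdname accessors
setMethod("bandOf", "BandPowerEnvelope", function(x) x@band)
#' @rdname accessors
setMethod("signalLabel", "BandPowerEnvelope", function(x) x@sourceLabel)
#' @rdname accessors
setMethod("duration", "BandPowerEnvelope",
          function(x) length(x@values) * x@resolutionS)

#' @rdname accessors
setMethod("frequencies", "MSCSpectrum", function(x) x@frequencies)
#' @rdname accessors
setMethod("mscValues", "MSCSpectrum", function(x) x@mscValues)
#' @rdname accessors
setMethod("nWindows", "MSCSpectrum", function(x) x@nWindows)

#' @rdname accessors
setMethod("nullMean", "CalibrationResult", function(x) x@nullMean)
#' @rdname accessors
setMethod("nullSd", "CalibrationResult", function(x) x@nullSd)
#' @rdname accessors
setMethod("nullMax", "CalibrationResult", function(x) x@nullMax)
#' @rdname accessors
setMethod("nullSamples", "CalibrationResult", function(x) x@samples)
#' @rdname accessors
setMethod("bandOf", "CalibrationResult", function(x) x@band)

#' @rdname accessors
setMethod("lagBinsOf", "LagScanResult", function(x) x@bins)
#' @rdname accessors
setMethod("mscSamples", "LagScanResult", function(x) x@samples)
#' @rdname accessors
setMethod("meanCurve", "LagScanResult", function(x) x@meanCurve)

#' Significance threshold of a calibrated null
#'
#' The empirical significance threshold is the null mean plus three null
#' standard deviations (nominal p < 0.005 for a roughly Gaussian right
#' tail). Dispatches on a [CalibrationResult-class], or on two numbers
#' (mean, SD) for direct arithmetic.
#'
#' @param x a [CalibrationResult-class], or the null mean as a number.
#' @param sd the null standard deviation when `x` is numeric.
#' @return A single number, `mean + 3 * sd`.
#' @examples
#' significanceThreshold(0.1, 0.01)   # 0.13
#' @seealso [calibrateEstimator()], [mscReferenceThreshold()]
#' @export
setGeneric("significanceThreshold",
           function(x, sd) standardGeneric("significanceThreshold"))

setMethod("show", "ChannelSignal", function(object) {
  cat(sprintf("ChannelSignal \"%s\": %d samples @ %g Hz (%.6g s)\n",
              object@label, length(object@samples), object@samplingRate,
              duration(object)))
})

setMethod("show", "BandDefinition", function(object) {
  cat(sprintf("BandDefinition \"%s\": [%g, %g) Hz\n",
              object@name, object@fLow, object@fHigh))
})

setMethod("show", "BandPowerEnvelope", function(object) {
  cat(sprintf(
    "BandPowerEnvelope of \"%s\", band %s [%g, %g) Hz: %d bins @ %g s\n",
    object@sourceLabel, object@band@name, object@band@fLow,
    object@band@fHigh, length(object@values), object@resolutionS))
})

setMethod("show", "EstimatorConfig", function(object) {
  cat(sprintf(
    "EstimatorConfig: %g-s windows, %.0f%% overlap, %s taper, mean deletion %s, infraslow cutoff %g Hz\n",
    object@windowS, 100 * object@overlapFraction, object@taper,
    if (object@meanDeletion) "on" else "off", object@infraslowCutoffHz))
})

setMethod("show", "MSCSpectrum", function(object) {
  cat(sprintf(
    "MSCSpectrum: %d bins, df = %g Hz, %d windows averaged\n",
    length(object@frequencies),
    if (length(object@frequencies) > 1)
      object@frequencies[2] - object@frequencies[1] else NA_real_,
    object@nWindows))
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf(
    "CalibrationResult (%s band, %d trials): null %0.4f +/- %0.4f, max %0.4f, threshold %0.4f\n",
    object@band@name, object@nTrials, object@nullMean, object@nullSd,
    object@nullMax, object@threshold))
})

setMethod("show", "LagScanResult", function(object) {
  cat(sprintf(
    "LagScanResult: %d lag bins over [%g, %g) s, %s trials/bin\n",
    nrow(object@bins), min(object@bins$lowerS), max(object@bins$upperS),
    paste(unique(lengths(object@samples)), collapse = "/")))
  if (is.finite(object@thresholdCrossingS))
    cat(sprintf("  mean curve first below threshold %0.4f at lag bin starting %g s\n",
                object@threshold, object@thresholdCrossingS))
})

setMethod("show", "StudyConfig", function(object) {
  cat(sprintf(
    "StudyConfig: %d subjects x %d pairs, %d bands, conditions: %s, seed %d\n",
    object@nSubjects, object@nPairs, length(object@bands),
    paste(object@conditions, collapse = ", "), object@seed))
})

setMethod("show", "StudyResult", function(object) {
  cat(sprintf("StudyResult: conditions %s\n",
              paste(names(object@lagScans), collapse = ", ")))
  if (nrow(object@comparisons)) {
    cat("Condition comparisons (Wilcoxon rank-sum, Bonferroni-adjusted):\n")
    print(object@comparisons, row.names = FALSE)
  }
})
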