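# Plain-text export/import helpers: YAML estimator configs, CSV envelope
# and spectrum tables, JSON calibration summaries.

#' Round-trip an estimator configuration through YAML
#'
#' `writeEstimatorConfig()` serializes an [EstimatorConfig-class] to a YAML
#' file; `readEstimatorConfig()` reads one back, applying the standard
#' defaults to any omitted field.
#'
#' @param config an [EstimatorConfig-class].
#' @param path YAML file path.
#' @return `writeEstimatorConfig()` returns `path` invisibly;
#'   `readEstimatorConfig()` returns an [EstimatorConfig-class].
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeEstimatorConfig(estimatorConfig(windowS = 360), f)
#' readEstimatorConfig(f)
#' @export
writeEstimatorConfig <- function(config, path) {
  stopifnot(is(config, "EstimatorConfig"))
  yaml::write_yaml(list(windowS = config@windowS,
                        overlapFraction = config@overlapFraction,
                        taper = config@taper,
                        meanDeletion = config@meanDeletion,
                        infraslowCutoffHz = config@infraslowCutoffHz),
                   path)
  invisible(path)
}

#' @rdname writeEstimatorConfig
#' @export
readEstimatorConfig <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(estimatorConfig, v[intersect(names(v),
                                       names(formals(estimatorConfig)))])
}

#' Export a band-power envelope as a CSV table
#'
#' Columns `time_s` (bin start), `band` and `power`.
#'
#' @param env a [BandPowerEnvelope-class].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
exportEnvelope <- function(env, path) {
  stopifnot(is(env, "BandPowerEnvelope"))
  utils::write.csv(
    data.frame(time_s = (seq_along(env@values) - 1) * env@resolutionS,
               band = env@band@name, power = env@values),
    path, row.names = FALSE)
  invisible(path)
}

#' Export an MSC spectrum as a CSV table
#'
#' Columns `frequency_hz` and `msc`.
#'
#' @param spectrum an [MSCSpectrum-class].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
exportMSCSpectrum <- function(spectrum, path) {
  stopifnot(is(spectrum, "MSCSpectrum"))
  utils::write.csv(data.frame(frequency_hz = spectrum@frequencies,
                              msc = spectrum@mscValues),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a calibration result as JSON
#'
#' All summary fields plus the estimator configuration; raw per-trial
#' samples are included when stored and `includeSamples` is TRUE.
#'
#' @param result a [CalibrationResult-class].
#' @param path JSON file path.
#' @param includeSamples include the raw per-trial values (default FALSE).
#' @return `path`, invisibly.
#' @export
exportCalibration <- function(result, path, includeSamples = FALSE) {
  stopifnot(is(result, "CalibrationResult"))
  x <- list(nTrials = result@nTrials,
            band = result@band@name,
            config = list(windowS = result@config@windowS,
                          overlapFraction = result@config@overlapFraction,
                          taper = result@config@taper,
                          meanDeletion = result@config@meanDeletion,
                          infraslowCutoffHz =
                            result@config@infraslowCutoffHz),
            nullMean = result@nullMean, nullSd = result@nullSd,
            nullMax = result@nullMax, threshold = result@threshold)
  if (includeSamples && length(result@samples))
    x$samples <- result@samples
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export lag-scan samples as a CSV table
#'
#' One row per stored MSC sample, with columns `bin_lower_s`,
#' `bin_upper_s` and `msc`.
#'
#' @param result a [LagScanResult-class].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
exportLagScan <- function(result, path) {
  stopifnot(is(result, "LagScanResult"))
  n <- lengths(result@samples)
  utils::write.csv(
    data.frame(bin_lower_s = rep(result@bins$lowerS, n),
               bin_upper_s = rep(result@bins$upperS, n),
               msc = unlist(result@samples, use.names = FALSE)),
    path, row.names = FALSE)
  invisible(path)
}
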