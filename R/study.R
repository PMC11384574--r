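# End-to-end study orchestration: channel-pair sampling, per-condition
# pipelines, pooling across subjects, and condition comparison.

#' Construct a study configuration
#'
#' Defaults mirror a full-scale study: 22 subjects, 5,000 sampled pairs per
#' subject, hour-long 256 Hz recordings, the five canonical bands, the
#' calibrated 3-min / 50% estimator, 15-s lag bins through 300 s, and two
#' conditions. Scale `nSubjects`, `nPairs`, `durationS` and `lagBins` down
#' for exploratory runs.
#'
#' @param bands list of [BandDefinition-class] (default [canonicalBands()]).
#' @param estimator an [EstimatorConfig-class].
#' @param nPairs channel pairs sampled per subject (default 5000).
#' @param lagBins data.frame from [lagBins()].
#' @param nSubjects number of subjects (default 22).
#' @param conditions character vector of unique condition labels.
#' @param durationS,samplingRate recording geometry (defaults 3600 s,
#'   256 Hz).
#' @param trialsPerBin lag-scan trials per bin per subject (default
#'   `nPairs`).
#' @param seed integer master seed; sub-streams for pair sampling, lags and
#'   surrogates all derive from it.
#' @return A [StudyConfig-class].
#' @examples
#' studyConfig(nSubjects = 2, nPairs = 10, durationS = 600)
#' @seealso [runStudy()]
#' @export
studyConfig <- function(bands = canonicalBands(),
                        estimator = estimatorConfig(), nPairs = 5000,
                        lagBins = iscoh::lagBins(), nSubjects = 22,
                        conditions = c("on_asm", "off_asm"),
                        durationS = 3600, samplingRate = 256,
                        trialsPerBin = nPairs, seed = 1) {
  new("StudyConfig", bands = bands, estimator = estimator,
      nPairs = as.integer(nPairs), lagBins = lagBins,
      nSubjects = as.integer(nSubjects), conditions = conditions,
      durationS = durationS, samplingRate = samplingRate,
      trialsPerBin = as.integer(trialsPerBin), seed = as.integer(seed))
}

#' Describe a synthetic study condition
#'
#' A generative specification for one condition of a synthetic study: every
#' sampled "contact pair" of that condition is a coupled pink-noise pair
#' from [generateCoupledPair()] with these parameters.
#'
#' @param modulatorFreq shared infraslow modulator frequency in Hz.
#' @param couplingStrength modulation depth in `[0, 1]`; 0 gives
#'   independent pink-noise pairs.
#' @param imposedLagS circular delay of channel 2's modulator in seconds.
#' @param carrierBand a [BandDefinition-class] carrying the coupling.
#' @param modulatorType `"sine"` or `"bandnoise"` (see
#'   [generateCoupledPair()]).
#' @param modulatorBand optional explicit modulator band (Hz).
#' @return A `SyntheticCondition` list.
#' @examples
#' syntheticCondition(couplingStrength = 0.8)
#' @export
syntheticCondition <- function(modulatorFreq = 0.02, couplingStrength = 0,
                               imposedLagS = 0,
                               carrierBand = canonicalBands()[["delta"]],
                               modulatorType = "bandnoise",
                               modulatorBand = NULL) {
  structure(list(modulatorFreq = modulatorFreq,
                 couplingStrength = couplingStrength,
                 imposedLagS = imposedLagS, carrierBand = carrierBand,
                 modulatorType = modulatorType,
                 modulatorBand = modulatorBand),
            class = c("SyntheticCondition", "list"))
}

#' Sample random unordered channel pairs
#'
#' Uniform draws of unordered pairs of distinct channel indices: without
#' replacement while `nPairs` does not exceed `choose(nChannels, 2)`, with
#' replacement beyond that. A channel is never paired with itself.
#'
#' @param nChannels number of channels (>= 2).
#' @param nPairs number of pairs to draw.
#' @param seed integer seed.
#' @param exclude optional integer vector of channel indices to exclude.
#' @return An `nPairs` x 2 integer matrix with columns `i < j`.
#' @examples
#' sampleChannelPairs(128, 10, seed = 1)
#' @seealso [runStudy()]
#' @export
sampleChannelPairs <- function(nChannels, nPairs, seed, exclude = NULL) {
  if (missing(seed)) stop("'seed' is required: reproducibility is mandatory")
  .assertScalarNumber(nChannels, "nChannels")
  .assertScalarNumber(nPairs, "nPairs")
  keep <- setdiff(seq_len(as.integer(nChannels)), exclude)
  n <- length(keep)
  if (n < 2) stop("need at least 2 (non-excluded) channels")
  nPairs <- as.integer(nPairs)
  total <- n * (n - 1) / 2
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  m <- if (nPairs > total) sample.int(total, nPairs, replace = TRUE)
       else sample.int(total, nPairs)
  cum0 <- c(0, cumsum(n - seq_len(n - 1)))
  i <- findInterval(m - 0.5, cum0)
  j <- i + (m - cum0[i])
  cbind(i = keep[i], j = keep[j])
}

# Child seed for a named sub-stream of a study.
.studySeed <- function(seed, ...) .streamSeed(seed, paste(..., sep = "/"))

# Per-band envelope pair lists for one subject's set of signal pairs.
.envelopePairsByBand <- function(signalPairs, bands) {
  bandNames <- vapply(bands, function(b) b@name, "")
  out <- lapply(bandNames, function(nm) vector("list", length(signalPairs)))
  names(out) <- bandNames
  for (p in seq_along(signalPairs)) {
    e1 <- allBandPowers(signalPairs[[p]][[1]], bands)
    e2 <- allBandPowers(signalPairs[[p]][[2]], bands)
    for (b in seq_along(bandNames))
      out[[b]][[p]] <- list(e1[[b]], e2[[b]])
  }
  out
}

# Pool per-bin samples of several LagScanResult objects (same bins).
.poolLagScans <- function(scans, threshold) {
  bins <- scans[[1]]@bins
  nb <- nrow(bins)
  samplesList <- lapply(seq_len(nb), function(j)
    unlist(lapply(scans, function(s) s@samples[[j]]), use.names = FALSE))
  mc <- vapply(samplesList, mean, 0)
  thr <- if (is.null(threshold)) NA_real_ else threshold
  crossing <- NA_real_
  if (is.finite(thr)) {
    below <- which(mc < thr)
    if (length(below)) crossing <- bins$lowerS[min(below)]
  }
  new("LagScanResult", bins = bins, samples = samplesList, meanCurve = mc,
      threshold = thr, thresholdCrossingS = crossing,
      config = scans[[1]]@config)
}

#' Run an end-to-end study
#'
#' For every condition and subject, obtains channel-pair signals (generated
#' per a [syntheticCondition()] specification, or read from EDF recordings
#' and paired by [sampleChannelPairs()]), extracts band-power envelopes in
#' every configured band, runs the circular lag scan, pools the MSC samples
#' across subjects per lag bin, and compares conditions per band with
#' two-sided Wilcoxon rank-sum tests Bonferroni-adjusted over the number of
#' bands. The comparison uses each band's pooled samples over all lag bins,
#' testing every non-reference condition against the first (reference)
#' condition.
#'
#' The result is a pure function of `(config, input)`: all randomness flows
#' from `config@seed` through named sub-streams, so re-running with the
#' same arguments reproduces the result bit for bit.
#'
#' @param config a [StudyConfig-class].
#' @param input named list with one element per condition (names must match
#'   `config@conditions`): either a [syntheticCondition()] specification,
#'   or a character vector of EDF file paths, one per subject.
#' @param threshold significance threshold for the lag-curve crossing
#'   summary; a number, a [CalibrationResult-class], or NULL (default) to
#'   calibrate freshly with `calibrationTrials` pink-noise trials at the
#'   study geometry.
#' @param calibrationTrials trials for the fresh calibration (default 200).
#' @return A [StudyResult-class].
#' @seealso [studyConfig()], [syntheticCondition()], [compareConditions()]
#' @export
runStudy <- function(config, input, threshold = NULL,
                     calibrationTrials = 200) {
  stopifnot(is(config, "StudyConfig"))
  if (!all(config@conditions %in% names(input)))
    stop("'input' must have one element per condition: ",
         paste(config@conditions, collapse = ", "))
  if (is(threshold, "CalibrationResult"))
    threshold <- significanceThreshold(threshold)
  if (is.null(threshold)) {
    cal <- calibrateEstimator(calibrationTrials, config@estimator,
                              config@bands[[1]], config@durationS,
                              config@samplingRate,
                              seed = .studySeed(config@seed, "calibration"))
    threshold <- significanceThreshold(cal)
  }
  bandNames <- vapply(config@bands, function(b) b@name, "")
  lagScans <- list()
  for (cond in config@conditions) {
    src <- input[[cond]]
    perBand <- lapply(bandNames, function(nm) list())
    names(perBand) <- bandNames
    for (s in seq_len(config@nSubjects)) {
      signalPairs <- .subjectSignalPairs(src, config, cond, s)
      envPairs <- .envelopePairsByBand(signalPairs, config@bands)
      for (b in bandNames) {
        scan <- runLagScan(envPairs[[b]], config@lagBins,
                           config@trialsPerBin, config@estimator,
                           seed = .studySeed(config@seed, "lags", cond,
                                             s, b),
                           threshold = threshold)
        perBand[[b]] <- c(perBand[[b]], list(scan))
      }
    }
    lagScans[[cond]] <- lapply(perBand, .poolLagScans,
                               threshold = threshold)
  }
  ref <- config@conditions[1]
  comparisons <- do.call(rbind, unlist(lapply(
    setdiff(config@conditions, ref), function(cond)
      lapply(bandNames, function(b) {
        a <- unlist(lagScans[[ref]][[b]]@samples, use.names = FALSE)
        bb <- unlist(lagScans[[cond]][[b]]@samples, use.names = FALSE)
        cbind(data.frame(reference = ref, condition = cond, band = b),
              compareConditions(a, bb,
                                nComparisons = length(bandNames)))
      })), recursive = FALSE))
  if (is.null(comparisons))
    comparisons <- data.frame(reference = character(),
                              condition = character(), band = character(),
                              statistic = numeric(), pValue = numeric(),
                              pAdjusted = numeric(), direction = numeric())
  new("StudyResult", lagScans = lagScans, comparisons = comparisons,
      threshold = threshold, config = config,
      provenance = list(
        input = input, seed = config@seed,
        packageVersion = as.character(utils::packageVersion("iscoh"))))
}

# Signal pairs for one subject under one condition: synthetic generation or
# EDF reading plus channel-pair sampling.
.subjectSignalPairs <- function(src, config, cond, subject) {
  if (inherits(src, "SyntheticCondition")) {
    seeds <- .spawnSeeds(.studySeed(config@seed, "surrogates", cond,
                                    subject),
                         config@nPairs)
    lapply(seq_len(config@nPairs), function(p)
      generateCoupledPair(config@durationS, config@samplingRate,
                          modulatorFreq = src$modulatorFreq,
                          couplingStrength = src$couplingStrength,
                          imposedLagS = src$imposedLagS,
                          carrierBand = src$carrierBand,
                          modulatorType = src$modulatorType,
                          modulatorBand = src$modulatorBand,
                          seed = seeds[p]))
  } else if (is.character(src)) {
    if (length(src) < subject)
      stop("condition has ", length(src), " recordings but subject ",
           subject, " was requested")
    channels <- readRecording(src[subject], durationS = config@durationS)
    if (length(channels) < 2)
      stop("recording ", src[subject], " has fewer than 2 channels")
    pairs <- sampleChannelPairs(length(channels), config@nPairs,
                                seed = .studySeed(config@seed, "pairs",
                                                  cond, subject))
    lapply(seq_len(nrow(pairs)), function(p)
      list(channels[[pairs[p, 1]]], channels[[pairs[p, 2]]]))
  } else {
    stop("condition input must be a syntheticCondition() or a character ",
         "vector of EDF paths")
  }
}
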