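# Circular time-lag scanning of envelope pairs and rank-based condition
# comparison.

#' Construct contiguous lag bins
#'
#' Half-open lag intervals `[lowerS, upperS)` tiling `[from, to)` in steps
#' of `width` seconds. The default tiles `[0, 300)` in 15-s bins — lags
#' 0-15 s, 15-30 s, ..., 285-300 s.
#'
#' @param from,to range in seconds (defaults 0 and 300).
#' @param width bin width in seconds (default 15).
#' @return A data.frame with columns `lowerS` and `upperS`.
#' @examples
#' head(lagBins())
#' @seealso [runLagScan()]
#' @export
lagBins <- function(from = 0, to = 300, width = 15) {
  if (from < 0 || to <= from || width <= 0)
    stop("need 0 <= from < to and width > 0")
  lower <- seq(from, to - width, by = width)
  data.frame(lowerS = lower, upperS = lower + width)
}

#' Circularly shift a band-power envelope
#'
#' `output[t] = input[(t - lagS) mod L]`: the series is rotated so that a
#' positive lag delays it, with the end wrapping back to the beginning.
#' Length is preserved; a lag equal to the envelope length (or 0) is the
#' identity, and shifting by `lagS` then `L - lagS` recovers the original.
#'
#' @param env a [BandPowerEnvelope-class] at 1-s (integer-bin) resolution.
#' @param lagS non-negative integer lag in seconds (must be a whole number
#'   of envelope bins).
#' @return A [BandPowerEnvelope-class] of the same length.
#' @examples
#' sig <- generatePinkNoise(256 * 10, samplingRate = 256, seed = 1)
#' env <- bandPowerSeries(sig, canonicalBands()[["delta"]])
#' shifted <- circularShiftEnvelope(env, 3)
#' @export
circularShiftEnvelope <- function(env, lagS) {
  stopifnot(is(env, "BandPowerEnvelope"))
  .assertScalarNumber(lagS, "lagS")
  if (lagS < 0) stop("'lagS' must be non-negative")
  bins <- lagS / env@resolutionS
  if (abs(bins - round(bins)) > 1e-9)
    stop("'lagS' must be an integer number of envelope bins (resolution ",
         env@resolutionS, " s)")
  L <- length(env@values)
  k <- as.integer(round(bins)) %% L
  if (k == 0) return(env)
  out <- env
  out@values <- c(env@values[(L - k + 1):L], env@values[1:(L - k)])
  out
}

#' Scan infraslow MSC over imposed circular lags
#'
#' For each lag bin and each trial, draws an envelope pair from `pairs`
#' (uniformly; with replacement when `trialsPerBin` exceeds the number of
#' pairs), draws an integer lag uniformly on `[lowerS, upperS)`, circularly
#' shifts the second envelope by it, and records the infraslow MSC. The
#' per-bin mean curve and the first bin whose mean falls below `threshold`
#' are derived from the stored samples. Fully reproducible from `seed`.
#'
#' A degenerate bin `[0, 1)` forces lag 0 and reproduces the unshifted
#' pipeline bit-exactly.
#'
#' @param pairs list of envelope pairs; each element is a list of two
#'   [BandPowerEnvelope-class] objects of equal length.
#' @param bins lag bins from [lagBins()].
#' @param trialsPerBin trials per lag bin (>= 1).
#' @param config an [EstimatorConfig-class].
#' @param seed integer seed.
#' @param threshold optional significance threshold for the crossing
#'   summary (e.g. from [significanceThreshold()] or
#'   [mscReferenceThreshold()]).
#' @return A [LagScanResult-class].
#' @seealso [circularShiftEnvelope()], [compareConditions()]
#' @export
runLagScan <- function(pairs, bins = lagBins(), trialsPerBin,
                       config = estimatorConfig(), seed,
                       threshold = NULL) {
  if (missing(seed)) stop("'seed' is required: reproducibility is mandatory")
  if (!length(pairs)) stop("need at least one envelope pair")
  .assertScalarNumber(trialsPerBin, "trialsPerBin")
  if (trialsPerBin < 1) stop("'trialsPerBin' must be >= 1")
  trialsPerBin <- as.integer(trialsPerBin)
  pairs <- lapply(pairs, function(p) {
    stopifnot(length(p) >= 2L, is(p[[1]], "BandPowerEnvelope"),
              is(p[[2]], "BandPowerEnvelope"))
    p[1:2]
  })
  L <- length(pairs[[1]][[1]]@values)
  res <- pairs[[1]][[1]]@resolutionS
  for (p in pairs)
    if (length(p[[1]]@values) != L || length(p[[2]]@values) != L)
      stop("all envelopes must have equal length")
  if (max(bins$upperS) / res > L)
    stop("largest lag bin upper bound (", max(bins$upperS),
         " s) reaches the envelope length (", L * res,
         " s): the shift would wrap more than once")
  pc <- .wosaPrecomp(L, config, res)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  nb <- nrow(bins)
  samplesList <- vector("list", nb)
  ex <- lapply(pairs, function(p) p[[1]]@values)
  ey <- lapply(pairs, function(p) p[[2]]@values)
  for (j in seq_len(nb)) {
    lo <- as.integer(bins$lowerS[j])
    hi <- as.integer(bins$upperS[j])
    idx <- if (trialsPerBin > length(pairs))
      sample.int(length(pairs), trialsPerBin, replace = TRUE)
    else sample.int(length(pairs), trialsPerBin)
    lags <- if (hi - lo <= 1L) rep(lo, trialsPerBin) else
      lo + sample.int(hi - lo, trialsPerBin, replace = TRUE) - 1L
    vals <- numeric(trialsPerBin)
    for (tr in seq_len(trialsPerBin)) {
      y <- ey[[idx[tr]]]
      k <- lags[tr] %% L
      if (k > 0) y <- c(y[(L - k + 1):L], y[1:(L - k)])
      vals[tr] <- .wosaInfraslowPair(ex[[idx[tr]]], y, pc)
    }
    samplesList[[j]] <- vals
  }
  mc <- vapply(samplesList, mean, 0)
  thr <- if (is.null(threshold)) NA_real_ else threshold
  crossing <- NA_real_
  if (is.finite(thr)) {
    below <- which(mc < thr)
    if (length(below)) crossing <- bins$lowerS[min(below)]
  }
  new("LagScanResult", bins = bins, samples = samplesList, meanCurve = mc,
      threshold = thr, thresholdCrossingS = crossing, config = config)
}

#' Compare two MSC sample collections (Wilcoxon rank-sum, Bonferroni)
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of `samplesA` vs
#' `samplesB`, with Bonferroni adjustment
#' `pAdjusted = min(1, p * nComparisons)` and the direction of the effect as
#' the sign of `median(samplesB) - median(samplesA)`. The exact null
#' distribution is used for small tie-free samples; the normal
#' approximation (without continuity correction, so identical collections
#' report p = 1) otherwise.
#'
#' @param samplesA,samplesB numeric vectors of MSC values (each >= 2
#'   values).
#' @param nComparisons size of the comparison family (>= 1, default 1).
#' @return A one-row data.frame with columns `statistic`, `pValue`,
#'   `pAdjusted` and `direction`.
#' @examples
#' compareConditions(c(1, 2), c(3, 4))  # exact two-sided p = 1/3
#' @seealso [runStudy()]
#' @export
compareConditions <- function(samplesA, samplesB, nComparisons = 1) {
  if (length(samplesA) < 2 || length(samplesB) < 2)
    stop("each sample collection needs at least 2 values")
  .assertScalarNumber(nComparisons, "nComparisons")
  if (nComparisons < 1) stop("'nComparisons' must be >= 1")
  wt <- suppressWarnings(
    stats::wilcox.test(samplesA, samplesB, alternative = "two.sided",
                       correct = FALSE))
  md <- stats::median(samplesB) - stats::median(samplesA)
  data.frame(statistic = unname(wt$statistic),
             pValue = wt$p.value,
             pAdjusted = min(1, wt$p.value * nComparisons),
             direction = sign(md))
}
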