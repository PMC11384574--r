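# Minimal EDF (European Data Format) writer and reader: 16-bit samples with
# physical/digital scaling, fixed-duration data records, ASCII header.
# Annotations (EDF+) are ignored. No R EDF package is available to the
# package's dependency set, so the format is implemented directly from its
# published layout.

.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: ", x)
  formatC(x, width = -width)  # left-justified, space-padded
}

# Format a number into an 8-char ASCII field, shrinking precision to fit.
.edfNum8 <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, format = "g", digits = d)
    if (nchar(s) <= 8) return(s)
  }
  stop("cannot format ", x, " into 8 characters")
}

#' Write channels to an EDF file
#'
#' Writes a list of equal-rate, equal-duration channels as 16-bit EDF with
#' per-channel physical scaling spanning each channel's observed range.
#' Quantization error is therefore at most `range / 2^16` per sample. The
#' start date/time fields are fixed placeholders so output is a pure
#' function of the input.
#'
#' @param signals list of [ChannelSignal-class] objects (same sampling rate
#'   and duration).
#' @param path output file path.
#' @param recordDurationS data-record duration in seconds (default 1; the
#'   total duration must be a whole number of records and
#'   `samplingRate * recordDurationS` must be an integer).
#' @return `path`, invisibly.
#' @examples
#' sig <- generatePinkNoise(256 * 4, samplingRate = 256, seed = 1)
#' f <- tempfile(fileext = ".edf")
#' writeEDF(list(sig), f)
#' @seealso [readRecording()]
#' @export
writeEDF <- function(signals, path, recordDurationS = 1) {
  if (!length(signals) || !all(vapply(signals, is, TRUE, "ChannelSignal")))
    stop("'signals' must be a non-empty list of ChannelSignal")
  fs <- unique(vapply(signals, samplingRate, 0))
  ns <- length(signals)
  lens <- vapply(signals, function(s) length(s@samples), 0L)
  if (length(fs) != 1L || length(unique(lens)) != 1L)
    stop("all channels must share one sampling rate and duration")
  spr <- fs * recordDurationS
  if (abs(spr - round(spr)) > 1e-9)
    stop("samplingRate * recordDurationS must be an integer")
  spr <- as.integer(round(spr))
  nrec <- lens[1] / spr
  if (abs(nrec - round(nrec)) > 1e-9)
    stop("duration must be a whole number of data records")
  nrec <- as.integer(round(nrec))

  dmin <- -32768L; dmax <- 32767L
  pminS <- pmaxS <- character(ns)
  digital <- matrix(0L, nrow = spr * ns, ncol = nrec)
  pminV <- pmaxV <- numeric(ns)
  for (k in seq_len(ns)) {
    x <- signals[[k]]@samples
    lo <- min(x); hi <- max(x)
    if (hi <= lo) hi <- lo + 1
    # use the header-rounded bounds for scaling so the round trip is exact
    pminS[k] <- .edfNum8(lo); pmaxS[k] <- .edfNum8(hi)
    lo <- as.numeric(pminS[k]); hi <- as.numeric(pmaxS[k])
    lo <- min(lo, min(x)); hi <- max(hi, max(x))
    if (hi <= lo) hi <- lo + 1
    pminS[k] <- .edfNum8(lo); pmaxS[k] <- .edfNum8(hi)
    lo <- as.numeric(pminS[k]); hi <- as.numeric(pmaxS[k])
    pminV[k] <- lo; pmaxV[k] <- hi
    d <- as.integer(round((x - lo) / (hi - lo) * (dmax - dmin) + dmin))
    d <- pmin(pmax(d, dmin), dmax)
    digital[(k - 1L) * spr + seq_len(spr), ] <- d
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(.edfPad(s, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr("Startdate 01-JAN-2000 X X X", 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(as.character(256L * (1L + ns)), 8)
  wr("", 44)
  wr(as.character(nrec), 8)
  wr(.edfNum8(recordDurationS), 8)
  wr(as.character(ns), 4)
  for (k in seq_len(ns)) wr(signals[[k]]@label, 16)
  for (k in seq_len(ns)) wr("", 80)                 # transducer
  for (k in seq_len(ns)) wr("uV", 8)                # physical dimension
  for (k in seq_len(ns)) wr(pminS[k], 8)
  for (k in seq_len(ns)) wr(pmaxS[k], 8)
  for (k in seq_len(ns)) wr(as.character(dmin), 8)
  for (k in seq_len(ns)) wr(as.character(dmax), 8)
  for (k in seq_len(ns)) wr("", 80)                 # prefiltering
  for (k in seq_len(ns)) wr(as.character(spr), 8)
  for (k in seq_len(ns)) wr("", 32)
  writeBin(as.vector(digital), con, size = 2L, endian = "little")
  invisible(path)
}

# Parse the EDF header of an open binary connection.
.edfHeader <- function(con) {
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  version <- trimws(rd(8))
  patient <- trimws(rd(80))
  recording <- trimws(rd(80))
  startDate <- trimws(rd(8))
  startTime <- trimws(rd(8))
  headerBytes <- as.integer(trimws(rd(8)))
  reserved <- trimws(rd(44))
  nrec <- as.integer(trimws(rd(8)))
  recDur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  fields <- function(width) vapply(seq_len(ns),
                                   function(i) trimws(rd(width)), "")
  labels <- fields(16)
  fields(80)  # transducer
  dims <- fields(8)
  pmin <- as.numeric(fields(8))
  pmax <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8))
  dmax <- as.numeric(fields(8))
  fields(80)  # prefiltering
  spr <- as.integer(fields(8))
  fields(32)
  list(version = version, nrec = nrec, recDur = recDur, ns = ns,
       labels = labels, dims = dims, pmin = pmin, pmax = pmax,
       dmin = dmin, dmax = dmax, spr = spr, headerBytes = headerBytes)
}

#' Read channels from an EDF recording
#'
#' Reads referential-montage channels as stored (no re-referencing, no
#' resampling); EDF+ annotation channels and record timestamps are ignored.
#' Requests that exceed the recording — an unknown channel label, or
#' `startS + durationS` beyond the recorded duration — are errors, never
#' silent truncation.
#'
#' @param path path to an EDF/EDF+ file.
#' @param channels channel selection: labels or integer indices, returned
#'   in the requested order; NULL (default) for all channels.
#' @param startS start offset in seconds (default 0; must be a whole
#'   number of data records).
#' @param durationS duration to read in seconds (default: to the end; must
#'   be a whole number of data records).
#' @return A list of [ChannelSignal-class] objects.
#' @examples
#' sig <- generatePinkNoise(256 * 4, samplingRate = 256, seed = 1)
#' f <- tempfile(fileext = ".edf")
#' writeEDF(list(sig), f)
#' back <- readRecording(f)
#' @seealso [writeEDF()]
#' @export
readRecording <- function(path, channels = NULL, startS = 0,
                          durationS = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- .edfHeader(con)
  totalS <- h$nrec * h$recDur
  if (is.null(durationS)) durationS <- totalS - startS
  if (startS < 0 || durationS <= 0)
    stop("need startS >= 0 and durationS > 0")
  if (startS + durationS > totalS + 1e-9)
    stop("requested ", startS + durationS, " s but \"", basename(path),
         "\" holds only ", totalS, " s")
  r0 <- startS / h$recDur
  nr <- durationS / h$recDur
  if (abs(r0 - round(r0)) > 1e-9 || abs(nr - round(nr)) > 1e-9)
    stop("startS and durationS must be whole numbers of data records (",
         h$recDur, " s)")
  r0 <- as.integer(round(r0)); nr <- as.integer(round(nr))

  idx <- if (is.null(channels)) seq_len(h$ns)
  else if (is.numeric(channels)) {
    if (any(channels < 1 | channels > h$ns))
      stop("channel index out of range 1..", h$ns)
    as.integer(channels)
  } else {
    pos <- match(channels, h$labels)
    if (anyNA(pos))
      stop("channel(s) not found: ",
           paste(channels[is.na(pos)], collapse = ", "))
    pos
  }

  recLen <- sum(h$spr)
  seek(con, h$headerBytes + r0 * recLen * 2L)
  raw <- readBin(con, "integer", n = nr * recLen, size = 2L, signed = TRUE,
                 endian = "little")
  if (length(raw) < nr * recLen)
    stop("file \"", basename(path), "\" is shorter than its header claims")
  recs <- matrix(raw, nrow = recLen, ncol = nr)
  offs <- c(0L, cumsum(h$spr))
  lapply(idx, function(k) {
    d <- as.vector(recs[offs[k] + seq_len(h$spr[k]), , drop = FALSE])
    x <- (d - h$dmin[k]) * (h$pmax[k] - h$pmin[k]) /
      (h$dmax[k] - h$dmin[k]) + h$pmin[k]
    new("ChannelSignal", samples = x,
        samplingRate = h$spr[k] / h$recDur, label = h$labels[k])
  })
}
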