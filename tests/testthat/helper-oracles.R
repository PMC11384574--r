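# Brute-force oracles and small fixture builders, independent of the
# package's FFT-based implementation paths.

# Direct O(n^2) discrete Fourier transform.
directDFT <- function(v) {
  n <- length(v)
  k <- 0:(n - 1)
  vapply(k, function(kk)
    sum(v * exp(-2i * pi * kk * k / n)), complex(1))
}

# One-sided folded periodogram of a segment, by direct DFT: bin sums over
# [0, Nyquist] equal the segment mean square.
directPeriodogram <- function(v) {
  n <- length(v)
  Z <- directDFT(v)
  half <- floor(n / 2)
  P <- Mod(Z[seq_len(half + 1)])^2 / n^2
  up <- if (n %% 2 == 0) half else half + 1L
  if (half >= 2) P[2:up] <- 2 * P[2:up]
  P
}

# Brute-force WOSA MSC on numeric envelope series: explicit segment loop,
# direct DFT, no packing tricks.
directWosaMSC <- function(x, y, windowS, overlap = 0.5, taper = "hann",
                          meanDeletion = TRUE) {
  w <- as.integer(windowS)
  step <- max(1L, as.integer(round(w * (1 - overlap))))
  n <- (length(x) - w) %/% step + 1L
  k <- 0:(w - 1)
  tap <- switch(taper,
                hann = 0.5 - 0.5 * cos(2 * pi * k / w),
                hamming = 0.54 - 0.46 * cos(2 * pi * k / w),
                boxcar = rep(1, w))
  Sxx <- Syy <- numeric(w)
  Sxy <- complex(real = numeric(w), imaginary = numeric(w))
  for (i in seq_len(n)) {
    sx <- x[(i - 1) * step + seq_len(w)]
    sy <- y[(i - 1) * step + seq_len(w)]
    if (meanDeletion) {
      sx <- sx - mean(sx)
      sy <- sy - mean(sy)
    }
    X <- directDFT(sx * tap)
    Y <- directDFT(sy * tap)
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + X * Conj(Y)
  }
  half <- w %/% 2L
  rows <- seq_len(half + 1L)
  denom <- Sxx[rows] * Syy[rows]
  msc <- rep(NaN, length(rows))
  ok <- denom > 0
  if (meanDeletion) ok[1] <- FALSE  # DC is analytically 0/0
  msc[ok] <- Mod(Sxy[rows][ok])^2 / denom[ok]
  list(frequencies = (rows - 1) / w, msc = msc, n = n)
}

# Wrap a numeric vector as a delta-band envelope object.
asEnvelope <- function(values, band = canonicalBands()[["delta"]],
                       label = "fixture") {
  new("BandPowerEnvelope", values = values, resolutionS = 1,
      band = band, sourceLabel = label)
}

# A pure sinusoidal test channel.
sineChannel <- function(freqHz, durationS, fs = 256, amplitude = 1,
                        label = "sine") {
  t <- (seq_len(durationS * fs) - 1) / fs
  new("ChannelSignal", samples = amplitude * sin(2 * pi * freqHz * t),
      samplingRate = fs, label = label)
}
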