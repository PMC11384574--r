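# Internal helpers: tapers, seed streams, folded frequency grids.

# Periodic taper windows of length n (0-based k/n convention).
.taperWindow <- function(name, n) {
  k <- seq_len(n) - 1
  switch(name,
    hann    = 0.5 - 0.5 * cos(2 * pi * k / n),
    hamming = 0.54 - 0.46 * cos(2 * pi * k / n),
    boxcar  = rep(1, n),
    stop("unknown taper: ", name))
}

# Derive n child seeds deterministically from one master seed. Child seeds
# stay below 2^31 so they are valid R integer seeds.
.spawnSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

# A deterministic per-stream seed so modules (pairs, lags, surrogates) can be
# re-run independently from one master seed.
.streamSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 69069 + h * 2654435761) %% 2147483647)
}

# Folded (two-sided -> one-sided) frequency of FFT bin k = 0..n-1 for
# sampling rate fs: min(k, n-k) * fs / n.
.foldedFrequencies <- function(n, fs) {
  k <- seq_len(n) - 1
  pmin(k, n - k) * fs / n
}

.assertScalarNumber <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  invisible(x)
}
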