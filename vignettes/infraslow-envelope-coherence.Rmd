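---
title: "Infraslow envelope coherence: model, calibration and design choices"
author: "iscoh authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Infraslow envelope coherence: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iscoh)
```

## The scientific problem

Neural recordings carry structure on two very different time scales. The
raw voltage of intracranial EEG (icEEG) oscillates in the classical bands
(delta through gamma, 0.5–55 Hz), while the *amplitude* of those
oscillations is itself slowly modulated, on scales of tens of seconds to
minutes — the infraslow range, below about 0.15 Hz, with periods up to
roughly two minutes. Correlated infraslow amplitude modulation between
recording sites ("envelope coupling") is a widely used marker of
functional connectivity, but any estimate of it rides on a spectral
estimator whose bias and variance must be characterized before an observed
coupling value can be called significantly nonzero. This package
implements that whole chain — envelope extraction, coherence estimation,
empirical null calibration, lag scanning and condition comparison — with
every stage reproducible from a single seed, and with synthetic signal
generators that serve as ground-truth fixtures for the pipeline.

## From raw signal to envelope

A channel is reduced to five *band-power time series*: each
non-overlapping 1-s segment gets a plain (untapered, non-detrended)
periodogram, normalized so its sum from DC to Nyquist equals the segment's
mean square, and the periodogram is summed over each canonical band —
delta $[0.5, 4)$, theta $[4, 8)$, alpha $[8, 13)$, beta $[13, 25)$ and
gamma $[25, 55)$ Hz. Band intervals are half-open so a bin on a shared
edge (4, 8, 13, 25 Hz) is counted once, in the upper band. An hour of
256 Hz data becomes 3,600 envelope samples per band.

Two consequences of the untapered per-second periodogram are worth
knowing. First, whole-second circular shifts commute exactly with
envelope extraction (shifting the raw signal by $k$ seconds permutes its
1-s segments), which is what licenses the lag module to shift envelopes
rather than recompute spectra. Second, the rectangular window leaks power
across neighbouring bins, so a very strong modulated band bleeds a little
of its modulation into the *adjacent* band's envelope; in the synthetic
coupling fixtures this shows up as attenuated delta-carrier coupling in
theta, while non-adjacent bands stay at the null level. No within-second
taper is applied because the envelope's own leakage is immaterial after
the coherence stage, which normalizes per frequency.

## The WOSA coherence estimator

Given two envelopes $x, y$ of length $L$, the Welch
overlapped-segment-averaging (WOSA) estimator splits both into $n$
segments of $w$ samples with step $s = \mathrm{round}(w(1-\rho))$ at
overlap fraction $\rho$, deletes each segment's own mean, applies a taper
$h$, and forms

$$\widehat{\mathrm{MSC}}(f) \;=\;
\frac{\bigl|\sum_{i=1}^{n} S_{xy}^{(i)}(f)\bigr|^{2}}
     {\sum_{i=1}^{n} S_{xx}^{(i)}(f)\; \sum_{i=1}^{n} S_{yy}^{(i)}(f)}
\;\in\; [0, 1],$$

with $S^{(i)}$ the tapered segment cross-/auto-spectra. The scalar
*infraslow MSC* is the unweighted mean of the spectrum over bins
$0 < f < 0.15$ Hz — strictly below the cutoff, and excluding DC, which is
$0/0$ under mean deletion. With the default 180-s windows the qualifying
bins are $k/180$ for $k = 1, \dots, 26$.

Defaults (180-s windows, 50% overlap, Hann taper, mean deletion,
0.15 Hz cutoff) are the calibrated operating point. The Hann taper is a
deliberate choice: at 50% overlap it renders overlapping segments nearly
independent, which is the regime in which the estimator's null mean
tracks the classical $1/n$ bias of averaged coherence — the behaviour the
calibration numbers below display. Segments are never zero-padded, so
the frequency grid is exactly $k/w$; fewer than two segments is an error
(a single-segment MSC is identically 1); tiny negative or
just-above-one values from roundoff are clipped at the $10^{-12}$ level.

## Synthetic signals: what they emulate and what they do not

`generatePinkNoise()` synthesizes $1/f$ noise in the frequency domain
(amplitudes $\propto 1/\sqrt f$, DC zeroed, i.i.d. phases), then rescales
to mean power $10^{\mathrm{dB}/10}$ exactly — "0 dB" means unit variance,
and the zeroed DC makes the sample mean exactly zero. The $1/f$ spectrum
is the accepted stand-in for icEEG background activity, and pairs of such
channels are *known* to be uncorrelated, which is what a null calibration
needs. Internally two independent channels are read off one complex
inverse FFT (its real and imaginary parts), halving the cost of surrogate
pairs; the equivalence of this packed path with the public estimator
route is itself under test.

`generateCoupledPair()` builds ground-truth coupling: two pink carriers
whose in-band component (an exact zero-phase frequency-domain split) is
scaled by $1 + c\,m(t)$ with a shared zero-mean infraslow modulator
$m(t)$, the second channel's copy delayed circularly by a configurable
lag. Two modulators are offered, and the choice matters more than it
first appears:

* a **sinusoid** at $f_m$ with random phase — the cleanest single-line
  second spectrum, used for zero-lag parameter recovery; but a
  deterministic sinusoid makes the WOSA coherence *invariant under
  circular lag*, because a lag only rotates the cross-spectrum phase by
  the same angle in every segment and the magnitude survives untouched;
* **band-limited Gaussian noise** (flat over $[0.5, 1.5] f_m$ by
  default; any band below the cutoff is selectable via `modulatorBand`,
  e.g. a wide flat 0.005–0.05 Hz band), whose finite coherence time
  makes estimated coherence decay with imposed lag the way genuinely
  stochastic infraslow oscillations do. Lag-decay experiments must use
  this modulator. The decay is governed jointly by the modulator's
  decorrelation and by the taper overlap factor (segments of the
  shifted channel share progressively less aligned content until, at
  lags beyond one window, they share none), so a window no longer than
  the decay horizon under study is the natural choice; the curve
  reaches the null plateau once the lag exceeds the window length plus
  the modulator's coherence time (about $1/\mathrm{bandwidth}$), which
  is why narrowband modulators keep residual coupling visible slightly
  beyond one nominal period.

The generators make no attempt to emulate epileptiform transients,
artifacts, inter-channel spatial covariance, or non-stationarity. Passing
the pipeline's tests on these fixtures therefore demonstrates estimator
correctness and calibration accuracy — not robustness to the pathologies
of clinical recordings, which remain the caller's responsibility.

## Null calibration

`calibrateEstimator()` (and the paired sweeps built on
`calibrationGrid()`) draw fresh pink-noise pairs per trial, push them
through the full envelope-plus-coherence pipeline, and summarize the
per-trial infraslow MSC: mean, SD, maximum, and the significance
threshold mean $+ 3$ SD (nominal $p < 0.005$). At the canonical
operating point — hour-long 0 dB pairs, delta band, 3-min windows, 50%
overlap — the null is approximately $0.027 \pm 0.007$ in every band, the
observed maximum over thousands of trials stays near 0.07, and the means
track $1/n_{\mathrm{windows}}$: about 0.055 with 6-min windows (19
windows), 0.116 with 12-min (9), 0.341 with 30-min (3), and 0.025 at 75%
overlap. The shipped compatibility constant
`mscReferenceThreshold()` $= 0.054$ is the published threshold from the
earlier calibration of the same estimator; note the canonical statistics
give $0.027 + 3 \times 0.007 = 0.048$, and the package surfaces both
rather than silently reconciling them. Freshly calibrated thresholds are
preferred wherever the configuration differs from canonical.

One subtlety in the window-size sweep is deliberate. Changing the window
changes the spectral grid $k/w$, so a fixed cutoff in Hz changes *how
many* bins enter the infraslow average — and the number of averaged bins
directly controls the variance of the scalar summary, confounding the
effect of segment count. `windowSizeSweep()` therefore defaults to
`matchBinCount = TRUE`: every window size averages the same number of
lowest non-DC bins (26, the canonical count), so the sweep isolates the
bias–variance effect of the segment count. This matched-count procedure
is what reproduces the reported sweep SDs (≈ 0.011, 0.022, 0.050 for 6-,
12-, 30-min windows); the literal fixed-Hz reading leaves the means
essentially unchanged but shrinks the SDs (≈ 0.009, 0.012, 0.016) because
longer windows then average ever more bins. Both procedures are
available; the default is the matched-count one.

Sweeps share one surrogate ensemble across configurations (the trial loop
is outermost), making comparisons paired; every trial derives its own
child seed from the master seed, so any single trial can be reproduced in
isolation.

## Lag scanning and condition comparison

`circularShiftEnvelope()` imposes `output[t] = input[(t − lag) mod L]`.
`runLagScan()` bins imposed lags (15-s bins tiling $[0, 300)$ s by
default), draws a pair and an integer lag uniformly within each bin per
trial, and collects infraslow MSC samples per bin; the per-bin mean curve
and the first bin whose mean falls below the significance threshold
summarize the decay. Lags are whole seconds — the envelope resolution
forces that granularity — and a bin may not reach the envelope length
(the shift would wrap past the start). For genuinely coupled pairs the
mean curve decays towards the null; for independent pairs it is flat at
the null level at every lag, which is the package's built-in negative
control.

`compareConditions()` performs the two-sided Wilcoxon rank-sum test with
Bonferroni adjustment (`min(1, p × nComparisons)`) and reports the
direction as the sign of the median difference. The exact null
distribution is used for small tie-free samples; otherwise the normal
approximation without continuity correction, so comparing a collection
with itself reports $p = 1$ exactly.

`runStudy()` chains everything per condition, subject and band — signals
(synthetic or EDF), envelopes, lag scan — pools MSC samples across
subjects by flat concatenation (no hierarchical model, matching how such
aggregates are usually reported), and compares each condition to the
first (reference) condition per band, Bonferroni-corrected over the
number of bands; lag bins are descriptive and not multiplicity-corrected.
The result is a pure function of configuration and input: all randomness
descends from one master seed through named sub-streams (surrogates,
pair sampling, lags, calibration), and the provenance slot carries what a
bit-identical re-run needs.

## Numerical and degenerate-input choices

* Step size is `round(w (1 − overlap))`, trailing samples that do not
  fill a window are dropped, and `floor((L − w)/step) + 1` windows
  result.
* The cutoff comparison is strict (`f < 0.15`); at 180-s windows the bin
  at exactly 0.15 Hz ($k = 27$) is excluded.
* The DC bin under mean deletion is reported as `NaN` rather than a
  roundoff quotient; bins with vanishing averaged auto-spectra likewise.
* MSC values are clipped to $[0, 1]$ only at the $10^{-12}$ roundoff
  level; the Cauchy–Schwarz bound holds analytically.
* A coupling strength of zero bypasses the modulation arithmetic
  entirely, so the degenerate case is bit-identical to independent pink
  noise.
* EDF output uses fixed placeholder start dates, making files a pure
  function of the signals; 16-bit quantization bounds round-trip error by
  the channel range divided by $2^{16}$.

## Problem sizes used by the shipped tests and acceptance script

Monte-Carlo sizes in the test suite and `scripts/acceptance.R` are chosen
to keep estimates' standard errors an order of magnitude inside the
tolerances they are checked against: the acceptance script calibrates
2,000 surrogate pairs (the null mean's standard error is then about
$1.3 \times 10^{-4}$, two orders below the reported 0.027), the
acceptance tests use a shared 400-trial ensemble for the calibration
criteria plus dedicated ensembles for lag-decay and condition-recovery
properties, and unit tests use hundreds of trials or exact small-case
oracles. The extreme-value summary (the observed null maximum) is the
one quantity that grows with ensemble size; it is reported together with
the number of draws it was taken over.

## Known limitations

* The per-second periodogram's spectral leakage couples adjacent bands'
  envelopes when one band dominates; a tapered variant is deliberately
  out of scope.
* Hilbert- or wavelet-based envelopes, multitaper or wavelet coherence,
  partial/imaginary coherence, and cross-correlation-based lag
  *estimation* between specific pairs are out of scope.
* The EDF reader handles plain EDF/EDF+ referential layouts only;
  annotations are ignored; no artifact rejection, re-referencing or
  resampling is performed.
* Clinical epoch selection (wakefulness, distance from seizures,
  medication state) is metadata the caller supplies; the package records
  explicit start/duration in provenance and does nothing more.
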