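# iscoh — infraslow band-power envelope coherence

`iscoh` estimates and statistically calibrates **magnitude-squared
coherence (MSC) between infraslow amplitude envelopes** of band-limited
electrophysiological signals — the kind of analysis used to quantify
slow (< 0.15 Hz) co-modulation of EEG band power between intracranial
recording sites. It is aimed at electrophysiologists and methods
researchers who need the estimator's bias and variance characterized
before trusting a connectivity value.

The pipeline:

1. **Envelopes** — each channel is reduced to per-second band-power time
   series in the canonical bands (delta [0.5–4), theta [4–8), alpha
   [8–13), beta [13–25), gamma [25–55) Hz): a plain periodogram per 1-s
   segment, summed over each band.
2. **Coherence** — the Welch overlapped-segment-averaging (WOSA)
   estimator on an envelope pair, with per-segment mean deletion and a
   Hann taper:

   MSC(f) = |Σᵢ S⁽ⁱ⁾ₓᵧ(f)|² / (Σᵢ S⁽ⁱ⁾ₓₓ(f) · Σᵢ S⁽ⁱ⁾ᵧᵧ(f)) ∈ [0, 1],

   collapsed to a scalar **infraslow MSC**: the mean over frequency bins
   0 < f < 0.15 Hz (26 bins at the default 3-min windows, 50% overlap).
3. **Calibration** — the null distribution of that scalar on seeded
   pairs of 1/f (pink-noise) surrogates known to be uncorrelated, with
   paired window-size and overlap sweeps, and the significance threshold
   mean + 3 SD.
4. **Lag scanning** — circular time shifts of one envelope in 15-s bins
   through 300 s, characterizing how coupling decays with imposed lag.
5. **Study orchestration** — multi-subject, multi-condition runs
   (synthetic generators or EDF recordings), pooled across subjects,
   with Bonferroni-adjusted Wilcoxon rank-sum condition comparisons.

Everything is reproducible from one master seed, and all inputs used by
the tests and the acceptance script are generated by the package itself.

## Worked example

Calibrate the estimator on a small pink-noise ensemble, then recover a
planted coupling:

```r
library(iscoh)

# null calibration: 100 pairs of 1-h, 256 Hz, 0 dB pink noise
cal <- calibrateEstimator(100, estimatorConfig(), seed = 11)
cal
#> CalibrationResult (delta band, 100 trials): null 0.0272 +/- 0.0060,
#>   max 0.0405, threshold 0.0453

# a coupled pair: shared 0.02 Hz modulator, coupling 0.8, delta carrier
pair <- generateCoupledPair(3600, modulatorFreq = 0.02,
                            couplingStrength = 0.8,
                            modulatorType = "sine", seed = 901)
e1 <- bandPowerSeries(pair[[1]], canonicalBands()[["delta"]])
e2 <- bandPowerSeries(pair[[2]], canonicalBands()[["delta"]])
msc <- infraslowMSC(wosaMSC(e1, e2), estimatorConfig())
round(msc, 3)
#> [1] 0.156
msc > significanceThreshold(cal)
#> [1] TRUE
```

The calibration says an uncorrelated pair of hour-long pink-noise
channels yields an infraslow delta-envelope MSC of about 0.027 ± 0.006
under the default estimator, so 0.156 for the coupled pair is far above
both the freshly calibrated threshold (0.045 here) and the published
compatibility constant `mscReferenceThreshold()` (0.054): the planted
coupling is recovered. An uncoupled pair (`couplingStrength = 0`) lands
inside the null distribution.

`windowSizeSweep()` and `overlapSweep()` reproduce the estimator's
bias–variance trade-off (null mean ≈ 0.027, 0.055, 0.116, 0.341 for 3-,
6-, 12-, 30-min windows at 50% overlap on hour-long series);
`runLagScan()` shows the decay of genuine coupling with imposed circular
lag; `runStudy()` ties the whole pipeline together across subjects and
conditions. The methods vignette
(`vignettes/infraslow-envelope-coherence.Rmd`) documents the model, the
design decisions and the generators' limitations.

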