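---
title: "Methods: conditioning wearable health streams and extracting clinical features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conditioning wearable health streams and extracting clinical features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearsig)
```

## The problem

Wrist wearables export one timestamped value stream per physiological
signal. The streams are irregular (the device samples opportunistically),
interrupted (sensor failures and non-wear periods are indistinguishable in
the data), and contaminated by artifacts such as pressure spikes during
sleep. `wearsig` conditions each stream onto a uniform grid and computes a
fixed catalogue of clinically motivated features per signal per day. One
`ts_signal` holds one signal for one calendar day, with timestamps in
seconds since local midnight; multi-day exports must be split upstream,
because every feature is defined over the full daily record and several
(times of extremes, segment statistics) use the day clock directly.

## Signal contract

| kind | grid step | aggregation | max fillable gap | plausible range |
|---|---|---|---|---|
| heart_rate | 15 s | instantaneous | 60 s | 20–250 bpm |
| bbi | 15 s | instantaneous | 60 s | 240–3000 ms |
| spo2 | 60 s | instantaneous | 120 s | 50–100 % |
| respiration_rate | 60 s | instantaneous | 300 s | 4–60 /min |
| steps, calories | 900 s | cumulative | none | ≥ 0 |
| intensity_minutes | daily | summary | — | 0–1440 |

The gap limits encode how fast each quantity can physiologically change
during sleep: respiration is stable over minutes (300 s), heart rate is not
(60 s), and SpO2 is kept tighter than respiration (120 s) because nocturnal
desaturations are the clinically critical events. The plausibility ranges
are not part of the acquisition protocol; they are conservative ingestion
guards, applied with a logged count and configurable. Cumulative counters
are converted to per-interval increments at ingestion (differences of the
running total, clipped at zero on counter resets) because summing onto a
grid is only meaningful for increments; the daily total is preserved and
re-exposed as a feature. SpO2 and respiration are collected only during
sleep, so their grid covers the observed span rounded outward rather than
the whole day — filling sixteen absent daytime hours would be meaningless.

## Preprocessing

**Retiming.** Each raw sample is assigned to the nearest grid point; cells
average their samples (instantaneous) or sum them (cumulative); empty cells
stay absent. A sample exactly halfway between two grid points goes to the
earlier one — an arbitrary but deterministic tie-break. This translation
preserves the data: the multiset of raw points partitions over grid cells,
and cumulative mass is conserved exactly.

**Gap filling.** Maximal absent runs whose duration is at or below the
kind's limit, and which have present neighbours on both sides, are replaced
by the straight line between those neighbours. Runs touching the day (or
sleep-window) boundary are never filled: one-sided extrapolation would
fabricate data. Filled values are therefore always bracketed by their
neighbours, and originally present samples are bit-identical after filling.

**Denoising.** A centred moving average of odd width (default 3) smooths
each present run. Absent values are hard boundaries: the window shrinks at
edges and next to unfilled gaps instead of padding or averaging across
missing time, so output length equals input length and no value is invented.
Width 1 disables smoothing. Cumulative counters skip both filling and
smoothing — interpolating or averaging counts would fabricate fractional
steps. The stage order is fixed (retime → fill → denoise), so the moving
average also smooths interpolated points; that is intentional, as the
interpolant is itself an estimate.

## Heart-rate features

RR intervals are derived by inversion, `RR = 60000/HR` ms, one interval per
present grid sample. Runs separated by unfilled gaps become segments;
successive differences Δᵢ = RRᵢ₊₁ − RRᵢ are never taken across a segment
break.

*Conventions worth stating.* Reported dispersion summaries (SDNN, SDSD,
SDANN, SDNNI) use the sample SD (n−1). Inside the Poincaré geometry the
population convention is used with no mean subtraction on Δ:
SD1² = mean(Δ²)/2, so SD1 = RMSSD/√2 holds exactly, and
SD2² = 2σ²(RR) − SD1² (population variance, floored at zero), so
SD1² + SD2² = 2σ² holds exactly. CSI and CVI use the ellipse axes L = 4·SD2
and T = 4·SD1: CSI = L/T, CVI = log₁₀(L·T), modified CSI = L²/T.

*Baseline.* "Baseline heart rate" has no standard operational definition;
here it is the median heart rate inside the 30-minute window with the lowest
rolling mean — a resting-level estimate that always lies between the daily
minimum and mean. The window width is configurable.

*Trends.* A single ordinary least-squares quadratic fit of HR on time gives
the linear and quadratic coefficients and its R². For a constant series R²
is defined as 0 (no variance explained) rather than undefined.

*Robust statistics.* MedianNN is the median RR, MadNN the median absolute
deviation scaled by 1.4826, HCVNN their ratio. (Catalogue descriptions that
conflate these with successive differences are internally inconsistent; the
conventional definitions are used.) HTI bins RR intervals at 1/128 s. TiNN
is carried in the output as always-null: no computable definition is
specified for it, and omitting the column silently would break the
fixed-catalogue contract.

*Asymmetry.* Poincaré points are classified by Δ: decelerations above the
identity line, accelerations below. Distance (Guzik), angle (slope index)
and sector-area shares are computed on the off-line points; Porta's index is
the share of points below. The variance decompositions use population
denominators over all m differences — SD1d² = Σ_{Δ>0}Δ²/(2m) and its mirror
sum exactly to SD1²; long-term analogues use along-line distances from the
centroid with points on the line contributing half to each side; total
decompositions are SDNNx² = (SD1x² + SD2x²)/2. All three contribution pairs
(C1d/C1a, C2d/C2a, Cd/Ca) sum to 1 by construction.

*Fragmentation.* The sign sequence of Δ drives PIP, IALS, PSS and PAS.
Zeros inherit the previous non-zero sign and leading zeros are dropped —
the standard convention that keeps runs well-defined on quantized data. PIP
is the percentage of consecutive sign pairs that invert, which makes a
perfectly alternating series score exactly 100 and a monotone one 0.
Alternation segments for PAS must span at least 4 intervals.

*Segment statistics.* SDANN/SDNNI use non-overlapping wall-clock segments
aligned to the series start; trailing segments covering less than half the
nominal length are dropped, and a statistic needing at least two usable
segments is null otherwise.

## SpO2 features

Desaturation events are maximal runs of present samples strictly below the
threshold (90% by default). This is deliberately the simple level-crossing
definition, not the clinical 3%/4%-dip rule: the acquisition context defines
desaturation as "below 90%", and the threshold is configurable. An event
never spans an unfilled hole in the grid. Integrals use left-rectangle
quadrature with the grid step as weight — at 60 s sampling, sub-sample
crossing interpolation would be spurious precision. Recording time is last
minus first present sample plus one grid step; unfilled gap time inside the
night is included in recording time but excluded from event segmentation.
ODI is reported as the floored integer events-per-hour, with the unrounded
rate kept in the record metadata. Two catalogue entries lack operational
definitions and are implemented as documented, configurable choices: Mx is
the percentage of samples at least 1 percentage point below the median, and
POD is events as a percentage of present samples.

## Respiration features

All respiration features act on breath-to-breath intervals BB = 60/rate s
— the catalogue names dictate the interval series, not the rate series.

*Spectral.* The interval tachogram is laid over cumulative breath time,
linearly interpolated to a uniform 4 Hz grid, and analysed with Welch's
method (256-sample Hann-tapered segments, 50% overlap, per-segment mean
removal). Band powers integrate the one-sided density over VLF/LF/HF;
normalized powers divide by their sum. These resampling and Welch
parameters are not dictated by the method's description; they are fixed in
`pipeline_config()` and echoed in the output metadata. Note the physical
limit: at ~4 s per breath the tachogram's intrinsic Nyquist frequency is
~0.125 Hz, so HF content of slow breathers reflects interpolation rolloff
more than physiology — a limitation of breath-interval spectra generally,
not of the estimator.

*Entropies.* ApEn and SampEn use Chebyshev distance with tolerance 0.2 × SD
and embedding dimension 2; ApEn includes self-matches, SampEn excludes
them. A constant series scores 0 for both.

*DFA.* The mean-centred series is integrated; non-overlapping windows of
each scale are linearly detrended; α is the log-log slope of the RMS
fluctuation over the regime's scales (4–16 short, 16–64 long, ten
geometrically spaced scales each). Plain first-order DFA is biased upward at
the smallest scales: for white noise the expected squared fluctuation is
σ²(s² − 4)/(15s) rather than σ²s/15, which inflates the 4–16 slope to about
0.6. The fluctuation function is therefore rescaled by the exact white-noise
factor s/√(s² − 4) (the standard modified-DFA correction), making the
estimator unbiased for uncorrelated series (≈0.50 recovered on white noise,
≈1.4 on its cumulative sum) while leaving long-range scaling asymptotically
untouched. A regime needs at least four times its maximum scale in samples,
else its exponent is null — with a typical 7–8 h night at 60 s sampling
(~450 intervals) α2 is computable but marginal, and shorter nights
correctly return null rather than extrapolating.

*Multifractal DFA.* Fluctuation functions of order q (−5…5, excluding 0)
are q-means of per-window RMS values; h(q) slopes feed the Legendre
transform τ(q) = q·h(q) − 1, with singularity exponents α = dτ/dq by
central finite differences and dimensions f(α) = qα − τ. Per regime the
spectrum's width (ExpRange, DimRange) and centre (ExpMean, DimMean) are
reported. Negative-q moments at scales 4–16 are dominated by near-zero
window residuals, so the short-regime spectrum is broad even for
monofractal input — a known finite-size property of the estimator. The
monofractal narrow-spectrum limit (width well under 0.5 for white noise) is
only meaningful, and only asserted, in the long regime.

## Synthetic data: what it does and does not emulate

The generators define the validation conditions. The heart-rate day is a
circadian sinusoid (baseline 70 bpm, amplitude 10 bpm, evening peak) plus
AR(1) noise (coefficient 0.8, innovation SD 2 bpm) — autocorrelated, as
physiological noise is, unlike white noise. The SpO2 night is 8 h at 60 s
sampling, baseline 96%, noise SD 0.4, with Poisson-placed desaturation
events (default 0.5/h, depth 8%, duration 180 s) kept disjoint so ground
truth is a clean event list. Respiration is generated on the
breath-interval sequence so oscillations can be embedded at a known
frequency for spectral tests. Artifacts are additive spikes and deleted
sample runs with log-uniform durations spanning both sides of each
fill-limit so both gap branches are exercised. Seeds make every stream
byte-reproducible.

What passing these tests shows: the pipeline's algebra is correct, its
estimators recover known structure, and the chain is robust to the modelled
artifact types at the modelled rates. What it does not show: robustness to
the device's proprietary onboard smoothing, to correlated artifact bursts
(e.g. a loose strap producing simultaneous spikes and dropouts), or to
motion-dependent noise spectra — none of which are in the generative model.

## Numerical choices and degenerate inputs

- Problem sizes in tests and the acceptance script (RR series of 300–1000,
  2000–4000-point noise series for exponent recovery, 10-seed end-to-end
  replicates) are chosen to make each property measurable at tight
  tolerance while keeping the default suite fast.
- Empty streams preprocess to an all-absent grid with a warning, and every
  feature on them is null; features whose preconditions (minimum counts)
  fail are null, never 0 — and serialization keeps null distinct from 0.
- Ratio features are null when their denominator is 0 (CSI with SD1 = 0,
  LF/HF with HF = 0, SD2/SD1 on a constant series).
- A constant series has R² defined as 0, zero entropies, and a degenerate
  (null) DFA exponent since its profile is identically zero.
- Ties: extreme times report the first occurrence; retiming ties go to the
  earlier grid point; Δ = 0 inherits the previous sign in fragmentation.

## Known limitations

- No beat detection and no waveform analysis: the device reports rates, so
  beat-to-beat intervals are reconstructed by inversion and inherit the
  grid's temporal resolution.
- Gap filling is linear only; model-based imputation (Kalman smoothing,
  Bayesian use of prior nights) is out of scope.
- No wear/non-wear classification: a gap is a gap.
- The short-regime multifractal width should be read comparatively, not as
  an absolute spectrum width, for the finite-size reasons above.
- Timestamps are day-local with no timezone arithmetic; daylight-saving
  transitions must be resolved upstream.
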