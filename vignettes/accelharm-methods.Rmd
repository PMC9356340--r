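---
title: "Harmonizing activity counts with open-source accelerometry measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing activity counts with open-source accelerometry measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelharm)
```

## The problem

Decades of physical-activity epidemiology are written in the language of
ActiGraph *activity counts* (AC), a proprietary minute-level summary of
wrist acceleration. Newer open-source measures — the monitor-independent
movement summary (MIMS), Euclidean norm minus one (ENMO), mean amplitude
deviation (MAD), and activity intensity (AI) — are computed directly from
raw tri-axial acceleration, but their scales are not interchangeable with
counts. `accelharm` computes all four measures from raw data, applies the
standard minute-level preprocessing used in wrist-accelerometry cohorts,
and fits a smooth harmonization map between counts and each measure so
that count-based thresholds and totals can be translated onto the
open-source scales (and back).

## Minute-level measures

All four measures are computed per calendar minute aligned to :00 seconds
from raw tri-axial acceleration $(x_t, y_t, z_t)$ in g, nominally sampled
at 80 Hz on a ±8 g device. Let $r_t = \sqrt{x_t^2+y_t^2+z_t^2}$.

* **ENMO** $= \frac1n \sum_t \max(r_t - 1, 0)$ (g). Computed on
  *autocalibrated* data: per-axis gains and offsets are estimated by
  iteratively reweighted least squares so that still-window means lie on
  the unit gravity sphere (`autocalibrate()`). Still windows are 10-s
  windows with per-axis SD below 0.013 g; if the still orientations do not
  span the sphere (per-axis spread < 0.4 g) the identity calibration is
  returned with a warning rather than an ill-posed fit.
* **MAD** $= \frac1n \sum_t |r_t - \bar r|$ (g), on uncalibrated data.
* **AI**: the minute is divided into 1-s sub-epochs; each contributes
  $\sqrt{\max\{\tfrac13\sum_m(\sigma^2_m - \bar\sigma^2),\,0\}}$ where
  $\sigma^2_m$ is the per-axis sample variance and $\bar\sigma^2$ the
  systematic noise variance (default 0); the minute value is the sum over
  sub-epochs.
* **MIMS**: linear interpolation to 100 Hz, extrapolation of runs clipped
  at the dynamic range (a local quadratic through neighboring samples,
  capped at 1.5× the range — a deliberate simplification of the reference
  spline scheme, switchable off), a zero-phase 4th-order Butterworth
  band-pass of 0.2–5 Hz per axis, rectification, trapezoidal integration
  per axis over the minute (g·s), per-axis truncation below $10^{-4}$,
  and summation over axes. Because the band-pass transient of a 0.2 Hz
  high-pass is seconds long and R's `filtfilt` does not initialize filter
  state, the signal is padded by 20 s of odd reflection at each end
  before filtering; the transient decays by ~$e^{-25}$ inside the pad, so
  pure gravity yields exactly 0 after truncation. The whole chain before
  truncation is linear-plus-rectification, hence degree-1 homogeneous,
  which the tests verify numerically on in-band sinusoids.

Every constant above is surfaced in `measure_params()`.

## Quality control, wear, and valid days

Three per-minute raw-data flags mark patterns unlikely to come from human
movement: sustained clipping (any axis at the dynamic range for ≥ 2 s),
stuck values (an identical (x, y, z) triplet for ≥ 1 s), and spikes
(sample-to-sample jumps above 11 g). The flags are fully parameterized in
`qc_params()`; they deliberately do not attempt nonwear detection, which
is count-based: a minute is **nonwear** iff it lies in a run of ≥ 90
consecutive zero-count minutes (an optional tolerance can absorb isolated
nonzero "artifactual" minutes inside a run; the literal rule is the
default). A minute is **valid** iff it is wear and passed QC; a **valid
day** (12:00 AM–11:59 PM, 1440 minutes) has at most 144 (10%) invalid
minutes, counting absent slots of partial days as invalid; participants
need ≥ 3 valid days and only their valid days are analyzed.

Each measure is then **winsorized** at its pooled cohort-level 0.999
quantile. The cap is the type-1 (inverse empirical CDF) order statistic
rather than the interpolated default: with an interpolated cap,
re-winsorizing capped data moves the cap slightly downward, so the
operation would not be exactly idempotent; the order-statistic cap makes
winsorization idempotent at the cost of at most one order-statistic gap.

## FPCA imputation

Where gap-free data are needed, invalid minutes are replaced from
smoothed diurnal profiles. For each participant and measure, the
day-by-minute (1440-column) matrix with invalid entries missing is
decomposed by functional principal component analysis: each day curve is
projected on a 30-function cubic B-spline basis with an exact
second-derivative penalty (smoothing chosen by GCV per row); the mean and
eigenfunctions come from the coefficient covariance eigendecomposed in
the grid inner product; scores are estimated from observed entries only
via the ridge/BLUP normal equations with eigenvalue shrinkage. The number
of components is the smallest K ≤ 10 explaining ≥ 95% of variance. Rows
with under 50% observed entries are excluded from fitting but still
scored and reconstructed. Imputed values are the smooth surface floored
at 0; valid minutes are never altered. Eigenfunctions are estimated per
participant (across that participant's days), not cohort-wide, matching
the participant- and day-specific construction of the matrices; the
minute-of-day grid is treated as non-periodic because each matrix row is
a day bounded at midnight.

## Harmonization mapping

For each measure, all valid minutes from all participants with AC > 0
enter a penalized least-squares fit of the measure on a cubic B-spline
basis in AC (basis dimension 30, knots at predictor quantiles), with the
exact integrated-squared-second-derivative penalty and the smoothing
parameter chosen by generalized cross-validation over a log-spaced grid
(`fit_pspline()`). AC = 0 minutes are excluded from *fitting* — the mass
of zeros would otherwise dominate the low-count region — but are still
mapped at prediction time. Monotonicity is not constrained during
fitting; for inversion the fitted values on a 2000-point log-spaced
evaluation grid are projected to the nearest nondecreasing sequence
(isotonic regression), with a warning reporting the magnitude of any
correction. The fitted map is floored at 0 because the measures are
nonnegative. `invert_to_ac()` performs linear interpolation on the
monotonized grid (values below the smallest fitted value map to 0; values
above the largest clamp to the grid maximum, flagged), and
`translate_cutoff()` maps count cut-offs such as 1853, 2860, and 3940
onto each measure's scale. For very large samples `max_n` caps the
fitting set by a seeded uniform subsample (default in the pipeline:
50,000).

## Evaluation statistics

* Participant-specific Pearson correlations between AC and each measure
  over valid minutes, summarized by intercept-only linear regression
  (mean and SE) and by regression adjusted for age, BMI, and sex (female
  as reference, α = .05).
* Percentage errors of mapped daily totals: per participant-day,
  $e_d = 100\,(\hat T_d - T_d)/T_d$ with $T_d$ the daily sum of counts
  and $\hat T_d$ the daily sum of inverted mapped counts on the imputed
  (gap-free) data; per participant MPE, MAPE, MdPE, MdAPE; cohort mean
  (SD). Days with $T_d = 0$ are excluded. Daily errors are averaged
  within participant (a per-participant-total variant would weight days
  by volume; the per-day reading is the default).
* Cut-off classification: per participant, minutes are classed by
  `AC > cutoff` (truth) versus `inverted mapped count > cutoff`
  (prediction), both strict inequalities; accuracy, sensitivity,
  specificity, cohort mean (SD).
* Smoothed 24-hour median curves: per age group (<60, 60–67, 68–74, ≥75)
  and minute of day, the median of AC and of mapped counts over all
  participant-days, each smoothed by the same GCV penalized spline; the
  curve MAPE is $100 \sum|\hat a - a| / \sum a$ pooled over minutes and
  groups.

## The synthetic cohort

The study data are not public, so the generator (`sim_profile()`,
`generate_minute_cohort()`, `generate_raw_day()`) defines the test-bed
conditions. Defaults emulate a 7-day wrist protocol in a predominantly
older cohort: ages ~ N(69.8, 14.2) truncated to 22–97, 54.5% female,
BMI ~ N(27.3, 5). Minute counts follow a zero-inflated gamma process with
diurnal zero-inflation (awake roughly 07:00–22:00) and a two-hump daytime
intensity profile scaled so mean daily count sums sit near 2×10⁶, with a
participant-level activity multiplier that makes younger participants
more active. Measures are generated from monotone power-law truths
$g(\mathrm{AC}) = a\,\mathrm{AC}^b$ with exponents 0.90–1.10 and
coefficients placing daily sums at free-living magnitudes (MIMS ~1.1×10⁴,
ENMO ~31 g·min, MAD ~48 g·min, AI ~4×10³), plus heteroscedastic noise
with SD proportional to the level. The noise fractions are graded per
measure (MIMS 0.10, AI 0.25, MAD 0.45, ENMO 0.60) so that the
participant-specific correlations with counts reproduce the ordering and
rough magnitude observed in free-living wrist data (MIMS strongest, ENMO
weakest). Scheduled nonwear blocks are ≥ 90-minute zero-count runs;
shorter "nap" zero runs stay wear; rare QC-invalid minutes are injected
at rate 0.001. Raw-signal days combine a drifting gravity orientation,
bout-structured 0.5–3 Hz oscillation, white noise, and injectable
clipped/stuck/spike artifacts. Everything is deterministic given the
profile seed (R's default Mersenne-Twister; the seed is set locally and
the caller's RNG state restored).

What the generator does **not** emulate: device temperature drift and the
associated calibration error, posture-specific gravity distributions,
autocorrelated measure noise within bouts, or the vendor count
algorithm's dead-band and saturation behavior. Passing tests therefore
show that the pipeline recovers the structure this generator encodes, not
that it reproduces any particular cohort's published values.

## Numerical choices and problem sizes

Spline penalties are scaled so the GCV grid `10^(-6..8)` is comparable
across problems; normal equations are solved by Cholesky with a tiny
ridge fallback for near-singular bases. Isotonic projection is used only
for inversion, never for fitting. The test suite runs the harmonization
recovery at 50,000+ generator-drawn pairs (15 participants × 7 days),
FPCA recovery on 14 × 1440 rank-1 matrices with 5% deletions, and the
end-to-end determinism check on an 8-participant, 4-day cohort; the
acceptance script simulates 40 participants × 7 days. These sizes were
chosen so the full suite completes in well under a minute per module
while keeping Monte-Carlo error far from the asserted tolerances.

Known limitations: the ENMO-scale curve MAPE is large under the default
noise (its 60% multiplicative noise passes through a concave inverse map,
biasing minute-of-day medians of mapped counts, and overnight minutes
with near-zero counts inflate the relative denominator); MIMS values are
on this package's g·s integration scale, which matches the reference
measure's ordering and homogeneity but is not bit-compatible with vendor
implementations; and the harmonization map is estimated at 80 Hz-style
minute summaries — translating it to other sampling rates or wear sites
is not supported.
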