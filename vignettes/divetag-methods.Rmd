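---
title: "Methods: vertical movement, activity and niche analysis for archival tags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vertical movement, activity and niche analysis for archival tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and data model

`divetag` analyses multichannel archival tag (PSAT) records from
free-swimming fish: depth (m, positive down), temperature (°C), light level
(dimensionless tag units) and triaxial acceleration, sampled at a fixed
rate, typically 0.2 Hz.  The central scientific questions it addresses are
(i) when and how strongly an individual expresses diel vertical migration
(DVM), (ii) how burst activity ("fast starts", a proxy for foraging or
escape events) is distributed over the diel cycle, depth and season, and
(iii) which part of depth–temperature space an individual or cohort
actually occupies.

A `tag_archive` is a plain data frame with one row per sample and a strict
contract: uniform sampling, strictly increasing timestamps, sensor gaps
encoded as missing values rather than dropped rows.  Everything downstream
(cleaning, aggregation, spectral analysis) relies on that regularity.

## The synthetic generator as ground truth

Real recovered archives are rarely public, so validation rests on
`generate_archive()`, which simulates archives with *known* behavioural
structure.  Its defaults describe the study system the package is built
around: a late-autumn, high-latitude (60.3°N, 5.2°E) fjord deployment of a
female spurdog-like animal.

* **Diel depth cycling.**  During normal-DVM (`nDVM`) days the depth
  baseline is 198.5 m by day and 60 m by night — the observed day/night
  median depths during migratory behaviour — with logistic ramps of
  `transition_minutes` (default 60) centred on sunrise (descent) and sunset
  (ascent).  `rDVM` swaps the baselines; `none` holds the night baseline.
  At this latitude in midsummer, twilight is undefined; the generator then
  simply holds the night baseline between sunset and sunrise, a degenerate
  but well-defined rule.
* **Depth noise.**  The noise model mirrors the null model of the
  significance test.  The wavelet surrogate test operates on *hourly*
  series and assumes lag-one autoregressive (AR(1)) red noise, so
  `ar1_coef_depth` (default 0.5) is defined at the hourly lag: the slow
  noise component is an hourly AR(1) with stationary standard deviation
  `depth_noise_sd` (default 25 m, matching the spread of observed daytime
  depths), held constant within each hour, plus fast white jitter
  (`depth_jitter_sd`, 1.5 m) at the sample level.  Aggregating such an
  archive to hourly medians recovers the AR(1) process almost exactly,
  which is what makes the calibration test meaningful: an archive
  generated with `mode = "none"` *is* a draw from the significance test's
  null, so the rejection rate at the 24-h period must sit at the nominal
  level.  A sample-level AR(1) would not have this property — hourly
  aggregation would whiten it and the null comparison would be
  systematically conservative.
* **Hydrography.**  Temperature is a two-layer profile: logistic relaxation
  from `surface_temp_C` (14 °C) to `deep_temp_C` (8 °C) across a
  `thermocline_width_m` transition centred at `thermocline_depth_m`
  (defaults 5 m and 15 m, a shallow summer-type thermocline).  The
  stochastic part is a slow offset shared across depth, so the
  instantaneous profile is always monotone non-increasing with depth — an
  invariant the tests check.
* **Light.**  Tag light sensors are log-scaled (20 units per decade of
  irradiance, anchored so that 150 units ≈ 1e-5 W cm⁻²).  Surface light
  follows the solar elevation on that log scale, depth attenuates linearly
  in tag units (`light_attenuation_per_m`), and the channel is floored at
  zero.
* **Acceleration.**  Isotropic Gaussian baseline noise per axis plus a
  Poisson burst process whose hourly rate depends on the day's DVM mode
  and the diel period (defaults: 25/h by day and 10/h by night during
  nDVM, 3/h outside DVM — day-skewed and DVM-elevated, as observed).
  Each burst adds a fixed-magnitude vector (default 10 units, ten baseline
  standard deviations) in a uniformly random direction; the magnitude
  statistic downstream is rotation-invariant, so direction is irrelevant.
  The planted burst indices are kept as an attribute, giving every
  detection test an exact ground truth.

What the generator deliberately does **not** emulate: horizontal movement,
tidal/internal-wave forcing, lunar cycles, seasonal hydrographic change
within a deployment, and multi-animal interaction.  Passing tests therefore
demonstrate that the estimators recover the behavioural structure they
target under realistic noise — not that real archives contain no further
structure.

## Cleaning and aggregation

`clean_track()` removes the first 24 h of each record (tagging and capture
effects) and excises two kinds of terminal artefact: surface drifting (a
trailing run at ≤ 1 m lasting ≥ 1 h; the duration threshold is a package
choice, configurable) and mortality-like constant pressure at depth.  The
mortality rule follows the tags' own release criterion — depth variation at
or below 2.5 m over a 48-h window while the median depth exceeds 1 m.  The
printed threshold carries a length unit, so it is interpreted on the
standard-deviation scale (metres), configurable via `mortality_sd_m`.
Cleaning marks its output, so re-cleaning a cleaned track is a no-op.

`aggregate_archive()` reduces archives to 1-min or hourly records: medians
for depth, temperature and light (skewed distributions), means for
acceleration magnitude and vertical speed, sums for fast-start flags.
Intervals are half-open `[t, t + Δ)`, labelled by their start, with diel
labels taken at the interval midpoint; intervals with under half their
nominal samples are emitted as missing rather than dropped.  Vertical speed
uses the oceanographic sign convention (positive = ascent) and is assigned
to the leading sample.

Solar geometry uses the NOAA low-accuracy ephemeris: sunrise/sunset at
solar elevation −0.833° and nautical dawn/dusk at −12°, all in UTC at a
single reference coordinate (60.3°N, 5.2°E by default) — adequate for a
coastal cohort resident within tens of kilometres.  Diel periods are
half-open and lower-inclusive; when nautical twilight is undefined the
4-level scheme degrades gracefully to day/night.

## Fast starts

The magnitude of acceleration is `MA = sqrt(ax² + ay² + az²)`.  A fast
start is a sample whose MA strictly exceeds the individual's empirical
95th percentile (type-7 quantile, linear interpolation of order
statistics), computed once per individual over the full cleaned track.
Strict exceedance means ties at the threshold are not flagged — "the upper
5%" excludes its own boundary.  Each supra-threshold sample counts as one
fast start; at 0.2 Hz a sub-second event occupies at most one sample, so
per-sample counting and per-event counting coincide in practice.  The
percentile basis makes the statistic unit-free, which is also why the
generator can treat acceleration units as arbitrary.

## Wavelet analysis and red-noise significance

Hourly depth series are transformed with a continuous Morlet wavelet
(central frequency ω₀ = 6) on a geometric scale grid
`s_j = s0 · 2^(j·dj)` with `dj = 1/20`, spanning Fourier periods from 2 h
to one third of the series length.  Conventions for the scale grid, the
Fourier-period relation `λ = 4π s / (ω₀ + sqrt(2 + ω₀²))`, zero-padding
and the cone of influence (e-folding time `sqrt(2)·s`) follow the classical
geophysical wavelet literature.  Power is bias-corrected by dividing by
scale, preventing high-frequency peaks from being underestimated.

Two numerical choices deserve note:

* **Sampled kernel.**  The frequency-domain "daughter" is the FFT of the
  *time-sampled* Morlet kernel rather than the band-limited analytic form.
  The two differ only near the Nyquist period, but the sampled form makes
  the FFT route agree with direct time-domain convolution at every scale
  to near machine precision, which is how the transform is validated.
* **Padding.**  Each scale is zero-padded to the smallest 2-3-5-smooth
  length of the form `2^k·{1, 1.25, 1.5}` that is at least
  `n + 6.5·s` samples.  The margin guarantees the circular convolution
  equals the non-circular one (the Morlet envelope at lag 6.5·s is below
  1e-9 of its peak); the coarse ladder keeps the number of distinct
  forward transforms small, which matters when a thousand surrogates are
  transformed per individual.

Significance is assessed empirically: 1000 surrogate series per individual
from an AR(1) model with the coefficient *fixed* at 0.5 (not estimated)
and the mean of the data, innovation variance matched so surrogate
variance equals the observed variance.  Each surrogate is transformed
identically; the cell-wise p-value is
`(1 + #{surrogate power ≥ observed}) / (n_sim + 1)` — the add-one
correction avoids zero p-values — and global p-values are computed the
same way on the time-averaged spectrum.  The test is pointwise; no
area-wise multiple-testing correction is applied.  Missing hourly values
(at most 10%) are linearly interpolated before transforming and the
affected indices recorded.

`summarize_periodicity()` reports a band (diel 24 h, its 12 h harmonic,
fortnightly, lunar ≈ 28 d, seasonal > 84 d) as significant when some grid
period inside it is a local maximum of the global spectrum with
`p ≤ 0.05`; bands outside the resolved range are reported as unresolved,
never dropped.

## Daily DVM classification and clustering

The hourly p-value at the grid period nearest 24 h drives the daily
classification: a day is DVM when a *strict majority* (> 0.5, matching
"more than half the time") of its valid hours is significant at
`α = 0.05`.  Days with fewer than 12 valid hours are left unclassified.
Hours inside the cone of influence are retained (but marked) — excluding
them would silently bias the first and last days of every deployment.

Daily mean p-values are smoothed with a centred 11-day rolling mean whose
ends shrink to the available days.  Individuals are compared on these
smoothed series aligned to a common Julian-day index (years overlaid, so
deployments from different years are matched by season): the distance is
Euclidean over co-observed days with the sum of squares scaled up
proportionally to the number of days used,
`d = sqrt((N/n_used)·Σ(p_a − p_b)²)`.  This scaled distance is not a
metric (the triangle inequality can fail under extreme missingness), which
is accepted as the price of comparing unequal deployment lengths.
Clustering is agglomerative with complete linkage — only the distance is
fixed by the method; the linkage is a package choice (complete linkage
keeps clusters compact and is deterministic once ids are sorted).
Dendrograms export as Newick text.

## Depth–temperature niche

The realised niche is a weighted product-Gaussian kernel density on a
200 × 200 grid covering the pooled hourly data with a 10% margin.
Bandwidths per axis use the normal-reference rule
`h = 4·1.06·min(sd, IQR/1.34)·n^(−1/5)` in the dialect where the Gaussian
kernel standard deviation is `h/4`.  Records are weighted by the
reciprocal of the number of *pooled* hourly records on their Julian day
(per-individual weighting is available as an option), so every covered day
of the year contributes equal mass regardless of how many animals were at
liberty — duplicating one day's records provably leaves the density
unchanged.  Isopleths for the 50% and 95% mass fractions are found by
sorting grid cells by density and accumulating mass; the same weights
drive occupancy summaries (25-m depth bins, 2 °C temperature bins, and the
named shallow ≤ 75 m / epipelagic ≤ 200 m / mesopelagic 200–1000 m zones),
reported as mean ± SE across individuals (n = animals).

One calibration caveat: the empirical coverage of a KDE isopleth matches
its nominal mass fraction only when the bandwidth suits the distribution.
The normal-reference rule is calibrated for unimodal data; on strongly
bimodal samples it oversmooths and the 95% region over-covers by a few
points.  The validation therefore checks normalisation on a bimodal sample
but coverage on a (weighted) near-normal one.

## Hotspot maps

Raw-rate samples are binned into 10 m × 1 h-of-day cells per calendar
month, pooling all individuals; fast-start counts per cell are divided by
the month's total sample count so maps are comparable between months.
Scaling uses *all* samples of the month (not only those of animals with
bursts); multiplying back by `n_points` recovers the integer totals
exactly, which the tests assert.  Depth bins are half-open from 0 and the
bin set extends automatically for deep samples.  A sensitivity variant
recomputes the maps with the first 120 h of each track excised.

## Diel statistics

The statistics layer wraps the standard tests the analysis calls for:
paired Wilcoxon signed-rank on per-animal-day (day, night) median-depth
pairs restricted to DVM days; one-sample t tests of hourly vertical speed
against zero per 4-level diel period; a pooled one-sided Mann–Whitney test
of fast starts in DVM versus non-DVM hours plus per-individual paired
day/night Wilcoxon tests; and Pearson correlations of hourly fast starts
with depth, temperature and light.  R's implementations switch between
exact and continuity-corrected normal approximations at the conventional
sample sizes.  Degenerate inputs (all-zero differences, zero variance,
constant covariates, groups with no data) return well-defined degenerate
results rather than failing, and no multiple-testing correction is
applied.  Day/night pairing uses the 2-level diel labels within a
calendar date (UTC).

## Problem sizes used in validation

The shipped validation runs at sizes chosen to exercise every code path at
full parameter settings: oracle equivalence on 256-point series across the
whole scale grid; surrogate calibration on 50 replicate AR(1) series of
720 h with 200 surrogates each; DVM recovery on a 120-day archive with
1000 surrogates; niche calibration on 5000-point samples; and an
end-to-end run of 19 simulated animals × 90 days at 0.2 Hz (≈ 30 million
samples) through the full pipeline with default settings.

## Known limitations

* Solar times use the low-accuracy NOAA ephemeris (±1–2 min), and one
  fixed coordinate serves the whole cohort.
* The 12-h band cannot distinguish tidal forcing from harmonics of
  non-sinusoidal diel movement; the package reports the band and leaves
  interpretation to the analyst.
* The scalogram significance test is pointwise; contiguous significant
  regions are easier to obtain by chance than the cell-wise level
  suggests.
* Hourly aggregation bounds the detectable period range from below at 2 h;
  burst detection at 0.2 Hz undercounts sub-second events, so fast-start
  counts are a relative, not absolute, activity measure.
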