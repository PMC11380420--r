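# divetag

Analysis of multichannel archival tag (PSAT) time series from fish —
depth, temperature, light and triaxial acceleration at a fixed sampling
rate (typically 0.2 Hz).  The package targets the questions a biologging
study of vertical movement asks of such archives:

* **When does an individual express diel vertical migration (DVM)?**
  Hourly depth series are analysed with a bias-corrected continuous Morlet
  wavelet transform (ω₀ = 6, scales `s_j = s₀·2^(j/20)`, periods
  `λ = 4πs/(ω₀ + √(2+ω₀²))`).  Significance against a red-noise null is
  assessed with 1000 AR(1) surrogates per individual (coefficient fixed at
  0.5, variance matched to the data):
  `p(s,t) = (1 + #{P_surr ≥ P_obs}) / (n_sim + 1)`.  A day is classified
  as DVM when a strict majority of its hours is significant at the grid
  period nearest 24 h; individuals are clustered on smoothed daily
  p-value series with a missing-value-scaled Euclidean distance
  `d = sqrt((N/n_used)·Σ(p_a − p_b)²)`.
* **How is burst activity distributed?**  Fast starts are samples whose
  acceleration magnitude `MA = √(ax²+ay²+az²)` exceeds the individual's
  empirical 95th percentile; they are summed per hour, compared across
  diel periods and DVM states (Wilcoxon/Mann–Whitney/t tests), correlated
  with depth, temperature and light, and mapped into monthly 10 m × 1 h
  hotspot grids scaled by each month's sample count.
* **What depth–temperature niche is occupied?**  A weighted 2-D Gaussian
  kernel density (normal-reference bandwidths
  `h = 4·1.06·min(sd, IQR/1.34)·n^(−1/5)`, records weighted by the
  reciprocal of entries per Julian day) with 50%/95% isopleths and
  occupancy fractions per depth/temperature bin.

Because recovered tag archives are rarely public, the package ships a
first-class synthetic generator (`generate_archive()`) that simulates
archives with known DVM schedules, hydrography, light and planted
acceleration bursts, so every estimator can be validated against ground
truth.  A pipeline driver (`run_pipeline()`) chains the full analysis:
simulate/read → clean → fast starts → aggregate → wavelet + surrogates →
DVM classification and clustering → niche → hotspots → statistics.

## Worked example

Simulate a three-animal, 30-day late-autumn cohort with normal DVM and run
the full pipeline:

```r
library(divetag)
cfg <- pipeline_config(
  simulation = list(n_animals = 3, duration_days = 30),
  wavelet = list(n_sim = 200), seed = 42)
res <- run_pipeline(cfg, out_dir = "out")

summarize_periodicity(res$wavelets[[1]])[, c(1, 4:7)]
#>   band resolved significant best_period_h       min_p
#> 1  24h     TRUE        TRUE      23.42537 0.004975124
#> 2  12h     TRUE        TRUE      11.71269 0.004975124
#> 3  14d    FALSE          NA            NA          NA
#> ...
```

The diel band (and its 12-h harmonic, a by-product of the non-sinusoidal
depth waveform) is significant; the fortnightly and longer bands are
unresolvable on a 30-day track and are reported as such.  The diel
statistics table recovers the expected directionality — deeper by day on
DVM days, descents at dawn, ascents at dusk, and fast starts increasing
with depth:

```r
print(res$stats, digits = 3)
#>              test_name             grouping statistic  p_value    n  direction
#> 1 wilcoxon_signed_rank   day_vs_night_depth  3828.000 5.56e-16   87 day deeper
#> 2         one_sample_t          vspeed_dawn   -11.729 8.47e-23  147    descent
#> 4         one_sample_t          vspeed_dusk    12.444 3.27e-25  159     ascent
#> 7  pearson_correlation fast_starts_vs_depth     0.691       NA 2088   positive
```

`res$occupancy$zones` summarises vertical habitat use (mean ± SE across
animals): this cohort spends 86.9 ± 0.9% of its time in the epipelagic
zone (≤ 200 m).  Per-animal DVM classifications, the cohort dendrogram
(Newick), the niche density grid with isopleth levels, and monthly hotspot
matrices are written to `out/` as delimited text together with a JSON run
manifest; the whole run is byte-identical for a fixed seed.

A thin command-line wrapper with `simulate`/`preprocess`/…/`all`
subcommands is installed at `inst/scripts/divetag-pipeline.R`.

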