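# asvseasons

Seasonal analysis of amplicon (ASV) relative-abundance time series from
moored autonomous samplers at two ocean stations.

Year-round biweekly sampling at high-latitude moorings yields, after
sequencing, a relative-abundance series per amplicon sequence variant (ASV)
per station. This package asks two things of such data: *when* does each
taxon occur (phenology under the polar light cycle), and *under which
upper-ocean regime* does it prosper when two consecutive years contrast a
meltwater-stratified state with a mixed-layer state.

## Method at its core

Each ASV series is interpolated to daily resolution and decomposed by an
unnormalized discrete Fourier transform,
`c_k = Σ_d x_d exp(−2πi·k·d/T)`. For a window of `m` whole years the
component `k = m` has a one-year period, and

* seasonality score **s = |c_m| / |c_0|** (scale-invariant annual strength),
* annual phase day **(−arg c_m)·T/(2πm) mod 365**,

summarize each taxon. ASVs are clustered by k-means on their (unit-mean
scaled) annual Fourier features, clusters are ordered and named by phase
(`H-01 … H-10`, `F-01 … F-10`), counted for abundance peaks, and annotated
with polar day-length light classes (LL ≤ 2 h daylight, HL > 2 h, NA for
anomalous/mixed clusters). Cross-station cluster overlaps on the shared
"core community" are scored by an upper-tail hypergeometric test
(−log10 p). At the contrast station, taxa at least twice as abundant in the
meltwater year (`log2(S₁/S₂) ≥ 1`) are classified meltwater-regime (MWR),
the mirror class mixed-layer regime (MLR), and group-level contrasts are
quantified by median abundance quotients, one-sided Kolmogorov–Smirnov
tests, and year-to-year area-under-the-curve (AUC) ratios over 365-day
windows.

A synthetic two-station community generator with known phases, regime
multipliers and shared/unique membership makes the whole pipeline testable
end to end; see the methods vignette
(`vignettes/seasonal-amplicon-analysis.Rmd`) for the model, parameter
defaults and design rationale.

## Worked example

```r
library(asvseasons)

cf  <- synth_config(seed = 42)                 # two stations, 2017-2018
sim <- generate_community(cf)
res <- run_pipeline(sim$table_a, sim$table_b, window = cf$window, seed = 7)

res$clusters_b[, c("name", "light_class", "n_peaks", "phase_day",
                   "cl_size", "s_score", "auc_y1y2", "ms_rel")]
#>    name light_class n_peaks phase_day cl_size s_score auc_y1y2 ms_rel
#> 1  H-01          LL       2      36.5      16   0.710    0.887     25
#> 2  H-02          HL       2      69.5      16   0.694    1.070     25
#> 3  H-03          HL       2     105.5      16   0.698    0.886     25
#> ...
#> 10 H-10          LL       2     364.3      16   0.715    0.980     25

table(res$regime$regime_class)
#>         MLR         MWR unspecified
#>          13          15          92

res$ratios$q_values
#>            z value
#> 1    F4-2017 1.342
#> 2    F4-2018 1.225
#> 3 HG-IV-2017 3.133
#> 4 HG-IV-2018 0.500
```

Reading the output: clusters at the contrast station are phase-ordered
through the year (`phase_day` is the day of year of the cluster's annual
maximum), with low-light clusters in winter and high-light clusters through
the bright season; `ms_rel` is the percentage of members not shared with
the partner station. The regime table recovers the generator's designated
taxa (15 MWR, 13 of 15 MLR here), and the within-site preference `q(z)` —
mean MWR abundance over mean MLR abundance — shows the injected contrast at
station HG-IV (3.13 in the meltwater year vs 0.50 in the mixed-layer year)
and near-indifference at the reference station F4.

Results are written as TSVs with `write_pipeline_results(res, out_dir)`.

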