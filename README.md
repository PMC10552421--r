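# msms — multi-scale movement syndromes from GPS tracking data

`msms` is an R toolkit for describing and comparing animal movement at three
nested temporal scales — the **step** (displacement between consecutive GPS
fixes), the **daily path** (all fixes in one activity period), and the
**life-history phase** (weeks to months of ranging) — and for asking whether
individuals or species fall into recurrent combinations of movement metrics
("movement syndromes"). It was built around high-resolution burst telemetry
of the kind collected on sympatric frugivorous mammals (kinkajous, coatis,
capuchins, spider monkeys): 4-minute bursts of six 1 Hz fixes, species
activity windows (including nocturnal windows spanning midnight), and
activity-informed collars that stop fixing when the animal is still.

## What it computes

**Step scale.** Step lengths are modeled with a Gamma distribution
(shape *k*, scale *θ*; profile-likelihood MLE) and turn angles with a von
Mises distribution (mean direction *μ*, concentration *κ*; *κ* solves
*A₁(κ) = R̄*), pooled per individual.

**Path scale.** For every individual-day with at least 100 locations and no
gap over an hour: total distance, straightness (beeline / travelled),
corrected sinuosity `S = 2·[p(1+c)/(1−c)]^(−1/2)` on the path rediscretized
at the species mean step length *p*, and the proportions of fixes in three
behaviors. Behavior is segmented by first-passage time: a fix whose 15-m
circle is not exited within 12 min is a *cluster* (< 15 m net movement,
e.g. feeding in one tree crown), a 30-m circle not exited within 12 min is
*ARS* (area-restricted search, 15–30 m), anything faster is *travel*. Fixes
near the start or end of a day, where the passage time is censored, get
labels imputed from a correlated-velocity model (η = rms speed, τ = velocity
autocorrelation timescale) via Ward clustering.

**Life-history scale.** Turn-angle correlation, residence time and
time-to-return (circle of radius = the individual's mean step length, 12-h
excursion cutoff), monthly home-range overlap (volume of intersection of
kernel utilization distributions), maximum net squared displacement scaled
by the species minimum, and the 95% kernel home range.

**Comparisons.** Per scale, a nested ANOVA partitions each metric's variance
into species vs. individual-within-species components, and a standardized
(correlation-matrix) PCA with Kaiser retention builds the syndrome space;
Ward clustering with silhouettes quantifies syndrome separation.

**Simulator.** A three-state (cluster/ARS/travel) Markov-switching
correlated random walk with home-range attraction, burst-structured
observation, negative-binomial GPS error, and activity-informed burst
dropout generates fully synthetic studies with known truth, so every stage
is testable without field data.

## Worked example

```r
library(msms)
library(dplyr)

# simulate a four-species study (3 individuals each, 8 activity periods)
study <- simulate_study(species_presets(days = 8), n_per_species = 3, seed = 2024)
write_tracking_csv(study$fixes, "tracks.csv")

# run the whole pipeline: preprocess -> steps -> segmentation -> paths ->
# life phase -> variance partition + syndrome PCAs
res <- run_pipeline(pipeline_config("tracks.csv", "out", seed = 2024))

res$variance_partition %>%
  filter(scale == "path_daily", metric %in% c("prop_ars", "prop_cluster"))
#>   metric       pct_species pct_individual statistic df1 df2   p_value   n
#> 1 prop_cluster        47.9           5.01      25.5    3   8 0.000190   96
#> 2 prop_ars            65.5           5.38      32.5    3   8 0.0000792  96

res$pca$path_individual
#> Syndrome space: 5 metrics, 12 rows; 2 component(s) with eigenvalue > 1
#> explaining 82.9% of variance

cluster_individuals(res$pca$path_individual, k = 3)
#> Syndrome clustering: k = 3, mean silhouette 0.670
```

Roughly half to two-thirds of the day-to-day variance in the behavioral time
budgets (cluster/ARS proportions) is attributable to species, only ~5% to
individuals within species, and the per-individual path syndrome space
separates into three clean clusters — one per cluster-heavy specialist
regime plus the two ARS-heavy species merged — which is the syndrome
structure the simulator's presets encode.

Each result type has `tidy()`/`glance()` methods and `autoplot()`/
`plot_daily_path()` graphics. A thin command-line front end is included at
`inst/cli/msms.R` (`Rscript msms.R simulate ...`, `Rscript msms.R run
--config study.yaml`).

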