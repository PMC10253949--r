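# cpforage

Age and environment effects on central-place seabird foraging.

`cpforage` is an R package for analysing GPS tracking data from
central-place foraging seabirds (built around the incubation-stage
foraging of a tropical booby colony, but general to any colony-based
forager). It turns raw fix tables into per-absence foraging traits,
selects among competing age functions with small-sample-corrected AIC in
linear mixed models, tests age-by-environment interactions, and measures
spatial segregation of age classes with kernel utilization-distribution
overlap and randomization inference. A synthetic track generator with
full ground truth backs every stage with recovery tests.

## The analysis in brief

**Traits.** A *foraging absence* is the period between two incubation
shifts (it may contain brief colony returns). From each bird's first
qualifying absence (> 3 h beyond a 1-km colony radius) five responses are
computed: absence duration (daylight h), total distance (daylight km,
haversine on R = 6371 km), time searching (daylight h in the
localized-search state), mass gain (g, return − departure mass), and mass
gain per hour (g/h over the full day+night duration). Steps are
classified into four states — rest, commute, relocate, search — by
binary splits of speed and turning angle (per-sex delimiters fitted by
two-component Gaussian EM, or the published reference splits 5.8/7.12 m/s
and 0.74/0.34 rad).

**Models.** Stage 1 compares age parameterizations per sex and trait:
null, linear, quadratic, and continuous piecewise (segment-slope)
threshold models — single thresholds and early×late two-threshold
combinations over sex-specific grids (29 male / 24 female candidates) —
each with Season, Date, Logger and Wing Loading
(`9.8·mass / (0.04 + 0.95·chord)²`, N/m²) and crossed random intercepts
for bird identity and 10-day departure window, fitted by maximum
likelihood and ranked by

```
AICc = −2·logLik + 2k + 2k(k+1)/(n − k − 1),  ω_i ∝ exp(−Δ_i/2)
```

The top-model set is ΔAICc ≤ 2, pruned of models that merely add
parameters to a nested model with lower AICc; coefficients are never
model-averaged. Stage 2 carries the winning age basis forward and
evaluates SST (8-day-window matched, seasonally detrended), median
breeding date, and cloud cover — each in separate models, with and
without age interactions, data restricted to ages 5–22.

**Space.** Searching locations per age group (Young 4–9, Middle Age
11–16, Old 17–20, Oldest 21–25) feed Gaussian kernel UDs on a 500-m grid
(reference bandwidth `href = sqrt((var_x+var_y)/2)·n^(−1/6)`; pairwise
comparisons use the smaller group href). Overlap is Bhattacharyya
affinity `BA = Σ √(p₁p₂)` in [0, 1]; significance comes from reassigning
whole tracks between groups (1000 iterations, p = proportion of null
overlaps below the observed), with Benjamini–Hochberg FDR at q = 0.05
over the six pairwise comparisons.

## Worked example

```r
library(cpforage)

cfg <- sim_config(n_birds = 16, seasons = default_seasons()[c(1, 4), ],
                  seed = 1)
ds  <- simulate_dataset(cfg)
delims <- list(male = reference_delimiters("male_paper"),
               female = reference_delimiters("female_paper"))
traits <- build_trait_table(ds$fixes, ds$birds, delims, cfg$colony)
head(traits[, c("bird_id", "sex", "age", "absence_duration_h",
                "total_distance_km", "time_searching_h", "mass_gain_g")], 4)
#>   bird_id  sex age absence_duration_h total_distance_km time_searching_h mass_gain_g
#> 1   B0001 male   4          21.083333          403.8260         4.083333   147.61409
#> 2   B0002 male  14           9.916667          145.2916         2.666667    90.23203
#> 3   B0003 male  19          21.916667          517.2352         4.250000   131.14134
#> 4   B0004 male  21          18.833333          367.0234         3.750000   138.62212
```

A 4-year-old travelled 404 km and gained 148 g over a 21-daylight-hour
absence; each row is one bird-season absence with its five traits.

Model selection at analysis scale (500 female absences from the
generator's trait layer, which embeds a U-shaped age effect on absence
duration):

```r
cfg <- sim_config(sex_ratio = 0)
tl  <- simulate_trait_table(cfg, n_absences = 500, seed = 42)
# ... add covariate columns, then:
fits <- lapply(enumerate_stage1_models("female", "absence_duration_h"),
               fit_lmm, data = tl)
rk <- rank_models(fits)
head(rk$table[, c("model", "k", "AICc", "delta", "weight", "top")], 2)
#>                                    model  k     AICc    delta   weight   top
#> 3  [...] age=quadratic + Season + ... + WL 10 388.2990  0.00000 1.00e+00  TRUE
#> 14 [...] age=two_threshold(8,16) + ... + WL 11 410.0701 21.77107 1.87e-05 FALSE
fits[[rk$best]]$coefficients[6:7, ]
#>   term estimate       se  ci_lo  ci_hi
#> 6  age   0.0800 0.002895 0.0743 0.0857
#> 7 age2   0.0129 0.000485 0.0119 0.0138
```

The quadratic age model wins decisively (ω ≈ 1.0) and the recovered
quadratic coefficient is positive (0.0129, CI [0.0119, 0.0138]) on the
square-root scale — the generator's U-shape with minimum near age 12.

Spatial segregation between two track groups 12 km apart:

```r
rt <- randomization_test(tracks_by_group, c("A", "B"), n_perm = 199, seed = 9)
rt
#> A vs B: BA = 0.145, p = 0.0000 (199 permutations)
```

Observed overlap (BA = 0.145) fell below all 199 null overlaps, so
p ≤ 1/199: the groups search in distinct areas.

The whole pipeline (simulate → process → behavior → traits → model →
spatial → report) also runs as one reproducible, manifest-tracked call:

```r
run_pipeline(default_pipeline_config(), out_dir = "runs/demo", seed = 1)
```

or from the shell via `inst/cli/cpforage-run.R`.

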