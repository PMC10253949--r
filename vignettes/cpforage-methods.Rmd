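---
title: "Methods: models, generator, and numerical choices in cpforage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generator, and numerical choices in cpforage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cpforage` analyses how age and environmental quality shape the foraging
of a central-place seabird during egg incubation. This vignette explains
the statistical machinery, the assumptions behind the synthetic-data
generator, and the numerical and design choices a maintainer should know
about. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

## 1. The unit of analysis: the foraging absence

Incubating pairs alternate nest duty; the analysis unit is the
*absence* — the interval between the end of one incubation shift and the
start of the next — rather than the trip, because birds may touch the
colony briefly without resuming a shift. `detect_first_absence()`
operationalises this with a colony-distance proxy: the first maximal run
of fixes beyond `radius_km` (default 1 km) whose away time exceeds
`min_duration_h` (default 3 h). Two refinements follow from the absence
concept:

* **Bridging.** Inside-radius interludes shorter than
  `min_attendance_h` (default 1 h) are absorbed into the surrounding
  absence. A 5-minute pass over the colony is not an incubation shift;
  real shifts last hours to days.
* **Clock anchoring.** Reported departure/return are the colony fixes
  bracketing the away run, so the clock starts when the previous
  attendance ends. Where the data begin or end away from the colony the
  run ends are used instead.

Both choices are configurable proxies for nest-attendance records the
package does not have.

## 2. Traits and transformations

Five responses per absence: absence duration, total distance and time
searching (daylight only — this species essentially neither forages nor
flies at night), mass gain, and mass gain per hour (over the full
day+night duration — the efficiency denominator includes resting time at
sea). Departure mass is deployment mass minus a daily incubation loss
(default 20 g/day — a configuration default, not an estimate). Wing
loading is `9.8·mass/(0.04 + 0.95·chord)²` with mass in kg and chord in
m; the chord unit is a documented convention (the formula's source is
dimensionally ambiguous, and metres make the denominator an area in m²).

Before modelling, the three effort traits are square-root transformed
and mass gain per hour is log transformed (natural log; any other base
rescales coefficients only). Non-positive gain rates cannot be logged;
such rows are excluded and the count is surfaced in the run manifest.

A *daylight step* is a step whose midpoint has solar elevation above
zero (Spencer-series solar position; a fixed 06:00–18:00 local fallback
exists). The same midpoint convention is used by the generator's truth
bookkeeping, so simulated and recovered traits are comparable at face
value.

## 3. Behavioural states

Four states from the speed/turn dichotomy: rest (low/low), commute
(high/low), relocate (high/high), search (low/high). The package
replaces full bivariate binary clustering with per-variable
two-component Gaussian EM (k-means initialisation, 10 restarts,
tolerance 1e-8, 500-iteration cap); the delimiter is the 0.5-posterior
crossing between the component means. Published delimiters are shipped
as `reference_delimiters("male_paper" | "female_paper")` so
classification can run without fitting. Ties on a split fall to the low
side; steps with undefined turning angle (track ends) are labelled by
speed alone and flagged. No temporal smoothing of labels is applied.

Degeneracy is decided by model comparison, not mean collapse: the
two-component fit must beat a single Gaussian by the BIC penalty of its
three extra parameters, because EM fits two offset components to
unimodal data without ever collapsing the means.

## 4. Mixed models and model selection

All models are linear mixed models with crossed random intercepts for
bird identity (repeat measures across seasons) and a 10-day departure
window (short-term environmental variation), fitted by **maximum
likelihood** — not REML — because AICc comparisons are across
fixed-effect structures. The parameter count is structural,
`k = n_fixed + 3` (two random-intercept variances plus the residual),
and is not reduced for boundary fits.

**Fitting engine.** The deviance is profiled over the two relative
random-effect SDs: with `U = [γ₁Z₁, γ₂Z₂]`,

```
-2 logLik(γ) = log|UᵀU + I| + n(1 + log(2π r²(γ)/n)),
```

where `r²` is the penalized residual sum of squares minimised over the
fixed effects and spherical random effects. Crossproducts are
precomputed once per design, each evaluation is a dense Cholesky, and
`optim(L-BFGS-B)` with a zero lower bound handles boundary estimates
(flagged, retained). The package's tests pin this engine to `lme4` ML
fits to 1e-6 in log-likelihood. Wald 95% CIs (±1.96 SE) are used; they
can be optimistic for variance-dominated terms near boundaries, which
is accepted at these sample sizes.

**Stage 1 (age function).** Candidates per sex: null, linear, quadratic,
single-threshold and two-threshold piecewise models over sex-specific
grids (early thresholds 6–8 for females, 7–10 for males; late 14–17
both; singles additionally at 12 and 13) — 29 male and 24 female
candidates. Thresholds use the *segment-slope* parameterization
(`min(Age,T)`, `max(Age−T,0)`, …), continuous at each threshold, so each
coefficient is a within-segment slope. The quadratic basis is built on
centred age to limit collinearity (predictions are invariant); piecewise
columns are left raw since centring only moves the intercept. All
Stage-1 models carry Season, Date (standardized day of season, pooled
across seasons), Logger, and standardized Wing Loading.

**Stage 2 (age × environment).** The Stage-1 winning basis is carried
forward; Season is replaced by one environmental predictor per model —
residual SST, median breeding date, or daylight cloud cover — each
alone, with wing loading, and interacting with every age column, giving
14 candidates (8 when Stage 1 chose the null basis). With an age basis
present the data are restricted to ages 5–22 (edge ages appear in few
seasons). Residual SST is the matched 8-day-window SST regressed on the
window-centre day, pooled across seasons: "warm or cool for the time of
year". Cloud is averaged over the daylight 6-h blocks spanned by the
absence — block-level matching standing in for per-fix annotation.

**Ranking.** AICc, ΔAICc and Akaike weights over the candidate set; the
top-model set is ΔAICc ≤ 2 *minus* models that merely add parameters to
a nested model with lower AICc. Nesting is decided numerically (column
span projection), not by name matching, so a two-threshold model
correctly nests its single-threshold parents. Coefficients are never
averaged across models: with polynomials, thresholds and interactions,
a coefficient's meaning changes with the accompanying terms, so averages
are not interpretable. Pairwise fixed-effect correlations above |r| 0.7
raise a collinearity warning.

## 5. Spatial segregation

Searching-state locations per age group (Young 4–9, Middle Age 11–16,
Old 17–20, Oldest 21–25; age 10 belongs to no group and is excluded with
a logged count) are projected to a local equirectangular plane about the
colony — at an equatorial site the distortion over trip extents is below
0.2%. UDs are Gaussian product-kernel densities on a 500-m grid padded
by three bandwidths and normalized to sum to one; the reference
bandwidth is `href = sqrt((var_x+var_y)/2)·n^(−1/6)` and a pairwise
comparison uses the smaller of the two groups' href on a shared grid
(mismatched grids are an error, never an implicit resample). Groups pool
all tracks without per-individual weighting — longer trips contribute
more data, deliberately.

Overlap is Bhattacharyya affinity; significance comes from reassigning
whole tracks between the two groups (preserving group sizes), with
p = proportion of null overlaps *below* the observed (low overlap means
segregation). The plain proportion is used by default; a conservative
`(b+1)/(n+1)` variant is available. Randomization is per pair, not
jointly across the four groups, matching the "within a given comparison"
reading. Two numerical choices: the bandwidth and grid are computed from
the observed comparison and held fixed across permutations (recomputing
href per shuffle costs ~20× for no change in the null's validity), and
the six pairwise p-values per sex/season are controlled by
Benjamini–Hochberg FDR at q = 0.05.

## 6. The synthetic generator: what it emulates, and what not

The generator states a world with the structure the analysis assumes:

* A cohort spanning ages 4–25 sampled across the four age groups (age 10
  absent, as in the study population), two sexes (females ~17% heavier),
  tracked over five seasons whose SST regimes span a cool-to-warm
  spectrum (offsets −1 to +2 °C; median breeding dates spanning ~3
  weeks).
* One absence per bird-season: a four-state Markov-switching correlated
  random walk at 5-min fixes (speeds truncated-Gaussian, turns
  wrapped-Cauchy), forced to rest at night, commuting home once the
  target duration passes. Deployment groups of four same-sex birds share
  a departure window.
* Target absence duration = `46.6 − 3.6·Age + 0.15·Age²` (a U with
  minimum at age 12, matching the early-improvement/late-decline
  pattern) − 2·SSTc (warm water shortens trips) + sex offset + bird and
  departure-window random intercepts (SD 2 and 1.5 h) + residual (SD
  3 h).
* Mass: 20 g/day incubation loss; gain accrues at ~30 g per daylight
  search hour with a positive (age−12)×SST interaction coefficient
  (0.4 g/h per year·°C) — warm conditions flatten the age decline in
  gain rate, the pattern the Stage-2 interaction machinery must detect.
* Movement defaults: rest 0.3, search 3, commute/relocate 10 m/s —
  either side of the published 5.8/7.12 m/s splits; turn concentrations
  0.98 (low) and 0.05 (high), chosen from the analytic equal-density
  crossing of the wrapped-Cauchy pair so that the binary turn dichotomy
  has ~7% overlap mass. These are conventions, not estimates: no
  per-state speed distributions were available to emulate.

Not emulated: logger artifacts (dropout, HDOP), at-sea environmental
gradients (night is computed at the colony), prey fields, and
individually simulated colony returns within an absence (returns arise
only from the walk's geometry). A green recovery test therefore
establishes that the pipeline recovers the *stated* structure at the
stated noise — not that the pipeline is robust to every pathology of
real tracking data.

The generator also exposes its trait layer directly
(`simulate_trait_table()`): the same fixed-effect/random-effect
structure as the track model's target duration, without the walk. Model
calibration suites (50 datasets × 500 absences) run on this layer for
budget; the track layer's realized durations are separately checked
against their targets.

## 7. Degenerate inputs and edge rules

* Interpolation fabricates nothing across gaps longer than `max_gap`
  (default 30 min) and refuses unsorted or single-fix input.
* Absences entirely at night yield zero daylight traits and a flag;
  missing return mass yields flagged records with empty mass fields.
* An all-identical point set has no UD (zero variance error); a UD level
  mask requires `level` strictly inside (0, 1).
* `rank_models()` refuses fits with differing n — likelihoods on
  different observation sets are not comparable.
* Random-effect variances at zero are legitimate fits, flagged
  `boundary`, with `k` unchanged.

## 8. Known limitations

* The univariate EM split is not full bivariate binary clustering; with
  strongly correlated speed/turn structure the two approaches can place
  delimiters differently. The published delimiters are available as
  fixed reference configurations precisely so the downstream pipeline
  does not depend on the fitting approximation.
* Wald CIs and ML variance components are both slightly anticonservative
  at small n; profile CIs were deliberately traded away for speed.
* The daylight rule uses solar elevation at the colony, not at each fix;
  at higher latitudes or larger ranges this would need per-fix solar
  positions.
* The equirectangular projection is only appropriate near the equator;
  other colonies need a configurable projection.
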