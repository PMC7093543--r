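---
title: "Body typing for anthropometric cohorts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Body typing for anthropometric cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodytyper)
```

## The problem

Whole-body laser scanners deliver on the order of 150 length, girth and angle
measures per participant. Single indices such as BMI or the waist-to-hip ratio
compress this into one number and lose most of the shape information; at the
other extreme, 150 correlated raw measures are unwieldy for epidemiological
stratification. `bodytyper` implements the middle road: aggregate correlated
measures into a small number of interpretable *meta-measures*, cluster
participants into *body types* in that space, and study how the types relate
to age, physical activity and health factors.

Because individual-level scanner cohorts are typically not publicly
distributable, the package ships a synthetic-cohort generator that reproduces
the statistical structure the analysis relies on. Every pipeline stage is
exercised and validated against this generator.

## The measure pipeline

1. **Selection.** Of 155 scanner outputs, 134 are retained for analysis
   (length/girth/angle measures plus the derived indices BMI and WHtR);
   auxiliary outputs such as volumes and symmetry scores are dropped.
2. **Height normalization.** Each measure is divided by the participant's
   body height, so that shapes rather than statures are compared.
   Dimensionless index columns are exempt from the division.
3. **Z-scoring.** Each height-normalized column is centred and scaled to unit
   variance using the population (1/n) standard-deviation convention —
   arbitrary but fixed; all internal reference values use it consistently.
   Scaling is pooled across sexes by default: pooled scaling is what makes
   male and female mean profiles interpretable as opposite contrasts around
   the cohort mean (a per-sex option exists). The state machine
   (`raw → height_normalized → z_scored`) is enforced; no step can be
   skipped.

Rows with any missing retained measure are dropped with a message; no
imputation or outlier rejection is attempted.

## Meta-measures

`derive_metameasures()` partitions the measures into 13 clusters of
correlated measures. The default route trains a small self-organizing map
(8×8 grid, batch algorithm, shrinking neighbourhood) on the transposed
Z-matrix — measures as items — then cuts the codebook by average-linkage
agglomeration under correlation distance and assigns each measure its
best-matching unit's group. A direct hierarchical route (average linkage on
`1 − r` between measure columns) is available and provably agrees on
well-separated block data; the test suite asserts the agreement.

Two design choices deserve a note:

* **Aggregation rule.** A participant's meta-measure score is the unweighted
  mean of the member measures' Z values — the simplest rule consistent with
  meta-measures expressed in Z units. A correlation-weighted option was
  considered and rejected as an unneeded degree of freedom.
* **Derived indices.** BMI and WHtR belong with the upper-body-girth cluster
  conceptually, but they are *computed from* measures (WHtR is definitionally
  identical to height-normalized waist girth), so clustering them alongside
  the measures distorts the correlation geometry and can fabricate a
  spurious extra cluster. They are therefore excluded from the partitioning
  step and attached afterwards to their maximally correlated cluster
  (`cluster_indices = TRUE` restores the literal behaviour).

Cluster labels A–M are assigned by maximal member overlap with the canonical
groups (shoulder width, upper-body girths, thigh girth, head circumference,
shoulder angle, sideseam length, inseam length, upper-body lengths, arm
length, neck length, neck girth, arm girth, torso length).

`auto_select_k()` chooses the cluster count by maximizing the mean silhouette
width of the measure partition over a range (ties to the smallest k).

## Body types

`assign_body_types()` clusters participants by k-means in meta-measure space
(default k = 15). Random restarts alone proved unreliable on strongly
clustered data — they fall into local optima that split one true cluster
while merging two others — so the search additionally seeds one run from the
centroids of a Ward-linkage cut and keeps the lowest-inertia solution; the
result is deterministic under a fixed seed. `auto_select_k_types()` applies
the same fitting rule inside a silhouette scan.

Types are labeled by composition: `F` if at least 90% female, `M` if at
least 90% male (the threshold operationalizes "almost exclusively" one sex
and is configurable), `B` otherwise, with indices assigned by increasing mean
member age. Mixed `B` types are split into sex-specific views (`B1F`, `B1M`,
…) for all downstream statistics.

Each type is compared against an **age-matched, sex-specific reference
group**: all same-sex participants within a ten-year window centred on the
type's *median* member age (the centring rule is a design choice; a pooled
per-member ±5 y alternative is available). Features are compared by
two-sided Wilcoxon rank-sum tests rendered as tiered marks (`+`/`-` for
p < 0.1, `++`/`--` for p < 0.01, `+++`/`---` for p < 0.001, direction by
median difference). No multiple-testing correction is applied by default, as
raw tiers are the conventional rendering here; users may apply
`p.adjust` to the returned p values.

## Aging analyses

* `metameasure_age_correlation()` — per-sex Pearson correlations of each
  meta-measure with age.
* `bodygram()` / `delta_bodygram()` — group mean profiles in Z units; the
  Δ-bodygram between the 40–49 and 70–80 year strata flags axes with
  |ΔZ| > 0.2 as pronounced aging changes.
* `incidence_by_age()` — per-sex, per-age-bin percentage of each body type
  (default bin width 5 years; bodygram age strata use decades). Percentages
  in every occupied bin sum to 100.
* `net_incidence_change()` — per type, incidence in the latest minus the
  earliest bin; the per-sex net change reports the sum of positive changes,
  which equals the sum of absolute negative changes because percentages are
  conserved. An alternative rule (half the total absolute change — identical
  under conservation) is exposed by flag because the informal "net change"
  phrasing is ambiguous.
* `smoothed_index_curve()` — LOESS (degree 1, span 0.5, direct surface) of an
  index on age per type, on a one-year grid. Degree-1 LOESS reproduces linear
  input exactly, which the tests exploit; the span is configurable and was
  fixed before any comparisons.

## Similarity links and trajectories

Cross-sectional data cannot observe transitions; the package infers
*candidate* transitions from similarity. All pairwise Euclidean distances in
meta-measure space are computed, the "most similar" pairs are selected, and
their counts are tallied per pair of body types. The selection rule is a
design parameter because "most similar pairs" admits several readings:

* default: union k-nearest-neighbour rule (each participant's m = 3 nearest
  neighbours; a pair links if either side selects the other) — scale-free in
  cohort size; distance ties break by participant order, deterministically;
* alternative: all pairs below a distance quantile (default the 1st
  percentile).

Within-type (diagonal) links are counted but excluded from transition
reporting. Under a homogeneous population randomly split into pseudo-types,
link frequencies are flat across type pairs (the suite verifies χ² goodness
of fit at the 1% level in ≥95% of simulations). `transition_graph()` keeps
the top half of nonzero off-diagonal cells and directs each edge from the
younger to the older type (ties toward higher mean BMI), yielding an edge
list in an age-versus-BMI coordinate frame.

`link_differential_profile()` contrasts the linked members of two types.
Note an intrinsic property: because links connect the most similar
individuals, the profile measures the small step *along* the transition, so
a planted offset between two types is recovered on the correct axis and with
the correct sign but strongly attenuated in magnitude. Tests assert the
former, not the latter.

## Activity and health

The wear-time filter implements the validity rules exactly: a day is valid
with ≥ 18 h wear on weekdays or ≥ 20 h on weekend days (inclusive), and a
participant is eligible with ≥ 8 valid days including ≥ 4 weekdays and ≥ 1
weekend day. Per-participant activity is the mean over valid days (the
per-participant aggregation is a documented choice), summarized per type as
medians and compared to the age-matched reference by rank-sum marks. MET
converts to oxygen uptake at 3.5 ml O₂/kg/min per MET. Prevalences and
medication/smoking percentages are rendered half-up to one decimal, matching
conventional table formatting; "smokers" subsumes current and former smoking,
with the current-only rate reported alongside.

`cross_type_correlation()` (mean MET vs mean BMI across types) is computed
over both sexes' types jointly by default; since the sexes' types may also be
analysed separately, both modes are reachable by subsetting the summaries.

## The synthetic-cohort generator

The generator emulates the structure the analysis assumes, not any real
individual-level data:

* **Marginals** (per sex): height 176 ± 7 / 165 ± 7 cm, weight 86 ± 14 /
  71 ± 14 kg, waist 101 ± 12 / 91 ± 13 cm, steps/day 9683 ± 4011 /
  9903 ± 3682, MET 1.41 ± 0.25 / 1.35 ± 0.24, alcohol 18.8 ± 21.7 /
  5.9 ± 10.0 g/day (zero-inflated), myocardial-infarction history rates
  4.0% / 1.1%, smoking current/former 22.8%/36.0% and 19.4%/20.8%. Ages are
  uniform on 40–80. Calibration is analytic: each measure's latent is
  standardized against the theoretical moments of the mixture (computed on an
  age grid) and mapped through an exact-moment lognormal (girths, weight,
  steps, alcohol — guaranteeing positivity) or linear (lengths) transform, so
  configured means and SDs are recovered up to sampling error at any
  configuration. BMI is deliberately *not* a parameter: the male/female mean
  BMIs of ≈ 28 / ≈ 26 emerge from the height–weight model and are verified
  through the pipeline's own index computation.
* **Correlation blocks.** Measures follow a one-global-plus-one-block factor
  model: within-block correlation 0.8, cross-block 0.2, on the
  height-normalized scale (raw lengths/girths are proportional to height, so
  the template survives normalization exactly; shoulder angles are not
  height-scaled and deviate from the template by < 0.02 at their default
  coefficient of variation). Configurations violating
  `0 ≤ cross ≤ within < 1` are rejected as non-positive-definite.
* **Archetype mixture.** Fifteen body-shape archetypes (6 female, 7 male, 2
  mixed) enter as mean-offset vectors in block space, encoding qualitative
  profiles (massive girths; long slim body and legs; broad neck with short
  legs; …). The block-level variance the mixture contributes is *absorbed
  into* the 0.8 within-block budget (the residual block factor shrinks, with
  a floor at zero), so the planted correlations hold with and without the
  mixture and the marginals stay calibrated. Offset magnitudes carry a global
  `separation` multiplier (default 1.15) chosen once so that neighbouring
  archetypes sit roughly three within-type standard deviations apart —
  making the planted structure recoverable, which is precisely what the
  generator exists to provide. Mixed-sex archetypes receive an *androgyny
  correction*: members of both sexes are pulled to the per-block sex
  midpoint by half the realized normalized dimorphism (computed from the
  registry marginals), which is what keeps androgynous types single clusters
  rather than sex-split pairs.
* **Age structure.** Each archetype has a central recruitment age and an age
  kernel width (narrower for elderly types, whose age distributions are
  narrower), so type incidence shifts along the age range; in addition,
  linear per-block aging slopes (positive for girths, negative for upper-body
  lengths and thigh girth; scaled 1.2× for women and 0.8× for men so female
  measures change more strongly) act within participants. Linearity in age
  is a deliberate simplification — it matches monotone age correlations
  without inventing curvature the model cannot justify.
* **Activity and health.** Participant MET loads negatively on BMI (−0.55)
  and age (−0.35) with empirical per-sex standardization; steps track the MET
  latent (0.8). Day records follow a two-week protocol (10 weekdays, 4
  weekend days) with a configurable invalid-wear fraction (default 0.15).
  Health records are Bernoulli/categorical draws at the configured rates;
  alcohol is zero-inflated with drinker moments solved so the overall mean
  and SD match the configuration exactly.
* **Determinism.** A single integer seed drives the generator; activity and
  health generation use fixed offsets of it. Identical configurations
  reproduce cohorts bit for bit.
* The height–weight correlation is not identifiable from published summary
  tables; it is a free parameter (default 0.5) and no validation target
  depends on its exact value.

**What the generator does not emulate** — and hence what passing tests do not
show about real data: measurement error structure of real scanners,
non-normal tails and skew beyond the lognormal family, nonlinear aging
trajectories, cohort effects (cross-sectional age differences are not
longitudinal change), genuine overlap structure of real body types (planted
archetypes are crisper than reality so that recovery is decidable), and any
real link between shape and infarction history (health outcomes are planted
at the configured rates, not mechanistically tied to shape).

## Numerical choices and degenerate inputs

* Population-SD convention throughout; zero-variance columns are an error
  naming the column.
* Half-up rounding to one decimal for printed percentages (base `round()`
  half-to-even would disagree with conventional table rendering).
* k-means: 25 restarts + Ward-initialized candidate, 100 iterations,
  best inertia; silhouette ties break toward the smallest k; an
  all-singleton measure partition scores silhouette zero.
* Distance ties in the nearest-neighbour rule break by participant order.
* Degenerate rank-sum inputs (all values tied) yield an empty mark with a
  warning rather than an error; empty age bins are missing, not zero;
  an empty transition graph is a warning, not an error.
* Problem sizes used in validation: structure-recovery checks run at
  n = 2000 (measure clustering) and n = 4000 (body typing); property checks
  run at n = 400–800; the null-calibration check uses 100 simulations at
  n = 500.

## Known limitations

* Similarity links are cross-sectional evidence; they suggest, but cannot
  demonstrate, longitudinal transitions.
* The SOM hyperparameters (grid size, schedule, cut rule) are re-derivations
  of a procedure class, not reproductions of any previously trained map.
* Auto-selection of the body-type count by silhouette is only decidable when
  types are genuinely separated; on heavily overlapping real data the
  profile can be flat, and a fixed k chosen on substantive grounds is the
  more defensible route.
* The archetype offset table is documented configuration encoding qualitative
  descriptions, not an estimate of any population's true body-type geometry.

## A worked run

```{r, eval = FALSE}
cfg <- generator_config(n_male = 500, n_female = 500, seed = 17)
res <- run_pipeline(config = cfg, out_dir = "bodytyper_out")
res$types$summary          # per-type size, mean age, sex fraction
res$net_change$F$net       # net female incidence change across the age range
res$graph                  # candidate transitions, youngest -> oldest
```
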