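---
title: "Modeling cyanophycin production in field-grown tobacco: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cyanophycin production in field-grown tobacco}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgpfield)
```

## The problem

Cyanophycin granular polypeptide (CGP) is a biodegradable polymer of
aspartate and arginine that transgenic tobacco can accumulate in its leaves
as a coproduct. Whether field production is worth pursuing hinges on a chain
of quantitative questions: how much CGP a hectare of plants yields, how well
it can be recovered from storable leaf material (sun-dried leaf or silage),
what the crude and fine-chemical revenue per hectare looks like under
uncertainty, and whether consumers would accept products derived from a
genetically modified crop. `cgpfield` implements that chain as composable,
seeded, tested functions, together with a synthetic-data generator that
emulates the field trial so the whole pipeline can run without access to the
original raw measurements (which are not public).

Because the raw field data are unavailable, nothing in this package
*re-analyzes* the original trial. The generator's defaults encode the
published summaries (event means, segregation ratios, extraction
efficiencies, scenario bounds); what the tests establish is that the
*methods* behave correctly on data with exactly that structure.

## The techno-economic model

The core defined computation is revenue per hectare. Deterministically:

- `PR = D × C / 1000` — CGP produced (kg/ha) from planting density `D`
  (plants/ha) and per-plant harvest `C` (g/plant). The default scenario uses
  `D = 22,000` and `C = 4.0`, giving `PR = 88` kg/ha.
- `Y = EY × PY` — total yield factor from extraction yield `EY` and
  purification yield `PY`, combined componentwise over (min, max, mode).
- `E = PR × Y` — CGP extracted (kg/ha); `R = E × P` — revenue (USD/ha) at
  price `P` (USD/kg).

Two numerical conventions matter for reproducing the printed scenario
table. First, display rounding is half-away-from-zero (`round_half_up()`):
banker's rounding would turn `Y_min = 0.55 × 0.70 = 0.385` into 0.38 rather
than the printed 0.39. Second, revenue is computed from the *unrounded*
extracted mass: `33.88 × 275 = 9,317` USD/ha, whereas the rounded mass would
give `34 × 275 = 9,350`. Only this order reproduces the printed row.

Under uncertainty, `EY`, `PY` and `P` are modeled as triangular
distributions — the standard minimal-information choice when only a minimum,
maximum and most-likely value are available:

- `EY ~ Triangular(0.55, 0.97, 0.90)`: the bounds are the measured
  extraction efficiencies of dried leaf (55%) and silage (97%).
- `PY ~ Triangular(0.70, 0.93, 0.90)`: purification requirements differ by
  application; min/max/mode are estimates.
- `P ~ Triangular(275, 550, 330)` USD/kg: the band of reported microbial
  CGP production costs, used directly as the crude-price distribution (the
  literature figures are quoted in EUR but applied as USD bounds without
  conversion, as in the source scenario).

`run_monte_carlo()` draws the three factors independently per repetition
(no correlation structure is implied by the scenario), forms
`E = PR × EY × PY` and `R = E × P`, and reports the
Min/1st-Qu/Median/Mean/3rd-Qu/Max summary. Sampling is by inverse CDF from a
single seeded uniform stream; quartiles use the linear-interpolation
convention (`quantile` type 7 — the reference summary's convention is
unstated, but at 100,000 repetitions convention differences are far below
sampling noise). The closed-form triangular mean `(a + b + c)/3` gives
independent oracles: `E[E] = 88 × 0.8067 × 0.8433 = 59.87` kg/ha and
`E[R] = 59.87 × 385 = 23,048` USD/ha, which the simulation must approach at
`n = 100,000`.

```{r}
scenario_table(scenario_inputs())
run_monte_carlo(scenario_inputs(), n_reps = 20000, seed = 1)
fine_chemical_revenue(60, 3300)  # fine-chemical scenario, USD/ha
```

## Quantification

SEC quantification rests on a linear calibration,
`area (mAu·mL) = 158.62 × concentration (mg/mL) + 2.6371` (R² = 0.99,
0.5-5 mg/mL standards). `integrate_peak()` implements trapezoidal
integration — the bench workflow is manual peak integration, which is not
algorithmic, and the trapezoid rule on the recorded grid is the natural
programmatic counterpart. Grid-step sensitivity is bounded in the tests: a
Gaussian peak integrated at step ≤ σ/10 matches its analytic area to 0.1%.
Inversion clamps areas at or below the intercept to zero concentration with
a `below_limit` flag rather than returning negative values. Bradford
quantification reuses the same machinery with µg/mL units; its calibration
coefficients are experiment-specific inputs (none are published).

The synthetic chromatogram generator places a single Gaussian peak on a
flat baseline and rescales it so its trapezoidal area on the actual grid
equals the calibration prediction *exactly*; round-tripping
concentration → trace → area → concentration is therefore limited only by
floating point (tested at relative error < 1e-6), and a zero-concentration
trace still integrates to the intercept 2.6371.

Unit bookkeeping: `percent_dw(c, V, m) = 100 × c·V / (1000·m)` converts an
extract concentration (mg/mL), extract volume (mL) and sample dry mass (g)
to % dw; the bench scale is 30 mL from 1.5 g, so 1 mg/mL ↦ 2% dw.
`cgp_per_plant(b, f) = b × f / 100` mirrors the event table; at one-decimal
half-up rounding five of the six published rows equal the product of their
printed biomass and CGP fraction, while event 549 (31.9 g × 10.3% = 3.3 g
vs printed 4.0 g) does not — `check_table_consistency()` flags it, and the
generator anchors to the product definition.

## Segregation classification

Selfed hemizygotes segregate 1:2:1, so 75% of seedlings are
kanamycin-resistant for one integration locus and `1 - 0.25^k` for `k`
unlinked loci. The published rule gives two anchors: ~75% resistant means
one locus, anything above 80% means multiple. The rule as printed is not
total (it does not say what happens between the anchors or far below 75%),
so `classify_loci()` operationalizes it as a window: `single_locus` iff the
fraction is ≤ 0.80 *and* a 1-df chi-square goodness of fit against 3:1 is
not rejected at α = 0.05 (without continuity correction by default; a Yates
flag exists); fractions above 0.80 are `multiple_loci`; zero resistant is
`non_transgenic`; everything else is `inconclusive`. At 150 seeds this
window is the count range 103-120, which a true single-locus event hits
with probability 0.905 — the classifier's per-event accuracy is therefore
~90%, a property the tests measure directly. Homozygosity calls from T2
counts require zero sensitive seedlings at n ≥ 30 (an all-resistant plate
of 10 occurs with probability ~0.056 under 3:1, too weak to call).

## Extraction accounting

The isolation protocol (maceration, acid extraction at pH < 1.3,
centrifugation/decanting, precipitation at pH 4.0-4.5, redissolution,
second precipitation) is modeled as a chain of per-step recovery fractions
with a mass-balance ledger; pH values are carried as metadata only. Only
end-to-end efficiencies are published (dried leaf 55% ± 9%, silage
97% ± 13%, relative to the lyophilized laboratory protocol), so the default
protocols attribute the entire material-dependent loss to the release step:
ensiling degrades cell walls and keeps CGP accessible, while drying locks
it in the tissue — the package's own reading of the observed difference.
Per-step recoveries are configuration inputs for anyone with better
resolution. `extraction_efficiency()` is the published statistic:
method yield over laboratory yield, in percent.

## Trial statistics

`select_test()` reproduces the gating logic: Shapiro-Wilk per group, Levene
(classic, mean-centered) across groups, then parametric (t/ANOVA), Welch,
or rank-based (Wilcoxon/Kruskal-Wallis) tests, two-sided, α = 0.05. The
source protocol's wording inverts the usual reading of both gate p-values
("p ≤ 0.05 defined as normally distributed"/"defined as homogenous") —
almost certainly a typo, but reproducible here via
`convention = "paper_literal"`; the default is the standard convention.
Pairwise comparisons reuse the omnibus test family, unadjusted by default
(no multiple-testing procedure is stated; Holm is available), and
`letter_display()` renders them as significance classes via the
insert-and-absorb algorithm. Correctness is established by brute force: for
every flag matrix with k ≤ 4 groups, two groups share a letter exactly when
they are not significantly different.

## The synthetic trial

`generate_trial()` emulates the field season: 4 randomized complete blocks
× (6 transgenic events + near-isogenic control) × 27 plants (3 rows of 9)
per 12 m² plot. Design choices where the publication gives only summaries:

- Genotypes within transgenic plots are 1:2:1 null:hemizygous:homozygous
  (the trial planted selfed-hemizygote offspring); null segregants and
  controls have CGP exactly 0.
- Biomass and seed yield are zero-truncated normal at the event means; no
  distributional form is published, and mean ± sd summaries make the
  truncated normal the least-structured match. Per-event sds are not
  printed, so the control's coefficients of variation (14.7/42.3 for
  biomass, 2.7/8.1 for seed) are applied to every event mean.
- Carrier CGP content is lognormal (positive, right-skewed, as content
  measurements are) with CV 0.3 by default; only event means are published.
- Homozygous carriers draw from the same content distribution as
  hemizygous by default; a `dose_effect` factor exists because the data are
  silent on dosage.
- Fresh weight is dry weight / 0.094, from the reported silage dry-matter
  share (9.4%).
- A `yield_penalty` factor (default 1) can depress carrier biomass; field
  biomass showed no significant penalty, so the default is none.

The generator does *not* model spatial heterogeneity (the plot-position
growth failures visible in the aerial imagery), ensiling biochemistry, or
year/site effects. Consequently, green tests demonstrate correct method
behavior under the published statistical structure — not robustness to
field artifacts absent from that structure.

## Conjoint analysis

The consumer-acceptance module implements choice-based conjoint for the
food-wrapping application: 12 tasks per respondent, four full profiles plus
a "no wrapping" opt-out per task. Attributes default to material
(conventional, paper, GM bioplastic, natural), antibacterial functionality,
environmental certification and a surcharge; surcharge levels are only
partially enumerated in the source and are configuration. Effects coding is
the default (conventional CBC practice; the source does not state its
coding), with the opt-out carrying its own alternative-specific constant.
Designs are randomized and level-balanced by dealing levels evenly over the
profile slots, with within-task duplicate profiles repaired by redrawing.

Estimation is a hierarchical Bayesian multinomial logit: respondent-level
part-worth vectors β_i ~ N(μ, Σ), choices multinomial-logit given β_i.
Priors are weakly informative — μ ~ N(0, 10² I), Σ ~ Inverse-Wishart(p + 2,
I) — since none are published. The sampler combines conjugate Gibbs updates
for μ and Σ with a joint random-walk Metropolis step per respondent whose
proposal covariance is the current Σ scaled by a single step size, adapted
during burn-in toward ~30% acceptance and frozen afterward (so the
post-burn-in chain is a valid fixed-kernel MCMC). Defaults in the recovery
benchmarks are 200 respondents and 1,200-1,500 iterations with half
discarded — enough for this model's dimension (9 parameters), as the
recovery tests verify.

No utility estimates are published to compare against, so this module's
validation is property-based: on synthetic data with a true GM-material
population part-worth of +0.8 and respondent heterogeneity sd 0.5, the 95%
posterior interval must be positive (checked over 20 seeded replicates, as
the published finding — positive and significant GM utilities — is a sign
claim); on zero-signal data the intervals must cover zero at their nominal
rate; with near-zero heterogeneity the population mean must collapse to the
pooled maximum-likelihood fit, whose Newton implementation is itself checked
against finite-difference gradients and sampling theory.

## Pipeline and reproducibility

`run_pipeline()` executes the stages in dependency order under a single
seed, fanned out to fixed per-stage child seeds so that toggling one stage
never shifts another's stream. Every stochastic function takes an explicit
integer seed and restores the caller's RNG state. `write_report()` emits
JSON (validated against the schema shipped in `inst/schema/`) plus a plain
text rendering of the scenario and Monte Carlo tables; every report carries
a provenance block (package version, seed, config hash). Problem sizes used
throughout the examples and tests — 100,000 Monte Carlo repetitions, 150
seeds per germination assay, 1,000 replicate events per classifier check,
200 respondents × 12 tasks for the conjoint benchmarks — are the study's
own scales.

## Known limitations

- The economic model is revenue-only: cultivation, extraction and capital
  costs are outside the published simulation and outside this package.
- The segregation window between the 75% and 80% anchors is this package's
  construction (the source states no procedure for it); sensitivity to the
  α of the goodness-of-fit gate is easy to probe via the `alpha` argument.
- Event 549's printed per-plant CGP cannot be reconciled with its biomass
  and content; the package takes the product definition and flags the row.
- The conjoint module covers the wrapping experiment's structure;
  willingness-to-pay transforms, country-level comparisons and survey
  weighting are out of scope.
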