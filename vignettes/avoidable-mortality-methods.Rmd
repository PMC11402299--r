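---
title: "Methods: avoidable mortality, counterfactual life tables and age-cause decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: avoidable mortality, counterfactual life tables and age-cause decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avoidmort)
```

`avoidmort` estimates how much of the gap in life expectancy at birth (e0)
and in lifespan disparity (e-dagger) between two blocs of countries is
attributable to avoidable mortality, and attributes the potential gains to
age groups and cause-of-death groups. This vignette is the package's own
account of the science: the models, the conventions chosen where demographic
practice offers several, the tunable parameters, what the synthetic-data
generator does and does not emulate, and the known limitations.

## 1. Data model

The working unit is the **rate surface**: a matrix of death rates
(deaths per person-year) for one (country, year, sex) stratum, with one row
per age group of the 19-group abridged grid (0, 1–4, 5–9, ..., 80–84, 85+)
and one column per cause. Surfaces are built from long- or wide-format
WHO-Mortality-Database-style count files; death counts are divided by
mid-year population, used here as the person-years of exposure. Two
conventions keep the cause axis *closed* — cause-specific rates always sum
to the all-cause rate in every age group:

* deaths not assigned to any listed cause (the all-cause total minus the sum
  over causes) go to a reserved `OTHER` column, and
* `split_avoidable()` reallocates every ICD-10 column onto the fixed axis
  {preventable, treatable} × 14 cause groups + `non_avoidable`, conserving
  each age group's total exactly.

Closure is what makes the counterfactuals well defined: deleting or
substituting category columns changes the all-cause schedule by exactly the
mass moved, and nothing else.

Ill-defined or unlisted causes are a genuinely open point in this kind of
analysis; the package's choice is to treat them as a dedicated non-avoidable
category rather than redistribute them proportionally, because it keeps the
closure property exact and testable. Users who prefer redistribution can
pre-process the panel.

## 2. Avoidability classification

An `avoidability_map()` is a table of ICD-10 patterns (single 3-character
codes, 3-character ranges, or exact 4-character refinements that shadow
their 3-character parent), an age window, fractional allocations to the
preventable and treatable categories, and one of 14 reporting cause groups.
The age cutoff defaults to 74: deaths at 75+ are never avoidable, and the
abridged grid is aligned so no group straddles the cutoff (a straddling
group raises an error rather than a silent misclassification).

The packaged default list (`default_avoidability_map()`) is a best-effort,
editable approximation of the OECD/Eurostat avoidability list — it covers
the major chapters with plausible category assignments but is *not* a
reproduction of any authoritative revision, and analyses that must match a
specific revision should load their own CSV. Causes listed under both
categories default to a 50/50 fractional split, overridable per entry; the
authoritative split is not published, so any choice here is a convention and
is treated as one. The 14 group labels are configurable; the default set
names the groups that dominate this literature (cardiovascular,
cerebrovascular, cancer, injuries, alcohol- and drug-related, ...).

The test-suite and the synthetic generator use a 10th-scale
`toy_avoidability_map()` over eight representative codes so that nothing
external is needed to build or validate the package.

## 3. Abridged life tables, e0 and e-dagger

Given age-specific all-cause rates m_x on groups of width n_x:

* closed intervals: q_x = n·m_x / (1 + (n − a_x)·m_x), the standard
  conversion under the assumption that those dying in the interval live
  a_x years of it on average;
* a_x = n/2 for all closed intervals except age 0, where an
  Andreev–Kingkade-style rule driven by m_0 is used (infant deaths cluster
  early in the first year, and the rule adapts to the mortality level);
* the open interval is closed with L = l/m and e = 1/m (exponential tail);
* radix l_0 = 100 000 (cancels in every reported measure);
* rates of exactly 0 in closed intervals are allowed (q = 0); a zero rate in
  the open interval is an error because the table cannot be closed;
* q is capped at 1; schedules that reach the cap (m_x > 0.4 in a 5-year
  group) are far outside the human range this package targets, and the
  decomposition should not be trusted across such schedules (section 5).

Lifespan disparity is computed from the table columns as
e† = (1/l_0) Σ_x d_x ē_x, where ē_x is the remaining life expectancy at the
mean age at death within the interval, interpolated consistently with the
a_x convention: ē_x = e_{x+n} + (1 − a_x/n)(e_x − e_{x+n}) for closed
intervals and ē = e_x for the open one. Two closed-form checks pin these
conventions down: a constant hazard m across all groups gives e_0 = 1/m
exactly (the m→q conversion preserves m = d/L identically), and e† = e_0
within 1% (for exponential lifetimes the remaining expectancy is constant);
a schedule with all deaths in the open group gives e† = 1/m_open.

The exact a_0 and open-interval treatments differ slightly across published
life-table systems and affect e_0 at the second decimal; results here are
therefore validated against the package's own exact-fraction oracle, not
against any external table.

## 4. Counterfactual scenarios

Two families of counterfactuals, applied to avoidability-split surfaces:

* **Deletion** (`delete_causes()`): the selected categories' rates are set
  to zero in every country, m′_x = m_x − Σ_c m_{c,x}. This is direct rate
  subtraction under the assumption of independent causes, *not* Chiang's
  associated-single-decrement construction: the scenario is "these deaths
  are averted", and subtraction composes additively (deleting preventable
  then treatable equals deleting avoidable in one step — a tested
  property). With categories {preventable}, {treatable} or both, plus the
  status quo and the three substitutions below, the seven standard
  scenarios of `table2_scenarios()` result.
* **Substitution** (`substitute_rates()`): NMS surfaces have their selected
  category rates set *equal* to a reference; EMS surfaces pass through. The
  reference (`reference_rates()`) is the unweighted mean over the EMS
  countries present in that year and sex — each country one vote, because
  the bloc comparison is a comparison of countries, not of persons; a
  population-weighted mean is available as a config switch for sensitivity.
  Matching is two-sided by default (an NMS rate already below the reference
  is raised to it, which is what "set equal to the average" means);
  `one_sided = TRUE` restricts to reductions. Both behaviours exist because
  published descriptions of this scenario type rarely say which was used.

Ages above the avoidability cutoff are untouched by construction in both
families — avoidable columns carry no mass there — and the pipeline tests
assert the 75+ rates are bit-identical across scenarios. For every stratum
and scenario both e0 and e† are computed from the transformed surface.

## 5. Linear integral decomposition

`horiuchi()` attributes a difference f(θ^to) − f(θ^from) in a scalar summary
of a parameter vector to the individual parameters by discretising the line
integral of the gradient along the straight path between the endpoints: the
path is cut into N equal steps, and at each step midpoint each changing
parameter is moved alone by ± half its per-step increment (a centred
difference, which cancels first-order interaction bias). For surfaces,
the parameters are the age × cause rate cells and f is e0 or e† of the
row-sum schedule.

Numerical choices:

* **n_steps defaults to 20**, standard practice for this estimator. The
  discretisation error — |Σ contributions − Δf| — scales as 1/N²
  (verified empirically in the tests) with a constant that grows roughly
  with the cube of the contrast. For scenario-sized contrasts (a few years
  of e0) the error at N = 20 is of order 1e−6…1e−5 years; for extreme
  contrasts of 8+ years it can reach a few 1e−4. If you decompose very
  distant surfaces, raise `n_steps`.
* **Straight-line path in rate space**, matching the additive
  rate-subtraction scenarios (the scenario path *is* linear in rates);
  `path = "log"` integrates on the log-rate scale as a sensitivity option
  and requires changing cells to be positive at both endpoints.
* Cells equal at both endpoints are skipped and contribute exactly 0;
  swapping the endpoints negates every contribution (path symmetry).
* The reported `total` is always the directly computed f(to) − f(from), so
  the conservation error is visible, never hidden.

`decompose_scenario_gain()` wires this to the pipeline: status quo versus
counterfactual for one stratum, with gains in e0 appearing as positive
contributions. `run_pipeline()` additionally decomposes pooled (bloc-mean)
surfaces per sex, bloc, scenario and measure.

## 6. The synthetic-data generator

`sim_config()`/`simulate_panel()` generate WHO-MDB-shaped panels with known
truth. The design mirrors the structure of the real analysis problem:

* two blocs (A plays the EMS role, B the NMS role) of
  `countries_per_bloc` countries each, a multi-year panel (default
  2005–2019), both sexes;
* per-sex Gompertz–Makeham total hazard μ(x) = a·e^{bx} + c, evaluated at
  interval midpoints (hazards constant within abridged intervals; the open
  group uses its start + 5 years). The defaults
  (male a = 2.2e−5, b = 0.097, c = 7.5e−4; female a = 1.2e−5, b = 0.100,
  c = 6.0e−4) give baseline e0 of about 78 and 83 years — a plausible
  European scale, recorded here as configuration, not asserted against any
  external source;
* an age-dependent cause mix over eight toy ICD-10 codes plus an unlisted
  ill-defined code (R99): cardiovascular and cerebrovascular shares rise
  with age, injuries fall, cancers and alcohol-related causes peak in
  mid-life. The shapes are qualitative, chosen to make age × cause
  decompositions non-trivial;
* the **avoidable excess**: in bloc B the avoidable fraction of each
  selected cause is multiplied by `avoidable_excess` (default 1.5, giving
  status-quo e0 gaps of roughly 2–2.5 years) within a configurable age
  window. Because the multiplier acts on the avoidable fraction only, the
  blocs are identical in every non-avoidable cell — which is exactly what
  makes ground-truth recovery assertions sharp: the substitution scenario
  must close the bloc gap to numerical precision, and the decomposition
  must place the gap in the injected cells;
* deaths are `population × rate` exactly (`sampling = "expected"`) or
  Poisson draws around it (default), fully reproducible from `seed`. The
  default populations (100k infants, 300–500k per older group, ~9M total)
  give count magnitudes typical of a mid-size European country.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: no year trends or period shocks, no migration
or cohort effects, no between-country heterogeneity within a bloc beyond
Poisson noise, no miscoded or ill-defined-cause patterns beyond a constant
R99 share, and no correlation between avoidable and non-avoidable levels.
Tests on this generator validate the *machinery* (closure, conventions,
conservation, recovery); they cannot validate the epidemiological content
of an avoidability list.

Three countries per bloc is the default because expected-mode blocs are
internally homogeneous — additional identical countries add computation,
not information; Poisson-mode analyses wanting realistic bloc sizes can
raise it.

## 7. Aggregation and reporting

Bloc summaries average the per-stratum e0 and e† over the (country, year)
cells present for each bloc — unweighted, each country-year one vote,
consistent with the unweighted reference; countries with partial coverage
(e.g. Ireland from 2007 in the packaged EU grouping) simply contribute
fewer cells. Differences are NMS minus EMS. Values are carried at full
precision throughout and rounded to two decimals only in the rendered
Markdown table, whose seven-row-per-sex layout is fixed and validated.

## 8. Problem sizes and runtime

The shipped test-suite and acceptance script are sized for a single CPU:
the acceptance run uses the full default conditions (3 countries per bloc,
15 years, both sexes, Poisson sampling — 180 strata, seven scenarios, 48
pooled decompositions) and completes in well under a minute; the
property-based decomposition checks run 100 randomised bloc contrasts at
n_steps = 20. These sizes are the package's own validation choices; all of
them scale linearly in strata and in active decomposition cells.

## 9. Known limitations

* The avoidability list shipped is an approximation; substantive
  conclusions require the user's own authoritative list revision.
* Cause deletion assumes independence of causes of death; competing-risk
  dependence would make "averting" less than the deleted mass.
* Mid-year population is used as exposure; no graduation or smoothing of
  rates is performed, and no confidence intervals are produced (the
  pipeline is deterministic given counts).
* The abridged grid cannot see within-interval age detail; e† in particular
  inherits the a_x interpolation inside intervals.
* The decomposition is exact only in the N → ∞ limit; see section 5 for
  the error scaling.
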