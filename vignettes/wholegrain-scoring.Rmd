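---
title: "Scoring whole grains in a points-based nutrient profile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring whole grains in a points-based nutrient profile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainscore)
```

## The model

Nutri-Score is a five-class (A–E) front-of-pack label computed from the
FSA-NPS points system. Per 100 g of food, each *unfavourable* component —
energy (kJ), saturated fat (g), total sugar (g), sodium (mg) — earns 0–10
points from a category-specific band table; each *favourable* component —
fibre (g), protein (g), and the combined fruit/vegetable/nut/legume/
walnut–rapeseed–olive-oil content (FVNLO, %) — earns 0–5 points (FVNLO
0–10 for beverages). The nutritional score is

```
score = (energy + satfat + sugar + sodium points)
        - (FVNLO + fibre + [protein] points)
```

an integer in [-15, 40]; *lower is healthier*. Protein is bracketed because
of the protein-counting rule: once the unfavourable total reaches 11
points, protein counts only for foods holding category-maximum FVNLO points
(cheese is exempt). Four categories modulate the band tables: solid foods,
beverages (whose energy and sugar tables are much tighter and whose FVNLO
reaches 10 points), cheese, and added fats (scored on the saturated-to-total
fat ratio instead of absolute saturated fat). Classes follow fixed score
ranges — foods: A ≤ -1, B 0–2, C 3–10, D 11–18, E ≥ 19; beverages: A is
reserved for water, B ≤ 1, C 2–5, D 6–9, E ≥ 10.

Whole grains — despite being a headline recommendation of essentially every
national dietary guideline — earn nothing in this system beyond their
incidental fibre. The modification implemented here adds a fifth favourable
component: up to **-5 points** on a non-linear sliding scale of whole-grain
content expressed as a percentage of the food's *dry matter*,

```
wg_pct_dry = 100 * wholegrain_g / (100 - water_g)
```

with `wholegrain_g` the grams of whole-grain ingredients on a dry basis per
100 g of food as consumed. The cut-offs follow the Whole Grain Initiative
food definition: below 25 % (the minimum for any front-of-pack whole-grain
claim) nothing is awarded; 100 % always earns the full -5; the larger step
sits at 50 %, the "whole-grain food" threshold, to reward crossing it. The
modification applies to solid foods only, and class thresholds are left
unchanged, so `modified_score = original_score + wg_pts` lies in [-20, 40]
and is never worse than the original.

### Band-table semantics and numerical choices

* Thresholds are exclusive on the favourable side: a content exactly equal
  to a printed threshold stays in the lower-points band ("≤ 27 g sugar ↔
  ≤ 5 points"). Beverage energy/sugar tables are stored in their published
  "at most" form; both conventions resolve to the same inclusive-upper-edge
  lookup. The added-fat ratio table is published with the opposite edge
  ("< 10 → 0") and is handled as such.
* No rounding is applied to nutrient inputs before band lookup; scores are
  exact integers, so no floating-point tolerance is needed downstream of
  the lookup.
* Two fibre band sets ship: AOAC (default) and NSP/Englyst
  (`fibre_method = "nsp"`), because some national databanks only report
  Englyst fibre.
* The printed two-row summary of the whole-grain scale does not pin every
  intermediate score unambiguously; the default mapping is ≥ 25 % → -1,
  ≥ 50 % → -3, 100 % → -5 (preset `"wgi"`), with the alternative reading
  -2/-4/-5 shipped as preset `"wgi_steep"`. Both satisfy the anchors
  (< 25 % → 0, 100 % → -5) and are non-increasing; either can be replaced
  via the YAML config key `wholegrain: bands`.
* Whole-grain points are awarded independently of the protein-counting
  rule's unfavourable-total condition; coupling them to a detrimental-point
  cap is a design alternative we deliberately leave to configuration-level
  experimentation.
* `wg_pct_dry` is capped at 100 to absorb rounding in source composition
  tables (dry-basis whole-grain grams occasionally exceed computed dry
  matter by a hair).

## Whole-diet scores

Applied to a single survey day, the per-food scores aggregate to a
whole-diet nutritional score as the energy-weighted mean of the consumed
foods' scores, `sum(FS_i * E_i) / sum(E_i)`. Water and other zero-energy
items carry no weight and are excluded beforehand; persons whose entire day
consists of such items are dropped (and reported). Whole-grain exposure is
summarised as grams of whole grain per 10 MJ of energy per day, an
energy-adjusted density that is comparable across big and small eaters.
Both statistics are invariant to splitting an intake row into two rows of
the same food with the same totals, and the whole-diet score always lies in
the convex hull of the consumed foods' scores.

## Evaluation statistics

Four analyses compare the algorithms, mirroring how nutrient-profile
modifications are typically audited:

* **Component–score Spearman correlations** between each component's
  content and the original/modified food score, overall and per food group,
  water items excluded. Rho is computed as Pearson on average ranks; the
  p-value uses the t approximation, switching to exact permutation below
  n = 10 where the approximation is poor.
* **Class transitions**: a 5×5 original-by-modified class table plus counts
  and percentages of score- and class-changers (water excluded from
  denominators). Because the modification only adds favourable points, all
  off-diagonal mass lies towards better classes.
* **Diet-quality correlation**: Pearson r between whole-diet scores and an
  externally supplied per-person diet-quality index (higher = better diet),
  so the expected sign is negative.
* **Whole-grain quantile analysis**: persons split into non-consumers and
  type-7 quartiles of whole-grain density among consumers (a density
  exactly on a cut point goes to the lower quartile — deterministic,
  standard, and stable under ties), with per-group mean scores and a
  one-way ANOVA across groups.

## What the synthetic data emulate — and what they do not

`ns_simulate()` generates a food-composition table and a one-day intake
survey with the statistical structure these analyses assume: per-group
truncated log-normal nutrient distributions over grain, produce, animal,
snack, beverage, cheese and added-fat groups; a grain group whose
whole-grain content mixes point masses at 0 and 100 % with spread over the
25/50 % bands (edge cases pinned exactly); zero-energy water items; heavily
zero-inflated whole-grain intake (about half of persons are designed
non-consumers, default `wg_consumer_fraction = 0.5`); and a pseudo
diet-quality score.

Two generator choices matter for interpretation:

* **Composition gradient.** Whole-grain foods are made genuinely healthier:
  fibre rises by `wg_fibre_effect` (default 0.06 g per percentage point of
  dry-matter whole grain) and sugar falls with whole-grain share. This is
  the real-world association that gives the modification something to
  detect; setting the effect to 0 removes it, and the measured
  whole-grain/score correlation strengthens monotonically with it.
* **Diet quality.** The pseudo index is a noisy monotone function of a
  person's latent diet healthfulness, defined as the negated modified
  whole-diet score plus an explicit whole-grain-adherence term
  (0.5 × the standardised whole-grain density) — guideline-based indices
  score whole-grain intake directly, so an index that rewards whole grain
  beyond what any food-level score captures is the realistic case. The
  mixture is rescaled so the Pearson correlation with the modified
  whole-diet score hits `dq_target_r` (default -0.6) in expectation.

Defaults are 500 foods and 2000 persons, sizes at which the full
generate → score → aggregate → evaluate pipeline runs in a few seconds and
correlation estimates carry a standard error of about 0.014, small enough
for parameter-recovery checks at three standard errors.

What passing tests on these data do **not** show: the generator draws
independent foods and independent persons, has no survey design, no
under-reporting, no recipe structure, no country-specific food coding, and
a single grain-specific group. Numeric results from national databases
(country correlation tables, class-shift percentages) are therefore out of
reach by construction; what the tests establish is that the engine computes
the algorithm exactly (band edges, rule interactions, ranges), that the
statistics match brute-force oracles, and that known generator structure is
recovered.

## Known limitations

* The 2023 revision of the algorithm (and later red-meat/sweetener rules)
  is out of scope; the engine implements the 2017-era tables the
  whole-grain modification was designed against.
* FVNLO percentage is taken as an input field; deriving it from recipes is
  upstream of this package.
* One day of intake per person; no usual-intake modelling, no survey
  weights.
* Item exclusions (alcohol, supplements, medical beverages) are honoured
  via a boolean `excluded` column supplied by the data provider, not by
  name matching.
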