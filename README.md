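# grainscore

Nutrient-profiling systems behind front-of-pack labels such as Nutri-Score
score foods on energy, saturated fat, sugar and sodium against fibre,
protein and fruit/vegetable content — but award nothing for whole grains,
even though dietary guidelines worldwide single them out. `grainscore` is a
configurable R implementation of the Nutri-Score (FSA-NPS derived) points
algorithm together with a whole-grain modification, for nutrition
researchers who want to score food-composition tables and dietary-survey
days under both algorithms and quantify what the modification changes.

## The algorithm

Per 100 g, each unfavourable component earns 0–10 points and each
favourable component 0–5 (FVNLO 0–10 for beverages) from category-specific
band tables (solid food / beverage / cheese / added fat):

```
score    = (energy + satfat + sugar + sodium pts)
           − (FVNLO + fibre + [protein] pts)          ∈ [−15, 40]
modified = score + wg_pts                              ∈ [−20, 40]
```

Protein is dropped once the unfavourable total reaches 11 points unless the
food holds maximum FVNLO points (cheese exempt). The whole-grain component
`wg_pts` applies to solid foods only, on a non-linear sliding scale over
the whole-grain percentage of food **dry matter**
(`100·wholegrain_g/(100−water_g)`): below 25 % → 0, ≥ 25 % → −1,
≥ 50 % → −3, 100 % → −5 (the 50 % step marks the "whole-grain food"
definition; an alternative −2/−4/−5 preset and fully custom bands are a
config key away). Classes A–E keep their original boundaries (foods:
A ≤ −1, B 0–2, C 3–10, D 11–18, E ≥ 19; beverages: A = water, B ≤ 1,
C 2–5, D 6–9, E ≥ 10), so added whole-grain points can only ever improve a
food's class.

At the intake level, a person-day's whole-diet nutritional score is the
energy-weighted mean of consumed foods' scores, `Σ FSᵢEᵢ / Σ Eᵢ`
(zero-energy items excluded), and whole-grain exposure is grams of whole
grain per 10 MJ of energy. Evaluation helpers compute component–score
Spearman correlations, class-transition tables, Pearson correlation with an
external diet-quality index, and ANOVA across non-consumers and quartiles
of whole-grain density.

## Worked example

```r
library(grainscore)

foods <- data.frame(
  food_id  = c("oats", "muesli", "white_bread", "cola"),
  name     = c("rolled oats", "fruit muesli", "white bread", "cola"),
  group    = c("grains", "grains", "grains", "beverages"),
  category = c("solid_food", "solid_food", "solid_food", "beverage"),
  is_water = FALSE,
  energy_kj = c(1590, 1400, 1050, 180),
  satfat_g  = c(1.5, 1.5, 0.4, 0), totalfat_g = c(8.5, 6, 1.6, 0),
  sugar_g   = c(1.1, 13, 3.8, 10.6), sodium_mg = c(2, 170, 450, 10),
  fibre_g   = c(10.4, 4.5, 2.9, 0), protein_g = c(13.3, 5, 9.4, 0),
  fvnlo_pct = c(0, 18, 0, 0),
  wholegrain_g = c(89, 50, 0, 0), water_g = c(9, 8, 38, 89))

scored <- ns_score_foods(foods)
scored[, c("food_id", "a_total", "c_total", "wg_pct_dry", "wg_pts",
           "original_score", "modified_score",
           "original_class", "modified_class")]
```

```
     food_id a_total c_total wg_pct_dry wg_pts original_score modified_score
        oats       5      10   97.80220     -3             -5             -8
      muesli       8       7   54.34783     -3              1             -2
 white_bread       7       8    0.00000      0             -1             -1
        cola      14       0    0.00000      0             14             14
 original_class modified_class
              A              A
              B              A
              A              A
              E              E
```

Reading the muesli row: 8 unfavourable points (4 energy, 1 saturated fat,
2 sugar, 1 sodium) against 7 favourable (4 fibre, 3 protein; 18 % FVNLO is
below the first 40 % band) give an original score of +1, class B. Its 50 g
of dry-basis whole grain is 54 % of the food's 92 g dry matter — past the
50 % "whole-grain food" cut-off — earning −3 points: the modified score is
−2 and the food moves from class B to A, the shift the modification is
designed to produce. The fully whole-grain oats improve from −5 to −8 but
were already class A; the refined bread and the beverage are untouched.

From intakes, `ns_score_diets()` aggregates person-days and
`ns_component_correlations()`, `ns_class_transition()`,
`ns_diet_quality_correlation()` and `ns_wg_quantile_analysis()` compare the
two algorithms. `ns_simulate()` generates seeded synthetic
food-composition and one-day survey tables (with known whole-grain
structure and a diet-quality index at a configurable target correlation)
so the whole pipeline is testable without national databases — see the
vignette in `vignettes/wholegrain-scoring.Rmd` for the generator's design
and its limits.

## Command line

An installed script exposes the pipeline:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "grainscore.R", package = "grainscore"))')
Rscript $CLI simulate    --seed 1 --out-dir run
Rscript $CLI score-foods --foods run/foods.csv --out-dir run
Rscript $CLI score-diets --foods run/foods.csv --intakes run/intakes.csv --out-dir run
Rscript $CLI evaluate    --foods run/foods.csv --intakes run/intakes.csv \
                         --dietquality run/dietquality.csv --group-col group --out-dir run
```

`--config config.yaml` overrides band tables, class thresholds and
whole-grain bands; `--fibre-method aoac|nsp` selects the fibre convention.
Exit code is 0 iff no hard error occurred; failures emit a JSON error
summary on stderr.

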