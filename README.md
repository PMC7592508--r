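# dietfootprint

Links individual-level **diet quality** to **food loss and waste** and to
the **agricultural resources** needed to produce what people demand.

The package is aimed at nutritional epidemiologists and food-system
researchers who want to ask: as diet quality rises across a population,
what happens to the mass of food demanded — consumed, wasted, inedible,
lost at retail — and to the land, fertilizer, pesticides and irrigation
water behind it? It implements the full analysis chain as tested, reusable
functions, exercised end to end on seeded synthetic survey data, with
numbered driver scripts under `analysis/` reproducing the workflow.

## The model in brief

**Diet quality.** Each individual's 24-h recall is scored with the
HEI-2015 (13 components, densities per 1000 kcal, max 100) and a modified
AHEI-2010 (10 components, trans fat excluded; amounts rescaled by
1849/energy; children < 18 y get 10 alcohol points for zero consumption,
0 for any). Components score by piecewise-linear interpolation between a
zero-score and a full-score threshold, clamped to [0, max]; population
means use the population-ratio method (score the ratio of weighted
totals, not the mean of scores). Individuals are grouped into
survey-weighted quintiles.

**Loss and waste.** With loss fractions r (retail), i (inedible), w
(consumer waste), consumed mass is inflated backwards through the chain

    edible_purchased = consumed/(1−w),  purchased = edible_purchased/(1−i),
    total_demand     = purchased/(1−r)

so that consumed + consumer waste + inedible + retail loss = **Total Food
Demand**, exactly, at every aggregation level.

**Survey estimation.** Weighted means with stratified between-PSU
Taylor-linearized variance (t intervals on PSUs − strata df), linear
trend tests across quintiles (WLS with design-based sandwich SEs,
optionally age/sex adjusted), and paired Wald tests for the
modified-vs-original AHEI sensitivity analysis.

**Footprint.** A simplified closed-food-system model: non-domestic
demand is reapportioned within food groups, plant foods convert to
primary crops (conversions embed pre-retail losses), animal foods to
feed and grazing requirements, crops to land via yields and double-crop
factors, land to resources via per-category application rates
(fertilizer = N + P₂O₅ + K₂O). The chain is linear in demand, so the
four loss/waste streams' footprints add exactly to the total and each
stream's attribution share is well defined. Uncertainty comes from Monte
Carlo draws of individuals without replacement.

## Worked example

The `analysis/` scripts run the whole pipeline on the default synthetic
world (900 individuals, 15 strata × 2 PSUs):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_score_diets.R
Rscript analysis/03_waste_accounting.R
Rscript analysis/04_trends.R
Rscript analysis/05_footprint.R
```

which prints, among other things:

```
Population-ratio HEI-2015: 56.9 / 100 (weighted mean of individual scores: 58.5).
Per capita Total Food Demand: 2746 g/d = 1387 consumed + 532 consumer waste
  + 630 inedible + 197 retail loss.
Total Food Demand: 2746 g/d (95% CI 2620-2873), design df 15.
Trend in Total Food Demand per quintile: HEI 273 g (P=6.1e-09), AHEI 272 g (P=2.8e-09).
Total Food Demand requires 78.2 million ha, 15372 million kg fertilizer nutrients,
  312.0 million kg pesticides, 195.9 billion m3 irrigation water per year.
Share of agricultural land by stream: consumed 61%, consumer waste 17%,
  inedible 16%, retail loss 6%.
Monte Carlo (500 draws of half the sample): land 78.2 million ha (95% interval 76.9-79.4).
```

Read: the population-ratio score (56.9) differs from the mean of
individual scores (58.5) because clamping is nonlinear. Total Food Demand
rises by ~270 g/d per diet-quality quintile in this synthetic world — the
gradient parameter couples healthful eating to overall intake — and
roughly two-fifths of demanded mass (and ~39% of the land behind it) is
never eaten. Tables land under `results/`.

The same chain is available programmatically via `run_pipeline()`:

```r
library(dietfootprint)
m <- run_pipeline(run_config(
  synthetic = list(design = survey_design_spec(), pop = population_spec()),
  seed = 1))
m$results$overall_demand
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance targets from
scratch — it builds the boundary dietary records from the shipped scoring
standards, scores them with the installed package, runs a small end-to-end
pipeline as a guard, and writes the values as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope

Synthetic data only (no national datasets are downloaded or reproduced);
no greenhouse-gas, water-scarcity or spatial indicators; no trans-fat
AHEI component; no replicate-weight variance methods. See the methods
vignette (`vignettes/dietfootprint-methods.Rmd`) for the model's
assumptions, parameter defaults and design decisions.
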