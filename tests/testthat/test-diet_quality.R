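hei_std <- hei2015_standards()
ahei_std <- ahei2010_standards()

test_that("component scoring is piecewise linear with clamping", {
  dairy <- hei_std[hei_std$component == "hei_dairy", ]
  expect_equal(score_component(1.3, dairy), 10)   # at full-score threshold
  expect_equal(score_component(5, dairy), 10)     # clamped above
  expect_equal(score_component(0, dairy), 0)      # zero threshold is zero
  expect_equal(score_component(0.65, dairy), 5)   # midpoint -> half points

  sodium <- hei_std[hei_std$component == "hei_sodium", ]
  expect_equal(score_component(1.1, sodium), 10)  # moderation reversed
  expect_equal(score_component(2.0, sodium), 0)
  expect_equal(score_component(1.55, sodium), 5)
  expect_equal(score_component(3, sodium), 0)     # clamped below

  expect_error(score_component(-1, dairy), ">= 0")
})

test_that("adult alcohol band is a trapezoid with non-drinker partial credit", {
  alc <- ahei_std[ahei_std$component == "ahei_alcohol", ]
  expect_equal(score_component(0, alc, "male"), 2.5)
  expect_equal(score_component(1.0, alc, "male"), 10)   # in band
  expect_equal(score_component(2.0, alc, "male"), 10)   # male band edge
  expect_equal(score_component(2.0, alc, "female"), 5)  # female: midway 1.5 -> 2.5
  expect_equal(score_component(3.5, alc, "male"), 0)
  expect_equal(score_component(2.75, alc, "male"), 5)   # halfway down 2.0 -> 3.5
})

test_that("full-compliance diets score 100 and floor diets score 0", {
  full <- manual_population(energy = 2000,
                            components = hei_full_compliance(2000))
  expect_equal(hei2015_score(full)$total, 100)

  # floor: zero adequacy intake, moderation at/above the zero-score standards
  floor_amounts <- list(hei_refined_grains = 2 * 4.3, hei_sodium = 2 * 2.0,
                        hei_added_sugars = 30, hei_saturated_fats = 20)
  floor <- manual_population(energy = 2000, components = floor_amounts)
  expect_equal(hei2015_score(floor)$total, 0)

  afull <- manual_population(energy = 1849, age = 30,
                             components = ahei_full_compliance())
  expect_equal(ahei2010_score(afull)$total, 100)
})

test_that("a mixed-density record matches the hand-evaluated component sum", {
  # densities per 1000 kcal at 2000 kcal: amounts are density * 2 except the
  # as-is components; expected points evaluated by hand from the standards.
  comp <- list(hei_total_fruits = 0.8, hei_whole_fruits = 0.2,
               hei_total_vegetables = 2.2, hei_greens_beans = 0.1,
               hei_whole_grains = 1.5, hei_dairy = 4.0,
               hei_total_protein = 2.5, hei_seafood_plant_protein = 0.4,
               hei_fatty_acid_ratio = 1.85, hei_refined_grains = 6.1,
               hei_sodium = 3.1, hei_added_sugars = 16.25,
               hei_saturated_fats = 12)
  p <- manual_population(energy = 2000, components = comp)
  # per-1000 densities: fruits .4, whole .1, veg 1.1, greens .05, wgrain .75,
  # dairy 2.0, protein 1.25, seafood .2, ratio 1.85, refined 3.05, sodium 1.55
  expect_equal(hei2015_score(p)$total,
               2.5 + 1.25 + 5 + 1.25 + 5 + 10 + 2.5 + 1.25 + 5 + 5 + 5 + 5 + 5)
})

test_that("AHEI energy adjustment rescales to the 1849 kcal reference", {
  comp <- ahei_full_compliance()
  comp$ahei_whole_grains <- 100

  # at the reference energy, modified and unmodified agree
  at_ref <- manual_population(energy = 1849, age = 30, components = comp)
  expect_equal(ahei2010_score(at_ref, modified = TRUE),
               ahei2010_score(at_ref, modified = FALSE))

  # at twice the reference, amounts are halved before scoring: 50 g of
  # whole grains against the 90 g male standard
  double <- manual_population(energy = 3698, age = 30, components = comp)
  sc <- ahei2010_score(double, modified = TRUE)
  expect_equal(sc$ahei_whole_grains, 50 / 90 * 10)
  raw <- ahei2010_score(double, modified = FALSE)
  expect_equal(raw$ahei_whole_grains, 10)
})

test_that("the child alcohol rule awards 10 for zero intake, 0 otherwise", {
  kid0 <- manual_population(energy = 1600, age = 10,
                            components = list(ahei_alcohol = 0))
  expect_equal(ahei2010_score(kid0, modified = TRUE)$ahei_alcohol, 10)
  kid1 <- manual_population(energy = 1600, age = 10,
                            components = list(ahei_alcohol = 0.2))
  expect_equal(ahei2010_score(kid1, modified = TRUE)$ahei_alcohol, 0)
  # unmodified: the adult band applies to everyone
  expect_equal(ahei2010_score(kid0, modified = FALSE)$ahei_alcohol, 2.5)
})

test_that("sex-specific whole-grain thresholds are honoured", {
  comp <- list(ahei_whole_grains = 75)
  f <- manual_population(energy = 1849, age = 30, sex = "female", components = comp)
  m <- manual_population(energy = 1849, age = 30, sex = "male", components = comp)
  expect_equal(ahei2010_score(f)$ahei_whole_grains, 10)
  expect_equal(ahei2010_score(m)$ahei_whole_grains, 75 / 90 * 10)
})

test_that("population-ratio mean scores the mean density, not the mean score", {
  # homogeneous population: population score equals the common score
  a <- manual_population(energy = 2000, components = hei_full_compliance(2000),
                         id = "a", weight = 2)
  b <- manual_population(energy = 2000, components = hei_full_compliance(2000),
                         id = "b", weight = 5)
  hom <- bind_populations(a, b)
  pr <- population_ratio_mean(hom, index = "HEI-2015")
  expect_equal(pr$total, 100)

  # clamping makes mean-of-scores differ from score-of-means; hand oracle:
  # dairy totals 3.9 cups over 4000 kcal -> density 0.975 -> 7.5 points;
  # zero-intake moderation components earn full credit (4 x 10).
  c1 <- manual_population(energy = 1000, components = list(hei_dairy = 3.9),
                          id = "c1")
  c2 <- manual_population(energy = 3000, components = list(), id = "c2")
  two <- bind_populations(c1, c2)
  pr2 <- population_ratio_mean(two, index = "HEI-2015")
  expect_equal(pr2$total, 7.5 + 40)
  ind <- hei2015_score(two)
  expect_equal(mean(ind$total), 5 + 40)  # mean of scores differs

  # ratio invariance: doubling all weights changes nothing
  two_doubled <- two
  two_doubled$records$weight <- two$records$weight * 2
  expect_equal(population_ratio_mean(two_doubled, index = "HEI-2015")$total,
               pr2$total)
})

test_that("HEI density scores are invariant to proportional energy scaling", {
  p <- tiny_population(seed = 13, n_strata = 2L, individuals_per_psu = 5L)
  base <- hei2015_score(p)
  k <- 1.7
  scaled <- p
  scaled$records$energy_kcal <- p$records$energy_kcal * k
  reg <- dietfootprint:::component_registry()
  per_day <- reg$component[reg$scales_with_energy & startsWith(reg$component, "hei_")]
  scaled$components <- p$components |>
    dplyr::mutate(amount = ifelse(component %in% per_day, amount * k, amount))
  expect_equal(hei2015_score(scaled), base, tolerance = 1e-12)
})

test_that("scores respect bounds and monotonicity (property)", {
  p <- tiny_population(seed = 17)
  hei <- hei2015_score(p)
  ahei <- ahei2010_score(p)
  for (sc in list(hei, ahei)) {
    comps <- setdiff(names(sc), c("id", "total"))
    expect_true(all(sc$total >= 0 & sc$total <= 100))
    expect_equal(sc$total, rowSums(sc[comps]), tolerance = 1e-9)
    for (cp in comps) expect_true(all(sc[[cp]] >= 0))
  }
  # adequacy monotone up, moderation monotone down
  std <- hei_std[hei_std$component == "hei_total_fruits", ]
  grid <- seq(0, 1.2, by = 0.05)
  expect_true(all(diff(score_component(grid, std)) >= 0))
  stdm <- hei_std[hei_std$component == "hei_refined_grains", ]
  expect_true(all(diff(score_component(grid * 5, stdm)) <= 0))
})

test_that("quintile assignment follows the weighted ECDF convention", {
  expect_equal(assign_quintiles(c(10, 20, 30, 40, 50), rep(1, 5)), 1:5)
  expect_warning(q <- assign_quintiles(rep(7, 6), rep(1, 6)), "degenerate")
  expect_equal(q, rep(1L, 6))
  expect_error(assign_quintiles(1:4, rep(1, 4)), "at least 5")

  set.seed(99)
  scores <- runif(400)
  w <- rlnorm(400, 0, 1)
  q <- assign_quintiles(scores, w)
  expect_true(all(q[order(scores)] == cummax(q[order(scores)])))  # monotone labels
  shares <- tapply(w, q, sum) / sum(w)
  expect_true(all(abs(shares - 0.2) < 0.05))
  # oracle: each cutpoint is the smallest score with weighted CDF >= p
  for (p in c(0.2, 0.4, 0.6, 0.8)) {
    cut <- max(scores[q <= match(p, c(0.2, 0.4, 0.6, 0.8))])
    cdf_at <- sum(w[scores <= cut]) / sum(w)
    cdf_below <- sum(w[scores < cut]) / sum(w)
    expect_gte(cdf_at, p)
    expect_lt(cdf_below, p)
  }
})

test_that("non-positive energy records follow the configured policy", {
  bad <- manual_population(energy = 0, id = "z")
  ok <- manual_population(energy = 2000, id = "k",
                          components = hei_full_compliance(2000))
  both <- bind_populations(bad, ok)
  expect_error(hei2015_score(both, energy_policy = "error"), "non-positive")
  expect_warning(sc <- hei2015_score(both, energy_policy = "drop"), "excluding 1")
  expect_equal(sc$id, "k")
})
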