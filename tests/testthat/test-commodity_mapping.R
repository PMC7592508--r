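simple_intake <- function(...) {
  rows <- list(...)
  tibble::tibble(
    id = vapply(rows, `[[`, "", 1),
    food_id = vapply(rows, `[[`, "", 2),
    grams = as.numeric(vapply(rows, `[[`, "", 3))
  )
}

test_that("disaggregation distributes grams by recipe fraction", {
  recipes <- tibble::tibble(food_id = c("f1", "f1"),
                            commodity_id = c("A", "B"),
                            fraction = c(0.6, 0.4))
  out <- disaggregate(simple_intake(c("p1", "f1", "100")), recipes)
  expect_equal(out$intakes$grams[out$intakes$commodity_id == "A"], 60)
  expect_equal(out$intakes$grams[out$intakes$commodity_id == "B"], 40)
  expect_equal(out$coverage$unmapped_share, 0)

  # identity recipe: commodity grams equal food grams
  idr <- tibble::tibble(food_id = c("f1", "f2"), commodity_id = c("f1", "f2"),
                        fraction = 1)
  out2 <- disaggregate(simple_intake(c("p1", "f1", "30"), c("p1", "f2", "70")), idr)
  expect_equal(sort(out2$intakes$grams), c(30, 70))

  # shared commodity, verified against an explicit row-wise accumulation
  recipes3 <- tibble::tibble(food_id = c("f1", "f1", "f2"),
                             commodity_id = c("A", "B", "A"),
                             fraction = c(0.5, 0.5, 1))
  intake3 <- simple_intake(c("p1", "f1", "100"), c("p1", "f2", "50"))
  out3 <- disaggregate(intake3, recipes3)$intakes
  oracle <- 0
  for (k in seq_len(nrow(intake3))) {
    rr <- recipes3[recipes3$food_id == intake3$food_id[k] &
                     recipes3$commodity_id == "A", ]
    if (nrow(rr)) oracle <- oracle + intake3$grams[k] * rr$fraction
  }
  expect_equal(out3$grams[out3$commodity_id == "A"], oracle)
  expect_equal(oracle, 100)
})

test_that("recipe validation rejects malformed tables", {
  expect_error(validate_recipes(tibble::tibble(
    food_id = c("f1", "f1"), commodity_id = c("A", "A"), fraction = c(0.5, 0.5))),
    "duplicate")
  expect_error(validate_recipes(tibble::tibble(
    food_id = "f1", commodity_id = "A", fraction = 0.8)), "sum to 1")
  expect_error(validate_recipes(tibble::tibble(
    food_id = c("f1", "f1"), commodity_id = c("A", "B"), fraction = c(1.2, -0.2))),
    ">= 0")
})

test_that("unmapped foods follow the configured policy and coverage report", {
  recipes <- tibble::tibble(food_id = "f1", commodity_id = "A", fraction = 1)
  intake <- simple_intake(c("p1", "f1", "75"), c("p1", "f9", "25"))
  expect_error(disaggregate(intake, recipes, "error"), "f9")
  expect_warning(out <- disaggregate(intake, recipes, "drop"), "25.0%")
  expect_identical(out$coverage$unmapped_foods, "f9")
  expect_equal(out$coverage$unmapped_grams, 25)
  expect_equal(out$coverage$unmapped_share, 0.25)
  expect_equal(out$coverage$mapped_grams, 75)
})

test_that("mass is conserved and row order is irrelevant (property)", {
  set.seed(42)
  for (rep in 1:5) {
    params <- generate_parameter_tables(seed = rep, n_foods = 20L,
                                        unmapped_fraction = 0)
    p <- generate_population(tiny_design(seed = rep, n_strata = 2L,
                                         individuals_per_psu = 5L),
                             population_spec(n_foods = 20L))
    out <- disaggregate(p, params$recipes)
    by_person <- tapply(out$intakes$grams, out$intakes$id, sum)
    food_tot <- tapply(p$intakes$grams, p$intakes$id, sum)
    expect_equal(as.numeric(by_person), as.numeric(food_tot[names(by_person)]),
                 tolerance = 1e-9)

    shuffle <- function(d) d[sample(nrow(d)), ]
    out2 <- disaggregate(
      structure(list(intakes = shuffle(p$intakes)), class = "diet_population"),
      shuffle(params$recipes))
    expect_equal(out$intakes, out2$intakes)
  }
})

test_that("food-group aggregation conserves mass and validates the map", {
  intakes <- tibble::tibble(id = c("p1", "p1", "p1"),
                            commodity_id = c("A", "B", "C"),
                            grams = c(10, 20, 5))
  gmap <- tibble::tibble(commodity_id = c("A", "B", "C"),
                         food_group = c("g1", "g1", "g2"))
  out <- aggregate_to_food_groups(intakes, gmap)
  expect_equal(out$grams[out$food_group == "g1"], 30)
  expect_equal(out$grams[out$food_group == "g2"], 5)
  expect_equal(sum(out$grams), sum(intakes$grams))

  expect_error(aggregate_to_food_groups(
    intakes, gmap[1:2, ]), "missing from group map")
  expect_error(aggregate_to_food_groups(
    intakes, dplyr::bind_rows(gmap, gmap[1, ])), "more than one group")

  single <- aggregate_to_food_groups(intakes[1, ], gmap)
  expect_equal(single$grams, 10)
  empty <- aggregate_to_food_groups(intakes[0, ], gmap)
  expect_equal(nrow(empty), 0L)
})
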