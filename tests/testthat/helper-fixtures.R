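# Shared fixtures: built in code, deterministic under the seeds given here.

tiny_design <- function(seed = 1L, n_strata = 4L, individuals_per_psu = 15L) {
  survey_design_spec(n_strata = n_strata, psus_per_stratum = 2L,
                     individuals_per_psu = individuals_per_psu, seed = seed)
}

tiny_population <- function(seed = 1L, gradient = 1, ...) {
  generate_population(tiny_design(seed = seed, ...),
                      population_spec(gradient = gradient))
}

# Hand-held single-record population: components given as a named list of
# daily amounts; anything unnamed defaults to zero.
manual_population <- function(energy = 2000, age = 40, sex = "male",
                              components = list(), weight = 1,
                              id = "p1", stratum = 1, psu = 1) {
  reg_components <- unique(dietfootprint:::component_registry()$component)
  reg_components <- union(reg_components, "ahei_alcohol")
  amounts <- setNames(rep(0, length(reg_components)), reg_components)
  amounts[names(components)] <- unlist(components)
  structure(list(
    records = tibble::tibble(id = id, stratum = stratum, psu = psu,
                             weight = weight, age = age, sex = sex,
                             energy_kcal = energy),
    components = tibble::tibble(id = id, component = names(amounts),
                                amount = unname(amounts)),
    intakes = tibble::tibble(id = character(), food_id = character(),
                             grams = numeric()),
    foods = tibble::tibble(food_id = character(), kcal_per_g = numeric(),
                           healthful = logical())
  ), class = "diet_population")
}

# Stack several manual single-record populations into one.
bind_populations <- function(...) {
  pops <- list(...)
  structure(list(
    records = dplyr::bind_rows(lapply(pops, `[[`, "records")),
    components = dplyr::bind_rows(lapply(pops, `[[`, "components")),
    intakes = dplyr::bind_rows(lapply(pops, `[[`, "intakes")),
    foods = pops[[1]]$foods
  ), class = "diet_population")
}

# HEI-2015 daily amounts that saturate every component's full-score
# standard at the given energy (adequacy at/above full, moderation at/below).
hei_full_compliance <- function(energy = 2000) {
  e <- energy / 1000
  list(hei_total_fruits = 0.8 * e, hei_whole_fruits = 0.4 * e,
       hei_total_vegetables = 1.1 * e, hei_greens_beans = 0.2 * e,
       hei_whole_grains = 1.5 * e, hei_dairy = 1.3 * e,
       hei_total_protein = 2.5 * e, hei_seafood_plant_protein = 0.8 * e,
       hei_fatty_acid_ratio = 2.5,
       hei_refined_grains = 1.8 * e, hei_sodium = 1.1 * e,
       hei_added_sugars = 6.5, hei_saturated_fats = 8)
}

# AHEI-2010 daily amounts that earn the maximum on every component for an
# adult at the reference energy intake.
ahei_full_compliance <- function() {
  list(ahei_vegetables = 5, ahei_fruit = 4, ahei_whole_grains = 90,
       ahei_nuts_legumes = 1, ahei_long_chain_fats = 250, ahei_pufa = 10,
       ahei_ssb_juice = 0, ahei_red_processed_meat = 0, ahei_sodium = 1112,
       ahei_alcohol = 1)
}

# Minimal hand-built agronomic parameter set: two plant commodities on two
# crops plus one animal commodity fed from a feed crop and hay, grazing on
# permanent pasture. All numbers chosen for easy hand arithmetic.
toy_agronomic <- function() {
  list(
    crops = tibble::tibble(
      crop_id = c("wheat", "apple", "feedcorn", "hay"),
      land_use = c("grains", "fruits", "feed_grains_oilseeds", "hay"),
      yield_kg_ha = c(4000, 20000, 8000, 5000),
      double_crop_factor = c(1, 1, 1, 1)
    ),
    rates = tibble::tibble(
      land_use = c("grains", "fruits", "feed_grains_oilseeds", "hay",
                   "cropland_pasture", "permanent_pasture"),
      n_rate_kg_ha = c(100, 50, 120, 30, 30, 5),
      p_rate_kg_ha = c(40, 20, 50, 10, 10, 2),
      k_rate_kg_ha = c(60, 30, 70, 15, 15, 2),
      pesticide_rate_kg_ha = c(2, 4, 3, 0.3, 0.3, 0.05),
      irrigation_rate_m3_ha = c(1000, 3000, 800, 150, 150, 20)
    ),
    commodity_map = tibble::tibble(
      commodity_id = c("flour", "apples", "milk"),
      kind = c("plant", "plant", "animal"),
      crop_id = c("wheat", "apple", NA),
      conversion = c(1.25, 1.1, 1.0)
    ),
    feed = tibble::tibble(
      commodity_id = c("milk", "milk"),
      crop_id = c("feedcorn", "hay"),
      kg_feed_per_kg = c(0.5, 1.2)
    ),
    pasture_req = tibble::tibble(
      commodity_id = "milk", land_use = "permanent_pasture",
      ha_per_kg = 1e-4
    ),
    allocation = tibble::tibble(
      crop_id = c("wheat", "apple"), commodity_id = c("flour", "apples"),
      allocation = c(1, 1)
    ),
    availability = tibble::tibble(
      commodity_id = c("flour", "apples", "milk"),
      availability = c(1, 1, 1)
    ),
    domestic = tibble::tibble(
      commodity_id = c("flour", "apples", "milk"),
      domestic = c(TRUE, TRUE, TRUE)
    ),
    population_size = 1000,
    pasture_utilization = 1,
    available_land = NULL
  )
}

toy_group_map <- function() {
  tibble::tibble(commodity_id = c("flour", "apples", "milk"),
                 food_group = c("grains", "fruits", "dairy"))
}
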