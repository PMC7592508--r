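#' Specify a stratified multistage survey design
#'
#' Describes the sampling frame the population generator emulates: a
#' stratified design with a fixed number of primary sampling units (PSUs)
#' per stratum and log-normal sampling weights. Two PSUs per stratum is
#' the minimum for design-based variance estimation and is the default,
#' mirroring public-use national survey files.
#'
#' @param n_strata Number of design strata.
#' @param psus_per_stratum PSUs sampled in each stratum (must be >= 2).
#' @param individuals_per_psu Individuals interviewed per PSU.
#' @param weight_meanlog,weight_sdlog Log-mean and log-sd of the sampling
#'   weights. The log-normal mimics the right skew of survey weights.
#' @param seed Integer seed; identical seeds reproduce identical populations.
#' @return A `survey_design_spec` list.
#' @export
survey_design_spec <- function(n_strata = 15L, psus_per_stratum = 2L,
                               individuals_per_psu = 30L,
                               weight_meanlog = log(1000), weight_sdlog = 0.7,
                               seed = 1L) {
  n_strata <- assert_positive_count(n_strata, "n_strata")
  psus_per_stratum <- assert_positive_count(psus_per_stratum, "psus_per_stratum")
  individuals_per_psu <- assert_positive_count(individuals_per_psu, "individuals_per_psu")
  if (psus_per_stratum < 2L) {
    abort("`psus_per_stratum` must be >= 2: variance estimation needs two PSUs per stratum")
  }
  if (!is.finite(weight_sdlog) || weight_sdlog < 0) abort("`weight_sdlog` must be >= 0")
  structure(list(n_strata = n_strata, psus_per_stratum = psus_per_stratum,
                 individuals_per_psu = individuals_per_psu,
                 weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog,
                 seed = as.integer(seed)),
            class = "survey_design_spec")
}

#' Specify the dietary heterogeneity of a synthetic population
#'
#' @param n_foods Number of as-consumed foods on the recall instrument.
#' @param n_commodities Number of commodities in the recipe universe (used
#'   by [generate_parameter_tables()]; recorded here for bookkeeping).
#' @param energy_mean,energy_sd,energy_floor Daily energy intake (kcal):
#'   normal with a hard floor, so density-based scoring is defined for
#'   every record.
#' @param gradient Diet-quality gradient: controls how strongly
#'   healthful-food intake and index-relevant component amounts co-vary
#'   with a latent healthfulness trait. 0 removes the association.
#' @param age_range Two-element integer range of ages (years).
#' @param sex_ratio Proportion female.
#' @return A `population_spec` list.
#' @export
population_spec <- function(n_foods = 40L, n_commodities = 24L,
                            energy_mean = 2100, energy_sd = 550,
                            energy_floor = 500,
                            gradient = 1, age_range = c(2L, 80L),
                            sex_ratio = 0.51) {
  n_foods <- assert_positive_count(n_foods, "n_foods")
  n_commodities <- assert_positive_count(n_commodities, "n_commodities")
  if (energy_floor <= 0) abort("`energy_floor` must be > 0")
  if (!is.finite(gradient)) abort("`gradient` must be finite")
  if (sex_ratio < 0 || sex_ratio > 1) abort("`sex_ratio` must be in [0, 1]")
  structure(list(n_foods = n_foods, n_commodities = n_commodities,
                 energy_mean = energy_mean, energy_sd = energy_sd,
                 energy_floor = energy_floor, gradient = gradient,
                 age_range = as.integer(age_range), sex_ratio = sex_ratio),
            class = "population_spec")
}

food_ids <- function(n) sprintf("food_%02d", seq_len(n))
commodity_ids <- function(n) sprintf("com_%02d", seq_len(n))

# By convention the first ceiling(n/2) foods (and commodities) form the
# "healthful" pool; the recipe generator maps healthful foods to commodities
# in fruit/vegetable/nut/dairy/grain groups.
healthful_foods <- function(n) seq_len(ceiling(n / 2))

# Registry of index-relevant components: daily-amount scale at ~2000 kcal.
# dir: +1 adequacy, -1 moderation, 0 special (alcohol). scales_with_energy
# marks per-day amounts that grow with total intake; percent-of-energy and
# ratio components do not.
component_registry <- function() {
  tibble::tribble(
    ~component,                  ~base_mean, ~dir, ~scales_with_energy,
    "hei_total_fruits",                1.00,   1L, TRUE,
    "hei_whole_fruits",                0.50,   1L, TRUE,
    "hei_total_vegetables",            1.60,   1L, TRUE,
    "hei_greens_beans",                0.25,   1L, TRUE,
    "hei_whole_grains",                0.90,   1L, TRUE,
    "hei_dairy",                       1.80,   1L, TRUE,
    "hei_total_protein",               6.50,   1L, TRUE,
    "hei_seafood_plant_protein",       0.90,   1L, TRUE,
    "hei_fatty_acid_ratio",            1.60,   1L, FALSE,
    "hei_refined_grains",              6.20,  -1L, TRUE,
    "hei_sodium",                      3.50,  -1L, TRUE,
    "hei_added_sugars",               14.00,  -1L, FALSE,
    "hei_saturated_fats",             11.00,  -1L, FALSE,
    "ahei_vegetables",                 1.80,   1L, TRUE,
    "ahei_fruit",                      1.00,   1L, TRUE,
    "ahei_whole_grains",              30.00,   1L, TRUE,
    "ahei_nuts_legumes",               0.45,   1L, TRUE,
    "ahei_long_chain_fats",          100.00,   1L, TRUE,
    "ahei_pufa",                       7.00,   1L, FALSE,
    "ahei_ssb_juice",                  1.20,  -1L, TRUE,
    "ahei_red_processed_meat",         1.10,  -1L, TRUE,
    "ahei_sodium",                  3500.00,  -1L, TRUE
  )
}

#' Generate a synthetic survey population of dietary recalls
#'
#' Simulates one 24-h recall per individual under a stratified
#' two-PSU-per-stratum design: log-normal weights, normal-with-floor energy
#' intake, per-food gram intakes allocated so that grams times each food's
#' energy density sum exactly to reported energy, and per-component daily
#' amounts for both diet indices. A latent healthfulness trait (strength set
#' by `pop$gradient`) induces the diet-quality gradient: healthful foods and
#' adequacy components rise with the trait, moderation components fall.
#'
#' @param design A [survey_design_spec()].
#' @param pop A [population_spec()].
#' @return A `diet_population` list with tibbles `records` (id, stratum,
#'   psu, weight, age, sex, energy_kcal, latent trait), `intakes`
#'   (id, food_id, grams), `components` (id, component, amount) and
#'   `foods` (food_id, kcal_per_g, healthful).
#' @export
generate_population <- function(design, pop) {
  stopifnot(inherits(design, "survey_design_spec"), inherits(pop, "population_spec"))
  set.seed(design$seed)

  n <- design$n_strata * design$psus_per_stratum * design$individuals_per_psu
  stratum <- rep(seq_len(design$n_strata),
                 each = design$psus_per_stratum * design$individuals_per_psu)
  psu <- rep(rep(seq_len(design$psus_per_stratum), each = design$individuals_per_psu),
             times = design$n_strata)
  id <- sprintf("ind_%05d", seq_len(n))
  weight <- rlnorm(n, design$weight_meanlog, design$weight_sdlog)
  age <- sample(seq(pop$age_range[1], pop$age_range[2]), n, replace = TRUE)
  sex <- ifelse(runif(n) < pop$sex_ratio, "female", "male")
  energy <- pmax(rnorm(n, pop$energy_mean, pop$energy_sd), pop$energy_floor)
  # Latent healthfulness trait, mildly PSU-clustered so the design matters.
  psu_key <- paste(stratum, psu)
  psu_effect <- rnorm(length(unique(psu_key)), 0, 0.3)[match(psu_key, unique(psu_key))]
  h <- rnorm(n, 0, 1) + psu_effect

  records <- tibble::tibble(id = id, stratum = stratum, psu = psu, weight = weight,
                            age = age, sex = sex, energy_kcal = energy, healthfulness = h)

  # Foods: fixed energy densities; healthful pool gets lower kcal/g.
  hf <- healthful_foods(pop$n_foods)
  kcal_per_g <- runif(pop$n_foods, 1.2, 4)
  kcal_per_g[hf] <- runif(length(hf), 0.4, 1.8)
  foods <- tibble::tibble(food_id = food_ids(pop$n_foods), kcal_per_g = kcal_per_g,
                          healthful = seq_len(pop$n_foods) %in% hf)

  # Per-individual food shares: gamma base tilted by the trait, then grams
  # chosen so sum(grams * kcal_per_g) == energy exactly.
  tilt <- ifelse(foods$healthful, 0.7, -0.7)
  share <- matrix(rgamma(n * pop$n_foods, shape = 0.5, rate = 1), nrow = n)
  share <- share * exp(outer(pop$gradient * h, tilt))
  gram_w <- sweep(share, 2, foods$kcal_per_g, "/")
  grams <- gram_w / rowSums(share) * energy
  intakes <- tibble::tibble(
    id = rep(id, times = pop$n_foods),
    food_id = rep(foods$food_id, each = n),
    grams = as.vector(grams)
  ) |>
    dplyr::filter(.data$grams > 0) |>
    dplyr::arrange(.data$id, .data$food_id)

  # Component daily amounts: log-normal around an energy-scaled mean, tilted
  # by the trait in the direction that rewards (adequacy) or penalises
  # (moderation) healthfulness.
  reg <- component_registry()
  comp_list <- lapply(seq_len(nrow(reg)), function(k) {
    escale <- if (reg$scales_with_energy[k]) energy / 2000 else 1
    amt <- reg$base_mean[k] * escale *
      exp(0.35 * reg$dir[k] * pop$gradient * h + rnorm(n, 0, 0.30))
    tibble::tibble(id = id, component = reg$component[k], amount = amt)
  })
  # Alcohol (drinks/day): zero-inflated; children almost never drink.
  is_child <- age < 18
  drinker <- runif(n) < ifelse(is_child, 0.02, 0.55)
  drinks <- ifelse(drinker, rlnorm(n, log(0.9), 0.7), 0)
  comp_list[[length(comp_list) + 1L]] <-
    tibble::tibble(id = id, component = "ahei_alcohol", amount = drinks)
  components <- dplyr::bind_rows(comp_list) |> dplyr::arrange(.data$id, .data$component)

  structure(list(records = records, intakes = intakes,
                 components = components, foods = foods,
                 design = design, pop = pop),
            class = "diet_population")
}

#' @export
print.diet_population <- function(x, ...) {
  cat(sprintf("<diet_population> %d individuals, %d strata x %d PSUs, %d foods\n",
              nrow(x$records), x$design$n_strata, x$design$psus_per_stratum,
              nrow(x$foods)))
  invisible(x)
}

#' Generate recipe, loss-rate, scoring and agronomic parameter tables
#'
#' Emits the parameter universe the pipeline consumes: a recipe table
#' distributing each mapped food's mass over commodities (fractions sum to
#' one), a commodity loss profile table (retail loss, inedible fraction,
#' consumer-waste fraction, each in \[0, 1) and jointly leaving a positive
#' consumed share), the published scoring-standards tables, and a small
#' crop/livestock parameter set for the footprint model (processing
#' conversions, feed requirements, yields, per-hectare application rates,
#' multi-use crop allocations, double-crop factors, domestic-production
#' flags with at least one non-domestic commodity, availability weights and
#' available-land bounds). A configurable fraction of foods is deliberately
#' left out of the recipe table to emulate recipe-coverage gaps.
#'
#' @param n_commodities,n_crops Universe sizes (n_crops >= 4; the last two
#'   crops are the feed-grain and hay crops).
#' @param seed Integer seed.
#' @param n_foods Number of foods the recipe table should cover.
#' @param unmapped_fraction Fraction of foods left unmapped.
#' @return A list with `recipes`, `loss_profiles`, `group_map`,
#'   `hei_standards`, `ahei_standards` and `agronomic` (itself a list:
#'   `crops`, `rates`, `commodity_map`, `feed`, `allocation`,
#'   `availability`, `domestic`, `population_size`, `pasture_utilization`,
#'   `available_land`).
#' @export
generate_parameter_tables <- function(n_commodities = 24L, n_crops = 12L,
                                      seed = 1L, n_foods = 40L,
                                      unmapped_fraction = 0.05) {
  n_commodities <- assert_positive_count(n_commodities, "n_commodities")
  n_crops <- assert_positive_count(n_crops, "n_crops")
  n_foods <- assert_positive_count(n_foods, "n_foods")
  if (n_crops < 4L) abort("`n_crops` must be >= 4 (food crops + feed grain + hay)")
  set.seed(seed)

  coms <- commodity_ids(n_commodities)
  n_healthful_com <- ceiling(n_commodities / 2)
  healthful_pool <- coms[seq_len(n_healthful_com)]
  other_pool <- coms[-seq_len(n_healthful_com)]

  healthful_groups <- c("fruits", "vegetables", "nuts_seeds", "dairy", "grains")
  other_groups <- c("meat", "sweeteners", "other", "grains")
  group_map <- tibble::tibble(
    commodity_id = coms,
    food_group = c(rep_len(healthful_groups, n_healthful_com),
                   rep_len(other_groups, n_commodities - n_healthful_com))
  )

  # Recipes: healthful foods draw on the healthful commodity pool.
  fids <- food_ids(n_foods)
  hf <- healthful_foods(n_foods)
  n_unmapped <- round(unmapped_fraction * n_foods)
  unmapped <- if (n_unmapped > 0) sample(fids, n_unmapped) else character()
  recipe_rows <- lapply(seq_along(fids), function(f) {
    if (fids[f] %in% unmapped) return(NULL)
    pool <- if (f %in% hf) healthful_pool else other_pool
    k <- sample(1:min(3, length(pool)), 1)
    cs <- sample(pool, k)
    fr <- rgamma(k, 2, 1)
    tibble::tibble(food_id = fids[f], commodity_id = cs, fraction = fr / sum(fr))
  })
  recipes <- dplyr::bind_rows(recipe_rows)

  loss_profiles <- tibble::tibble(
    commodity_id = coms,
    retail_loss = runif(n_commodities, 0.02, 0.12),
    inedible = ifelse(runif(n_commodities) < 0.4, 0, runif(n_commodities, 0.05, 0.45)),
    consumer_waste = runif(n_commodities, 0.10, 0.45)
  )

  # Availability weights (fixed, availability-series style) drive import
  # reapportionment so the footprint chain stays linear in demand.
  availability <- tibble::tibble(commodity_id = coms,
                                 availability = rgamma(n_commodities, 2, 1) + 0.1)

  # Domestic flags: one non-domestic commodity per eligible multi-member group.
  domestic <- tibble::tibble(commodity_id = coms, domestic = TRUE)
  for (g in unique(group_map$food_group)) {
    members <- group_map$commodity_id[group_map$food_group == g]
    if (length(members) >= 2 && runif(1) < 0.6) {
      domestic$domestic[domestic$commodity_id == sample(members, 1)] <- FALSE
    }
  }
  if (all(domestic$domestic)) {  # guarantee at least one, per contract
    g <- names(which(table(group_map$food_group) >= 2))[1]
    members <- group_map$commodity_id[group_map$food_group == g]
    domestic$domestic[domestic$commodity_id == members[1]] <- FALSE
  }

  # Crops: last two are dedicated feed-grain and hay crops.
  crop_id <- sprintf("crop_%02d", seq_len(n_crops))
  food_land_uses <- c("grains", "fruits", "vegetables", "legumes", "nuts", "sweeteners")
  land_use <- c(rep_len(food_land_uses, n_crops - 2), "feed_grains_oilseeds", "hay")
  crops <- tibble::tibble(
    crop_id = crop_id,
    land_use = land_use,
    yield_kg_ha = runif(n_crops, 2000, 30000),
    double_crop_factor = ifelse(runif(n_crops) < 0.2, runif(n_crops, 1.3, 2), 1)
  )
  # Application rates keyed by land-use category (annual amount per hectare);
  # hay/pasture rates are low, literature-style defaults.
  rate_categories <- c(unique(crops$land_use), "cropland_pasture", "permanent_pasture")
  n_rc <- length(rate_categories)
  rates <- tibble::tibble(
    land_use = rate_categories,
    n_rate_kg_ha = runif(n_rc, 20, 180),
    p_rate_kg_ha = runif(n_rc, 10, 80),
    k_rate_kg_ha = runif(n_rc, 10, 100),
    pesticide_rate_kg_ha = runif(n_rc, 0.5, 8),
    irrigation_rate_m3_ha = runif(n_rc, 200, 6000)
  )
  rates[rates$land_use == "cropland_pasture", -1] <- list(30, 10, 15, 0.3, 150)
  rates[rates$land_use == "permanent_pasture", -1] <- list(5, 2, 2, 0.05, 20)

  # Commodity -> crop/livestock mapping. Animal commodities are those in the
  # meat and dairy groups; the rest are plant commodities.
  animal <- group_map$food_group %in% c("meat", "dairy")
  food_crops <- crop_id[seq_len(n_crops - 2)]
  commodity_map <- tibble::tibble(
    commodity_id = coms,
    kind = ifelse(animal, "animal", "plant"),
    crop_id = ifelse(animal, NA_character_, rep_len(food_crops, n_commodities)),
    conversion = ifelse(animal, runif(n_commodities, 1.1, 1.8),
                        runif(n_commodities, 1.0, 1.6))
  )
  feed_crop <- crop_id[n_crops - 1]
  hay_crop <- crop_id[n_crops]
  feed <- commodity_map |>
    dplyr::filter(.data$kind == "animal") |>
    dplyr::reframe(
      commodity_id = rep(.data$commodity_id, each = 2),
      crop_id = rep(c(feed_crop, hay_crop), dplyr::n()),
      kg_feed_per_kg = runif(2 * dplyr::n(), c(2, 1), c(6, 4))
    )
  pasture_req <- commodity_map |>
    dplyr::filter(.data$kind == "animal") |>
    dplyr::reframe(
      commodity_id = rep(.data$commodity_id, each = 2),
      land_use = rep(c("cropland_pasture", "permanent_pasture"), dplyr::n()),
      ha_per_kg = runif(2 * dplyr::n(), c(5e-6, 2e-5), c(2e-5, 2e-4))
    )

  # Multi-use allocation: fractions of each crop's mass attributed to the
  # commodities drawing on it (sum to one per used crop).
  allocation <- commodity_map |>
    dplyr::filter(.data$kind == "plant") |>
    dplyr::group_by(.data$crop_id) |>
    dplyr::mutate(allocation = {
      a <- rgamma(dplyr::n(), 2, 1)
      a / sum(a)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("crop_id", "commodity_id", "allocation")

  available_land <- tibble::tibble(
    land_use = rate_categories,
    available_ha = runif(n_rc, 5e6, 2e8)
  )

  list(
    recipes = recipes,
    loss_profiles = loss_profiles,
    group_map = group_map,
    hei_standards = hei2015_standards(),
    ahei_standards = ahei2010_standards(),
    agronomic = list(
      crops = crops, rates = rates, commodity_map = commodity_map,
      feed = feed, pasture_req = pasture_req, allocation = allocation,
      availability = availability, domestic = domestic,
      population_size = 3.21e8, pasture_utilization = 0.6,
      available_land = available_land
    ),
    unmapped_foods = sort(unmapped),
    seed = as.integer(seed)
  )
}

#' Write the synthetic input tables to disk
#'
#' Writes the recall, intake, component, recipe, loss-profile, group-map and
#' scoring-standards tables as CSV, the agronomic parameter tables as CSVs
#' under `agronomic/`, and the generation specs as YAML.
#'
#' @param popdata A `diet_population` from [generate_population()].
#' @param params Parameter list from [generate_parameter_tables()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_synthetic_inputs <- function(popdata, params, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "agronomic"), showWarnings = FALSE)
  w <- function(x, f) {
    readr::write_csv(x, file.path(dir, f))
    file.path(dir, f)
  }
  files <- c(
    w(popdata$records, "records.csv"),
    w(popdata$intakes, "intakes.csv"),
    w(popdata$components, "components.csv"),
    w(popdata$foods, "foods.csv"),
    w(params$recipes, "recipes.csv"),
    w(params$loss_profiles, "loss_profiles.csv"),
    w(params$group_map, "group_map.csv"),
    w(params$hei_standards, "hei2015_standards.csv"),
    w(params$ahei_standards, "ahei2010_standards.csv"),
    w(params$agronomic$crops, "agronomic/crops.csv"),
    w(params$agronomic$rates, "agronomic/rates.csv"),
    w(params$agronomic$commodity_map, "agronomic/commodity_map.csv"),
    w(params$agronomic$feed, "agronomic/feed.csv"),
    w(params$agronomic$pasture_req, "agronomic/pasture_req.csv"),
    w(params$agronomic$allocation, "agronomic/allocation.csv"),
    w(params$agronomic$availability, "agronomic/availability.csv"),
    w(params$agronomic$domestic, "agronomic/domestic.csv"),
    w(params$agronomic$available_land, "agronomic/available_land.csv")
  )
  spec_path <- file.path(dir, "generation_spec.yaml")
  yaml::write_yaml(list(
    design = unclass(popdata$design), population = unclass(popdata$pop),
    parameter_seed = params$seed,
    population_size = params$agronomic$population_size,
    pasture_utilization = params$agronomic$pasture_utilization,
    unmapped_foods = params$unmapped_foods
  ), spec_path)
  invisible(c(files, spec_path))
}
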