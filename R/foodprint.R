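# Simplified closed-food-system biophysical model: population food demand
# in, agricultural land by land-use category and fertilizer / pesticide /
# irrigation totals out. The original model's retail and consumer loss
# stages are structurally absent here (loss and waste enter as separate
# demand streams); pre-retail losses live inside the processing conversion
# factors.

#' Reapportion non-domestic demand within food groups
#'
#' Under the closed-system assumption all demanded food is produced
#' domestically, so demand for commodities flagged as not produced
#' domestically is redistributed to the other members of the same food
#' group. By default the split is proportional to fixed availability
#' weights (an availability-series analogue), which keeps the operation
#' linear in demand; passing `availability = NULL` splits proportionally
#' to the current demand vector instead. Group totals are conserved
#' exactly.
#'
#' @param demand Tibble (commodity_id, value); `value` is any mass on a
#'   linear scale (g/d per capita or kg/yr).
#' @param domestic Tibble (commodity_id, domestic logical).
#' @param group_map Tibble (commodity_id, food_group).
#' @param availability Optional tibble (commodity_id, availability) of
#'   fixed redistribution weights.
#' @return Tibble (commodity_id, value) with non-domestic rows zeroed and
#'   their mass redistributed.
#' @export
reapportion_imports <- function(demand, domestic, group_map, availability = NULL) {
  # Complete the demand vector over the commodity universe of the flagged
  # groups: a domestic commodity that happens to have zero observed demand
  # must still be able to receive redistributed mass.
  flagged_groups <- group_map$food_group[
    group_map$commodity_id %in% domestic$commodity_id[!domestic$domestic]]
  universe <- group_map$commodity_id[group_map$food_group %in% flagged_groups]
  extra <- setdiff(universe, demand$commodity_id)
  if (length(extra)) {
    demand <- dplyr::bind_rows(
      demand, tibble::tibble(commodity_id = extra, value = 0))
  }
  d <- demand |>
    dplyr::inner_join(domestic, by = "commodity_id") |>
    dplyr::inner_join(group_map, by = "commodity_id")
  if (nrow(d) != nrow(demand)) {
    abort("some commodities lack a domestic flag or food group")
  }
  if (!is.null(availability)) {
    d <- dplyr::inner_join(d, availability, by = "commodity_id")
  } else {
    d$availability <- d$value
  }
  out <- d |>
    dplyr::group_by(.data$food_group) |>
    dplyr::group_modify(function(g, key) {
      flagged <- sum(g$value[!g$domestic])
      if (flagged > 0 && !any(g$domestic)) {
        abort(sprintf("food group '%s' has demand but no domestic member",
                      key$food_group))
      }
      if (flagged > 0) {
        wts <- ifelse(g$domestic, g$availability, 0)
        if (sum(wts) <= 0) {
          abort(sprintf("food group '%s': zero redistribution weight", key$food_group))
        }
        g$value <- ifelse(g$domestic, g$value + flagged * wts / sum(wts), 0)
      } else {
        g$value[!g$domestic] <- 0
      }
      g
    }) |>
    dplyr::ungroup()
  out[match(demand$commodity_id, out$commodity_id), c("commodity_id", "value")]
}

#' Convert food demand to primary crop production requirements
#'
#' Plant commodities are converted from as-consumed to primary-crop mass by
#' their processing conversion factor (which also carries pre-retail
#' losses). Animal commodities are converted to carcass weight and then to
#' feed-crop requirements through their feed vectors, plus grazing-land
#' requirements per pasture category (adjusted by the pasture utilization
#' scalar). Every conversion is recorded in an allocation ledger (use,
#' crop, kg) whose column sums give total crop requirements, so multi-use
#' crops are attributed on a mass basis without double counting.
#'
#' @param demand Tibble (commodity_id, kg_yr) of population-scale demand.
#' @param agronomic Agronomic parameter list (see
#'   [generate_parameter_tables()]).
#' @return List: `ledger` (commodity_id, crop_id, kg_yr),
#'   `crop_requirements` (crop_id, kg_yr), `pasture_land` (land_use, ha).
#' @export
demand_to_primary_crops <- function(demand, agronomic) {
  cm <- agronomic$commodity_map
  missing <- setdiff(demand$commodity_id, cm$commodity_id)
  if (length(missing)) {
    abort(sprintf("no conversion parameters for: %s",
                  paste(sort(missing), collapse = ", ")))
  }
  d <- dplyr::inner_join(demand, cm, by = "commodity_id")

  plant <- d |>
    dplyr::filter(.data$kind == "plant") |>
    dplyr::transmute(.data$commodity_id, .data$crop_id,
                     kg_yr = .data$kg_yr * .data$conversion)

  animal <- d |> dplyr::filter(.data$kind == "animal")
  feed_rows <- animal |>
    dplyr::select("commodity_id", carcass_conv = "conversion", demand_kg = "kg_yr") |>
    dplyr::inner_join(agronomic$feed, by = "commodity_id",
                      relationship = "many-to-many") |>
    dplyr::transmute(.data$commodity_id, .data$crop_id,
                     kg_yr = .data$demand_kg * .data$carcass_conv * .data$kg_feed_per_kg)

  ledger <- dplyr::bind_rows(plant, feed_rows)
  crop_requirements <- ledger |>
    dplyr::group_by(.data$crop_id) |>
    dplyr::summarise(kg_yr = sum(.data$kg_yr), .groups = "drop")

  utilization <- agronomic$pasture_utilization %||% 1
  pasture_land <- animal |>
    dplyr::select("commodity_id", carcass_conv = "conversion", demand_kg = "kg_yr") |>
    dplyr::inner_join(agronomic$pasture_req, by = "commodity_id",
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$land_use) |>
    dplyr::summarise(
      ha = sum(.data$demand_kg * .data$carcass_conv * .data$ha_per_kg) / utilization,
      .groups = "drop")

  list(ledger = ledger, crop_requirements = crop_requirements,
       pasture_land = pasture_land)
}

#' Convert crop requirements to agricultural land by category
#'
#' Land for each crop is its mass requirement divided by yield, divided by
#' the double-crop factor where the same field produces more than one crop
#' per year. Crop-level areas are aggregated to land-use categories and
#' grazing land (from [demand_to_primary_crops()]) is appended.
#'
#' @param crop_requirements Tibble (crop_id, kg_yr).
#' @param agronomic Agronomic parameter list.
#' @param pasture_land Optional tibble (land_use, ha) of grazing land.
#' @return Tibble (land_use, land_ha).
#' @export
crops_to_land <- function(crop_requirements, agronomic, pasture_land = NULL) {
  crops <- agronomic$crops
  missing <- setdiff(crop_requirements$crop_id, crops$crop_id)
  if (length(missing)) {
    abort(sprintf("no crop parameters for: %s", paste(sort(missing), collapse = ", ")))
  }
  if (any(crops$yield_kg_ha <= 0)) abort("crop yields must be > 0")
  land <- crop_requirements |>
    dplyr::inner_join(crops, by = "crop_id") |>
    dplyr::mutate(ha = .data$kg_yr / .data$yield_kg_ha / .data$double_crop_factor) |>
    dplyr::group_by(.data$land_use) |>
    dplyr::summarise(land_ha = sum(.data$ha), .groups = "drop")
  if (!is.null(pasture_land) && nrow(pasture_land)) {
    land <- dplyr::bind_rows(
      land, dplyr::rename(pasture_land, land_ha = "ha")) |>
      dplyr::group_by(.data$land_use) |>
      dplyr::summarise(land_ha = sum(.data$land_ha), .groups = "drop")
  }
  dplyr::arrange(land, .data$land_use)
}

#' Convert land by category to resource use
#'
#' Applies the per-hectare application rates of each land-use category:
#' fertilizer nutrients are the sum of nitrogen, phosphate (P2O5) and
#' potash (K2O); pesticides and irrigation water are applied directly. A
#' missing rate for a category with nonzero land is a configuration error.
#'
#' @param land Tibble (land_use, land_ha).
#' @param agronomic Agronomic parameter list with a `rates` table.
#' @return Tibble (land_use, land_ha, fertilizer_kg, pesticide_kg,
#'   irrigation_m3).
#' @export
land_to_resources <- function(land, agronomic) {
  rates <- agronomic$rates
  joined <- dplyr::left_join(land, rates, by = "land_use")
  bad <- joined$land_ha > 0 & !is.finite(joined$n_rate_kg_ha)
  if (any(bad)) {
    abort(sprintf("no application rates for land-use category(ies): %s",
                  paste(joined$land_use[bad], collapse = ", ")))
  }
  joined |>
    dplyr::transmute(
      .data$land_use, .data$land_ha,
      fertilizer_kg = .data$land_ha *
        (.data$n_rate_kg_ha + .data$p_rate_kg_ha + .data$k_rate_kg_ha),
      pesticide_kg = .data$land_ha * .data$pesticide_rate_kg_ha,
      irrigation_m3 = .data$land_ha * .data$irrigation_rate_m3_ha
    )
}

resource_names <- c("land_ha", "fertilizer_kg", "pesticide_kg", "irrigation_m3")

#' Total a resource footprint over land-use categories
#'
#' @param footprint Output of [land_to_resources()].
#' @return One-row tibble of resource totals.
#' @export
footprint_totals <- function(footprint) {
  dplyr::summarise(footprint,
                   dplyr::across(dplyr::all_of(resource_names), sum))
}

#' Run the full demand-to-resources chain
#'
#' Scales per-capita daily demand to annual population demand, reapportions
#' non-domestic commodities, converts demand to primary crops, crops to
#' land, and land to resource use. When the parameter set carries
#' available-land bounds, required land per category is reported against
#' availability with an exceedance flag (no optimization is attempted).
#'
#' @param demand_g_day Tibble (commodity_id, grams) of per-capita demand.
#' @param agronomic Agronomic parameter list.
#' @param group_map Tibble (commodity_id, food_group) for reapportionment.
#' @param population_size Number of people the per-capita demand scales to;
#'   defaults to the value embedded in the parameter set.
#' @param days_per_year Days used to annualise daily intake.
#' @return List: `footprint` (by land-use category), `totals` (one row),
#'   `land`, `crops` (requirements), `ledger`, `demand_kg_yr`, and
#'   `land_check` (or NULL).
#' @export
compute_footprint <- function(demand_g_day, agronomic, group_map,
                              population_size = NULL, days_per_year = 365) {
  population_size <- population_size %||% agronomic$population_size
  demand <- tibble::tibble(
    commodity_id = demand_g_day$commodity_id,
    value = demand_g_day$grams * population_size * days_per_year / 1000
  )
  demand <- reapportion_imports(demand, agronomic$domestic, group_map,
                                agronomic$availability)
  demand <- dplyr::rename(demand, kg_yr = "value")
  conv <- demand_to_primary_crops(demand, agronomic)
  land <- crops_to_land(conv$crop_requirements, agronomic, conv$pasture_land)
  fp <- land_to_resources(land, agronomic)
  land_check <- NULL
  if (!is.null(agronomic$available_land)) {
    land_check <- dplyr::left_join(land, agronomic$available_land, by = "land_use") |>
      dplyr::mutate(exceeds = .data$land_ha > .data$available_ha)
  }
  list(footprint = fp, totals = footprint_totals(fp), land = land,
       crops = conv$crop_requirements, ledger = conv$ledger,
       demand_kg_yr = demand, land_check = land_check)
}

#' Attribute resource use to loss/waste input streams
#'
#' The model chain is linear in demand, so running it once per input
#' stream (retail loss, inedible, consumer waste, consumed) and
#' normalising gives each stream's share of every resource; shares sum to
#' one per resource.
#'
#' @param footprints Named list of footprint-by-category tibbles (or
#'   `compute_footprint()` results), one per stream.
#' @return Tibble (resource, stream, value, share).
#' @export
attribute_to_loss_categories <- function(footprints) {
  totals <- lapply(footprints, function(f) {
    if (is.list(f) && !is.data.frame(f) && !is.null(f$totals)) f$totals
    else footprint_totals(f)
  })
  long <- dplyr::bind_rows(totals, .id = "stream") |>
    tidyr::pivot_longer(dplyr::all_of(resource_names),
                        names_to = "resource", values_to = "value")
  out <- long |>
    dplyr::group_by(.data$resource) |>
    dplyr::mutate(share = {
      tot <- sum(.data$value)
      if (tot <= 0) abort(sprintf("resource '%s' is zero across all streams; shares undefined",
                                  dplyr::cur_group()$resource))
      .data$value / tot
    }) |>
    dplyr::ungroup()
  out
}

#' Monte Carlo uncertainty for the footprint
#'
#' Propagates inter-individual dietary variability: each replicate draws
#' `draw_size` individuals without replacement (with probability
#' proportional to survey weight by default), recomputes the weighted
#' per-capita commodity demand from the subsample, runs the full model
#' chain scaled to the population, and stores the resource totals. Point
#' estimates are replicate means; intervals are the 2.5th and 97.5th
#' percentiles. Deterministic under a fixed seed.
#'
#' @param individual_demand Tibble (id, commodity_id, grams) of the chosen
#'   demand stream per individual (e.g. `total_demand` from
#'   [demand_breakdown()]).
#' @param records Tibble (id, weight, ...covering every individual).
#' @param agronomic,group_map Model parameters as in [compute_footprint()].
#' @param draw_size Individuals per draw (default half the sample).
#' @param n_reps Number of replicates (>= 2; default 500).
#' @param seed Integer seed.
#' @param weighted Draw with probability proportional to weight?
#' @param population_size Passed to [compute_footprint()].
#' @return List: `summary` tibble (resource, mean, lower, upper) and
#'   `replicates` (n_reps x 4 matrix of resource totals).
#' @export
monte_carlo_footprint <- function(individual_demand, records, agronomic,
                                  group_map, draw_size = NULL, n_reps = 500,
                                  seed = 1L, weighted = TRUE,
                                  population_size = NULL) {
  n <- nrow(records)
  draw_size <- draw_size %||% floor(n / 2)
  if (draw_size > n) abort("`draw_size` cannot exceed the number of individuals")
  if (n_reps < 2) abort("`n_reps` must be >= 2")
  set.seed(seed)
  reps <- matrix(NA_real_, n_reps, length(resource_names),
                 dimnames = list(NULL, resource_names))
  prob <- if (weighted) records$weight else NULL
  for (r in seq_len(n_reps)) {
    ids <- sample(records$id, draw_size, replace = FALSE, prob = prob)
    sub_w <- records$weight[match(ids, records$id)]
    sub <- individual_demand[individual_demand$id %in% ids, , drop = FALSE]
    demand <- sub |>
      dplyr::mutate(w = records$weight[match(.data$id, records$id)]) |>
      dplyr::group_by(.data$commodity_id) |>
      dplyr::summarise(grams = sum(.data$grams * .data$w) / sum(sub_w),
                       .groups = "drop")
    fp <- compute_footprint(demand, agronomic, group_map,
                            population_size = population_size)
    reps[r, ] <- as.numeric(fp$totals[1, resource_names])
  }
  summary <- tibble::tibble(
    resource = resource_names,
    mean = colMeans(reps),
    lower = unname(apply(reps, 2, quantile, probs = 0.025, names = FALSE)),
    upper = unname(apply(reps, 2, quantile, probs = 0.975, names = FALSE))
  )
  list(summary = summary, replicates = reps)
}
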