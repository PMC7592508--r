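#' Back-calculate the loss/waste mass balance for consumed mass
#'
#' Given consumed grams and a commodity's loss profile, works the retail
#' supply chain backwards: consumer waste is a fraction `w` of edible
#' purchased mass, inedible portions a fraction `i` of purchased mass, and
#' retail loss a fraction `r` of retail-level supply, so
#' `edible_purchased = consumed / (1 - w)`,
#' `purchased = edible_purchased / (1 - i)`,
#' `total_demand = purchased / (1 - r)`,
#' with category masses recovered by subtraction. The four categories
#' (consumed, consumer waste, inedible, retail loss) sum to Total Food
#' Demand by construction.
#'
#' @param consumed_g Consumed grams/day (vectorised).
#' @param retail_loss,inedible,consumer_waste Loss fractions in \[0, 1),
#'   recycled against `consumed_g`.
#' @return Tibble with columns `consumed`, `consumer_waste`, `inedible`,
#'   `edible_purchased`, `purchased`, `retail_loss`, `total_demand` (g/d).
#' @export
partition_commodity <- function(consumed_g, retail_loss, inedible, consumer_waste) {
  if (any(consumed_g < 0)) abort("consumed mass must be >= 0")
  fr <- c(retail_loss, inedible, consumer_waste)
  if (any(fr < 0) || any(fr >= 1)) abort("loss fractions must lie in [0, 1)")
  n <- length(consumed_g)
  r <- rep_len(retail_loss, n)
  i <- rep_len(inedible, n)
  w <- rep_len(consumer_waste, n)

  edible_purchased <- consumed_g / (1 - w)
  purchased <- edible_purchased / (1 - i)
  total_demand <- purchased / (1 - r)
  tibble::tibble(
    consumed = consumed_g,
    consumer_waste = edible_purchased - consumed_g,
    inedible = purchased - edible_purchased,
    edible_purchased = edible_purchased,
    purchased = purchased,
    retail_loss = total_demand - purchased,
    total_demand = total_demand
  )
}

demand_categories <- c("consumed", "consumer_waste", "inedible", "retail_loss")

#' Per-individual, per-commodity demand breakdown
#'
#' Joins commodity intakes with their loss profiles and partitions each
#' consumed mass into the loss/waste categories. Commodities absent from
#' the loss table get zero loss with a logged warning by default.
#'
#' @param intakes Tibble (id, commodity_id, grams consumed/day).
#' @param loss_profiles Tibble (commodity_id, retail_loss, inedible,
#'   consumer_waste).
#' @param missing_policy `"zero"` (default) or `"error"` for commodities
#'   without a loss profile.
#' @return Tibble (id, commodity_id, consumed, consumer_waste, inedible,
#'   edible_purchased, purchased, retail_loss, total_demand).
#' @export
demand_breakdown <- function(intakes, loss_profiles,
                             missing_policy = c("zero", "error")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(all(c("commodity_id", "retail_loss", "inedible", "consumer_waste")
                %in% names(loss_profiles)))
  missing <- setdiff(unique(intakes$commodity_id), loss_profiles$commodity_id)
  if (length(missing)) {
    if (missing_policy == "error") {
      abort(sprintf("no loss profile for: %s", paste(sort(missing), collapse = ", ")))
    }
    warn(sprintf("assigning zero loss to %d commodity(ies) without a loss profile",
                 length(missing)))
  }
  joined <- dplyr::left_join(intakes, loss_profiles, by = "commodity_id") |>
    dplyr::mutate(dplyr::across(c("retail_loss", "inedible", "consumer_waste"),
                                ~ dplyr::coalesce(.x, 0)))
  parts <- partition_commodity(joined$grams, joined$retail_loss,
                               joined$inedible, joined$consumer_waste)
  dplyr::bind_cols(joined[c("id", "commodity_id")], parts)
}

#' Survey-weighted per-capita demand breakdown
#'
#' Aggregates individual commodity-level breakdowns to survey-weighted
#' per-capita means of each loss/waste category, overall and by food
#' group. Category additivity (the four categories summing to Total Food
#' Demand) is preserved at every scope, and the overall row equals the sum
#' over food groups.
#'
#' @param breakdown Output of [demand_breakdown()].
#' @param records Tibble with `id` and `weight` (one row per individual;
#'   individuals with no intake contribute zeros).
#' @param group_map Tibble (commodity_id, food_group) covering every
#'   commodity present.
#' @return Tibble with `scope` (`"overall"` or the food group) and the
#'   per-capita category columns of [partition_commodity()] (g/d).
#' @export
per_capita_breakdown <- function(breakdown, records, group_map) {
  if (nrow(breakdown) == 0) abort("empty breakdown: nothing to aggregate")
  if (any(records$weight <= 0)) abort("all weights must be positive")
  missing <- setdiff(unique(breakdown$commodity_id), group_map$commodity_id)
  if (length(missing)) {
    abort(sprintf("commodities missing from group map: %s",
                  paste(sort(missing), collapse = ", ")))
  }
  cats <- c(demand_categories, "edible_purchased", "purchased", "total_demand")
  sum_w <- sum(records$weight)

  per_group_person <- breakdown |>
    dplyr::inner_join(group_map, by = "commodity_id") |>
    dplyr::group_by(.data$food_group, .data$id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cats), sum), .groups = "drop") |>
    dplyr::inner_join(records[c("id", "weight")], by = "id")

  # Weighted mean with the FULL weight denominator: individuals consuming
  # nothing in a group still count in the per-capita base.
  groups <- per_group_person |>
    dplyr::group_by(scope = .data$food_group) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cats),
                                   ~ sum(.x * .data$weight) / sum_w),
                     .groups = "drop")
  overall <- groups |>
    dplyr::summarise(scope = "overall",
                     dplyr::across(dplyr::all_of(cats), sum))
  dplyr::bind_rows(overall, groups)
}
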