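#' Validate a recipe table
#'
#' A recipe table maps each as-consumed food (including mixed dishes) to
#' commodity-level ingredients by mass fraction. Fractions must be
#' non-negative, no (food, commodity) pair may repeat, and each food's
#' fractions must sum to one within `tol`. Rows failing validation abort
#' the run rather than being silently renormalised.
#'
#' @param recipes Tibble with columns `food_id`, `commodity_id`, `fraction`.
#' @param tol Tolerance on per-food fraction sums (default 1e-6).
#' @return The validated table, invisibly.
#' @export
validate_recipes <- function(recipes, tol = 1e-6) {
  stopifnot(all(c("food_id", "commodity_id", "fraction") %in% names(recipes)))
  if (any(recipes$fraction < 0)) abort("recipe fractions must be >= 0")
  if (anyDuplicated(recipes[c("food_id", "commodity_id")])) {
    abort("recipe table has duplicate (food, commodity) pairs")
  }
  sums <- tapply(recipes$fraction, recipes$food_id, sum)
  bad <- names(sums)[abs(sums - 1) > tol]
  if (length(bad)) {
    abort(sprintf("recipe fractions do not sum to 1 (tol %g) for: %s",
                  tol, paste(head(bad, 5), collapse = ", ")))
  }
  invisible(recipes)
}

#' Disaggregate as-consumed foods into commodity intakes
#'
#' Distributes each individual's per-food grams over commodities by recipe
#' mass fraction, the recipe-database step that turns mixed dishes into
#' ingredient-level consumed mass. Foods absent from the recipe table are
#' either dropped with a logged mass-share warning (default, mirroring
#' recipe databases that lag the recall instrument) or raise an error.
#'
#' @param popdata A `diet_population`, or a tibble of intakes with columns
#'   `id`, `food_id`, `grams`.
#' @param recipes Recipe table (validated with [validate_recipes()]).
#' @param unmapped_policy `"drop"` (default) or `"error"`.
#' @param tol Recipe-sum tolerance passed to [validate_recipes()].
#' @return A list: `intakes` — tibble (id, commodity_id, grams consumed/day);
#'   `coverage` — list with `unmapped_foods`, `unmapped_grams`,
#'   `total_grams`, `mapped_grams` and `unmapped_share` (share of total
#'   recalled mass carried by unmapped foods).
#' @export
disaggregate <- function(popdata, recipes, unmapped_policy = c("drop", "error"),
                         tol = 1e-6) {
  unmapped_policy <- match.arg(unmapped_policy)
  validate_recipes(recipes, tol)
  intakes <- if (inherits(popdata, "diet_population")) popdata$intakes else popdata
  stopifnot(all(c("id", "food_id", "grams") %in% names(intakes)))
  if (any(intakes$grams < 0)) abort("food grams must be >= 0")

  unmapped <- setdiff(unique(intakes$food_id), unique(recipes$food_id))
  if (length(unmapped) && unmapped_policy == "error") {
    abort(sprintf("foods missing from recipe table: %s",
                  paste(sort(unmapped), collapse = ", ")))
  }
  total_grams <- sum(intakes$grams)
  unmapped_grams <- sum(intakes$grams[intakes$food_id %in% unmapped])
  if (length(unmapped)) {
    warn(sprintf("dropping %d unmapped food(s) carrying %.1f%% of recalled mass",
                 length(unmapped),
                 100 * unmapped_grams / max(total_grams, .Machine$double.eps)))
  }

  mapped <- dplyr::inner_join(intakes, recipes, by = "food_id",
                              relationship = "many-to-many")
  out <- mapped |>
    dplyr::mutate(grams = .data$grams * .data$fraction) |>
    dplyr::group_by(.data$id, .data$commodity_id) |>
    dplyr::summarise(grams = sum(.data$grams), .groups = "drop") |>
    dplyr::arrange(.data$id, .data$commodity_id)

  list(
    intakes = out,
    coverage = list(
      unmapped_foods = sort(unmapped),
      unmapped_grams = unmapped_grams,
      total_grams = total_grams,
      mapped_grams = total_grams - unmapped_grams,
      unmapped_share = if (total_grams > 0) unmapped_grams / total_grams else 0
    )
  )
}

#' Aggregate commodity intakes to food groups
#'
#' @param intakes Tibble (id, commodity_id, grams).
#' @param group_map Tibble (commodity_id, food_group); every commodity must
#'   appear exactly once.
#' @return Tibble (id, food_group, grams); group totals conserve commodity
#'   mass exactly.
#' @export
aggregate_to_food_groups <- function(intakes, group_map) {
  stopifnot(all(c("commodity_id", "food_group") %in% names(group_map)))
  if (anyDuplicated(group_map$commodity_id)) {
    abort("group map assigns some commodity to more than one group")
  }
  missing <- setdiff(unique(intakes$commodity_id), group_map$commodity_id)
  if (length(missing)) {
    abort(sprintf("commodities missing from group map: %s",
                  paste(sort(missing), collapse = ", ")))
  }
  dplyr::inner_join(intakes, group_map, by = "commodity_id") |>
    dplyr::group_by(.data$id, .data$food_group) |>
    dplyr::summarise(grams = sum(.data$grams), .groups = "drop")
}
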