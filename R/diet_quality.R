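#' Score one index component
#'
#' Piecewise-linear scoring between the zero-score and full-score
#' thresholds, clamped to \[0, max\]. Adequacy components award more points
#' for more intake; moderation components are reverse scored. The adult
#' alcohol rule is a two-sided trapezoid: non-consumers receive the partial
#' credit recorded in the standards table (2.5 points), points rise to the
#' maximum over the moderate band, hold there, and fall to zero at heavy
#' intake, with sex-specific band edges.
#'
#' @param amount Amount(s) already expressed on the component's scoring
#'   basis (e.g. cup equivalents per 1000 kcal, servings/day, percent of
#'   energy).
#' @param standard One row of a standards table (see [hei2015_standards()]).
#' @param sex `"male"`/`"female"` vector recycled against `amount`; used
#'   only where the standards table carries sex-specific thresholds.
#' @return Numeric points in \[0, max_points\].
#' @export
score_component <- function(amount, standard, sex = "male") {
  if (nrow(standard) != 1L) abort("`standard` must be a single standards row")
  if (any(amount < 0, na.rm = TRUE)) abort("component amounts must be >= 0")
  sex <- rep_len(sex, length(amount))
  mx <- standard$max_points

  if (standard$special_rule == "adult-alcohol-band") {
    lo <- standard$band_low
    hi <- resolve_threshold(standard$band_high, standard$band_high_female, sex)
    z  <- resolve_threshold(standard$zero_above, standard$zero_above_female, sex)
    nc <- standard$nonconsumer_points
    pts <- numeric(length(amount))
    pts[amount == 0] <- nc
    rising <- amount > 0 & amount < lo
    pts[rising] <- nc + (mx - nc) * amount[rising] / lo
    band <- amount >= lo & amount <= hi
    pts[band] <- mx
    falling <- amount > hi & amount < z
    pts[falling] <- mx * (z[falling] - amount[falling]) / (z[falling] - hi[falling])
    pts[amount >= z] <- 0
    return(pts)
  }

  z <- resolve_threshold(standard$zero_score, standard$zero_score_female %||% NA, sex)
  f <- resolve_threshold(standard$full_score, standard$full_score_female %||% NA, sex)
  frac <- switch(standard$direction,
    adequacy   = (amount - z) / (f - z),
    moderation = (z - amount) / (z - f),
    abort(sprintf("unknown direction '%s'", standard$direction))
  )
  mx * pmin(pmax(frac, 0), 1)
}

# Pivot the long component table to wide, one row per individual.
components_wide <- function(components, prefix) {
  components |>
    dplyr::filter(startsWith(.data$component, prefix)) |>
    tidyr::pivot_wider(id_cols = "id", names_from = "component",
                       values_from = "amount", values_fill = 0)
}

drop_nonpositive_energy <- function(records, energy_policy) {
  bad <- records$energy_kcal <= 0
  if (any(bad)) {
    if (energy_policy == "error") {
      abort(sprintf("%d record(s) report non-positive energy", sum(bad)))
    }
    warn(sprintf("excluding %d record(s) with non-positive energy from scoring",
                 sum(bad)))
    records <- records[!bad, , drop = FALSE]
  }
  records
}

score_index <- function(basis_amounts, standards, sex) {
  pts <- lapply(standards$component, function(cp) {
    score_component(basis_amounts[[cp]], standards[standards$component == cp, ], sex)
  })
  names(pts) <- standards$component
  tibble::as_tibble(pts)
}

#' Score diets with the Healthy Eating Index 2015
#'
#' Scores all 13 HEI-2015 components for each individual. Density-basis
#' components are standardised per 1000 kcal of reported energy; the
#' fatty-acid ratio and the percent-of-energy components are scored as is.
#' Component points sum to a total with a maximum of 100.
#'
#' @param popdata A `diet_population`, or a list with `records`
#'   (id, sex, energy_kcal, ...) and `components` (id, component, amount).
#' @param standards HEI-2015 standards table; defaults to the published one.
#' @param energy_policy `"drop"` (default) excludes non-positive-energy
#'   records with a logged count; `"error"` aborts.
#' @return Tibble: `id`, one points column per component, `total`.
#' @export
hei2015_score <- function(popdata, standards = hei2015_standards(),
                          energy_policy = c("drop", "error")) {
  energy_policy <- match.arg(energy_policy)
  records <- drop_nonpositive_energy(popdata$records, energy_policy)
  wide <- components_wide(popdata$components, "hei_") |>
    dplyr::inner_join(records[c("id", "sex", "energy_kcal")], by = "id")
  for (k in seq_len(nrow(standards))) {
    cp <- standards$component[k]
    if (!cp %in% names(wide)) abort(sprintf("component '%s' missing from data", cp))
    if (standards$basis[k] == "density_1000") {
      wide[[cp]] <- wide[[cp]] / wide$energy_kcal * 1000
    }
  }
  pts <- score_index(wide, standards, wide$sex)
  dplyr::bind_cols(tibble::tibble(id = wide$id), pts) |>
    dplyr::mutate(total = rowSums(pts))
}

#' Score diets with the (modified) Alternative Healthy Eating Index 2010
#'
#' Scores the 10 AHEI-2010 components used here (trans fat excluded). Under
#' the modified variant every daily amount is first rescaled to the 1849
#' kcal/d reference intake of the index's source population
#' (`amount * 1849 / energy`), and individuals younger than 18 receive 10
#' alcohol points for zero reported consumption and 0 points otherwise.
#' Unmodified, amounts are scored raw and the adult alcohol band applies to
#' everyone. Percent-of-energy components are already energy-adjusted and
#' are never rescaled.
#'
#' @inheritParams hei2015_score
#' @param standards AHEI-2010 standards table.
#' @param modified Apply the energy adjustment and child alcohol rule?
#' @param reference_kcal Source-population mean energy intake (kcal/d).
#' @return Tibble: `id`, one points column per component, `total`.
#' @export
ahei2010_score <- function(popdata, standards = ahei2010_standards(),
                           modified = TRUE, reference_kcal = 1849,
                           energy_policy = c("drop", "error")) {
  energy_policy <- match.arg(energy_policy)
  records <- drop_nonpositive_energy(popdata$records, energy_policy)
  wide <- components_wide(popdata$components, "ahei_") |>
    dplyr::inner_join(records[c("id", "sex", "age", "energy_kcal")], by = "id")
  for (k in seq_len(nrow(standards))) {
    cp <- standards$component[k]
    if (!cp %in% names(wide)) abort(sprintf("component '%s' missing from data", cp))
    if (modified && standards$basis[k] == "per_day") {
      wide[[cp]] <- wide[[cp]] * reference_kcal / wide$energy_kcal
    }
  }
  pts <- score_index(wide, standards, wide$sex)
  if (modified) {
    # Child rule operates on reported (unscaled) consumption: any intake at
    # all forfeits the component.
    raw_alcohol <- components_wide(popdata$components, "ahei_")
    raw_alcohol <- raw_alcohol$ahei_alcohol[match(wide$id, raw_alcohol$id)]
    child <- wide$age < 18
    mx <- standards$max_points[standards$component == "ahei_alcohol"]
    pts$ahei_alcohol[child] <- ifelse(raw_alcohol[child] == 0, mx, 0)
  }
  dplyr::bind_cols(tibble::tibble(id = wide$id), pts) |>
    dplyr::mutate(total = rowSums(pts))
}

#' Population-ratio mean index score
#'
#' Scores the population's mean component densities rather than averaging
#' individual scores: for each component the survey-weighted total amount is
#' divided by the survey-weighted total energy (rescaled to the component's
#' basis) and that single population-level density is scored. Because
#' clamping is nonlinear, this generally differs from the weighted mean of
#' individual scores. Doubling every weight leaves the result unchanged.
#'
#' @param popdata A `diet_population` (or compatible list).
#' @param standards Standards table for the chosen index.
#' @param index `"HEI-2015"` or `"AHEI-2010"`.
#' @param modified For AHEI-2010: use the 1849 kcal reference basis.
#' @param reference_kcal AHEI source-population mean energy intake.
#' @return List: `components` tibble (component, basis_amount, points) and
#'   `total` (the population score).
#' @export
population_ratio_mean <- function(popdata, standards = NULL,
                                  index = c("HEI-2015", "AHEI-2010"),
                                  modified = TRUE, reference_kcal = 1849) {
  index <- match.arg(index)
  standards <- standards %||%
    if (index == "HEI-2015") hei2015_standards() else ahei2010_standards()
  prefix <- if (index == "HEI-2015") "hei_" else "ahei_"
  records <- popdata$records
  if (any(records$weight <= 0)) abort("all weights must be positive")
  wide <- components_wide(popdata$components, prefix) |>
    dplyr::inner_join(records[c("id", "sex", "weight", "energy_kcal")], by = "id")
  w <- wide$weight
  total_energy <- sum(w * wide$energy_kcal)
  if (total_energy <= 0) abort("population total energy is not positive")
  # Sex-specific thresholds are resolved to the weighted population mix.
  share_female <- sum(w[wide$sex == "female"]) / sum(w)
  pop_sex <- if (share_female >= 0.5) "female" else "male"

  rows <- lapply(seq_len(nrow(standards)), function(k) {
    cp <- standards$component[k]
    amt <- wide[[cp]]
    basis_amount <- switch(standards$basis[k],
      density_1000 = sum(w * amt) / total_energy * 1000,
      per_day = if (modified) sum(w * amt) / total_energy * reference_kcal
                else sum(w * amt) / sum(w),
      as_is = sum(w * amt * wide$energy_kcal) / total_energy,
      abort(sprintf("unknown basis '%s'", standards$basis[k]))
    )
    tibble::tibble(
      component = cp, basis_amount = basis_amount,
      points = score_component(basis_amount, standards[k, ], pop_sex)
    )
  })
  components <- dplyr::bind_rows(rows)
  list(components = components, total = sum(components$points))
}

#' Assign survey-weighted quintiles of diet quality
#'
#' Cutpoints are the weighted 20/40/60/80th percentiles computed as the
#' left-continuous inverse of the weighted ECDF; scores tied with a
#' cutpoint fall in the lower quintile. Quintile 1 is the lowest diet
#' quality. With heavy ties (fewer than five distinct scores) labels
#' degenerate toward the lower quintiles and a warning is emitted.
#'
#' @param scores Numeric total scores.
#' @param weights Survey weights (ignored when `weighted = FALSE`).
#' @param weighted Form cutpoints on the weighted (default) or unweighted
#'   score distribution.
#' @return Integer quintile labels (1–5), same order as `scores`.
#' @export
assign_quintiles <- function(scores, weights = NULL, weighted = TRUE) {
  n <- length(scores)
  if (n < 5L) abort("quintile assignment needs at least 5 individuals")
  w <- if (weighted) {
    if (is.null(weights)) abort("`weights` required when weighted = TRUE")
    weights
  } else {
    rep(1, n)
  }
  if (any(w <= 0)) abort("all weights must be positive")
  if (length(unique(scores)) < 5L) {
    warn("fewer than 5 distinct scores; quintile labels are degenerate")
  }
  cuts <- weighted_quantile(scores, w, c(0.2, 0.4, 0.6, 0.8))
  q <- 1L + rowSums(outer(scores, cuts, ">"))
  as.integer(q)
}
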