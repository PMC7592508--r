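#' Configure a pipeline run
#'
#' Exactly one of `input_dir` (a directory of CSV inputs as written by
#' [write_synthetic_inputs()]) or `synthetic` (a list with `design` and
#' `pop` specs plus optional parameter-table arguments) must be supplied.
#'
#' @param synthetic List: `design` ([survey_design_spec()]), `pop`
#'   ([population_spec()]), and optionally `n_crops`,
#'   `unmapped_fraction` for [generate_parameter_tables()].
#' @param input_dir Directory containing pre-generated input tables.
#' @param quintile_weighted Form quintiles on the weighted distribution?
#' @param unmapped_policy,missing_policy Policies for recipe and loss-table
#'   gaps (see [disaggregate()], [demand_breakdown()]).
#' @param monte_carlo List: `n_reps`, `draw_size` (NULL = half the sample),
#'   or NULL to skip the Monte Carlo stage.
#' @param seed Integer master seed, recorded in every output's metadata.
#' @param output_dir Where to write tables and the manifest.
#' @return A validated `run_config` list.
#' @export
run_config <- function(synthetic = NULL, input_dir = NULL,
                       quintile_weighted = TRUE,
                       unmapped_policy = "drop", missing_policy = "zero",
                       monte_carlo = list(n_reps = 100, draw_size = NULL),
                       seed = 1L, output_dir = tempfile("dietfootprint_run_")) {
  if (is.null(synthetic) == is.null(input_dir)) {
    abort("exactly one of `synthetic` or `input_dir` must be supplied")
  }
  structure(list(synthetic = synthetic, input_dir = input_dir,
                 quintile_weighted = quintile_weighted,
                 unmapped_policy = unmapped_policy,
                 missing_policy = missing_policy,
                 monte_carlo = monte_carlo,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

write_output_csv <- function(x, path, hash, seed) {
  writeLines(sprintf("# config_hash: %s seed: %d", hash, seed), path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  path
}

#' Read a directory of input tables written by [write_synthetic_inputs()]
#'
#' @param dir Directory containing the CSV tables and `generation_spec.yaml`.
#' @return List with `popdata` (a `diet_population`) and `params` (the
#'   parameter list in the shape of [generate_parameter_tables()]).
#' @export
read_input_tables <- function(dir) {
  rd <- function(f) readr::read_csv(file.path(dir, f), show_col_types = FALSE,
                                    progress = FALSE)
  popdata <- structure(list(records = rd("records.csv"), intakes = rd("intakes.csv"),
                            components = rd("components.csv"), foods = rd("foods.csv")),
                       class = "diet_population")
  params <- list(
    recipes = rd("recipes.csv"), loss_profiles = rd("loss_profiles.csv"),
    group_map = rd("group_map.csv"),
    hei_standards = hei2015_standards(file.path(dir, "hei2015_standards.csv")),
    ahei_standards = ahei2010_standards(file.path(dir, "ahei2010_standards.csv")),
    agronomic = list(
      crops = rd("agronomic/crops.csv"), rates = rd("agronomic/rates.csv"),
      commodity_map = rd("agronomic/commodity_map.csv"),
      feed = rd("agronomic/feed.csv"), pasture_req = rd("agronomic/pasture_req.csv"),
      allocation = rd("agronomic/allocation.csv"),
      availability = rd("agronomic/availability.csv"),
      domestic = rd("agronomic/domestic.csv"),
      available_land = rd("agronomic/available_land.csv"),
      population_size = 3.21e8, pasture_utilization = 0.6
    )
  )
  spec_path <- file.path(dir, "generation_spec.yaml")
  if (file.exists(spec_path)) {
    gs <- yaml::read_yaml(spec_path)
    params$agronomic$population_size <- gs$population_size %||% 3.21e8
    params$agronomic$pasture_utilization <- gs$pasture_utilization %||% 0.6
  }
  list(popdata = popdata, params = params)
}

#' Per-capita commodity demand by loss/waste stream
#'
#' Survey-weighted per-capita grams of each stream for every commodity,
#' the demand vectors the footprint model consumes.
#'
#' @param breakdown Output of [demand_breakdown()].
#' @param records Tibble with `id` and `weight`.
#' @param streams Category columns to extract.
#' @return Named list of tibbles (commodity_id, grams).
#' @keywords internal
stream_demands <- function(breakdown, records,
                           streams = c(demand_categories, "total_demand")) {
  sum_w <- sum(records$weight)
  joined <- dplyr::inner_join(breakdown, records[c("id", "weight")], by = "id")
  lapply(setNames(streams, streams), function(s) {
    joined |>
      dplyr::group_by(.data$commodity_id) |>
      dplyr::summarise(grams = sum(.data[[s]] * .data$weight) / sum_w,
                       .groups = "drop")
  })
}

#' Run the full analysis pipeline
#'
#' Sequences the stages end-to-end: recipe disaggregation, diet-index
#' scoring and quintile assignment, loss/waste accounting, survey-weighted
#' estimation and quintile trend tests (unadjusted and age/sex adjusted),
#' the footprint model per loss/waste stream (with attribution shares),
#' per-quintile footprints, the modified-vs-original AHEI Wald tests, and
#' optionally the Monte Carlo footprint. Every output CSV carries a header
#' comment with the config hash and seed; a JSON manifest lists artifacts.
#' Identical config and seed reproduce identical outputs.
#'
#' @param config A [run_config()].
#' @return The run manifest (list), invisibly; results are also returned
#'   in the `results` element.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  hash <- rlang::hash(config[setdiff(names(config), "output_dir")])
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run.log")
  logf <- function(stage, msg) {
    cat(sprintf("[%s] %s\n", stage, msg), file = log_path, append = TRUE)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    sy <- config$synthetic
    design <- sy$design %||% survey_design_spec(seed = config$seed)
    design$seed <- config$seed
    pop <- sy$pop %||% population_spec()
    popdata <- stage("simulate", generate_population(design, pop))
    params <- stage("simulate", generate_parameter_tables(
      n_commodities = pop$n_commodities, n_crops = sy$n_crops %||% 12L,
      seed = config$seed + 1L, n_foods = pop$n_foods,
      unmapped_fraction = sy$unmapped_fraction %||% 0.05))
    logf("simulate", sprintf("%d individuals generated", nrow(popdata$records)))
  } else {
    inputs <- stage("load", read_input_tables(config$input_dir))
    popdata <- inputs$popdata
    params <- inputs$params
    logf("load", sprintf("%d individuals loaded", nrow(popdata$records)))
  }
  records <- popdata$records

  # --- disaggregation -----------------------------------------------------
  dis <- stage("disaggregate",
               disaggregate(popdata, params$recipes, config$unmapped_policy))
  logf("disaggregate", sprintf("%d commodity-intake rows; %.2f%% mass unmapped",
                               nrow(dis$intakes), 100 * dis$coverage$unmapped_share))

  # --- diet quality -------------------------------------------------------
  hei <- stage("score", hei2015_score(popdata, params$hei_standards))
  ahei <- stage("score", ahei2010_score(popdata, params$ahei_standards, modified = TRUE))
  ahei_orig <- stage("score",
                     ahei2010_score(popdata, params$ahei_standards, modified = FALSE))
  scores <- tibble::tibble(
    id = hei$id,
    hei2015 = hei$total,
    ahei2010 = ahei$total[match(hei$id, ahei$id)],
    ahei2010_original = ahei_orig$total[match(hei$id, ahei_orig$id)]
  ) |>
    dplyr::inner_join(records, by = "id")
  scores$hei_quintile <- assign_quintiles(scores$hei2015, scores$weight,
                                          config$quintile_weighted)
  scores$ahei_quintile <- assign_quintiles(scores$ahei2010, scores$weight,
                                           config$quintile_weighted)
  pop_ratio <- list(
    hei2015 = population_ratio_mean(popdata, params$hei_standards, "HEI-2015"),
    ahei2010 = population_ratio_mean(popdata, params$ahei_standards, "AHEI-2010")
  )
  logf("score", sprintf("population-ratio HEI-2015 %.1f, AHEI-2010 %.1f",
                        pop_ratio$hei2015$total, pop_ratio$ahei2010$total))

  # --- waste accounting ---------------------------------------------------
  breakdown <- stage("account",
                     demand_breakdown(dis$intakes, params$loss_profiles,
                                      config$missing_policy))
  percap <- stage("account",
                  per_capita_breakdown(breakdown, records, params$group_map))
  person_demand <- breakdown |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(
      c(demand_categories, "total_demand")), sum), .groups = "drop") |>
    dplyr::right_join(records, by = "id") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(
      c(demand_categories, "total_demand")), ~ dplyr::coalesce(.x, 0)))
  overall_demand <- svy_mean(person_demand$total_demand, person_demand$weight,
                             person_demand$stratum, person_demand$psu)
  logf("account", sprintf("per-capita Total Food Demand %.0f g/d", overall_demand$estimate))

  # --- trend tests --------------------------------------------------------
  sc <- dplyr::inner_join(person_demand,
                          scores[c("id", "hei_quintile", "ahei_quintile")], by = "id")
  trend_rows <- list()
  for (idx in c("hei", "ahei")) {
    q <- sc[[paste0(idx, "_quintile")]]
    for (cat in c(demand_categories, "total_demand")) {
      for (adj in c(FALSE, TRUE)) {
        covs <- if (adj) sc[c("age", "sex")] else NULL
        tr <- stage("trend", trend_test(sc[[cat]], q, sc$weight, sc$stratum,
                                        sc$psu, covs))
        trend_rows[[length(trend_rows) + 1L]] <-
          dplyr::bind_cols(tibble::tibble(index = idx, category = cat), tr)
      }
    }
  }
  trends <- dplyr::bind_rows(trend_rows)

  # --- AHEI sensitivity ---------------------------------------------------
  wald_rows <- lapply(list(adults = scores$age >= 18, children = scores$age < 18),
                      function(keep) {
    if (sum(keep) < 4 || length(unique(scores$stratum[keep])) < 1) return(NULL)
    ok <- tryCatch(
      wald_difference_test(scores$ahei2010[keep], scores$ahei2010_original[keep],
                           scores$weight[keep], scores$stratum[keep],
                           scores$psu[keep]),
      error = function(e) NULL)
    ok
  })
  wald <- dplyr::bind_rows(wald_rows[!vapply(wald_rows, is.null, logical(1))],
                           .id = "age_group")

  # --- footprint ----------------------------------------------------------
  streams <- stream_demands(breakdown, records)
  fps <- lapply(streams[demand_categories], function(d) {
    stage("footprint", compute_footprint(d, params$agronomic, params$group_map))
  })
  fp_total <- stage("footprint",
                    compute_footprint(streams$total_demand, params$agronomic,
                                      params$group_map))
  shares <- attribute_to_loss_categories(fps)

  quintile_fps <- list()
  for (idx in c("hei", "ahei")) {
    qcol <- paste0(idx, "_quintile")
    for (q in sort(unique(scores[[qcol]]))) {
      ids <- scores$id[scores[[qcol]] == q]
      sub_records <- records[records$id %in% ids, , drop = FALSE]
      sub_breakdown <- breakdown[breakdown$id %in% ids, , drop = FALSE]
      d <- stream_demands(sub_breakdown, sub_records, "total_demand")$total_demand
      fp <- compute_footprint(d, params$agronomic, params$group_map)
      quintile_fps[[length(quintile_fps) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(index = idx, quintile = q), fp$totals)
    }
  }
  quintile_fps <- dplyr::bind_rows(quintile_fps)

  mc <- NULL
  if (!is.null(config$monte_carlo)) {
    demand_stream <- breakdown[c("id", "commodity_id", "total_demand")] |>
      dplyr::rename(grams = "total_demand")
    mc <- stage("footprint", monte_carlo_footprint(
      demand_stream, records, params$agronomic, params$group_map,
      draw_size = config$monte_carlo$draw_size,
      n_reps = config$monte_carlo$n_reps %||% 100,
      seed = config$seed + 2L))
  }

  # --- outputs ------------------------------------------------------------
  out <- function(x, f) write_output_csv(x, file.path(config$output_dir, f),
                                         hash, config$seed)
  artifacts <- c(
    out(dis$intakes, "commodity_intakes.csv"),
    out(scores[c("id", "hei2015", "ahei2010", "ahei2010_original",
                 "hei_quintile", "ahei_quintile")], "scores.csv"),
    out(percap, "per_capita_breakdown.csv"),
    out(trends, "trend_tests.csv"),
    out(if (nrow(wald)) wald else tibble::tibble(), "ahei_sensitivity.csv"),
    out(shares, "attribution_shares.csv"),
    out(quintile_fps, "quintile_footprints.csv"),
    out(fp_total$footprint, "footprint_by_category.csv")
  )
  if (!is.null(mc)) artifacts <- c(artifacts, out(mc$summary, "monte_carlo_footprint.csv"))
  coverage_path <- file.path(config$output_dir, "coverage_report.json")
  jsonlite::write_json(dis$coverage, coverage_path, auto_unbox = TRUE, digits = NA)
  artifacts <- c(artifacts, coverage_path)

  manifest <- list(
    seed = config$seed, config_hash = hash,
    package_version = as.character(utils::packageVersion("dietfootprint")),
    n_individuals = nrow(records), artifacts = basename(artifacts)
  )
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  manifest$results <- list(
    scores = scores, pop_ratio = pop_ratio, per_capita = percap,
    overall_demand = overall_demand, trends = trends, wald = wald,
    footprints = fps, footprint_total = fp_total, shares = shares,
    quintile_footprints = quintile_fps, monte_carlo = mc,
    coverage = dis$coverage
  )
  invisible(manifest)
}
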