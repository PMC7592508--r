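#!/usr/bin/env Rscript
# Stage 5: the closed-food-system footprint. Runs the biophysical chain
# once per loss/waste stream (retail loss, inedible, consumer waste,
# consumed), attributes each agricultural resource to the streams, repeats
# per diet-quality quintile, and propagates inter-individual variability
# with Monte Carlo draws.

library(dietfootprint)

inputs <- read_input_tables("results/inputs")
popdata <- inputs$popdata
params <- inputs$params
scores <- readr::read_csv("results/scores.csv", show_col_types = FALSE)

dis <- disaggregate(popdata, params$recipes)
bd <- demand_breakdown(dis$intakes, params$loss_profiles)
streams <- dietfootprint:::stream_demands(bd, popdata$records)

fps <- lapply(streams[c("consumed", "consumer_waste", "inedible", "retail_loss")],
              compute_footprint, agronomic = params$agronomic,
              group_map = params$group_map)
fp_total <- compute_footprint(streams$total_demand, params$agronomic,
                              params$group_map)
readr::write_csv(fp_total$footprint, "results/footprint_by_category.csv")

shares <- attribute_to_loss_categories(fps)
readr::write_csv(shares, "results/attribution_shares.csv")

tt <- fp_total$totals
cat(sprintf("Total Food Demand requires %.1f million ha, %.0f million kg fertilizer nutrients, %.1f million kg pesticides, %.1f billion m3 irrigation water per year.\n",
            tt$land_ha / 1e6, tt$fertilizer_kg / 1e6, tt$pesticide_kg / 1e6,
            tt$irrigation_m3 / 1e9))
land_share <- shares[shares$resource == "land_ha", ]
cat(sprintf("Share of agricultural land by stream: consumed %.0f%%, consumer waste %.0f%%, inedible %.0f%%, retail loss %.0f%%.\n",
            100 * land_share$share[land_share$stream == "consumed"],
            100 * land_share$share[land_share$stream == "consumer_waste"],
            100 * land_share$share[land_share$stream == "inedible"],
            100 * land_share$share[land_share$stream == "retail_loss"]))

# per-quintile footprints of total demand
rows <- list()
for (idx in c("hei", "ahei")) {
  qcol <- paste0(idx, "_quintile")
  for (q in 1:5) {
    ids <- scores$id[scores[[qcol]] == q]
    d <- dietfootprint:::stream_demands(
      bd[bd$id %in% ids, ],
      popdata$records[popdata$records$id %in% ids, ], "total_demand")$total_demand
    fp <- compute_footprint(d, params$agronomic, params$group_map)
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(index = toupper(idx), quintile = q), fp$totals)
  }
}
qfp <- dplyr::bind_rows(rows)
readr::write_csv(qfp, "results/footprint_by_quintile.csv")
hei_land <- qfp$land_ha[qfp$index == "HEI"]
cat(sprintf("Agricultural land, HEI quintile 1 -> 5: %.1f -> %.1f million ha.\n",
            hei_land[1] / 1e6, hei_land[5] / 1e6))

# Monte Carlo uncertainty on the total-demand footprint
demand_stream <- dplyr::rename(bd[c("id", "commodity_id", "total_demand")],
                               grams = "total_demand")
mc <- monte_carlo_footprint(demand_stream, popdata$records, params$agronomic,
                            params$group_map, n_reps = 500, seed = 99L)
readr::write_csv(mc$summary, "results/monte_carlo_footprint.csv")
cat(sprintf("Monte Carlo (500 draws of half the sample): land %.1f million ha (95%% interval %.1f-%.1f).\n",
            mc$summary$mean[1] / 1e6, mc$summary$lower[1] / 1e6,
            mc$summary$upper[1] / 1e6))
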