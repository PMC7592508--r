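test_that("import reapportionment conserves group mass", {
  gmap <- tibble::tibble(commodity_id = c("A", "B", "C"), food_group = "g")
  dom <- tibble::tibble(commodity_id = c("A", "B", "C"),
                        domestic = c(FALSE, TRUE, TRUE))
  demand <- tibble::tibble(commodity_id = c("A", "B", "C"), value = c(50, 30, 20))

  out <- reapportion_imports(demand, dom, gmap)  # proportional to demand
  expect_equal(out$value, c(0, 60, 40))          # 30:20 split of the 50 g
  expect_equal(sum(out$value), 100)

  # no flagged items -> identity
  dom_all <- dom; dom_all$domestic <- TRUE
  expect_equal(reapportion_imports(demand, dom_all, gmap)$value, demand$value)

  # flagged item with zero mass -> no change to the others
  demand0 <- demand; demand0$value[1] <- 0
  expect_equal(reapportion_imports(demand0, dom, gmap)$value, c(0, 30, 20))

  # entirely non-domestic group with demand -> model error
  dom_none <- dom; dom_none$domestic <- FALSE
  expect_error(reapportion_imports(demand, dom_none, gmap), "no domestic member")

  # fixed availability weights steer the split
  avail <- tibble::tibble(commodity_id = c("A", "B", "C"), availability = c(9, 3, 1))
  out2 <- reapportion_imports(demand, dom, gmap, avail)
  expect_equal(out2$value, c(0, 30 + 50 * 3 / 4, 20 + 50 * 1 / 4))

  # a domestic member absent from the observed demand table still receives
  # the redistributed mass (zero-intake commodities stay in the universe)
  out3 <- reapportion_imports(demand[1:2, ], dom, gmap, avail)
  expect_equal(out3$value[out3$commodity_id == "C"], 50 * 1 / 4)
  expect_equal(sum(out3$value), sum(demand$value[1:2]))
})

test_that("demand converts to primary crops through conversions and feed", {
  ag <- toy_agronomic()

  # conversion 1 everywhere, plants only -> crop requirement equals demand
  ag1 <- ag
  ag1$commodity_map$conversion <- 1
  d <- tibble::tibble(commodity_id = c("flour", "apples"), kg_yr = c(100, 200))
  conv <- demand_to_primary_crops(d, ag1)
  expect_equal(sort(conv$crop_requirements$kg_yr), c(100, 200))

  # 100 kg milk with hay feed 1.2 kg/kg -> 120 kg hay requirement
  dm <- tibble::tibble(commodity_id = "milk", kg_yr = 100)
  convm <- demand_to_primary_crops(dm, ag)
  expect_equal(convm$crop_requirements$kg_yr[convm$crop_requirements$crop_id == "hay"],
               120)
  expect_equal(convm$crop_requirements$kg_yr[convm$crop_requirements$crop_id == "feedcorn"],
               50)
  expect_equal(convm$pasture_land$ha, 100 * 1e-4)

  expect_error(demand_to_primary_crops(
    tibble::tibble(commodity_id = "nope", kg_yr = 1), ag), "nope")

  # multi-use crop: two commodities on one crop; the ledger's brute-force
  # row sum is the total crop requirement (mass conserved, no double count)
  ag2 <- ag
  ag2$commodity_map <- tibble::tibble(
    commodity_id = c("oil", "meal"), kind = "plant",
    crop_id = "soy", conversion = c(2, 1.25))
  ag2$crops <- tibble::tibble(crop_id = "soy", land_use = "legumes",
                              yield_kg_ha = 2500, double_crop_factor = 1)
  d2 <- tibble::tibble(commodity_id = c("oil", "meal"), kg_yr = c(70, 120))
  conv2 <- demand_to_primary_crops(d2, ag2)
  oracle <- sum(c(70 * 2, 120 * 1.25))  # explicit ledger expansion
  expect_equal(conv2$crop_requirements$kg_yr, oracle)
  expect_equal(sum(conv2$ledger$kg_yr), oracle, tolerance = 1e-9)
})

test_that("crops convert to land through yields and double-crop factors", {
  ag <- toy_agronomic()
  req <- tibble::tibble(crop_id = "wheat", kg_yr = 2000)
  ag$crops$yield_kg_ha[ag$crops$crop_id == "wheat"] <- 2000
  expect_equal(crops_to_land(req, ag)$land_ha, 1)

  ag$crops$double_crop_factor[ag$crops$crop_id == "wheat"] <- 2
  expect_equal(crops_to_land(req, ag)$land_ha, 0.5)

  # 3-crop toy system vs hand-computed category table
  req3 <- tibble::tibble(crop_id = c("wheat", "apple", "hay"),
                         kg_yr = c(4000, 40000, 10000))
  ag3 <- toy_agronomic()
  land <- crops_to_land(req3, ag3)
  expect_equal(land$land_ha[land$land_use == "grains"], 1)     # 4000/4000
  expect_equal(land$land_ha[land$land_use == "fruits"], 2)     # 40000/20000
  expect_equal(land$land_ha[land$land_use == "hay"], 2)        # 10000/5000

  expect_error(crops_to_land(tibble::tibble(crop_id = "x", kg_yr = 1), ag3), "x")
})

test_that("land converts to resources through category application rates", {
  ag <- toy_agronomic()
  land <- tibble::tibble(land_use = "grains", land_ha = 1)
  fp <- land_to_resources(land, ag)
  expect_equal(fp$fertilizer_kg, 100 + 40 + 60)
  expect_equal(fp$pesticide_kg, 2)
  expect_equal(fp$irrigation_m3, 1000)

  zero <- land_to_resources(tibble::tibble(land_use = "fruits", land_ha = 0), ag)
  expect_equal(zero$fertilizer_kg + zero$pesticide_kg + zero$irrigation_m3, 0)

  two <- land_to_resources(tibble::tibble(land_use = c("grains", "fruits"),
                                          land_ha = c(2, 3)), ag)
  tot <- footprint_totals(two)
  expect_equal(tot$fertilizer_kg, 2 * 200 + 3 * 100)  # hand sums
  expect_equal(tot$irrigation_m3, 2 * 1000 + 3 * 3000)

  expect_error(land_to_resources(
    tibble::tibble(land_use = "moon", land_ha = 1), ag), "moon")
})

test_that("attribution shares normalise per resource and sum to one", {
  f1 <- tibble::tibble(land_use = "grains", land_ha = 1,
                       fertilizer_kg = 10, pesticide_kg = 1, irrigation_m3 = 5)
  sh1 <- attribute_to_loss_categories(list(consumed = f1))
  expect_true(all(sh1$share == 1))

  sh2 <- attribute_to_loss_categories(list(a = f1, b = f1))
  expect_true(all(sh2$share == 0.5))

  f2 <- f1; f2$fertilizer_kg <- 30
  f3 <- f1; f3$fertilizer_kg <- 50
  f4 <- f1; f4$fertilizer_kg <- 10
  sh4 <- attribute_to_loss_categories(list(w = f1, x = f2, y = f3, z = f4))
  fert <- sh4[sh4$resource == "fertilizer_kg", ]
  expect_equal(fert$share, c(10, 30, 50, 10) / 100)  # brute-force normalisation
  expect_equal(sum(fert$share), 1)
  by_res <- tapply(sh4$share, sh4$resource, sum)
  expect_true(all(abs(by_res - 1) < 1e-12))

  f0 <- f1; f0[, -(1:2)] <- 0; f0$land_ha <- 0
  expect_error(attribute_to_loss_categories(list(a = f0, b = f0)), "undefined")
})

test_that("the full chain is linear in demand and additive across streams", {
  ag <- toy_agronomic()
  gmap <- toy_group_map()
  d <- tibble::tibble(commodity_id = c("flour", "apples", "milk"),
                      grams = c(120, 150, 200))
  fp <- compute_footprint(d, ag, gmap)
  k <- 2.5
  dk <- d; dk$grams <- d$grams * k
  fpk <- compute_footprint(dk, ag, gmap)
  expect_equal(as.numeric(fpk$totals), k * as.numeric(fp$totals), tolerance = 1e-12)

  # four streams summing to total demand -> footprints add within 1e-6 rel.
  set.seed(2)
  streams <- lapply(1:4, function(s) {
    d2 <- d
    d2$grams <- runif(3, 10, 100)
    d2
  })
  total <- streams[[1]]
  total$grams <- Reduce(`+`, lapply(streams, `[[`, "grams"))
  fps <- lapply(streams, compute_footprint, agronomic = ag, group_map = gmap)
  sum_tot <- Reduce(`+`, lapply(fps, function(f) as.numeric(f$totals)))
  fp_tot <- as.numeric(compute_footprint(total, ag, gmap)$totals)
  expect_equal(sum_tot, fp_tot, tolerance = 1e-6)
})

test_that("available-land checks flag exceedance without optimising", {
  ag <- toy_agronomic()
  ag$available_land <- tibble::tibble(land_use = c("grains", "fruits"),
                                      available_ha = c(1e-3, 1e9))
  d <- tibble::tibble(commodity_id = c("flour", "apples"), grams = c(500, 100))
  fp <- compute_footprint(d, ag, toy_group_map())
  chk <- fp$land_check
  expect_true(chk$exceeds[chk$land_use == "grains"])
  expect_false(chk$exceeds[chk$land_use == "fruits"])
})

test_that("Monte Carlo footprints are seeded, bounded and percentile-exact", {
  ag <- toy_agronomic()
  gmap <- toy_group_map()
  set.seed(5)
  n <- 24
  records <- tibble::tibble(id = sprintf("p%02d", 1:n), weight = rlnorm(n, 0, 0.5))
  demand <- tidyr::expand_grid(id = records$id,
                               commodity_id = c("flour", "apples", "milk")) |>
    dplyr::mutate(grams = runif(dplyr::n(), 20, 200))

  mc1 <- monte_carlo_footprint(demand, records, ag, gmap, n_reps = 30, seed = 42)
  mc2 <- monte_carlo_footprint(demand, records, ag, gmap, n_reps = 30, seed = 42)
  expect_identical(mc1$summary, mc2$summary)

  # interval endpoints equal brute-force percentiles of the replicate store
  expect_equal(mc1$summary$lower,
               unname(apply(mc1$replicates, 2, quantile, probs = 0.025)))
  expect_equal(mc1$summary$upper,
               unname(apply(mc1$replicates, 2, quantile, probs = 0.975)))

  # homogeneous individuals -> zero-width interval
  hom <- demand
  hom$grams <- rep(c(50, 80, 120), times = n)
  rec_eq <- records; rec_eq$weight <- 1
  mch <- monte_carlo_footprint(hom, rec_eq, ag, gmap, n_reps = 10, seed = 1)
  expect_equal(mch$summary$lower, mch$summary$upper, tolerance = 1e-9)

  expect_error(monte_carlo_footprint(demand, records, ag, gmap,
                                     draw_size = n + 1, n_reps = 5), "exceed")
  expect_error(monte_carlo_footprint(demand, records, ag, gmap, n_reps = 1),
               ">= 2")
})
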