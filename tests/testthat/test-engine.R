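test_that("tier-2 enteric methane follows the GEI x Ym energy equation", {
  co <- housed_cohort(headcount = 1, gei = 200)
  r <- enteric_ch4_tier2(co, ym = 6.5)
  expect_equal(r$mass, 200 * 0.065 * 365 / 55.65, tolerance = 1e-12)
  expect_equal(round(r$mass, 2), 85.27)

  expect_equal(enteric_ch4_tier2(co, ym = 0)$mass, 0)

  r10 <- enteric_ch4_tier2(housed_cohort(headcount = 10, gei = 200), 5.0)
  expect_equal(r10$mass, 10 * 200 * 0.05 * 365 / 55.65, tolerance = 1e-12)
  expect_equal(r10$mass, 655.89, tolerance = 1e-5)

  expect_error(enteric_ch4_tier2(co, ym = -1), "ym")
  expect_error(enteric_ch4_tier2(co, ym = 15), "ym")
})

test_that("per-head enteric methane is a table lookup scaled by headcount", {
  tbl <- c(suckler_cow = 90)
  expect_equal(enteric_ch4_per_head(housed_cohort(1), tbl)$mass, 90)
  expect_equal(enteric_ch4_per_head(housed_cohort(10), tbl)$mass, 900)
  expect_error(
    enteric_ch4_per_head(housed_cohort(1), c(weanling = 45)),
    "suckler_cow"
  )
})

test_that("manure methane applies B0 and system-weighted MCF", {
  efs <- test_efs()
  r <- manure_ch4(housed_cohort(1, vs = 2.5), c(slurry_tank = 1), efs)
  storage <- r$mass[r$source == "manure_storage"]
  expect_equal(storage, 2.5 * 365 * 0.17 * 0.67 * 0.17, tolerance = 1e-12)
  expect_equal(round(storage, 2), 17.67)

  # zero MCF everywhere -> no manure methane
  efs0 <- test_efs(mcf = c(slurry_tank = 0, solid_storage = 0,
                           pasture_deposition = 0))
  expect_equal(sum(manure_ch4(housed_cohort(1), c(slurry_tank = 1),
                              efs0)$mass), 0)

  # 50/50 housed split -> mean of the two pure-system results (linearity)
  half <- manure_ch4(housed_cohort(1, vs = 2.5),
                     c(slurry_tank = 0.5, solid_storage = 0.5), efs)
  pure_a <- manure_ch4(housed_cohort(1, vs = 2.5), c(slurry_tank = 1), efs)
  pure_b <- manure_ch4(housed_cohort(1, vs = 2.5), c(solid_storage = 1), efs)
  expect_equal(half$mass[half$source == "manure_storage"],
               mean(c(pure_a$mass[pure_a$source == "manure_storage"],
                      pure_b$mass[pure_b$source == "manure_storage"])))

  expect_error(manure_ch4(housed_cohort(1), c(slurry_tank = 0.7), efs),
               "sum to 1")
})

test_that("stored-manure N2O covers the housed period only", {
  efs <- test_efs()
  r <- manure_n2o(housed_cohort(1, nex = 80), c(slurry_tank = 1), efs)
  expect_equal(r$mass, 80 * 0.005 * 44 / 28, tolerance = 1e-12)
  expect_equal(round(r$mass, 4), 0.6286)

  efs0 <- test_efs(ef3_storage = c(slurry_tank = 0, solid_storage = 0))
  expect_equal(manure_n2o(housed_cohort(1), c(slurry_tank = 1), efs0)$mass, 0)

  half <- manure_n2o(housed_cohort(1, nex = 80, days_grazing = 182.5),
                     c(slurry_tank = 1), efs)
  expect_equal(half$mass, r$mass / 2)
})

test_that("grazing-deposited N2O scales with time at pasture", {
  efs <- test_efs()
  co <- housed_cohort(1, nex = 80, days_grazing = 182.5)
  r <- grazing_n2o(co, efs)
  expect_equal(round(r$mass, 4), 1.2571)
  expect_equal(grazing_n2o(housed_cohort(1, nex = 80), efs)$mass, 0)
  full <- grazing_n2o(housed_cohort(1, nex = 80, days_grazing = 365), efs)
  expect_equal(full$mass, 2 * r$mass)
})

test_that("soil N2O from applied N uses EF1 and splits by N origin", {
  efs <- test_efs()
  r <- soil_n2o_fertilizer(100, 0, efs)
  expect_equal(round(sum(r$mass), 3), 1.571)
  expect_equal(sum(soil_n2o_fertilizer(0, 0, efs)$mass), 0)
  r2 <- soil_n2o_fertilizer(100, 50, efs)
  expect_equal(sum(r2$mass), 1.5 * sum(r$mass))
  expect_setequal(r2$source, c("soil_fertilizer", "manure_spreading"))
})

test_that("indirect N2O sums volatilization and leaching pathways", {
  vol_only <- test_efs(frac_leach = 0)
  expect_equal(round(indirect_n2o(100, 0, vol_only)$mass, 4), 0.1571)
  leach_only <- test_efs(frac_gas_synthetic = 0, frac_gas_manure = 0)
  expect_equal(round(indirect_n2o(100, 0, leach_only)$mass, 4), 0.3536)
  none <- test_efs(frac_leach = 0, frac_gas_synthetic = 0,
                   frac_gas_manure = 0)
  expect_equal(indirect_n2o(100, 100, none)$mass, 0)
})

test_that("liming, fuel and off-farm sources are linear in their inputs", {
  efs <- test_efs()
  r <- liming_and_fuel_co2(1000, 500, efs)
  expect_equal(r$mass[r$source == "liming"], 440)
  expect_equal(r$mass[r$source == "energy"], 1335)
  expect_equal(sum(liming_and_fuel_co2(0, 0, efs)$mass), 0)

  farm <- tiny_farm(concentrate_fed = c(cereal_mix = 10000),
                    fert_n_applied = 1000, electricity_used = 0)
  off <- offfarm_co2e(farm, efs)
  expect_equal(off$mass[off$source == "concentrate"], 8000)
  expect_equal(off$mass[off$source == "fert_manufacture"], 6000)
  expect_true(all(off$co2e_preaggregated))

  none <- tiny_farm(concentrate_fed = c(cereal_mix = 0),
                    fert_n_applied = 0, electricity_used = 0)
  expect_equal(sum(offfarm_co2e(none, efs)$mass), 0)

  exotic <- tiny_farm(concentrate_fed = c(soy_hulls = 100))
  expect_error(offfarm_co2e(exotic, efs), "soy_hulls")
})

test_that("sequestration is a per-area and per-length removal", {
  efs <- test_efs()
  f <- tiny_farm(grassland_area = 50, hedgerow_length = 0)
  expect_equal(sequestration(f, efs)$sequestration, 35000)
  zero <- tiny_farm(grassland_area = 0, hedgerow_length = 0)
  expect_equal(sequestration(zero, efs)$sequestration, 0)
  hedge <- tiny_farm(grassland_area = 50, hedgerow_length = 1000)
  expect_equal(hedge$hedgerow_length, 1000)
  expect_equal(sequestration(hedge, efs)$sequestration, 36000)
})

test_that("a zero-livestock, zero-input farm yields an all-zero inventory", {
  empty <- farm_record("Z", "beef_fattening", grassland_area = 0,
                       lw_sold = 1, concentrate_fed = c(cereal_mix = 0))
  inv <- build_inventory(empty, test_efs())
  expect_true(all(inv$mass == 0))
  expect_gt(nrow(inv), 0)
})

test_that("build_inventory equals the sum of component source operations", {
  efs <- load_ef_set("IE_style")
  suite <- generate_suite(seed = 11)
  for (i in c(1, 7, 13, 20)) {
    farm <- suite[i, ]
    inv <- build_inventory(farm, efs)
    ch <- farm$cohorts[[1]]
    shares <- farm$manure_system_shares[[1]]
    nex_tot <- sum(ch$headcount * ch$n_excretion)
    nex_housed <- sum(ch$headcount * ch$n_excretion * ch$days_housed / 365)
    comp <- dplyr::bind_rows(
      enteric_ch4_tier2(ch, efs$ym),
      manure_ch4(ch, shares, efs),
      manure_n2o(ch, shares, efs),
      grazing_n2o(ch, efs),
      soil_n2o_fertilizer(farm$fert_n_applied, nex_housed, efs),
      indirect_n2o(farm$fert_n_applied, nex_tot, efs),
      liming_and_fuel_co2(farm$lime_applied, farm$diesel_used, efs),
      offfarm_co2e(farm, efs)
    ) |>
      dplyr::group_by(source, gas) |>
      dplyr::summarise(mass = sum(mass), .groups = "drop")
    joined <- dplyr::left_join(inv, comp, by = c("source", "gas"),
                               suffix = c("_inv", "_comp"))
    joined$mass_comp[is.na(joined$mass_comp)] <- 0
    expect_equal(joined$mass_inv, joined$mass_comp, tolerance = 1e-12)
  }
})

test_that("livestock sources are homogeneous of degree 1 in headcount", {
  efs <- load_ef_set("IE_style")
  suite <- generate_suite(seed = 3)
  farm <- suite[2, ]
  doubled <- farm
  doubled$cohorts[[1]]$headcount <- 2 * doubled$cohorts[[1]]$headcount
  inv1 <- build_inventory(farm, efs)
  inv2 <- build_inventory(doubled, efs)
  livestock <- c("enteric", "manure_storage", "grazing_returns")
  for (s in livestock) {
    expect_equal(inv2$mass[inv2$source == s],
                 2 * inv1$mass[inv1$source == s], tolerance = 1e-12)
  }
})

test_that("emitted N2O-N never exceeds N entering the farm system", {
  efs <- load_ef_set("IE_style")
  suite <- generate_suite(seed = 19)
  inv <- build_inventory(suite, efs)
  n2o <- inv |>
    dplyr::filter(gas == "N2O") |>
    dplyr::group_by(farm_id) |>
    dplyr::summarise(n2o_n = sum(mass) * 28 / 44)
  n_in <- tibble::tibble(
    farm_id = suite$farm_id,
    n = suite$fert_n_applied +
      purrr::map_dbl(suite$cohorts,
                     ~ sum(.x$headcount * .x$n_excretion))
  )
  j <- dplyr::left_join(n2o, n_in, by = "farm_id")
  expect_true(all(j$n2o_n <= j$n))
})

test_that("switching to the per-head table raises enteric methane on
           grass-based farms", {
  ie <- load_ef_set("IE_style")
  fr <- load_ef_set("FR_style")
  suite <- generate_suite(seed = 5)
  grass <- suite[suite$system %in% c("suckler_to_weaning",
                                     "suckler_to_beef") &
                   suite$country %in% c("IE", "FR"), ]
  for (i in seq_len(nrow(grass))) {
    e_ie <- build_inventory(grass[i, ], ie)
    e_fr <- build_inventory(grass[i, ], fr)
    expect_gt(e_fr$mass[e_fr$source == "enteric"],
              e_ie$mass[e_ie$source == "enteric"])
  }
})
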