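inv_row <- function(source, gas, mass, preagg = FALSE) {
  tibble::tibble(source = source, gas = gas, mass = mass,
                 co2e_preaggregated = preagg)
}

test_that("CO2e aggregation weighs gases by their warming potentials", {
  expect_equal(co2e_aggregate(inv_row("enteric", "CH4", 1)), 25)
  expect_equal(co2e_aggregate(inv_row("manure_storage", "N2O", 1)), 298)
  mixed <- dplyr::bind_rows(inv_row("enteric", "CH4", 2),
                            inv_row("soil_fertilizer", "N2O", 0.5),
                            inv_row("liming", "CO2", 100))
  expect_equal(co2e_aggregate(mixed), 2 * 25 + 0.5 * 298 + 100)
  # pre-aggregated CO2e entries are multiplied by 1, never re-weighted
  expect_equal(co2e_aggregate(inv_row("concentrate", "CO2", 10, TRUE)), 10)
  expect_error(co2e_aggregate(inv_row("enteric", "NH3", 1)), "NH3")
})

test_that("CO2e aggregation is linear", {
  a <- inv_row("enteric", "CH4", 3)
  b <- inv_row("soil_fertilizer", "N2O", 0.2)
  expect_equal(co2e_aggregate(dplyr::bind_rows(a, b)),
               co2e_aggregate(a) + co2e_aggregate(b))
})

test_that("live-weight gain follows the stock-and-flow definition", {
  f <- tiny_farm(lw_sold = 30000, lw_closing = 50000,
                 lw_purchased = 10000, lw_opening = 45000)
  expect_equal(compute_lwg(f)$lwg, 25000)

  zero <- tiny_farm(lw_sold = 0, lw_closing = 0, lw_purchased = 0,
                    lw_opening = 0)
  expect_error(compute_lwg(zero), "Live-weight gain")

  stable <- tiny_farm(lw_sold = 12000, lw_opening = 30000,
                      lw_closing = 30000, lw_purchased = 0)
  expect_equal(compute_lwg(stable)$lwg, stable$lw_sold)
})

test_that("allocation scales emissions by the beef fraction", {
  expect_equal(allocate_emissions(100000, 1), 100000)
  expect_equal(allocate_emissions(100000, 0.15), 15000)
  expect_equal(allocate_emissions(100000, 0), 0)
  expect_error(allocate_emissions(1, 1.2), "beef_fraction")
})

test_that("gross, net and per-unit footprints satisfy their identities", {
  # a farm engineered to gross 100000 kg CO2e with controllable sinks:
  # lime is the only emission source (CO2, GWP 1)
  efs <- test_efs(seq_rate_grassland = 0, seq_rate_hedgerow = 0)
  f <- farm_record("FP", "suckler_to_beef", grassland_area = 10,
                   lw_sold = 10000, lime_applied = 100000 / 0.44,
                   concentrate_fed = c(cereal_mix = 0))
  fp <- farm_footprint(f, efs)
  expect_equal(fp$gross_total, 100000)
  expect_equal(fp$sequestration, 0)
  expect_equal(fp$gross_per_lwg, 10)
  expect_equal(fp$net_per_lwg, 10)

  efs2 <- test_efs(seq_rate_grassland = 2000, seq_rate_hedgerow = 0)
  fp2 <- farm_footprint(f, efs2) # 10 ha x 2000 = 20000 sequestered
  expect_equal(fp2$net_total, fp2$gross_total - fp2$sequestration)
  expect_equal(fp2$net_per_lwg, 8)
  expect_false(fp2$negative_net)

  # carcass-weight basis: per-LW value divided by the 55% dressing
  expect_equal(fp$per_cw, fp$per_lw_sold / 0.55)
  expect_equal(17.6 / 0.55, 32)
})

test_that("negative net footprints are flagged, not clamped", {
  efs <- test_efs(seq_rate_grassland = 1e6)
  f <- tiny_farm()
  fp <- farm_footprint(f, efs)
  expect_lt(fp$net_total, 0)
  expect_true(fp$negative_net)
})

test_that("emission profiles are shares of gross summing to 100", {
  single <- inv_row("enteric", "CH4", 5)
  p1 <- emission_profile(single)
  expect_equal(p1$share, 100)

  two <- dplyr::bind_rows(inv_row("enteric", "CH4", 60000 / 25),
                          inv_row("liming", "CO2", 40000))
  p2 <- emission_profile(two)
  expect_equal(sort(p2$share), c(40, 60))

  suite <- generate_suite(seed = 2)
  inv <- build_inventory(suite, load_ef_set("IE_style"))
  p <- emission_profile(inv)
  sums <- tapply(p$share, p$farm_id, sum)
  expect_true(all(abs(sums - 100) < 1e-6))

  expect_error(emission_profile(inv_row("enteric", "CH4", 0)), "zero")
})

test_that("footprint tables carry tidy() profiles and glance() summaries", {
  fp <- farm_footprint(generate_suite(seed = 4)[1:3, ], "IE_style")
  td <- generics::tidy(fp)
  expect_true(all(c("farm_id", "source", "share") %in% names(td)))
  gl <- generics::glance(fp)
  expect_identical(gl$n_farms, 3L)
  expect_gt(gl$mean_gross_per_lwg, 0)
})
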