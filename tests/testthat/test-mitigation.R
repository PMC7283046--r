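# An emission-factor set where enteric methane is the only nonzero
# source, so measure arithmetic can be checked in closed form.
enteric_only_efs <- function(...) {
  test_efs(b0 = 0,
           ef3_storage = c(slurry_tank = 0, solid_storage = 0),
           ef3_prp = 0, ef1 = 0,
           frac_gas_synthetic = 0, frac_gas_manure = 0, frac_leach = 0,
           ef_lime = 0, ef_fert_manufacture = 0,
           ef_concentrate = c(cereal_mix = 0),
           ef_diesel = 0, ef_electricity = 0,
           seq_rate_grassland = 0, seq_rate_hedgerow = 0, ...)
}

test_that("a measure with all-zero deltas is the identity", {
  null_m <- mitigation_measure("null", mechanism = "intensity_delta",
                               deltas = c(CH4 = 0),
                               affected_sources = "enteric")
  f <- tiny_farm()
  sc <- apply_measure(f, test_efs(), null_m)
  expect_equal(sc$reduction_pct, 0)
  expect_equal(sc$mitigated_net_per_lwg, sc$baseline_net_per_lwg)
})

test_that("capping Ym from 6.5 to 5.0 cuts enteric-only footprints by
           1 - 5/6.5", {
  m <- mitigation_measure("additive", mechanism = "parameter_override",
                          overrides = list(ym = 5.0))
  sc <- apply_measure(tiny_farm(), enteric_only_efs(), m)
  expect_equal(sc$reduction_pct, 100 * (1 - 5 / 6.5), tolerance = 1e-9)
  expect_equal(round(sc$reduction_pct, 2), 23.08)
})

test_that("a -10% CH4 delta on a 50%-share source cuts gross by 5%", {
  # lime tuned so liming CO2e equals enteric CO2e exactly (50/50 split)
  efs <- enteric_only_efs(ef_lime = 0.44)
  f <- tiny_farm(lime_applied = 0)
  enteric_co2e <- co2e_aggregate(build_inventory(f, efs))$co2e
  f2 <- tiny_farm(lime_applied = enteric_co2e / 0.44)
  m <- mitigation_measure("diet", mechanism = "intensity_delta",
                          deltas = c(CH4 = -10),
                          affected_sources = "enteric")
  sc <- apply_measure(f2, efs, m)
  expect_equal(sc$reduction_pct, 5, tolerance = 1e-9)
})

test_that("an empty plan changes nothing", {
  plan <- mitigation_plan(list())
  sc <- stack_plan(tiny_farm(), test_efs(), plan)
  expect_equal(sc$reduction_pct, 0)
})

test_that("stacked deltas on one source combine multiplicatively", {
  efs <- enteric_only_efs()
  m <- mitigation_measure("cut10", mechanism = "intensity_delta",
                          deltas = c(CH4 = -10),
                          affected_sources = "enteric")
  m2 <- m
  m2$name <- "cut10_again"
  sc1 <- apply_measure(tiny_farm(), efs, m)
  plan <- mitigation_plan(list(m, m2))
  sc2 <- stack_plan(tiny_farm(), efs, plan)
  expect_equal(sc1$reduction_pct, 10, tolerance = 1e-9)
  expect_equal(sc2$reduction_pct, 100 * (1 - 0.9^2), tolerance = 1e-9)
  expect_lt(sc2$reduction_pct, 2 * sc1$reduction_pct)
})

test_that("total plan reduction is invariant to measure order", {
  cat_ <- measure_catalogue()
  ms <- list(cat_$improved_genetic_merit, cat_$white_clover_swards,
             cat_$slurry_store_cover, cat_$preserve_permanent_grassland)
  f <- generate_suite(seed = 6)[1, ]
  fwd <- stack_plan(f, "IE_style", mitigation_plan(ms))
  rev <- stack_plan(f, "IE_style", mitigation_plan(rev(ms)))
  expect_equal(fwd$reduction_pct, rev$reduction_pct, tolerance = 1e-9)
  # sequential marginal contributions account for the whole reduction
  expect_equal(sum(fwd$contributions[[1]]$marginal_pct),
               fwd$reduction_pct, tolerance = 1e-9)
})

test_that("measures with only negative deltas never increase the
           footprint", {
  cat_ <- measure_catalogue()
  f <- generate_suite(seed = 9)[1, ] # IE suckler-to-beef
  for (m in cat_) {
    if (m$mechanism != "intensity_delta" || any(m$deltas > 0)) next
    if (!beefcarbon:::measure_applies(m, f$system)) next
    sc <- apply_measure(f, "IE_style", m)
    expect_gte(sc$reduction_pct, 0)
  }
})

test_that("inapplicable measures and unknown overrides are rejected", {
  cat_ <- measure_catalogue()
  weaning <- generate_suite(seed = 10)
  weaning <- weaning[weaning$system == "suckler_to_weaning", ][1, ]
  expect_error(
    apply_measure(weaning, "IE_style", cat_$feed_additive_ch4_suppressant),
    "not applicable"
  )
  bad <- mitigation_measure("typo", mechanism = "parameter_override",
                            overrides = list(not_a_param = 1))
  expect_error(apply_measure(tiny_farm(), test_efs(), bad),
               "not_a_param")
})

test_that("conflicting overrides resolve last-writer-wins with a note", {
  a <- mitigation_measure("a", mechanism = "parameter_override",
                          overrides = list(ym = 6.0))
  b <- mitigation_measure("b", mechanism = "parameter_override",
                          overrides = list(ym = 5.0))
  expect_message(
    sc <- stack_plan(tiny_farm(), enteric_only_efs(),
                     mitigation_plan(list(a, b))),
    "last writer wins"
  )
  expect_equal(sc$reduction_pct, 100 * (1 - 5 / 6.5), tolerance = 1e-9)
})

test_that("target evaluation passes at and above the threshold only", {
  sc <- tibble::tibble(farm_id = c("a", "b", "c"),
                       reduction_pct = c(15, 14.9, 20))
  ev <- evaluate_target(sc, 15)
  expect_identical(ev$pass, c(TRUE, FALSE, TRUE))
  expect_equal(ev$margin, c(0, -0.1, 5))
})
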