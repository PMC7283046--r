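test_that("generation is deterministic under a fixed seed", {
  prof <- archetype_profiles()$profile[[1]]
  f1 <- generate_farm(prof, seed = 123)
  f2 <- generate_farm(prof, seed = 123)
  expect_identical(f1, f2)
  f3 <- generate_farm(prof, seed = 124)
  expect_false(identical(f1$grassland_area, f3$grassland_area))

  s1 <- generate_suite(seed = 42)
  s2 <- generate_suite(seed = 42)
  expect_identical(s1, s2)
})

test_that("the suite reproduces the 20-archetype country and system mix", {
  suite <- generate_suite(seed = 42)
  expect_identical(nrow(suite), 20L)
  expect_equal(unname(table(suite$country)), rep(5L, 4L),
               ignore_attr = TRUE)
  it <- suite[suite$country == "IT", ]
  expect_identical(sum(it$system == "beef_fattening"), 4L)
  expect_identical(sum(it$system == "suckler_to_beef"), 1L)
  ie <- suite[suite$country == "IE", ]
  expect_setequal(ie$system, farm_systems())
  es <- suite[suite$country == "ES", ]
  expect_identical(sum(es$system == "suckler_to_beef"), 3L)
  expect_identical(sum(es$system == "beef_fattening"), 2L)
  expect_true(all(es$lw_purchased[es$system == "suckler_to_beef"] > 0))
})

test_that("Spanish and Italian fattening units stay small and housed;
           weaning archetypes carry the 8-month sale age", {
  for (seed in c(1, 42, 77)) {
    suite <- generate_suite(seed = seed)
    es_fat <- suite[suite$country == "ES" &
                      suite$system == "beef_fattening", ]
    expect_true(all(es_fat$grassland_area + es_fat$cropland_area < 5))
    intensive <- suite[suite$country %in% c("IT", "ES") &
                         suite$system == "beef_fattening", ]
    graze_days <- purrr::map_dbl(intensive$cohorts,
                                 ~ max(.x$days_grazing))
    expect_true(all(graze_days <= 20))
    # Irish herds graze at least as long as continental fattening herds
    ie_days <- purrr::map_dbl(
      suite$cohorts[suite$country == "IE"], ~ min(.x$days_grazing))
    expect_true(all(ie_days >= max(graze_days)))
  }
  prof <- archetype_profiles()
  weaning <- prof$profile[prof$system == "suckler_to_weaning"]
  expect_true(all(purrr::map_dbl(weaning, "sale_age_months") == 8))
})

test_that("fattening farms produce more live-weight gain per hectare", {
  suite <- generate_suite(seed = 42)
  lwg <- compute_lwg(suite)
  per_ha <- lwg$lwg / (suite$grassland_area + suite$cropland_area)
  expect_gt(min(per_ha[suite$system == "beef_fattening"]),
            max(per_ha[suite$system %in% c("suckler_to_weaning",
                                           "suckler_to_beef")]))
})

test_that("enteric methane dominates grass-based suckler footprints", {
  suite <- generate_suite(seed = 42)
  fp <- farm_footprint(suite, "IE_style")
  prof <- generics::tidy(fp)
  suckler <- fp$farm_id[fp$system %in% c("suckler_to_weaning",
                                         "suckler_to_beef") &
                          fp$country %in% c("IE", "FR")]
  for (id in suckler) {
    p <- prof[prof$farm_id == id, ]
    expect_identical(p$source[which.max(p$share)], "enteric")
  }
})
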