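#' Synthetic case-study farm archetypes
#'
#' The package ships a deterministic generator of synthetic beef farms
#' emulating the structure of a 20-farm, four-country case-study panel:
#' grass-based Irish systems spanning the five farm systems, low-input
#' French suckler systems, intensive Italian maize-based fattening farms,
#' and Spanish systems including very small (< 5 ha) intensive fattening
#' units. Every archetype is described by uniform low/high bounds on
#' areas, headcounts, weights, intakes, N rates, concentrate use and
#' grazing days; [generate_farm()] samples one farm from those bounds.
#' Suckler-to-weaning archetypes sell progeny at a fixed sale age of
#' 8 months, and the sold weight is derived from birth weight plus
#' pre-weaning daily gain over that age.
#'
#' @return `archetype_profiles()` returns a tibble with one row per
#'   archetype (columns `tag`, `country`, `system`, `profile`
#'   list-column).
#' @name synthetic_farms
NULL

# Per-category biological parameter bounds: gross energy intake
# (MJ/head/day), N excretion (kg N/head/year), volatile solids
# (kg VS/head/day), live weight (kg) and daily gain (kg/day).
category_bounds <- function() {
  list(
    suckler_cow       = list(gei = c(145, 175), nex = c(75, 95),
                             vs = c(3.2, 4.0), lw = c(580, 660),
                             adg = c(0.0, 0.15)),
    dairy_origin_calf = list(gei = c(35, 55), nex = c(18, 28),
                             vs = c(0.8, 1.4), lw = c(90, 170),
                             adg = c(0.6, 0.9)),
    weanling          = list(gei = c(55, 80), nex = c(25, 38),
                             vs = c(1.2, 2.0), lw = c(180, 280),
                             adg = c(0.7, 1.05)),
    store             = list(gei = c(95, 125), nex = c(42, 58),
                             vs = c(2.2, 3.0), lw = c(330, 450),
                             adg = c(0.6, 0.95)),
    finishing_bull    = list(gei = c(115, 145), nex = c(48, 65),
                             vs = c(2.6, 3.4), lw = c(480, 620),
                             adg = c(1.1, 1.45)),
    finishing_steer   = list(gei = c(105, 135), nex = c(46, 60),
                             vs = c(2.5, 3.3), lw = c(470, 580),
                             adg = c(0.8, 1.1)),
    finishing_heifer  = list(gei = c(90, 120), nex = c(40, 54),
                             vs = c(2.2, 3.0), lw = c(420, 520),
                             adg = c(0.7, 1.0)),
    breeding_bull     = list(gei = c(160, 195), nex = c(70, 88),
                             vs = c(3.4, 4.4), lw = c(750, 950),
                             adg = c(0.0, 0.1))
  )
}

# Grazing-day bounds by country and whether the system is an intensive
# (housed) fattening unit. Irish systems graze longest; Italian/Spanish
# fattening units are essentially year-round housed.
grazing_bounds <- function(country, intensive) {
  if (intensive) {
    switch(country,
           IE = c(140, 180), FR = c(30, 90),
           IT = c(0, 20), ES = c(0, 20))
  } else {
    switch(country,
           IE = c(210, 250), FR = c(170, 215),
           IT = c(120, 200), ES = c(180, 270))
  }
}

n_rate_grass <- function(country) {
  switch(country, IE = c(80, 110), FR = c(40, 70),
         IT = c(30, 60), ES = c(10, 40))
}

n_rate_crop <- function(country) {
  switch(country, IE = c(80, 120), FR = c(140, 200),
         IT = c(140, 200), ES = c(80, 150))
}

hedge_bounds <- function(country) {
  switch(country, IE = c(1800, 3400), FR = c(1000, 3000),
         IT = c(100, 1000), ES = c(0, 600))
}

lime_bounds <- function(country) {
  switch(country, IE = c(3000, 10000), FR = c(0, 4000),
         IT = c(0, 1500), ES = c(0, 1500))
}

#' @rdname synthetic_farms
#' @export
archetype_profiles <- function() {
  def <- tibble::tribble(
    ~tag, ~country, ~system, ~purchases,
    "IE1", "IE", "suckler_to_beef", FALSE,
    "IE2", "IE", "suckler_to_weaning", FALSE,
    "IE3", "IE", "dairy_calf_to_beef", FALSE,
    "IE4", "IE", "dairy_calf_to_store", FALSE,
    "IE5", "IE", "beef_fattening", FALSE,
    "FR1", "FR", "suckler_to_weaning", FALSE,
    "FR2", "FR", "suckler_to_weaning", FALSE,
    "FR3", "FR", "suckler_to_beef", TRUE,
    "FR4", "FR", "beef_fattening", FALSE,
    "FR5", "FR", "suckler_to_beef", FALSE,
    "IT1", "IT", "beef_fattening", FALSE,
    "IT2", "IT", "beef_fattening", FALSE,
    "IT3", "IT", "beef_fattening", FALSE,
    "IT4", "IT", "beef_fattening", FALSE,
    "IT5", "IT", "suckler_to_beef", FALSE,
    "ES1", "ES", "suckler_to_beef", TRUE,
    "ES2", "ES", "beef_fattening", FALSE,
    "ES3", "ES", "suckler_to_beef", TRUE,
    "ES4", "ES", "suckler_to_beef", TRUE,
    "ES5", "ES", "beef_fattening", FALSE
  )
  def$profile <- purrr::pmap(def, function(tag, country, system, purchases) {
    list(tag = tag, country = country, system = system,
         purchases = purchases,
         sale_age_months = if (system == "suckler_to_weaning") 8 else NA)
  })
  def
}

# Uniform draw within bounds (vectorized over paired bounds).
u <- function(b) runif(1, b[1], b[2])

sample_cohort <- function(category, headcount, days_grazing) {
  cb <- category_bounds()[[category]]
  animal_cohort(
    category = category, headcount = headcount,
    avg_live_weight = u(cb$lw), daily_gain = u(cb$adg),
    gross_energy_intake = u(cb$gei), n_excretion = u(cb$nex),
    volatile_solids = u(cb$vs), days_grazing = round(days_grazing)
  )
}

#' Generate one synthetic farm
#'
#' Samples a farm record from an archetype profile. Identical
#' `(profile, seed)` pairs give bit-identical farms; every generated farm
#' passes [validate_farm()].
#'
#' @param profile One profile from [archetype_profiles()] (an element of
#'   its `profile` list-column).
#' @param seed Integer seed for the draw.
#' @return A one-row farm table.
#' @export
generate_farm <- function(profile, seed) {
  stopifnot(is.list(profile), !is.null(profile$system))
  withr::with_seed(as.integer(seed), generate_farm_impl(profile))
}

generate_farm_impl <- function(p) {
  ctry <- p$country
  sys <- p$system
  gb <- grazing_bounds(ctry, intensive = sys == "beef_fattening")

  if (sys %in% c("suckler_to_weaning", "suckler_to_beef")) {
    cows <- round(u(switch(ctry, IE = c(35, 50), FR = c(45, 70),
                           IT = c(40, 60), ES = c(60, 90))))
    dg_cow <- u(gb)
    bull <- max(1, round(cows * 0.03))
    cull_rate <- u(c(0.11, 0.15))
    cull_w <- u(c(550, 610))
    weaned <- u(c(0.78, 0.88))

    if (sys == "suckler_to_weaning") {
      # progeny sold at the fixed 8-month sale age; sold weight follows
      # birth weight + pre-weaning gain over 8 months
      adg_pre <- u(c(0.85, 1.05))
      sale_w <- 45 + adg_pre * p$sale_age_months * 30.4
      cohorts <- bind_rows(
        sample_cohort("suckler_cow", cows, dg_cow),
        sample_cohort("weanling", round(cows * weaned * 8 / 12 * 0.55),
                      min(dg_cow, u(c(150, 220)))),
        sample_cohort("breeding_bull", bull, dg_cow * u(c(0.8, 1)))
      )
      sold_head <- cows * weaned * u(c(0.75, 0.85)) # less retained heifers
      lw_sold <- sold_head * sale_w + cows * cull_rate * cull_w
      lw_purch <- 0
      area_grass <- cows * u(c(1.0, 1.35))
      area_crop <- u(c(0, 4))
    } else {
      fin_cat <- switch(ctry, IE = "finishing_steer", "finishing_bull")
      fin_out <- u(switch(ctry, IE = c(600, 660), FR = c(620, 690),
                          IT = c(540, 620), ES = c(560, 640)))
      purch_head <- if (isTRUE(p$purchases)) round(cows * u(c(0.3, 0.6))) else 0
      purch_w <- u(c(320, 380))
      cohorts <- bind_rows(
        sample_cohort("suckler_cow", cows, dg_cow),
        sample_cohort("weanling", round(cows * weaned * 0.62),
                      min(dg_cow, u(c(150, 220)))),
        sample_cohort("store", round(cows * weaned * 1.0),
                      u(gb) * u(c(0.85, 1))),
        sample_cohort(fin_cat,
                      round(cows * weaned * 0.45 + purch_head * 0.55),
                      u(c(0, 60))),
        sample_cohort("breeding_bull", bull, dg_cow * u(c(0.8, 1)))
      )
      sold_own <- cows * weaned * u(c(0.78, 0.88))
      lw_sold <- sold_own * fin_out + cows * cull_rate * cull_w +
        purch_head * fin_out
      lw_purch <- purch_head * purch_w
      area_grass <- cows * u(switch(ctry, ES = c(1.5, 2.2), c(1.2, 1.7)))
      area_crop <- u(switch(ctry, IT = c(8, 18), FR = c(3, 10), c(0, 5)))
    }
  } else if (sys == "beef_fattening") {
    turnover <- u(switch(ctry, IE = c(2.4, 3.2), FR = c(1.1, 1.4),
                         IT = c(1.1, 1.4), ES = c(1.5, 2.0)))
    head_avg <- round(u(switch(ctry, IE = c(60, 110), FR = c(100, 200),
                               IT = c(150, 350), ES = c(150, 320))))
    fin_cat <- switch(ctry, IE = "finishing_steer", "finishing_bull")
    in_w <- u(switch(ctry, IE = c(470, 530), FR = c(360, 420),
                     IT = c(370, 420), ES = c(250, 320)))
    out_w <- in_w + u(switch(ctry, IE = c(110, 160), FR = c(260, 320),
                             IT = c(260, 320), ES = c(220, 280)))
    throughput <- head_avg * turnover
    cohorts <- sample_cohort(fin_cat, head_avg, u(gb))
    lw_sold <- throughput * out_w
    lw_purch <- throughput * in_w
    area_grass <- switch(ctry, IE = head_avg * u(c(0.45, 0.7)),
                         FR = u(c(5, 15)), IT = u(c(2, 6)),
                         ES = u(c(0.3, 1.5)))
    area_crop <- switch(ctry, IE = u(c(0, 4)), FR = u(c(10, 25)),
                        IT = u(c(12, 30)), ES = u(c(0.8, 2.8)))
  } else { # dairy calf systems (Irish flavour)
    throughput <- round(u(c(26, 40)))
    to_beef <- sys == "dairy_calf_to_beef"
    dg <- u(gb)
    cohorts <- bind_rows(
      sample_cohort("dairy_origin_calf", round(throughput * 0.7),
                    dg * u(c(0.5, 0.8))),
      sample_cohort("store", round(throughput * 0.9), dg),
      if (to_beef) sample_cohort("finishing_steer",
                                 round(throughput * 0.45), u(c(60, 140)))
    )
    in_w <- u(c(48, 60))
    out_w <- if (to_beef) u(c(580, 640)) else u(c(420, 460))
    lw_sold <- throughput * out_w
    lw_purch <- throughput * in_w
    area_grass <- throughput * u(if (to_beef) c(0.8, 1.1) else c(0.5, 0.8))
    area_crop <- u(c(0, 3))
  }

  # input use scaled to land and herd
  fert_n <- area_grass * u(n_rate_grass(ctry)) +
    area_crop * u(n_rate_crop(ctry))
  lime <- u(lime_bounds(ctry))
  diesel <- (area_grass + area_crop) * u(c(40, 70)) +
    sum(cohorts$headcount) * u(c(4, 8))
  elec <- sum(cohorts$headcount) * u(c(50, 120)) + u(c(1000, 3000))
  hedge <- u(hedge_bounds(ctry))

  conc <- concentrate_draw(sys, ctry, cohorts)

  # housed manure split; pasture entry mirrors the herd's grazing time
  slurry <- u(switch(ctry, IE = c(0.55, 0.75), FR = c(0.45, 0.65),
                     c(0.75, 0.95)))
  nex_w <- cohorts$headcount * cohorts$n_excretion
  graze_frac <- if (sum(nex_w) > 0) {
    sum(nex_w * cohorts$days_grazing / 365) / sum(nex_w)
  } else 0
  shares <- c(slurry_tank = (1 - graze_frac) * slurry,
              solid_storage = (1 - graze_frac) * (1 - slurry),
              pasture_deposition = graze_frac)

  herd_lw <- sum(cohorts$headcount * cohorts$avg_live_weight)
  farm_record(
    farm_id = p$tag %||% paste0(ctry, "_", sys),
    system = sys, country = ctry,
    grassland_area = area_grass, cropland_area = area_crop,
    cohorts = cohorts,
    lw_sold = lw_sold, lw_purchased = lw_purch,
    lw_opening = herd_lw, lw_closing = herd_lw,
    fert_n_applied = fert_n, lime_applied = lime,
    concentrate_fed = conc,
    diesel_used = diesel, electricity_used = elec,
    manure_system_shares = shares,
    hedgerow_length = hedge
  )
}

# Concentrate use (kg/year by type): grass-based suckler systems feed low
# levels; intensive fattening systems feed ad libitum.
concentrate_draw <- function(sys, ctry, cohorts) {
  heads <- sum(cohorts$headcount)
  if (sys == "beef_fattening" && ctry %in% c("IT", "ES", "FR")) {
    per_head <- u(c(1300, 2000))
    c(cereal_mix = 0.45 * heads * per_head,
      maize_meal = 0.35 * heads * per_head,
      protein_mix = 0.20 * heads * per_head)
  } else if (sys == "beef_fattening") { # Irish forage-based finishing
    per_head <- u(c(500, 900))
    c(cereal_mix = 0.6 * heads * per_head,
      compound_feed = 0.4 * heads * per_head)
  } else if (sys %in% c("dairy_calf_to_beef", "dairy_calf_to_store")) {
    per_head <- u(c(350, 700))
    calves <- sum(cohorts$headcount[cohorts$category == "dairy_origin_calf"])
    c(compound_feed = heads * per_head,
      milk_replacer = calves * u(c(40, 70)))
  } else {
    per_head <- u(c(80, 250)) # low-concentrate grass systems
    c(cereal_mix = 0.7 * heads * per_head,
      compound_feed = 0.3 * heads * per_head)
  }
}

#' Generate the packaged 20-farm synthetic suite
#'
#' Five farms per country flavour with the archetype mix of the panel:
#' Ireland one farm of each system; France two suckler-to-weaning, two
#' suckler-to-beef (one with purchases) and one fattening; Italy four
#' fattening and one suckler-to-beef; Spain three suckler-to-beef with
#' purchases and two fattening. Deterministic under a fixed seed.
#'
#' @param seed Integer seed.
#' @return A 20-row farm table.
#' @examples
#' suite <- generate_suite(seed = 42)
#' table(suite$country, suite$system)
#' @export
generate_suite <- function(seed = 42) {
  prof <- archetype_profiles()
  sub_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max - 1L,
                                           nrow(prof)))
  purrr::map(seq_len(nrow(prof)), function(i) {
    generate_farm(prof$profile[[i]], sub_seeds[i])
  }) |>
    bind_rows()
}
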