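#' Emission source operations
#'
#' Each operation computes one emission source of the cradle-to-farm-gate
#' boundary and returns a tidy source table with columns `source`, `gas`,
#' `mass` (kg of gas per year) and `co2e_preaggregated` (TRUE for off-farm
#' factors only available as CO2e, which the GWP aggregation multiplies
#' by 1). Cohort-level operations accept the cohort tibble of a farm and
#' are linear in headcount and in every activity datum. Set
#' `by_cohort = TRUE` to obtain the per-cohort breakdown (an extra
#' `category` column) instead of the aggregated rows.
#'
#' @param cohorts A cohort tibble (see [animal_cohort()]).
#' @param by_cohort Return per-cohort rows instead of aggregated rows.
#' @name source_ops
NULL

source_row <- function(source, gas, mass, preagg = FALSE,
                       category = NULL) {
  out <- tibble(source = source, gas = gas, mass = as.numeric(mass),
                co2e_preaggregated = preagg)
  if (!is.null(category)) out <- mutate(out, category = category,
                                        .before = 1)
  out
}

finish_source <- function(rows, by_cohort) {
  if (by_cohort) return(rows)
  rows |>
    group_by(.data$source, .data$gas, .data$co2e_preaggregated) |>
    summarise(mass = sum(.data$mass), .groups = "drop") |>
    select("source", "gas", "mass", "co2e_preaggregated")
}

#' @describeIn source_ops Enteric methane by the IPCC tier-2 equation:
#'   kg CH4/head/year = GEI x (Ym/100) x 365 / 55.65, scaled by headcount.
#' @param ym Methane conversion factor, percent of gross energy intake.
#' @export
enteric_ch4_tier2 <- function(cohorts, ym, by_cohort = FALSE) {
  if (!is.numeric(ym) || ym < 0 || ym >= 15) {
    abort("'ym' must be a percentage in [0, 15).")
  }
  if (any(cohorts$gross_energy_intake < 0)) {
    abort("gross_energy_intake must be >= 0.")
  }
  mass <- cohorts$headcount * cohorts$gross_energy_intake * (ym / 100) *
    365 / CH4_ENERGY_MJ_PER_KG
  finish_source(
    source_row("enteric", "CH4", mass, category = cohorts$category),
    by_cohort
  )
}

#' @describeIn source_ops Enteric methane from a per-head table
#'   (kg CH4/head/year by animal category), the shape national tier-3
#'   tools expose.
#' @param per_head Named numeric vector, kg CH4/head/year by category.
#' @export
enteric_ch4_per_head <- function(cohorts, per_head, by_cohort = FALSE) {
  missing_cat <- setdiff(unique(cohorts$category[cohorts$headcount > 0]),
                         names(per_head))
  if (length(missing_cat)) {
    abort(paste0("No per-head enteric factor for category: ",
                 paste(missing_cat, collapse = ", ")))
  }
  factor <- unname(per_head[cohorts$category])
  factor[is.na(factor)] <- 0
  mass <- cohorts$headcount * factor
  finish_source(
    source_row("enteric", "CH4", mass, category = cohorts$category),
    by_cohort
  )
}

# Split the housed fraction of excreted manure across the non-pasture
# management systems, renormalized; pasture deposition is governed by
# days_grazing, not by the shares entry.
housed_system_shares <- function(shares) {
  check_shares(shares)
  hs <- shares[setdiff(names(shares), "pasture_deposition")]
  s <- sum(hs)
  if (s > 0) hs / s else hs
}

check_shares <- function(shares) {
  if (is.null(names(shares)) || !all(names(shares) %in% manure_systems())) {
    abort("manure shares must be named by manure-management system.")
  }
  if (any(shares < 0) || abs(sum(shares) - 1) > 1e-9) {
    abort(paste0("manure shares must be >= 0 and sum to 1 (got ",
                 format(sum(shares)), ")."))
  }
  invisible(shares)
}

#' @describeIn source_ops Manure methane: VS x 365 x B0 x 0.67 kg/m3 x
#'   MCF/100 per head, with the housed share of the year apportioned
#'   across storage systems and the grazing share using the pasture MCF
#'   (reported under `grazing_returns`).
#' @param shares Named manure-system shares summing to 1.
#' @param efs An [ef_set()].
#' @export
manure_ch4 <- function(cohorts, shares, efs, by_cohort = FALSE) {
  stopifnot(inherits(efs, "ef_set"))
  hs <- housed_system_shares(shares)
  missing_sys <- setdiff(names(hs)[hs > 0], names(efs$mcf))
  if (length(missing_sys)) {
    abort(paste0("No MCF for manure system: ",
                 paste(missing_sys, collapse = ", ")))
  }
  mcf_housed <- sum(hs * efs$mcf[names(hs)] / 100)
  mcf_pasture <- unname(efs$mcf["pasture_deposition"] %||% 0) / 100
  if (is.na(mcf_pasture)) mcf_pasture <- 0
  base <- cohorts$headcount * cohorts$volatile_solids * 365 *
    efs$b0 * 0.67
  housed <- base * (cohorts$days_housed / 365) * mcf_housed
  pasture <- base * (cohorts$days_grazing / 365) * mcf_pasture
  rows <- bind_rows(
    source_row("manure_storage", "CH4", housed,
               category = cohorts$category),
    source_row("grazing_returns", "CH4", pasture,
               category = cohorts$category)
  )
  finish_source(rows, by_cohort)
}

#' @describeIn source_ops Direct nitrous oxide from stored manure:
#'   N2O-N = housed-period N excretion x EF3(system), converted to N2O
#'   by 44/28.
#' @export
manure_n2o <- function(cohorts, shares, efs, by_cohort = FALSE) {
  stopifnot(inherits(efs, "ef_set"))
  hs <- housed_system_shares(shares)
  missing_sys <- setdiff(names(hs)[hs > 0], names(efs$ef3_storage))
  if (length(missing_sys)) {
    abort(paste0("No EF3 storage factor for manure system: ",
                 paste(missing_sys, collapse = ", ")))
  }
  ef3 <- if (length(hs)) sum(hs * efs$ef3_storage[names(hs)]) else 0
  n_housed <- cohorts$headcount * cohorts$n_excretion *
    (cohorts$days_housed / 365)
  mass <- n_housed * ef3 * N2O_N_TO_N2O
  finish_source(
    source_row("manure_storage", "N2O", mass, category = cohorts$category),
    by_cohort
  )
}

#' @describeIn source_ops Nitrous oxide from manure deposited by grazing
#'   cattle: N2O-N = Nex x (days_grazing/365) x EF3_prp.
#' @export
grazing_n2o <- function(cohorts, efs, by_cohort = FALSE) {
  stopifnot(inherits(efs, "ef_set"))
  mass <- cohorts$headcount * cohorts$n_excretion *
    (cohorts$days_grazing / 365) * efs$ef3_prp * N2O_N_TO_N2O
  finish_source(
    source_row("grazing_returns", "N2O", mass, category = cohorts$category),
    by_cohort
  )
}

#' Soil and indirect nitrous oxide, liming/fuel CO2, off-farm CO2e,
#' sequestration
#'
#' Farm-level source operations complementing the cohort-level ones.
#' `soil_n2o_fertilizer()` applies EF1 to synthetic fertilizer N and to
#' spread manure N (reported under `soil_fertilizer` and
#' `manure_spreading` respectively). `indirect_n2o()` covers the
#' volatilization (Frac_gas x EF4) and leaching (Frac_leach x EF5)
#' pathways. `liming_and_fuel_co2()` and `offfarm_co2e()` are linear in
#' their inputs; off-farm factors are only available pre-aggregated in
#' CO2e and are carried under gas CO2 with `co2e_preaggregated = TRUE`.
#' `sequestration()` returns carbon removal by grassland and hedgerows,
#' kept separate from the gross inventory so gross and net footprints are
#' both reportable.
#'
#' @param fert_n Synthetic fertilizer N applied, kg N/year.
#' @param spread_manure_n Manure N spread on soils, kg N/year.
#' @param excreted_n Total N excreted by the herd, kg N/year.
#' @param efs An [ef_set()].
#' @return A source table (see [source_ops]); `sequestration()` returns a
#'   tibble with columns `farm_id` and `sequestration` (kg CO2e/year
#'   removed).
#' @name farm_ops
NULL

#' @rdname farm_ops
#' @export
soil_n2o_fertilizer <- function(fert_n, spread_manure_n = 0, efs) {
  stopifnot(inherits(efs, "ef_set"), fert_n >= 0, spread_manure_n >= 0)
  bind_rows(
    source_row("soil_fertilizer", "N2O",
               fert_n * efs$ef1 * N2O_N_TO_N2O),
    source_row("manure_spreading", "N2O",
               spread_manure_n * efs$ef1 * N2O_N_TO_N2O)
  )
}

#' @rdname farm_ops
#' @export
indirect_n2o <- function(fert_n, excreted_n = 0, efs) {
  stopifnot(inherits(efs, "ef_set"), fert_n >= 0, excreted_n >= 0)
  n2o_n <- fert_n * efs$frac_gas_synthetic * efs$ef4 +
    excreted_n * efs$frac_gas_manure * efs$ef4 +
    (fert_n + excreted_n) * efs$frac_leach * efs$ef5
  source_row("indirect_n", "N2O", n2o_n * N2O_N_TO_N2O)
}

#' @rdname farm_ops
#' @param lime Lime applied, kg/year.
#' @param diesel Diesel used, L/year.
#' @export
liming_and_fuel_co2 <- function(lime, diesel, efs) {
  stopifnot(inherits(efs, "ef_set"), lime >= 0, diesel >= 0)
  bind_rows(
    source_row("liming", "CO2", lime * efs$ef_lime),
    source_row("energy", "CO2", diesel * efs$ef_diesel, preagg = TRUE)
  )
}

#' @rdname farm_ops
#' @param farm A one-row farm table (see [farm_record()]).
#' @export
offfarm_co2e <- function(farm, efs) {
  stopifnot(inherits(efs, "ef_set"), nrow(farm) == 1L)
  conc <- farm$concentrate_fed[[1]]
  conc <- conc[conc > 0]
  missing_type <- setdiff(names(conc), names(efs$ef_concentrate))
  if (length(missing_type)) {
    abort(paste0("No concentrate emission factor for type: ",
                 paste(missing_type, collapse = ", ")))
  }
  conc_mass <- if (length(conc)) {
    sum(conc * efs$ef_concentrate[names(conc)])
  } else 0
  bind_rows(
    source_row("fert_manufacture", "CO2",
               farm$fert_n_applied * efs$ef_fert_manufacture, preagg = TRUE),
    source_row("concentrate", "CO2", conc_mass, preagg = TRUE),
    source_row("energy", "CO2",
               farm$electricity_used * efs$ef_electricity, preagg = TRUE)
  )
}

#' @rdname farm_ops
#' @param farms A farm table (one or more rows).
#' @export
sequestration <- function(farms, efs) {
  stopifnot(inherits(efs, "ef_set"))
  tibble(
    farm_id = farms$farm_id,
    sequestration = farms$grassland_area * efs$seq_rate_grassland +
      farms$hedgerow_length * efs$seq_rate_hedgerow
  )
}

# Canonical (source, gas, preagg) grid an inventory always reports,
# so zero farms yield explicit zero rows and no source is double counted.
inventory_grid <- function() {
  tibble(
    source = c("enteric", "manure_storage", "grazing_returns",
               "manure_storage", "manure_spreading", "grazing_returns",
               "soil_fertilizer", "indirect_n",
               "liming", "energy", "fert_manufacture", "concentrate"),
    gas = c("CH4", "CH4", "CH4",
            "N2O", "N2O", "N2O", "N2O", "N2O",
            "CO2", "CO2", "CO2", "CO2"),
    co2e_preaggregated = c(FALSE, FALSE, FALSE,
                           FALSE, FALSE, FALSE, FALSE, FALSE,
                           FALSE, TRUE, TRUE, TRUE)
  )
}

#' Build the annual emission inventory of one or more farms
#'
#' Runs every source operation of the cradle-to-farm-gate boundary on each
#' farm under one emission-factor set and assembles the per-source,
#' per-gas annual gas masses. The boundary excludes upstream emissions of
#' purchased cattle: purchased animals contribute only through the cohort
#' records describing their time on this farm. Carbon sequestration is not
#' part of the inventory; obtain it with [sequestration()].
#'
#' @param farms A validated farm table (see [farm_record()]).
#' @param efs An [ef_set()]; its `enteric_mode` decides whether enteric
#'   methane uses the tier-2 equation or the per-head table.
#' @return A tibble with columns `farm_id`, `source`, `gas`, `mass`
#'   (kg gas/year) and `co2e_preaggregated`, one row per entry of the
#'   fixed source-gas grid.
#' @examples
#' suite <- generate_suite(seed = 1)
#' inv <- build_inventory(suite[1, ], load_ef_set("IE_style"))
#' inv
#' @export
build_inventory <- function(farms, efs) {
  stopifnot(inherits(efs, "ef_set"))
  assert_valid_farm(farms)
  purrr::map(seq_len(nrow(farms)), function(i) {
    farm <- farms[i, ]
    build_inventory_one(farm, efs) |>
      mutate(farm_id = farm$farm_id, .before = 1)
  }) |>
    bind_rows()
}

build_inventory_one <- function(farm, efs) {
  ch <- farm$cohorts[[1]]
  shares <- farm$manure_system_shares[[1]]
  rows <- list()
  if (nrow(ch) > 0) {
    enteric <- if (efs$enteric_mode == "tier2") {
      enteric_ch4_tier2(ch, efs$ym)
    } else {
      enteric_ch4_per_head(ch, efs$per_head_enteric)
    }
    rows <- c(rows, list(
      enteric,
      manure_ch4(ch, shares, efs),
      manure_n2o(ch, shares, efs),
      grazing_n2o(ch, efs)
    ))
  }
  nex_total <- if (nrow(ch)) sum(ch$headcount * ch$n_excretion) else 0
  nex_housed <- if (nrow(ch)) {
    sum(ch$headcount * ch$n_excretion * ch$days_housed / 365)
  } else 0
  rows <- c(rows, list(
    soil_n2o_fertilizer(farm$fert_n_applied, nex_housed, efs),
    indirect_n2o(farm$fert_n_applied, nex_total, efs),
    liming_and_fuel_co2(farm$lime_applied, farm$diesel_used, efs),
    offfarm_co2e(farm, efs)
  ))
  bind_rows(rows) |>
    group_by(.data$source, .data$gas, .data$co2e_preaggregated) |>
    summarise(mass = sum(.data$mass), .groups = "drop") |>
    right_join_grid()
}

right_join_grid <- function(x) {
  grid <- inventory_grid()
  out <- dplyr::left_join(grid, x,
                          by = c("source", "gas", "co2e_preaggregated"))
  out$mass[is.na(out$mass)] <- 0
  select(out, "source", "gas", "mass", "co2e_preaggregated")
}
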