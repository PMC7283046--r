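#' Build an animal-cohort table
#'
#' A cohort is a group of animals of one category sharing average annual
#' headcount, live weight, daily gain, gross energy intake, N excretion,
#' volatile-solids excretion and a grazing/housing split of the year.
#' Cohort tables are stored in the `cohorts` list-column of a farm record.
#'
#' @param category Animal class; one of [cohort_categories()].
#' @param headcount Average annual number of animals.
#' @param avg_live_weight Average live weight, kg.
#' @param daily_gain Average daily live-weight gain, kg/day.
#' @param gross_energy_intake Gross energy intake, MJ/head/day.
#' @param n_excretion N excretion, kg N/head/year.
#' @param volatile_solids Volatile-solids excretion, kg VS/head/day.
#' @param days_grazing Days per year at pasture, in \[0, 365\].
#' @param days_housed Days per year housed; defaults to `365 - days_grazing`.
#' @return A one-row tibble; rows from repeated calls can be bound together.
#' @export
animal_cohort <- function(category, headcount, avg_live_weight = 0,
                          daily_gain = 0, gross_energy_intake = 0,
                          n_excretion = 0, volatile_solids = 0,
                          days_grazing = 0,
                          days_housed = 365 - days_grazing) {
  tibble(
    category = as.character(category),
    headcount = as.numeric(headcount),
    avg_live_weight = as.numeric(avg_live_weight),
    daily_gain = as.numeric(daily_gain),
    gross_energy_intake = as.numeric(gross_energy_intake),
    n_excretion = as.numeric(n_excretion),
    volatile_solids = as.numeric(volatile_solids),
    days_grazing = as.numeric(days_grazing),
    days_housed = as.numeric(days_housed)
  )
}

#' Build a farm record
#'
#' One farm-year of activity data: land areas, the animal cohorts, live
#' weight flows (sold, purchased, opening and closing inventory), nitrogen
#' and lime inputs, concentrate feeding, fuel and electricity use, the
#' split of excreted manure across management systems, and hedgerow length.
#' All quantities are annual and in SI base units (kg, ha, m, L, kWh).
#'
#' @param farm_id Farm identifier.
#' @param system Farm system; one of [farm_systems()].
#' @param grassland_area,cropland_area Areas, ha.
#' @param cohorts A cohort tibble built with [animal_cohort()].
#' @param lw_sold,lw_purchased Live weight sold / purchased, kg/year.
#' @param lw_opening,lw_closing Opening and closing herd live weight, kg.
#' @param fert_n_applied Synthetic fertilizer N applied, kg N/year.
#' @param lime_applied Lime applied, kg/year.
#' @param concentrate_fed Named numeric vector: kg/year by concentrate type.
#' @param diesel_used Diesel, L/year.
#' @param electricity_used Electricity, kWh/year.
#' @param manure_system_shares Named numeric vector over
#'   [manure_systems()], summing to 1.
#' @param hedgerow_length Hedgerow length, m.
#' @param country Optional two-letter country flavour label.
#' @return A one-row tibble with list-columns `cohorts`, `concentrate_fed`
#'   and `manure_system_shares`; bind rows to form a multi-farm table.
#' @seealso [validate_farm()], [generate_suite()]
#' @export
farm_record <- function(farm_id, system, grassland_area, cropland_area = 0,
                        cohorts = animal_cohort("suckler_cow", 0)[0, ],
                        lw_sold = 0, lw_purchased = 0,
                        lw_opening = 0, lw_closing = 0,
                        fert_n_applied = 0, lime_applied = 0,
                        concentrate_fed = c(cereal_mix = 0),
                        diesel_used = 0, electricity_used = 0,
                        manure_system_shares = c(slurry_tank = 0.5,
                                                 solid_storage = 0.2,
                                                 pasture_deposition = 0.3),
                        hedgerow_length = 0, country = NA_character_) {
  tibble(
    farm_id = as.character(farm_id),
    system = as.character(system),
    country = as.character(country),
    grassland_area = as.numeric(grassland_area),
    cropland_area = as.numeric(cropland_area),
    cohorts = list(as_tibble(cohorts)),
    lw_sold = as.numeric(lw_sold),
    lw_purchased = as.numeric(lw_purchased),
    lw_opening = as.numeric(lw_opening),
    lw_closing = as.numeric(lw_closing),
    fert_n_applied = as.numeric(fert_n_applied),
    lime_applied = as.numeric(lime_applied),
    concentrate_fed = list(concentrate_fed),
    diesel_used = as.numeric(diesel_used),
    electricity_used = as.numeric(electricity_used),
    manure_system_shares = list(manure_system_shares),
    hedgerow_length = as.numeric(hedgerow_length)
  )
}

#' Validate farm records
#'
#' Checks every type invariant of the farm-record and cohort schemas and
#' returns the findings as data rather than raising: an empty tibble means
#' the farm(s) are valid. Each finding names the farm, the offending field
#' and the violated rule.
#'
#' @param farms A farm table (one or more rows) built with [farm_record()]
#'   or read with [read_farms()].
#' @return A tibble with columns `farm_id`, `field`, `message`;
#'   zero rows when all invariants hold.
#' @examples
#' f <- farm_record("demo", "suckler_to_beef", grassland_area = 40,
#'                  cohorts = animal_cohort("suckler_cow", 30,
#'                    gross_energy_intake = 160, n_excretion = 85,
#'                    volatile_solids = 3.5, days_grazing = 220),
#'                  lw_sold = 15000)
#' validate_farm(f)
#' @export
validate_farm <- function(farms) {
  stopifnot(is.data.frame(farms))
  finding <- function(id, field, msg) {
    tibble(farm_id = id, field = field, message = msg)
  }
  out <- list()
  num_fields <- c("grassland_area", "cropland_area", "lw_sold",
                  "lw_purchased", "lw_opening", "lw_closing",
                  "fert_n_applied", "lime_applied", "diesel_used",
                  "electricity_used", "hedgerow_length")
  missing_cols <- setdiff(c("farm_id", "system", "cohorts",
                            "concentrate_fed", "manure_system_shares",
                            num_fields), names(farms))
  if (length(missing_cols)) {
    abort(paste0("Farm table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (i in seq_len(nrow(farms))) {
    fm <- farms[i, ]
    id <- fm$farm_id
    if (!fm$system %in% farm_systems()) {
      out <- c(out, list(finding(id, "system",
        paste0("unknown farm system '", fm$system, "'"))))
    }
    for (f in num_fields) {
      v <- fm[[f]]
      if (!is.finite(v) || v < 0) {
        out <- c(out, list(finding(id, f, "must be a finite number >= 0")))
      }
    }
    shares <- fm$manure_system_shares[[1]]
    if (is.null(names(shares)) || !all(names(shares) %in% manure_systems())) {
      out <- c(out, list(finding(id, "manure_system_shares",
        "keys must be manure-management systems")))
    }
    if (any(shares < 0) || abs(sum(shares) - 1) > 1e-9) {
      out <- c(out, list(finding(id, "manure_system_shares",
        paste0("shares must be >= 0 and sum to 1 (got ",
               format(sum(shares)), ")"))))
    }
    conc <- fm$concentrate_fed[[1]]
    if (length(conc) && (any(conc < 0) || is.null(names(conc)))) {
      out <- c(out, list(finding(id, "concentrate_fed",
        "must be a named vector of kg >= 0 by concentrate type")))
    }
    ch <- fm$cohorts[[1]]
    for (j in seq_len(nrow(ch))) {
      co <- ch[j, ]
      lab <- paste0("cohorts[", j, ":", co$category, "]")
      if (!co$category %in% cohort_categories()) {
        out <- c(out, list(finding(id, lab, "unknown animal category")))
      }
      if (abs(co$days_grazing + co$days_housed - 365) > 1e-9) {
        out <- c(out, list(finding(id, lab,
          "days_grazing + days_housed must equal 365")))
      }
      if (co$days_grazing < 0 || co$days_grazing > 365) {
        out <- c(out, list(finding(id, lab,
          "days_grazing must lie in [0, 365]")))
      }
      nonneg <- c("headcount", "avg_live_weight", "daily_gain",
                  "gross_energy_intake", "n_excretion", "volatile_solids")
      for (f in nonneg) {
        if (!is.finite(co[[f]]) || co[[f]] < 0) {
          out <- c(out, list(finding(id, paste0(lab, ".", f),
            "must be a finite number >= 0")))
        }
      }
      if (co$headcount > 0 && co$gross_energy_intake <= 0) {
        out <- c(out, list(finding(id, paste0(lab, ".gross_energy_intake"),
          "must be > 0 when headcount > 0")))
      }
    }
  }
  if (length(out)) bind_rows(out) else
    tibble(farm_id = character(), field = character(), message = character())
}

# Stop unless a farm table validates cleanly; used by engine entry points.
assert_valid_farm <- function(farms) {
  v <- validate_farm(farms)
  if (nrow(v) > 0) {
    abort(paste0(
      "Invalid farm record(s):\n",
      paste0("  [", v$farm_id, "] ", v$field, ": ", v$message,
             collapse = "\n")
    ))
  }
  invisible(farms)
}
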