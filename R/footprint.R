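#' Aggregate an inventory to CO2 equivalents
#'
#' Weights each gas mass by its global-warming potential; entries flagged
#' `co2e_preaggregated` are already CO2e and are multiplied by 1.
#'
#' @param inv An inventory table from [build_inventory()] or a source
#'   table from the individual source operations.
#' @param gwp A [gwp_set()].
#' @return If `inv` has a `farm_id` column, a tibble with columns
#'   `farm_id` and `co2e`; otherwise a single number (kg CO2e/year).
#' @examples
#' co2e_aggregate(tibble::tibble(source = "enteric", gas = "CH4", mass = 1,
#'                               co2e_preaggregated = FALSE))
#' @export
co2e_aggregate <- function(inv, gwp = gwp_set()) {
  stopifnot(inherits(gwp, "gwp_set"), is.data.frame(inv))
  if (!"co2e_preaggregated" %in% names(inv)) {
    inv$co2e_preaggregated <- FALSE
  }
  w <- ifelse(inv$co2e_preaggregated, 1, gwp_weight(gwp, inv$gas))
  inv$co2e <- inv$mass * w
  if ("farm_id" %in% names(inv)) {
    inv |>
      group_by(.data$farm_id) |>
      summarise(co2e = sum(.data$co2e), .groups = "drop")
  } else {
    sum(inv$co2e)
  }
}

#' Live-weight gain produced on-farm
#'
#' LWG = (live weight sold + closing herd weight) - (live weight purchased
#' + opening herd weight). This is the functional unit of the footprint;
#' purchased weight is subtracted so emissions relate only to weight put
#' on while on this farm.
#'
#' @param farms A farm table.
#' @return A tibble with columns `farm_id` and `lwg` (kg/year).
#' @export
compute_lwg <- function(farms) {
  lwg <- (farms$lw_sold + farms$lw_closing) -
    (farms$lw_purchased + farms$lw_opening)
  bad <- which(lwg <= 0)
  if (length(bad)) {
    abort(paste0(
      "Live-weight gain must be > 0 for a footprint to be defined; ",
      "offending farm(s): ",
      paste0(farms$farm_id[bad], " (", lwg[bad], " kg)", collapse = ", ")
    ))
  }
  tibble(farm_id = farms$farm_id, lwg = lwg)
}

#' Allocate emissions to the beef output
#'
#' Beef farms produce live weight only, so the default allocates all
#' emissions to beef (`beef_fraction = 1`). A smaller fraction supports
#' co-product situations such as dairy herds, where most cow emissions
#' are carried by milk rather than beef.
#'
#' @param total_co2e Total emissions, kg CO2e/year.
#' @param beef_fraction Fraction in \[0, 1\] allocated to beef.
#' @return kg CO2e/year allocated to beef.
#' @export
allocate_emissions <- function(total_co2e, beef_fraction = 1) {
  if (!is.numeric(beef_fraction) || any(beef_fraction < 0) ||
      any(beef_fraction > 1)) {
    abort("'beef_fraction' must lie in [0, 1].")
  }
  total_co2e * beef_fraction
}

#' Per-source emission profile
#'
#' Shares of the gross CO2e footprint by source, on the 0-100 scale.
#'
#' @inheritParams co2e_aggregate
#' @return A tibble with columns (`farm_id`,) `source`, `share`; shares
#'   sum to 100 per farm.
#' @export
emission_profile <- function(inv, gwp = gwp_set()) {
  stopifnot(is.data.frame(inv))
  if (!"co2e_preaggregated" %in% names(inv)) inv$co2e_preaggregated <- FALSE
  has_id <- "farm_id" %in% names(inv)
  if (!has_id) inv$farm_id <- "farm"
  w <- ifelse(inv$co2e_preaggregated, 1, gwp_weight(gwp, inv$gas))
  inv$co2e <- inv$mass * w
  prof <- inv |>
    group_by(.data$farm_id, .data$source) |>
    summarise(co2e = sum(.data$co2e), .groups = "drop_last") |>
    mutate(total = sum(.data$co2e)) |>
    ungroup()
  if (any(prof$total <= 0)) {
    abort("Gross emissions are zero; the emission profile is undefined.")
  }
  prof <- prof |>
    mutate(share = 100 * .data$co2e / .data$total) |>
    select("farm_id", "source", "share")
  if (!has_id) prof$farm_id <- NULL
  prof
}

#' Gross and net carbon footprint of beef farms
#'
#' The central result: for each farm, the inventory is built under the
#' given emission-factor set, aggregated to CO2e under the GWP set,
#' optionally allocated to beef, and related to three functional units:
#' live-weight gain (the primary basis), live weight sold, and carcass
#' weight (live weight sold x the 55% dressing percentage). The net
#' footprint subtracts carbon sequestration by grassland and hedgerows
#' from the gross total; a negative net total is reported, not clamped,
#' and flagged in `negative_net`.
#'
#' @param farms A validated farm table.
#' @param efs An [ef_set()] or the name of a packaged set.
#' @param gwp A [gwp_set()].
#' @param beef_fraction Fraction of emissions allocated to beef output.
#' @return A `footprint_tbl`: one row per farm with columns `farm_id`,
#'   `system`, `country`, `gross_total`, `sequestration`, `net_total`
#'   (kg CO2e/year), `lwg`, `lw_sold` (kg/year), `gross_per_lwg`,
#'   `net_per_lwg`, `per_lw_sold`, `per_cw` (kg CO2e/kg), `negative_net`,
#'   and a `profile` list-column of per-source shares (percent of gross).
#' @examples
#' suite <- generate_suite(seed = 1)
#' fp <- farm_footprint(suite, "IE_style")
#' fp[, c("farm_id", "system", "gross_per_lwg", "net_per_lwg")]
#' @param .inventory Optional precomputed inventory for these farms (used
#'   by the mitigation engine to rescale source masses); by default the
#'   inventory is built from `farms` and `efs`.
#' @export
farm_footprint <- function(farms, efs, gwp = gwp_set(), beef_fraction = 1,
                           .inventory = NULL) {
  if (is.character(efs)) efs <- load_ef_set(efs)
  stopifnot(inherits(efs, "ef_set"), inherits(gwp, "gwp_set"))
  assert_valid_farm(farms)
  inv <- .inventory %||% build_inventory(farms, efs)
  gross <- co2e_aggregate(inv, gwp) |>
    mutate(gross_total = allocate_emissions(.data$co2e, beef_fraction)) |>
    select("farm_id", "gross_total")
  seq_tbl <- sequestration(farms, efs)
  lwg_tbl <- compute_lwg(farms)
  prof <- emission_profile(inv, gwp) |>
    tidyr::nest(profile = c("source", "share"))
  out <- tibble(farm_id = farms$farm_id, system = farms$system,
                country = farms$country, lw_sold = farms$lw_sold) |>
    left_join(gross, by = "farm_id") |>
    left_join(seq_tbl, by = "farm_id") |>
    left_join(lwg_tbl, by = "farm_id") |>
    left_join(prof, by = "farm_id") |>
    mutate(
      net_total = .data$gross_total - .data$sequestration,
      gross_per_lwg = .data$gross_total / .data$lwg,
      net_per_lwg = .data$net_total / .data$lwg,
      per_lw_sold = ifelse(.data$lw_sold > 0,
                           .data$gross_total / .data$lw_sold, NA_real_),
      per_cw = .data$per_lw_sold / DRESSING_PCT,
      negative_net = .data$net_total < 0
    ) |>
    select("farm_id", "system", "country", "gross_total", "sequestration",
           "net_total", "lwg", "lw_sold", "gross_per_lwg", "net_per_lwg",
           "per_lw_sold", "per_cw", "negative_net", "profile")
  class(out) <- c("footprint_tbl", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.footprint_tbl <- function(x, ...) {
  x |>
    as_tibble() |>
    select("farm_id", "system", "profile") |>
    tidyr::unnest("profile")
}

#' @exportS3Method generics::glance
glance.footprint_tbl <- function(x, ...) {
  tibble(
    n_farms = nrow(x),
    mean_gross_per_lwg = mean(x$gross_per_lwg),
    mean_net_per_lwg = mean(x$net_per_lwg),
    median_gross_per_lwg = median(x$gross_per_lwg),
    total_gross = sum(x$gross_total),
    total_sequestration = sum(x$sequestration),
    n_negative_net = sum(x$negative_net)
  )
}
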