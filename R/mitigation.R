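#' Define a mitigation measure
#'
#' A measure changes a farm's footprint through exactly one of two
#' mechanisms: a `parameter_override` re-runs the engine with named
#' engine parameters (emission-factor fields such as `ym` or
#' `seq_rate_grassland`, or farm fields such as `hedgerow_length`) set to
#' new values; an `intensity_delta` rescales the named gas masses of the
#' affected sources by a percentage (negative = reduction). Measures with
#' high uncertainty in the achievable reduction carry
#' `uncertainty = TRUE`.
#'
#' @param name Measure name (unique within a catalogue).
#' @param category Grouping label, e.g. `"animal_performance_diet"`,
#'   `"soil_land_use"`, `"manure"`, `"energy"`.
#' @param mechanism `"parameter_override"` or `"intensity_delta"`.
#' @param overrides Named list of engine parameter -> new value
#'   (override mechanism only).
#' @param deltas Named numeric vector of gas -> percent change in
#'   \[-100, 100\] (delta mechanism only).
#' @param affected_sources Sources the deltas apply to.
#' @param applicable_systems Farm systems the measure applies to, or
#'   `"all"`.
#' @param uncertainty Flag for measures whose reduction is highly
#'   uncertain.
#' @return An object of class `mitigation_measure`.
#' @export
mitigation_measure <- function(name, category = "other",
                               mechanism = c("intensity_delta",
                                             "parameter_override"),
                               overrides = NULL, deltas = NULL,
                               affected_sources = character(),
                               applicable_systems = "all",
                               uncertainty = FALSE) {
  mechanism <- match.arg(mechanism)
  if (mechanism == "parameter_override") {
    if (is.null(overrides) || !length(overrides) || !is.null(deltas)) {
      abort("parameter_override measures need 'overrides' and no 'deltas'.")
    }
  } else {
    if (is.null(deltas) || !is.null(overrides)) {
      abort("intensity_delta measures need 'deltas' and no 'overrides'.")
    }
    deltas <- unlist(deltas)
    if (is.null(names(deltas)) || !all(names(deltas) %in% gases())) {
      abort("'deltas' must be named by gas (CH4, N2O, CO2).")
    }
    if (any(deltas < -100) || any(deltas > 100)) {
      abort("'deltas' must lie in [-100, 100] percent.")
    }
    if (!length(affected_sources) && any(deltas != 0)) {
      abort("intensity_delta measures must name 'affected_sources'.")
    }
    bad <- setdiff(affected_sources, emission_sources())
    if (length(bad)) {
      abort(paste0("Unknown affected source(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  if (!identical(applicable_systems, "all")) {
    bad <- setdiff(applicable_systems, farm_systems())
    if (length(bad)) {
      abort(paste0("Unknown applicable system(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  structure(list(name = name, category = category, mechanism = mechanism,
                 overrides = overrides, deltas = deltas,
                 affected_sources = affected_sources,
                 applicable_systems = applicable_systems,
                 uncertainty = isTRUE(uncertainty)),
            class = "mitigation_measure")
}

#' @export
print.mitigation_measure <- function(x, ...) {
  cat("<mitigation_measure>", x$name, paste0("[", x$category, "]"),
      if (x$uncertainty) "(?)" else "", "\n")
  if (x$mechanism == "parameter_override") {
    cat("  overrides:",
        paste(names(x$overrides), unlist(x$overrides), sep = " -> ",
              collapse = ", "), "\n")
  } else {
    cat("  deltas:", paste(names(x$deltas), x$deltas, sep = " ",
                           collapse = ", "),
        "% on", paste(x$affected_sources, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Load the mitigation-measure catalogue
#'
#' Reads a measure catalogue from a YAML/JSON config file; with no path,
#' the packaged catalogue is loaded. The packaged catalogue encodes the
#' four measure families (animal performance and diet, soil and land use,
#' manure, energy) with per-gas signs and uncertainty flags; its
#' magnitudes are illustrative configuration values chosen so that
#' families rank animal/diet > soil > manure > energy in mitigation
#' potential.
#'
#' @param path Optional path to a catalogue file.
#' @return A named list of [mitigation_measure()] objects, class
#'   `measure_catalogue`.
#' @export
measure_catalogue <- function(path = NULL) {
  path <- path %||% system.file("extdata", "measures.yaml",
                                package = "beefcarbon", mustWork = TRUE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  ms <- purrr::map(raw$measures, function(m) {
    mitigation_measure(
      name = m$name, category = m$category %||% "other",
      mechanism = m$mechanism,
      overrides = m$overrides,
      deltas = if (!is.null(m$deltas)) unlist(m$deltas),
      affected_sources = unlist(m$affected_sources) %||% character(),
      applicable_systems = unlist(m$applicable_systems) %||% "all",
      uncertainty = isTRUE(m$uncertainty)
    )
  })
  names(ms) <- purrr::map_chr(ms, "name")
  if (anyDuplicated(names(ms))) {
    abort("Measure names in the catalogue must be unique.")
  }
  structure(ms, class = "measure_catalogue")
}

#' Assemble a mitigation plan
#'
#' @param measures A list of [mitigation_measure()] objects (e.g. a
#'   subset of [measure_catalogue()]).
#' @param combination_rule How intensity deltas hitting the same
#'   (source, gas) combine: `"multiplicative"` (default; stacked
#'   reductions on one source can never exceed 100%) or
#'   `"additive_capped"` (summed, floored at -100%).
#' @return An object of class `mitigation_plan`.
#' @export
mitigation_plan <- function(measures,
                            combination_rule = c("multiplicative",
                                                 "additive_capped")) {
  combination_rule <- match.arg(combination_rule)
  measures <- unname(purrr::map(measures, identity))
  stopifnot(all(purrr::map_lgl(measures,
                               inherits, "mitigation_measure")))
  nm <- purrr::map_chr(measures, "name")
  if (anyDuplicated(nm)) abort("Plan measure names must be unique.")
  structure(list(measures = measures, combination_rule = combination_rule),
            class = "mitigation_plan")
}

#' The packaged combined mitigation plan
#'
#' All catalogue measures stacked under the multiplicative rule: the
#' package's rendering of a common plan aggregating each family's
#' options.
#'
#' @param catalogue A `measure_catalogue`.
#' @return A [mitigation_plan()].
#' @export
default_plan <- function(catalogue = measure_catalogue()) {
  mitigation_plan(catalogue, combination_rule = "multiplicative")
}

measure_applies <- function(m, system) {
  identical(m$applicable_systems, "all") || system %in% m$applicable_systems
}

# Apply parameter overrides jointly; last writer wins per parameter (a
# message is emitted when a later measure overwrites an earlier value).
apply_overrides <- function(farm, efs, overrides_list) {
  seen <- character()
  for (ov in overrides_list) {
    for (nm in names(ov)) {
      val <- ov[[nm]]
      if (nm %in% seen) {
        inform(paste0("Override conflict on '", nm,
                      "': last writer wins (", val, ")."))
      }
      seen <- union(seen, nm)
      if (nm %in% ef_numeric_fields()) {
        efs[[nm]] <- if (is.numeric(efs[[nm]]) && !is.null(names(efs[[nm]])) &&
                         is.list(val)) unlist(val) else val
        validate_ef_set(efs)
      } else if (nm %in% names(farm) && is.numeric(farm[[nm]])) {
        farm[[nm]] <- as.numeric(val)
      } else {
        abort(paste0("Unknown engine parameter in override: '", nm, "'"))
      }
    }
  }
  list(farm = farm, efs = efs)
}

# Rescale inventory masses for intensity-delta measures. Factors for the
# same (source, gas) combine multiplicatively or additively (capped).
apply_deltas <- function(inv, measures, rule) {
  factor <- rep(1, nrow(inv))
  add <- rep(0, nrow(inv))
  for (m in measures) {
    for (g in names(m$deltas)) {
      hit <- inv$source %in% m$affected_sources & inv$gas == g
      if (rule == "multiplicative") {
        factor[hit] <- factor[hit] * (1 + m$deltas[[g]] / 100)
      } else {
        add[hit] <- add[hit] + m$deltas[[g]] / 100
      }
    }
  }
  if (rule == "additive_capped") factor <- pmax(0, 1 + add)
  inv$mass <- inv$mass * pmax(0, factor)
  inv
}

scenario_run <- function(farms, efs, measures, rule, gwp, baseline = NULL) {
  over <- purrr::map(keep(measures,
                          ~ .x$mechanism == "parameter_override"),
                     "overrides")
  deltas <- keep(measures, ~ .x$mechanism == "intensity_delta")
  baseline <- baseline %||% farm_footprint(farms, efs, gwp)
  mitigated <- purrr::map(seq_len(nrow(farms)), function(i) {
    st <- apply_overrides(farms[i, ], efs, over)
    inv <- build_inventory(st$farm, st$efs)
    inv <- apply_deltas(inv, deltas, rule)
    farm_footprint(st$farm, st$efs, gwp, .inventory = inv)
  }) |>
    bind_rows()
  class(mitigated) <- class(baseline)
  list(baseline = baseline, mitigated = mitigated)
}

make_scenario_tbl <- function(pair, label, contributions = NULL) {
  b <- pair$baseline
  m <- pair$mitigated
  out <- tibble(
    farm_id = b$farm_id, system = b$system, scenario = label,
    baseline_gross_per_lwg = b$gross_per_lwg,
    mitigated_gross_per_lwg = m$gross_per_lwg,
    baseline_net_per_lwg = b$net_per_lwg,
    mitigated_net_per_lwg = m$net_per_lwg,
    reduction_pct = (1 - m$net_per_lwg / b$net_per_lwg) * 100
  )
  if (!is.null(contributions)) out$contributions <- contributions
  attr(out, "baseline") <- b
  attr(out, "mitigated") <- m
  class(out) <- c("scenario_tbl", class(out))
  out
}

#' Apply a single mitigation measure
#'
#' Recomputes the footprint of each farm with the measure applied and
#' reports the percentage reduction in net footprint per kg LWG
#' (positive = reduction). Parameter-override measures re-run the engine
#' under the overridden parameters; intensity-delta measures rescale the
#' affected source masses of the baseline inventory. Live-weight gain is
#' held fixed unless the measure overrides the weight-flow fields.
#'
#' @param farms A farm table; every farm's system must be applicable.
#' @param efs An [ef_set()] or packaged set name.
#' @param measure A [mitigation_measure()].
#' @param gwp A [gwp_set()].
#' @return A `scenario_tbl`: per-farm baseline and mitigated footprints
#'   plus `reduction_pct`.
#' @examples
#' suite <- generate_suite(seed = 1)
#' cat <- measure_catalogue()
#' sc <- apply_measure(suite[1, ], "IE_style", cat$improved_forage_quality)
#' sc$reduction_pct
#' @export
apply_measure <- function(farms, efs, measure, gwp = gwp_set()) {
  if (is.character(efs)) efs <- load_ef_set(efs)
  stopifnot(inherits(measure, "mitigation_measure"))
  bad <- !purrr::map_lgl(farms$system, ~ measure_applies(measure, .x))
  if (any(bad)) {
    abort(paste0("Measure '", measure$name, "' is not applicable to ",
                 "system(s): ",
                 paste(unique(farms$system[bad]), collapse = ", ")))
  }
  pair <- scenario_run(farms, efs, list(measure), "multiplicative", gwp)
  make_scenario_tbl(pair, measure$name)
}

#' Stack a mitigation plan
#'
#' Applies all measures of a plan together: parameter overrides are
#' applied jointly (last writer wins per parameter), and intensity deltas
#' on the same source and gas combine under the plan's combination rule.
#' Measures not applicable to a farm's system are skipped for that farm.
#' Per-measure contributions are reported as sequential marginal
#' reductions (percentage points of baseline net footprint), which depend
#' on measure order; under the multiplicative rule the total does not.
#'
#' @param farms A farm table.
#' @param efs An [ef_set()] or packaged set name.
#' @param plan A [mitigation_plan()].
#' @param gwp A [gwp_set()].
#' @return A `scenario_tbl` with a `contributions` list-column
#'   (tibble: measure, marginal_pct per farm).
#' @export
stack_plan <- function(farms, efs, plan, gwp = gwp_set()) {
  if (is.character(efs)) efs <- load_ef_set(efs)
  stopifnot(inherits(plan, "mitigation_plan"))
  rule <- plan$combination_rule
  rows <- purrr::map(seq_len(nrow(farms)), function(i) {
    farm <- farms[i, ]
    ms <- keep(plan$measures, ~ measure_applies(.x, farm$system))
    baseline <- farm_footprint(farm, efs, gwp)
    if (!length(ms)) {
      pair <- list(baseline = baseline, mitigated = baseline)
      return(make_scenario_tbl(pair, "plan",
                               contributions = list(tibble(
                                 measure = character(),
                                 marginal_pct = numeric()))))
    }
    red_k <- numeric(length(ms))
    pair <- NULL
    for (k in seq_along(ms)) {
      pair <- scenario_run(farm, efs, ms[seq_len(k)], rule, gwp,
                           baseline = baseline)
      red_k[k] <- (1 - pair$mitigated$net_per_lwg /
                     baseline$net_per_lwg) * 100
    }
    contrib <- tibble(measure = purrr::map_chr(ms, "name"),
                      marginal_pct = diff(c(0, red_k)))
    make_scenario_tbl(pair, "plan", contributions = list(contrib))
  })
  out <- bind_rows(rows)
  class(out) <- c("scenario_tbl", class(out))
  out
}

#' Evaluate a scenario against a reduction target
#'
#' @param result A `scenario_tbl` from [apply_measure()] or
#'   [stack_plan()].
#' @param target_pct Reduction target in percent (default 15).
#' @return A tibble with per-farm `reduction_pct`, `pass` (reduction >=
#'   target) and `margin` (percentage points above the target).
#' @export
evaluate_target <- function(result, target_pct = 15) {
  stopifnot(is.data.frame(result), "reduction_pct" %in% names(result))
  tibble(
    farm_id = result$farm_id,
    reduction_pct = result$reduction_pct,
    target_pct = target_pct,
    pass = result$reduction_pct >= target_pct,
    margin = result$reduction_pct - target_pct
  )
}

#' @exportS3Method generics::tidy
tidy.scenario_tbl <- function(x, ...) {
  if ("contributions" %in% names(x)) {
    x |>
      as_tibble() |>
      select("farm_id", "contributions") |>
      tidyr::unnest("contributions")
  } else {
    as_tibble(x)[, c("farm_id", "scenario", "reduction_pct")]
  }
}

#' @exportS3Method generics::glance
glance.scenario_tbl <- function(x, ...) {
  tibble(
    n_farms = nrow(x),
    mean_reduction_pct = mean(x$reduction_pct),
    median_reduction_pct = median(x$reduction_pct),
    min_reduction_pct = min(x$reduction_pct),
    max_reduction_pct = max(x$reduction_pct)
  )
}
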