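#' Read and write farm tables
#'
#' Farms are exchanged either as a nested JSON document (one object per
#' farm, cohorts as an array, concentrate and manure shares as maps) or
#' as a two-table CSV dialect: `farms.csv` (one row per farm, concentrate
#' columns prefixed `conc_`, manure-share columns prefixed `share_`) plus
#' a companion `cohorts.csv` keyed by `farm_id`. A JSON write/read
#' round-trip reproduces the records exactly; numbers are written at full
#' precision.
#'
#' @param farms A farm table.
#' @param path For JSON, the file path (`.json`); for CSV, the path of
#'   the farms table (the cohort table is read/written as `cohorts.csv`
#'   next to it, or at `cohorts_path`).
#' @param cohorts_path Optional explicit path of the cohort CSV.
#' @return `read_farms()` returns a validated farm table; `write_farms()`
#'   returns the written path(s) invisibly.
#' @name farm_io
NULL

farm_csv_columns <- function() {
  c("farm_id", "system", "country", "grassland_area", "cropland_area",
    "lw_sold", "lw_purchased", "lw_opening", "lw_closing",
    "fert_n_applied", "lime_applied", "diesel_used", "electricity_used",
    "hedgerow_length")
}

cohort_csv_columns <- function() {
  c("farm_id", "category", "headcount", "avg_live_weight", "daily_gain",
    "gross_energy_intake", "n_excretion", "volatile_solids",
    "days_grazing", "days_housed")
}

#' @rdname farm_io
#' @export
write_farms <- function(farms, path, cohorts_path = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- purrr::map(seq_len(nrow(farms)), function(i) {
      fm <- farms[i, ]
      list(
        farm_id = fm$farm_id, system = fm$system, country = fm$country,
        grassland_area = fm$grassland_area,
        cropland_area = fm$cropland_area,
        lw_sold = fm$lw_sold, lw_purchased = fm$lw_purchased,
        lw_opening = fm$lw_opening, lw_closing = fm$lw_closing,
        fert_n_applied = fm$fert_n_applied,
        lime_applied = fm$lime_applied,
        diesel_used = fm$diesel_used,
        electricity_used = fm$electricity_used,
        hedgerow_length = fm$hedgerow_length,
        concentrate_fed = as.list(fm$concentrate_fed[[1]]),
        manure_system_shares = as.list(fm$manure_system_shares[[1]]),
        cohorts = fm$cohorts[[1]]
      )
    })
    # I(17) significant digits: doubles survive the round-trip exactly
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = I(17))
    return(invisible(path))
  }
  cohorts_path <- cohorts_path %||% file.path(dirname(path), "cohorts.csv")
  flat <- farms |>
    select(all_of(farm_csv_columns()))
  conc <- purrr::map(farms$concentrate_fed, ~ as.list(.x)) |>
    purrr::map(~ setNames(.x, paste0("conc_", names(.x)))) |>
    bind_rows()
  shares <- purrr::map(farms$manure_system_shares, ~ as.list(.x)) |>
    purrr::map(~ setNames(.x, paste0("share_", names(.x)))) |>
    bind_rows()
  readr::write_csv(bind_cols(flat, conc, shares), path)
  co <- purrr::map2(farms$farm_id, farms$cohorts,
                    ~ mutate(.y, farm_id = .x, .before = 1)) |>
    bind_rows()
  readr::write_csv(co[, cohort_csv_columns()], cohorts_path)
  invisible(c(path, cohorts_path))
}

#' @rdname farm_io
#' @export
read_farms <- function(path, cohorts_path = NULL) {
  if (!file.exists(path)) abort(paste0("Farm file not found: ", path))
  farms <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    read_farms_json(path)
  } else {
    read_farms_csv(path, cohorts_path)
  }
  v <- validate_farm(farms)
  if (nrow(v) > 0) {
    abort(paste0("Farm file ", path, " failed validation:\n",
                 paste0("  [", v$farm_id, "] ", v$field, ": ", v$message,
                        collapse = "\n")))
  }
  farms
}

read_farms_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  purrr::map(recs, function(r) {
    need <- c("farm_id", "system", "cohorts")
    miss <- setdiff(need, names(r))
    if (length(miss)) {
      abort(paste0("Farm JSON record is missing field(s): ",
                   paste(miss, collapse = ", ")))
    }
    ch <- bind_rows(purrr::map(r$cohorts, function(co) {
      do.call(animal_cohort,
              co[intersect(names(co), names(formals(animal_cohort)))])
    }))
    farm_record(
      farm_id = r$farm_id, system = r$system,
      country = r$country %||% NA_character_,
      grassland_area = r$grassland_area %||% 0,
      cropland_area = r$cropland_area %||% 0,
      cohorts = ch,
      lw_sold = r$lw_sold %||% 0, lw_purchased = r$lw_purchased %||% 0,
      lw_opening = r$lw_opening %||% 0, lw_closing = r$lw_closing %||% 0,
      fert_n_applied = r$fert_n_applied %||% 0,
      lime_applied = r$lime_applied %||% 0,
      concentrate_fed = unlist(r$concentrate_fed),
      diesel_used = r$diesel_used %||% 0,
      electricity_used = r$electricity_used %||% 0,
      manure_system_shares = unlist(r$manure_system_shares),
      hedgerow_length = r$hedgerow_length %||% 0
    )
  }) |>
    bind_rows()
}

read_farms_csv <- function(path, cohorts_path = NULL) {
  cohorts_path <- cohorts_path %||% file.path(dirname(path), "cohorts.csv")
  if (!file.exists(cohorts_path)) {
    abort(paste0("Cohort table not found: ", cohorts_path))
  }
  fl <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(farm_csv_columns(), names(fl))
  if (length(miss)) {
    abort(paste0("farms CSV is missing mandatory column(s): ",
                 paste(miss, collapse = ", ")))
  }
  co <- readr::read_csv(cohorts_path, show_col_types = FALSE)
  miss_co <- setdiff(cohort_csv_columns(), names(co))
  if (length(miss_co)) {
    abort(paste0("cohorts CSV is missing mandatory column(s): ",
                 paste(miss_co, collapse = ", ")))
  }
  check_numeric_cols(fl, setdiff(farm_csv_columns(),
                                 c("farm_id", "system", "country")), path)
  check_numeric_cols(co, setdiff(cohort_csv_columns(),
                                 c("farm_id", "category")), cohorts_path)
  purrr::map(seq_len(nrow(fl)), function(i) {
    fm <- fl[i, ]
    conc_cols <- grep("^conc_", names(fl), value = TRUE)
    share_cols <- grep("^share_", names(fl), value = TRUE)
    conc <- setNames(as.numeric(fm[conc_cols]),
                     sub("^conc_", "", conc_cols))
    conc <- conc[!is.na(conc)] # absent types in a mixed-farm file
    shares <- setNames(as.numeric(fm[share_cols]),
                       sub("^share_", "", share_cols))
    shares <- shares[!is.na(shares)]
    ch <- co |>
      filter(.data$farm_id == fm$farm_id) |>
      select(-"farm_id")
    farm_record(
      farm_id = fm$farm_id, system = fm$system,
      country = if ("country" %in% names(fm)) fm$country else NA_character_,
      grassland_area = fm$grassland_area, cropland_area = fm$cropland_area,
      cohorts = ch,
      lw_sold = fm$lw_sold, lw_purchased = fm$lw_purchased,
      lw_opening = fm$lw_opening, lw_closing = fm$lw_closing,
      fert_n_applied = fm$fert_n_applied, lime_applied = fm$lime_applied,
      concentrate_fed = conc,
      diesel_used = fm$diesel_used,
      electricity_used = fm$electricity_used,
      manure_system_shares = shares,
      hedgerow_length = fm$hedgerow_length
    )
  }) |>
    bind_rows()
}

check_numeric_cols <- function(df, cols, path) {
  for (cl in intersect(cols, names(df))) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      abort(paste0("Non-numeric value in column '", cl, "' of ", path,
                   if (length(bad)) paste0(" (row ", bad[1], ")")))
    }
  }
  invisible(df)
}

#' Write result reports
#'
#' Writes deterministic CSV reports at 4 significant digits:
#' footprint tables (`footprints.csv` + `profiles.csv`), comparison
#' grids (`comparison.csv` + `comparison_wide.csv` + `concordance.csv`)
#' and mitigation scenarios (`scenarios.csv` + `contributions.csv`),
#' depending on the class of `x`.
#'
#' @param x A `footprint_tbl`, `comparison_tbl` or `scenario_tbl`.
#' @param dir Output directory (created if needed).
#' @return The written file paths, invisibly.
#' @export
write_report <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sig <- function(df) mutate(df, across(dplyr::where(is.numeric),
                                        ~ signif(.x, 4)))
  paths <- character()
  if (inherits(x, "footprint_tbl")) {
    fp_path <- file.path(dir, "footprints.csv")
    readr::write_csv(sig(select(as_tibble(x), -"profile")), fp_path)
    pr_path <- file.path(dir, "profiles.csv")
    readr::write_csv(sig(tidy(x)), pr_path)
    paths <- c(fp_path, pr_path)
  } else if (inherits(x, "comparison_tbl")) {
    cmp_path <- file.path(dir, "comparison.csv")
    tmp <- as_tibble(x)
    readr::write_csv(sig(tmp), cmp_path)
    wide <- tmp |>
      select("farm_id", "set", "gross_per_lwg") |>
      tidyr::pivot_wider(names_from = "set",
                         values_from = "gross_per_lwg")
    wide_path <- file.path(dir, "comparison_wide.csv")
    readr::write_csv(sig(wide), wide_path)
    paths <- c(cmp_path, wide_path)
    if (length(unique(tmp$set)) >= 2 &&
        length(unique(tmp$farm_id)) >= 2) {
      conc <- ranking_concordance(x)
      conc_path <- file.path(dir, "concordance.csv")
      readr::write_csv(sig(conc$tau), conc_path)
      paths <- c(paths, conc_path)
    }
  } else if (inherits(x, "scenario_tbl")) {
    sc_path <- file.path(dir, "scenarios.csv")
    tmp <- as_tibble(x)
    has_contrib <- "contributions" %in% names(tmp)
    readr::write_csv(sig(select(tmp, -dplyr::any_of("contributions"))),
                     sc_path)
    paths <- sc_path
    if (has_contrib) {
      ct_path <- file.path(dir, "contributions.csv")
      readr::write_csv(sig(tidy(x)), ct_path)
      paths <- c(paths, ct_path)
    }
  } else {
    abort("write_report() expects a footprint, comparison or scenario table.")
  }
  invisible(paths)
}

#' Load a GWP set from a config file
#'
#' @param path YAML/JSON file with fields `gwp_ch4`, `gwp_n2o`,
#'   `gwp_co2`, `horizon`; `NULL` returns the default GWP100 set
#'   (25, 298, 1).
#' @return A [gwp_set()].
#' @export
load_gwp_set <- function(path = NULL) {
  if (is.null(path)) return(gwp_set())
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(gwp_set, raw[intersect(names(raw), names(formals(gwp_set)))])
}

#' Load a mitigation plan from a config file
#'
#' The file lists `combination_rule` and `measures`; each measure entry
#' is either the name of a catalogue measure or a full measure
#' definition.
#'
#' @param path Plan config file; `NULL` returns the packaged
#'   [default_plan()].
#' @param catalogue Catalogue used to resolve measure names.
#' @return A [mitigation_plan()].
#' @export
load_plan <- function(path = NULL, catalogue = measure_catalogue()) {
  if (is.null(path)) return(default_plan(catalogue))
  raw <- yaml::read_yaml(path)
  ms <- purrr::map(raw$measures, function(m) {
    if (is.character(m)) {
      if (!m %in% names(catalogue)) {
        abort(paste0("Plan references unknown measure '", m, "'."))
      }
      catalogue[[m]]
    } else {
      mitigation_measure(
        name = m$name, category = m$category %||% "other",
        mechanism = m$mechanism, overrides = m$overrides,
        deltas = if (!is.null(m$deltas)) unlist(m$deltas),
        affected_sources = unlist(m$affected_sources) %||% character(),
        applicable_systems = unlist(m$applicable_systems) %||% "all",
        uncertainty = isTRUE(m$uncertainty)
      )
    }
  })
  mitigation_plan(ms, combination_rule = raw$combination_rule %||%
                    "multiplicative")
}
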