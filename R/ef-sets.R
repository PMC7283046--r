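#' Construct an emission-factor set
#'
#' An emission-factor set bundles every loss factor and embedded-emission
#' factor the engine needs: the enteric methane method (IPCC tier-2 from
#' gross energy intake, or a per-head table in the style of national tier-3
#' tools), manure methane parameters (B0, MCF), the nitrous-oxide factor
#' chain (EF1, EF3, EF4, EF5 with volatilization and leaching fractions),
#' and CO2/CO2e factors for lime, fertilizer manufacture, concentrates,
#' diesel and electricity, plus carbon-sequestration rates for grassland
#' and hedgerows. Sets are the pluggable "models" the comparison harness
#' contrasts; three region-flavoured sets ship with the package
#' (`"IE_style"`, `"FR_style"`, `"ES_style"`).
#'
#' @param name Identifier for the set.
#' @param enteric_mode `"tier2"` (uses `ym`) or `"per_head_table"`
#'   (uses `per_head_enteric`).
#' @param ym Methane conversion factor: percent of gross energy intake lost
#'   as enteric CH4 (tier-2 mode). Must lie in (0, 15).
#' @param per_head_enteric Named numeric vector, kg CH4/head/year by animal
#'   category (per-head mode).
#' @param b0 Maximum methane-producing capacity of manure, m3 CH4/kg VS.
#' @param mcf Named numeric vector of methane conversion factors (percent)
#'   by manure-management system.
#' @param ef3_storage Named numeric vector, kg N2O-N per kg N excreted into
#'   each housed manure-management system.
#' @param ef3_prp kg N2O-N per kg N deposited by grazing animals on pasture.
#' @param ef1 kg N2O-N per kg N applied to soil (fertilizer and spread
#'   manure).
#' @param frac_gas_synthetic,frac_gas_manure Fractions of applied synthetic
#'   N / excreted manure N volatilized as NH3 and NOx.
#' @param frac_leach Fraction of N applied or excreted that leaches.
#' @param ef4 kg N2O-N per kg N volatilized (indirect, re-deposition).
#' @param ef5 kg N2O-N per kg N leached (indirect).
#' @param ef_lime kg CO2 per kg lime applied.
#' @param ef_fert_manufacture kg CO2e per kg N manufactured.
#' @param ef_concentrate Named numeric vector, kg CO2e per kg concentrate
#'   by concentrate type.
#' @param ef_diesel kg CO2e per litre of diesel.
#' @param ef_electricity kg CO2e per kWh.
#' @param seq_rate_grassland kg CO2e sequestered per ha grassland per year.
#' @param seq_rate_hedgerow kg CO2e sequestered per m hedgerow per year.
#'
#' @return An object of class `ef_set` (a named list).
#' @seealso [load_ef_set()], [gwp_set()]
#' @export
ef_set <- function(name,
                   enteric_mode = c("tier2", "per_head_table"),
                   ym = 6.5,
                   per_head_enteric = NULL,
                   b0 = 0.17,
                   mcf = c(slurry_tank = 17, solid_storage = 4,
                           pasture_deposition = 1),
                   ef3_storage = c(slurry_tank = 0.005, solid_storage = 0.005),
                   ef3_prp = 0.02,
                   ef1 = 0.01,
                   frac_gas_synthetic = 0.10,
                   frac_gas_manure = 0.20,
                   frac_leach = 0.30,
                   ef4 = 0.01,
                   ef5 = 0.0075,
                   ef_lime = 0.44,
                   ef_fert_manufacture = 6.0,
                   ef_concentrate = c(cereal_mix = 0.75, protein_mix = 1.1,
                                      maize_meal = 0.65, compound_feed = 0.85,
                                      milk_replacer = 1.6),
                   ef_diesel = 2.67,
                   ef_electricity = 0.45,
                   seq_rate_grassland = 250,
                   seq_rate_hedgerow = 1.25) {
  enteric_mode <- match.arg(enteric_mode)
  x <- list(
    name = name, enteric_mode = enteric_mode, ym = ym,
    per_head_enteric = per_head_enteric, b0 = b0, mcf = mcf,
    ef3_storage = ef3_storage, ef3_prp = ef3_prp, ef1 = ef1,
    frac_gas_synthetic = frac_gas_synthetic,
    frac_gas_manure = frac_gas_manure, frac_leach = frac_leach,
    ef4 = ef4, ef5 = ef5, ef_lime = ef_lime,
    ef_fert_manufacture = ef_fert_manufacture,
    ef_concentrate = ef_concentrate, ef_diesel = ef_diesel,
    ef_electricity = ef_electricity,
    seq_rate_grassland = seq_rate_grassland,
    seq_rate_hedgerow = seq_rate_hedgerow
  )
  class(x) <- "ef_set"
  validate_ef_set(x)
  x
}

# Numeric scalar/vector fields an ef_set must carry; all must be >= 0.
ef_numeric_fields <- function() {
  c("ym", "b0", "mcf", "ef3_storage", "ef3_prp", "ef1",
    "frac_gas_synthetic", "frac_gas_manure", "frac_leach", "ef4", "ef5",
    "ef_lime", "ef_fert_manufacture", "ef_concentrate", "ef_diesel",
    "ef_electricity", "seq_rate_grassland", "seq_rate_hedgerow")
}

validate_ef_set <- function(x) {
  if (!is.character(x$name) || length(x$name) != 1L || !nzchar(x$name)) {
    abort("ef_set field 'name' must be a non-empty string.")
  }
  if (!x$enteric_mode %in% c("tier2", "per_head_table")) {
    abort("ef_set field 'enteric_mode' must be 'tier2' or 'per_head_table'.")
  }
  for (f in ef_numeric_fields()) {
    v <- x[[f]]
    if (is.null(v) || !is.numeric(v) || anyNA(v)) {
      abort(paste0("ef_set field '", f, "' must be numeric and non-missing."))
    }
    if (any(v < 0)) {
      abort(paste0("ef_set field '", f, "' must be >= 0."))
    }
  }
  if (x$enteric_mode == "tier2" && (x$ym <= 0 || x$ym >= 15)) {
    abort("ef_set field 'ym' must lie in (0, 15) percent in tier2 mode.")
  }
  if (any(x$mcf > 100)) {
    abort("ef_set field 'mcf' values must lie in [0, 100] percent.")
  }
  if (!all(names(x$mcf) %in% manure_systems())) {
    abort("ef_set field 'mcf' has unknown manure-system keys.")
  }
  if (!all(names(x$ef3_storage) %in% setdiff(manure_systems(),
                                             "pasture_deposition"))) {
    abort("ef_set field 'ef3_storage' keys must be housed manure systems.")
  }
  if (x$enteric_mode == "per_head_table") {
    t <- x$per_head_enteric
    if (is.null(t) || !is.numeric(t) || is.null(names(t)) || length(t) == 0) {
      abort("per_head_table mode requires a named 'per_head_enteric' table.")
    }
    if (!all(names(t) %in% cohort_categories())) {
      abort("ef_set field 'per_head_enteric' has unknown animal categories.")
    }
    if (any(t < 0)) abort("ef_set field 'per_head_enteric' must be >= 0.")
  }
  invisible(x)
}

#' Load a packaged or user-supplied emission-factor set
#'
#' Resolves `name_or_path` against the registry of packaged sets
#' (`"IE_style"`, `"FR_style"`, `"ES_style"`) and otherwise treats it as a
#' path to a YAML or JSON configuration file with the fields of [ef_set()].
#'
#' @param name_or_path A packaged set name or a readable config-file path.
#' @return A validated `ef_set`.
#' @examples
#' ie <- load_ef_set("IE_style")
#' ie$enteric_mode
#' @export
load_ef_set <- function(name_or_path) {
  stopifnot(is.character(name_or_path), length(name_or_path) == 1L)
  reg <- builtin_ef_sets()
  if (name_or_path %in% reg) {
    path <- system.file("extdata", "ef_sets",
                        paste0(name_or_path, ".yaml"),
                        package = "beefcarbon", mustWork = TRUE)
    return(read_ef_set_file(path))
  }
  if (file.exists(name_or_path)) {
    return(read_ef_set_file(name_or_path))
  }
  abort(paste0(
    "Unknown emission-factor set '", name_or_path, "'. ",
    "Packaged sets: ", paste(reg, collapse = ", "),
    ". Otherwise supply a path to a YAML/JSON config file."
  ))
}

#' @rdname load_ef_set
#' @export
builtin_ef_sets <- function() {
  dir <- system.file("extdata", "ef_sets", package = "beefcarbon")
  sort(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
}

read_ef_set_file <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  ef_set_from_list(raw)
}

ef_set_from_list <- function(raw) {
  for (f in c("per_head_enteric", "mcf", "ef3_storage", "ef_concentrate")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  # whole numbers parse as integers; factors are doubles throughout
  for (f in intersect(ef_numeric_fields(), names(raw))) {
    if (!is.null(raw[[f]])) storage.mode(raw[[f]]) <- "double"
  }
  if (!is.null(raw$per_head_enteric)) {
    storage.mode(raw$per_head_enteric) <- "double"
  }
  args <- raw[intersect(names(raw), names(formals(ef_set)))]
  unknown <- setdiff(names(raw), names(formals(ef_set)))
  if (length(unknown)) {
    abort(paste0("Unknown ef_set fields in config: ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(ef_set, args)
}

#' Serialize an emission-factor set
#'
#' Writes the set as JSON at full double precision, so a write/read
#' round-trip reproduces every factor bit-exactly.
#'
#' @param efs An `ef_set`.
#' @param path Output file path (`.json` or `.yaml`).
#' @return `path`, invisibly.
#' @export
write_ef_set <- function(efs, path) {
  stopifnot(inherits(efs, "ef_set"))
  x <- unclass(efs)
  # named atomic vectors must become lists to serialize as maps
  for (f in c("per_head_enteric", "mcf", "ef3_storage",
              "ef_concentrate")) {
    if (!is.null(x[[f]])) x[[f]] <- as.list(x[[f]])
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path, precision = 17L)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                         null = "null")
  }
  invisible(path)
}

#' @export
print.ef_set <- function(x, ...) {
  cat("<ef_set>", x$name, "\n")
  cat("  enteric:", x$enteric_mode,
      if (x$enteric_mode == "tier2") paste0("(Ym = ", x$ym, "% of GEI)")
      else paste0("(", length(x$per_head_enteric), " per-head factors)"), "\n")
  cat("  manure: B0 =", x$b0, "m3/kg VS; MCF% =",
      paste(names(x$mcf), x$mcf, sep = "=", collapse = ", "), "\n")
  cat("  N2O chain: EF1 =", x$ef1, "EF3prp =", x$ef3_prp,
      "EF4 =", x$ef4, "EF5 =", x$ef5, "\n")
  cat("  sequestration: grassland", x$seq_rate_grassland,
      "kg CO2e/ha/yr; hedgerow", x$seq_rate_hedgerow, "kg CO2e/m/yr\n")
  invisible(x)
}

#' Global-warming-potential set
#'
#' Weights used to aggregate gas masses to CO2 equivalents. The default is
#' the 100-year set standardized across the packaged models: 25 for CH4,
#' 298 for N2O and 1 for CO2.
#'
#' @param gwp_ch4,gwp_n2o,gwp_co2 kg CO2e per kg of gas.
#' @param horizon Time horizon in years (label only).
#' @return An object of class `gwp_set`.
#' @export
gwp_set <- function(gwp_ch4 = 25, gwp_n2o = 298, gwp_co2 = 1, horizon = 100) {
  vals <- c(gwp_ch4, gwp_n2o, gwp_co2, horizon)
  if (!is.numeric(vals) || anyNA(vals) || any(vals <= 0)) {
    abort("All gwp_set values must be positive numbers.")
  }
  structure(list(gwp_ch4 = gwp_ch4, gwp_n2o = gwp_n2o, gwp_co2 = gwp_co2,
                 horizon = horizon),
            class = "gwp_set")
}

#' @export
print.gwp_set <- function(x, ...) {
  cat("<gwp_set> GWP", x$horizon, ": CH4 =", x$gwp_ch4,
      "N2O =", x$gwp_n2o, "CO2 =", x$gwp_co2, "\n")
  invisible(x)
}

gwp_weight <- function(gwp, gas) {
  w <- c(CH4 = gwp$gwp_ch4, N2O = gwp$gwp_n2o, CO2 = gwp$gwp_co2)[gas]
  if (anyNA(w)) {
    abort(paste0("Unknown gas(es): ",
                 paste(unique(gas[is.na(w)]), collapse = ", ")))
  }
  unname(w)
}
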