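#' Run several emission-factor sets over the same farms
#'
#' The multi-model comparison harness: computes the gross footprint per kg
#' live-weight gain of every farm under every emission-factor set. A
#' failing farm x set cell (for example, zero live-weight gain) is
#' recorded with `status = "failed"` and an `NA` footprint rather than
#' aborting the grid.
#'
#' @param farms A farm table.
#' @param sets A list of [ef_set()] objects and/or packaged set names.
#' @param gwp A [gwp_set()].
#' @return A `comparison_tbl`: tidy tibble with columns `farm_id`,
#'   `system`, `set`, `gross_per_lwg`, `net_per_lwg`, `status`.
#' @examples
#' suite <- generate_suite(seed = 1)
#' cmp <- compare_ef_sets(suite, list("IE_style", "FR_style", "ES_style"))
#' head(cmp)
#' @export
compare_ef_sets <- function(farms, sets, gwp = gwp_set()) {
  stopifnot(nrow(farms) >= 1, length(sets) >= 1)
  sets <- purrr::map(sets, function(s) {
    if (is.character(s)) load_ef_set(s) else s
  })
  out <- purrr::map(sets, function(efs) {
    res <- tryCatch(
      farm_footprint(farms, efs, gwp),
      error = function(e) NULL
    )
    if (is.null(res)) {
      # retry farm-by-farm so one bad farm does not void a column
      rows <- purrr::map(seq_len(nrow(farms)), function(i) {
        r <- tryCatch(farm_footprint(farms[i, ], efs, gwp),
                      error = function(e) NULL)
        if (is.null(r)) {
          tibble(farm_id = farms$farm_id[i], system = farms$system[i],
                 set = efs$name, gross_per_lwg = NA_real_,
                 net_per_lwg = NA_real_, status = "failed")
        } else {
          tibble(farm_id = r$farm_id, system = r$system, set = efs$name,
                 gross_per_lwg = r$gross_per_lwg,
                 net_per_lwg = r$net_per_lwg, status = "ok")
        }
      })
      bind_rows(rows)
    } else {
      tibble(farm_id = res$farm_id, system = res$system, set = efs$name,
             gross_per_lwg = res$gross_per_lwg,
             net_per_lwg = res$net_per_lwg, status = "ok")
    }
  }) |>
    bind_rows()
  class(out) <- c("comparison_tbl", class(out))
  out
}

#' Mean pairwise footprint difference between two sets
#'
#' Mean over common farms of (footprint under `set_a` - footprint under
#' `set_b`); positive means `set_a` estimates higher. Failed cells are
#' dropped pairwise.
#'
#' @param table A `comparison_tbl` from [compare_ef_sets()].
#' @param set_a,set_b Set names present in the table.
#' @return A single number, kg CO2e/kg LWG.
#' @export
pairwise_mean_diff <- function(table, set_a, set_b) {
  stopifnot(is.data.frame(table))
  for (s in c(set_a, set_b)) {
    if (!s %in% table$set) {
      abort(paste0("Set '", s, "' is not present in the comparison table."))
    }
  }
  wide <- table |>
    filter(.data$set %in% c(set_a, set_b), .data$status == "ok") |>
    select("farm_id", "set", "gross_per_lwg") |>
    tidyr::pivot_wider(names_from = "set", values_from = "gross_per_lwg") |>
    tidyr::drop_na()
  if (nrow(wide) == 0) {
    abort("No common farms with successful footprints for both sets.")
  }
  mean(wide[[set_a]] - wide[[set_b]])
}

# Kendall tau between two footprint columns after breaking ties by farm
# order (first occurrence wins), per the reporting convention.
kendall_tau <- function(a, b) {
  ra <- rank(a, ties.method = "first")
  rb <- rank(b, ties.method = "first")
  stats::cor(ra, rb, method = "kendall")
}

#' Ranking concordance of farm footprints across sets
#'
#' Ranks farms by gross footprint per kg LWG within each set and measures
#' pairwise Kendall tau between the sets' rankings. Also builds a
#' "mixed-model" ranking, in which each farm is scored by a different set
#' (cycling through the sets in order), and reports its tau against each
#' pure set: a demonstration that mixing models across farms destabilizes
#' rankings even when each pure model ranks them consistently. Ties are
#' broken by farm order in the table.
#'
#' @param table A `comparison_tbl` with at least 2 farms and 2 sets.
#' @return A list of class `concordance` with elements `rankings`
#'   (tibble: set, farm_id, footprint, rank), `tau` (tibble: set_a,
#'   set_b, tau) and `mixed_tau` (tibble: set, tau_vs_mixed).
#' @export
ranking_concordance <- function(table) {
  stopifnot(is.data.frame(table))
  ok <- filter(table, .data$status == "ok")
  sets <- unique(ok$set)
  farm_ids <- unique(ok$farm_id)
  if (length(sets) < 2 || length(farm_ids) < 2) {
    abort("Ranking concordance needs at least 2 farms and 2 sets.")
  }
  complete <- ok |>
    group_by(.data$farm_id) |>
    filter(dplyr::n_distinct(.data$set) == length(sets)) |>
    ungroup()
  wide <- complete |>
    select("farm_id", "set", "gross_per_lwg") |>
    tidyr::pivot_wider(names_from = "set", values_from = "gross_per_lwg") |>
    arrange(match(.data$farm_id, farm_ids))
  rankings <- complete |>
    group_by(.data$set) |>
    arrange(match(.data$farm_id, farm_ids), .by_group = TRUE) |>
    mutate(rank = rank(.data$gross_per_lwg, ties.method = "first")) |>
    ungroup() |>
    select("set", "farm_id", footprint = "gross_per_lwg", "rank")
  pairs <- utils::combn(sets, 2, simplify = FALSE)
  tau <- purrr::map(pairs, function(p) {
    tibble(set_a = p[1], set_b = p[2],
           tau = kendall_tau(wide[[p[1]]], wide[[p[2]]]))
  }) |>
    bind_rows()
  # mixed-model column: farm i scored by set ((i - 1) mod n_sets) + 1
  idx <- ((seq_len(nrow(wide)) - 1) %% length(sets)) + 1
  mixed <- purrr::map_dbl(seq_len(nrow(wide)),
                          function(i) wide[[sets[idx[i]]]][i])
  mixed_tau <- tibble(
    set = sets,
    tau_vs_mixed = purrr::map_dbl(sets,
                                  function(s) kendall_tau(wide[[s]], mixed))
  )
  structure(list(rankings = rankings, tau = tau, mixed_tau = mixed_tau),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat("<concordance> pairwise Kendall tau of farm rankings\n")
  print(as.data.frame(x$tau), row.names = FALSE)
  cat("tau of each set against the mixed-model ranking:\n")
  print(as.data.frame(x$mixed_tau), row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.concordance <- function(x, ...) x$tau

#' @exportS3Method generics::glance
glance.comparison_tbl <- function(x, ...) {
  x |>
    as_tibble() |>
    group_by(.data$set) |>
    summarise(
      n_farms = sum(.data$status == "ok"),
      mean_gross_per_lwg = mean(.data$gross_per_lwg, na.rm = TRUE),
      median_gross_per_lwg = median(.data$gross_per_lwg, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Export a comparison table
#'
#' Writes the tidy (farm, set, footprint) table and a wide farm x set
#' grid next to it.
#'
#' @param table A `comparison_tbl`.
#' @param path Path of the tidy CSV; the wide grid is written alongside
#'   with suffix `_wide.csv`.
#' @return Paths of the written files, invisibly.
#' @export
write_comparison <- function(table, path) {
  readr::write_csv(as_tibble(table), path)
  wide <- table |>
    as_tibble() |>
    select("farm_id", "set", "gross_per_lwg") |>
    tidyr::pivot_wider(names_from = "set", values_from = "gross_per_lwg")
  wide_path <- sub("\\.csv$", "_wide.csv", path)
  readr::write_csv(wide, wide_path)
  invisible(c(path, wide_path))
}
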