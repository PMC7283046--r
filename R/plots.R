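#' Plot methods
#'
#' `autoplot()` methods for the three result types: footprint tables show
#' per-farm source profiles as stacked bars; comparison tables show the
#' footprint of every farm under every emission-factor set; scenario
#' tables show per-farm net-footprint reductions against a target line.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @exportS3Method ggplot2::autoplot
autoplot.footprint_tbl <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$farm_id, y = .data$share,
                                 fill = .data$source)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "share of gross footprint (%)",
                  fill = "source",
                  title = "Emission profile by farm") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname plots
#' @exportS3Method ggplot2::autoplot
autoplot.comparison_tbl <- function(object, ...) {
  as_tibble(object) |>
    filter(.data$status == "ok") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$farm_id,
                                 y = .data$gross_per_lwg,
                                 colour = .data$set, group = .data$set)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = "gross footprint (kg CO2e/kg LWG)",
                  colour = "EF set",
                  title = "Gross carbon footprints by farm and model") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname plots
#' @param target_pct Reference reduction target drawn as a line.
#' @exportS3Method ggplot2::autoplot
autoplot.scenario_tbl <- function(object, target_pct = 15, ...) {
  as_tibble(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$farm_id,
                                 y = .data$reduction_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = target_pct, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "net footprint reduction (%)",
                  title = "Mitigation-scenario reductions",
                  subtitle = paste0("dashed line: ", target_pct,
                                    "% target")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname plots
#' @param fp A `footprint_tbl`.
#' @export
plot_footprints <- function(fp) {
  as_tibble(fp) |>
    ggplot2::ggplot(ggplot2::aes(x = stats::reorder(.data$farm_id,
                                                    .data$gross_per_lwg),
                                 y = .data$gross_per_lwg,
                                 fill = .data$system)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "gross footprint (kg CO2e/kg LWG)",
                  fill = "system") +
    ggplot2::theme_minimal()
}
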