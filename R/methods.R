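#' Tidy an optimized design table
#'
#' @param x An `"expo_results"` tibble from [optimize_design()].
#' @param ... Unused.
#' @return A plain tibble with the scenario parameters and the optimal
#'   design columns (`n_s`, `n_d`, `variance`, `cost`, `utilization_pct`,
#'   `case`, `locus`, `method`).
#' @export
tidy.expo_results <- function(x, ...) {
  keep <- intersect(
    c("variance_set", "cost_set", scenario_cols,
      "n_s", "n_d", "variance", "variance_2dp", "cost",
      "utilization_pct", "case", "locus", "method"),
    names(x)
  )
  out <- tibble::as_tibble(x)[, keep]
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of an optimized design table
#'
#' @inheritParams tidy.expo_results
#' @return The [grid_summary()] of the results: median and 5th/95th
#'   percentile budget utilization and the count of single-occasion optima.
#' @export
glance.expo_results <- function(x, ...) {
  grid_summary(x)
}

#' Plot an optimized design table
#'
#' For results with several `alpha`/`beta` combinations (such as
#' [scenario_grid()] output), draws a tile map of the minimized variance
#' over the exponent grid, annotated with the optimal `(n_s, n_d)` and
#' faceted by variance and cost set when present. For a single scenario,
#' falls back to the sensitivity profile plot.
#'
#' @param object An `"expo_results"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.expo_results <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (nrow(df) == 1) {
    return(autoplot.expo_profile(design_profile(df[, scenario_cols])))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$alpha),
                                        y = factor(.data$beta),
                                        fill = .data$variance)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = paste0("(", .data$n_s, ",", .data$n_d, ")")), size = 2.6) +
    ggplot2::scale_fill_viridis_c(name = "variance") +
    ggplot2::labs(x = expression(alpha), y = expression(beta),
                  title = "Minimized mean-exposure variance and optimal design")
  if (all(c("variance_set", "cost_set") %in% names(df)) &&
      (dplyr::n_distinct(df$variance_set) > 1 ||
       dplyr::n_distinct(df$cost_set) > 1)) {
    p <- p + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$variance_set),
      cols = ggplot2::vars(.data$cost_set)
    )
  }
  p
}

#' Plot a budget-saturating sensitivity profile
#'
#' Variance of the best affordable design at each subject count, the view
#' used to pick an optimum in the fully non-linear case: each point is the
#' design `(n_s, max_occasions(n_s))`, the minimum is highlighted.
#'
#' @param object An `"expo_profile"` tibble from [design_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.expo_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (!"scenario" %in% names(df)) df$scenario <- 1L
  best <- df |>
    dplyr::group_by(.data$scenario) |>
    dplyr::slice_min(.data$variance, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$n_s, y = .data$variance)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_d), shape = 21,
                        fill = "white") +
    ggplot2::geom_point(data = best, colour = "red", size = 2) +
    ggplot2::scale_size_continuous(name = expression(n[d])) +
    ggplot2::labs(x = "subjects", y = "variance of the mean",
                  title = "Budget-saturating designs by subject count")
  if (dplyr::n_distinct(df$scenario) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$scenario),
                                 scales = "free")
  }
  p
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
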