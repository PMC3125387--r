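# The reference study: a 3 x 3 x 5 x 5 grid of scenarios in which the
# variance triples and the unit-cost triples are the same three sets, and
# both sum to 22, so that measuring one subject on one occasion always
# costs 22 and always leaves a mean-exposure variance of 22.

grid_triples <- list(
  c(2, 10, 10),
  c(11, 5.5, 5.5),
  c(20, 1, 1)
)

grid_exponents <- c(0.50, 0.75, 1.00, 1.25, 1.50)

triple_label <- function(x) paste0("(", paste(as.character(x), collapse = ", "), ")")

#' The 225-scenario reference grid
#'
#' Crosses three variance-component triples (2, 10, 10), (11, 5.5, 5.5) and
#' (20, 1, 1) — large, medium and small between-subjects to within-subject
#' variance ratios — with the same three triples used as unit costs, and
#' with subject/occasion cost exponents `alpha, beta` in
#' \{0.50, 0.75, 1.00, 1.25, 1.50\}. Every scenario's cost and variance at
#' the minimal design (1, 1) equal 22.
#'
#' Row order follows the reference layout: variance triple, then cost
#' triple, then `beta` down the rows, then `alpha` across.
#'
#' @param budget Budget per scenario (default 500; must exceed 22 or no
#'   scenario is feasible).
#' @return A 225-row scenario tibble with label columns `variance_set` and
#'   `cost_set` in addition to the [scenario_tbl()] columns.
#' @export
scenario_grid <- function(budget = 500) {
  if (budget <= 22) {
    stop("budget must exceed 22, the cost of a single observation",
         call. = FALSE)
  }
  layout <- tidyr_free_grid()
  df <- scenario_tbl(
    s2_bs = layout$v1, s2_bd = layout$v2, s2_mu_wd = layout$v3,
    pi_s = layout$c1, pi_d = layout$c2, c_q = layout$c3,
    alpha = layout$alpha, beta = layout$beta, budget = budget
  )
  dplyr::mutate(df,
                variance_set = layout$variance_set,
                cost_set = layout$cost_set,
                .before = 1)
}

# expand.grid in the reference's reading order without a tidyr dependency
tidyr_free_grid <- function() {
  rows <- list()
  for (v in grid_triples) {
    for (cs in grid_triples) {
      for (b in grid_exponents) {
        for (a in grid_exponents) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            variance_set = triple_label(v), cost_set = triple_label(cs),
            v1 = v[1], v2 = v[2], v3 = v[3],
            c1 = cs[1], c2 = cs[2], c3 = cs[3],
            alpha = a, beta = b
          )
        }
      }
    }
  }
  purrr::list_rbind(rows)
}

#' Summarize a table of optimized designs
#'
#' @param results An optimized grid, as returned by [optimize_design()]
#'   (typically on [scenario_grid()]).
#' @return A one-row tibble: budget, median and 5th/95th percentile budget
#'   utilization (linear interpolation between order statistics,
#'   `stats::quantile()` type 7), and the number of scenarios whose optimum
#'   uses a single occasion per subject.
#' @export
grid_summary <- function(results) {
  stopifnot(all(c("utilization_pct", "n_d", "budget") %in% names(results)))
  q <- stats::quantile(results$utilization_pct, c(0.05, 0.5, 0.95),
                       type = 7, names = FALSE)
  tibble::tibble(
    budget = unique(results$budget)[1],
    n_scenarios = nrow(results),
    median_utilization_pct = q[2],
    p5_utilization_pct = q[1],
    p95_utilization_pct = q[3],
    n_single_occasion = sum(results$n_d == 1),
    percentile_convention = "linear interpolation (quantile type 7)"
  )
}

#' Reference grid at two budgets
#'
#' Optimizes the 225-scenario grid at two budgets and reports how optima
#' move between the single-occasion boundary and multi-occasion designs as
#' money becomes available. Because the designs are integers, a larger
#' budget occasionally pushes an optimum *away* from the single-occasion
#' boundary ("reversed" scenarios).
#'
#' @param budget1,budget2 The two budgets (defaults 500 and 1000).
#' @return A list with `summary1`, `summary2` (see [grid_summary()]),
#'   `n_gained` (scenarios with `n_d > 1` at `budget1` but `n_d = 1` at
#'   `budget2`), `n_reversed` (the opposite move), and the two result
#'   tables `results1`, `results2`.
#' @export
compare_budgets <- function(budget1 = 500, budget2 = 1000) {
  r1 <- optimize_design(scenario_grid(budget1))
  r2 <- optimize_design(scenario_grid(budget2))
  list(
    summary1 = grid_summary(r1),
    summary2 = grid_summary(r2),
    n_gained = sum(r1$n_d > 1 & r2$n_d == 1),
    n_reversed = sum(r1$n_d == 1 & r2$n_d > 1),
    results1 = r1,
    results2 = r2
  )
}

#' Deterministic random scenarios for property testing
#'
#' Draws variance components and unit costs log-uniformly on (0.1, 50),
#' exponents uniformly on (0.3, 2.5), and sets the budget to the cost of a
#' randomly chosen subject-boundary design so that between 1 and 80
#' subjects are affordable. Scenarios whose occasion boundary at a single
#' subject exceeds 800 are redrawn, keeping exhaustive cross-checks cheap.
#' The same seed always yields the same scenarios.
#'
#' @param n Number of scenarios.
#' @param seed Integer seed.
#' @return A scenario tibble with `n` rows.
#' @export
random_scenarios <- function(n, seed) {
  stopifnot(n >= 1)
  withr::with_seed(seed, {
    draw_one <- function() {
      repeat {
        lu <- function(k) exp(stats::runif(k, log(0.1), log(50)))
        v <- lu(3); cst <- lu(3)
        ab <- stats::runif(2, 0.3, 2.5)
        ns_target <- sample(1:80, 1)
        budget <- cst[1] * ns_target^ab[1] + ns_target * (cst[2] + cst[3])
        df <- scenario_tbl(v[1], v[2], v[3], cst[1], cst[2], cst[3],
                           ab[1], ab[2], budget)
        if (max_occasions_one(1L, df) <= 800) return(df)
      }
    }
    purrr::map(seq_len(n), function(i) draw_one()) |> purrr::list_rbind()
  })
}

#' Write optimized results or profiles to disk
#'
#' @param x A tibble (results, profile or summary).
#' @param path Output file; format chosen by extension `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    readr::write_csv(tibble::as_tibble(x), path)
  } else if (ext == "json") {
    jsonlite::write_json(tibble::as_tibble(x), path, digits = NA, pretty = TRUE)
  } else {
    stop("unsupported output format: .", ext, " (use .csv or .json)",
         call. = FALSE)
  }
  invisible(path)
}
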