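#' Mean-of-means estimate of a balanced nested exposure data set
#'
#' Averages quanta within each occasion, then occasions within each
#' subject, then subjects. For balanced data this equals the grand mean;
#' unbalanced (ragged) input is not supported and raises an error.
#'
#' @param x Either a 3-dimensional array with dimensions
#'   `n_s x n_d x n_q`, or a nested list: one element per subject, each a
#'   list of occasions, each a numeric vector of quanta.
#' @return The estimated group mean exposure (a single number).
#' @examples
#' balanced_mean(array(c(1, 5, 3, 7), dim = c(2, 1, 2)))  # 4
#' @export
balanced_mean <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) {
    if (any(dim(x) < 1)) stop("all dimensions must be >= 1", call. = FALSE)
    if (anyNA(x)) stop("missing values imply unbalanced data, which is unsupported",
                       call. = FALSE)
    within_occ <- apply(x, c(1, 2), mean)   # over quanta
    per_subject <- rowMeans(within_occ)     # over occasions
    return(mean(per_subject))               # over subjects
  }
  if (is.list(x)) {
    if (length(x) < 1) stop("need at least one subject", call. = FALSE)
    n_d <- lengths(x)
    if (length(unique(n_d)) != 1 || any(n_d < 1)) {
      stop("unbalanced data (unequal occasions per subject) is unsupported",
           call. = FALSE)
    }
    n_q <- unlist(lapply(x, lengths))
    if (length(unique(n_q)) != 1 || any(n_q < 1)) {
      stop("unbalanced data (unequal quanta per occasion) is unsupported",
           call. = FALSE)
    }
    per_subject <- vapply(
      x, function(subj) mean(vapply(subj, mean, numeric(1))), numeric(1)
    )
    return(mean(per_subject))
  }
  stop("x must be a 3-d array or a nested list (subjects / occasions / quanta)",
       call. = FALSE)
}

#' Variance of the estimated group mean exposure
#'
#' Two-stage form of the objective function:
#' `s2_bs / n_s + (s2_bd + s2_mu_wd) / (n_s * n_d)`. All arguments are
#' recycled, so the function evaluates whole design grids at once.
#'
#' @param n_s Number of subjects (integer >= 1).
#' @param n_d Occasions per subject (integer >= 1).
#' @inheritParams scenario_tbl
#' @return Variance of the mean exposure estimate (exposure units squared).
#' @seealso [mean_variance3()] for the three-stage form.
#' @examples
#' mean_variance(22, 1, s2_bs = 2, s2_bd = 10, s2_mu_wd = 10)  # 1
#' @export
mean_variance <- function(n_s, n_d, s2_bs, s2_bd, s2_mu_wd) {
  check_alloc(n_s, n_d)
  s2_bs / n_s + (s2_bd + s2_mu_wd) / (n_s * n_d)
}

#' Three-stage variance of the estimated group mean exposure
#'
#' `s2_bs/n_s + s2_bd/(n_s*n_d) + s2_q/(n_s*n_d*n_q)`.
#'
#' @inheritParams mean_variance
#' @param n_q Quanta per occasion (integer >= 1).
#' @param s2_q Between-quanta-within-occasion variance.
#' @return Variance of the mean exposure estimate.
#' @export
mean_variance3 <- function(n_s, n_d, n_q, s2_bs, s2_bd, s2_q) {
  check_alloc(n_s, n_d, n_q)
  s2_bs / n_s + s2_bd / (n_s * n_d) + s2_q / (n_s * n_d * n_q)
}

#' Power-law cost of a two-stage design
#'
#' `pi_s * n_s^alpha + n_s * pi_d * n_d^beta + n_s * n_d * c_q`. With
#' `alpha = beta = 1` this is the classical linear cost model; exponents
#' above (below) 1 describe increasing (decreasing) marginal costs.
#'
#' @inheritParams mean_variance
#' @inheritParams scenario_tbl
#' @return Total variable cost (money).
#' @examples
#' design_cost(22, 1, pi_s = 2, pi_d = 10, c_q = 10, alpha = 1, beta = 1)
#' @export
design_cost <- function(n_s, n_d, pi_s, pi_d, c_q, alpha = 1, beta = 1) {
  check_alloc(n_s, n_d)
  pi_s * n_s^alpha + n_s * pi_d * n_d^beta + n_s * n_d * c_q
}

#' Power-law cost of a three-stage design
#'
#' `pi_s*n_s^alpha + n_s*pi_d*n_d^beta + n_s*n_d*pi_q*n_q^gamma`.
#'
#' @inheritParams design_cost
#' @param n_q Quanta per occasion (integer >= 1).
#' @param pi_q Unit cost of one quantum.
#' @param gamma Power exponent of the quantum cost stage.
#' @return Total variable cost (money).
#' @export
design_cost3 <- function(n_s, n_d, n_q, pi_s, pi_d, pi_q,
                         alpha = 1, beta = 1, gamma = 1) {
  check_alloc(n_s, n_d, n_q)
  pi_s * n_s^alpha + n_s * pi_d * n_d^beta + n_s * n_d * pi_q * n_q^gamma
}

#' Budget utilization of an allocation
#'
#' @param cost Cost of the allocation, e.g. from [design_cost()].
#' @param budget The available budget.
#' @return `100 * cost / budget` (percent). Costs beyond the budget
#'   (tolerance absorbed) raise an error: the allocation is infeasible.
#' @export
utilization <- function(cost, budget) {
  if (any(cost > budget_limit(budget))) {
    stop("infeasible allocation: cost exceeds the budget", call. = FALSE)
  }
  100 * cost / budget
}

#' Evaluate designs against scenarios
#'
#' Adds variance, cost, utilization and feasibility of the allocation
#' `(n_s, n_d)` to each scenario row. The data-frame-first companion of
#' [mean_variance()] and [design_cost()].
#'
#' @param scenarios A scenario tibble, see [scenario_tbl()].
#' @param n_s,n_d Allocation to evaluate; recycled along the rows.
#' @return The scenario tibble with columns `n_s`, `n_d`, `variance`,
#'   `cost`, `utilization_pct` (NA where infeasible) and `feasible`.
#' @examples
#' scenario_tbl(2, 10, 10, 20, 1, 1, budget = 500) |>
#'   evaluate_design(n_s = 13, n_d = 9)
#' @export
evaluate_design <- function(scenarios, n_s, n_d) {
  df <- validate_scenarios(scenarios)
  df$n_s <- as.integer(rep_len(n_s, nrow(df)))
  df$n_d <- as.integer(rep_len(n_d, nrow(df)))
  df$variance <- mean_variance(df$n_s, df$n_d, df$s2_bs, df$s2_bd, df$s2_mu_wd)
  df$cost <- design_cost(df$n_s, df$n_d, df$pi_s, df$pi_d, df$c_q,
                         df$alpha, df$beta)
  df$feasible <- df$cost <= budget_limit(df$budget)
  df$utilization_pct <- ifelse(df$feasible, 100 * df$cost / df$budget, NA_real_)
  df
}

check_alloc <- function(n_s, n_d, n_q = NULL) {
  bad <- function(n) any(n < 1 | n != floor(n))
  if (bad(n_s) || bad(n_d) || (!is.null(n_q) && bad(n_q))) {
    stop("allocation counts must be integers >= 1", call. = FALSE)
  }
  invisible(TRUE)
}
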