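#' Build a tibble of exposure-design scenarios
#'
#' A scenario bundles everything the optimizer needs: the variance
#' components of the two-stage exposure model, the unit costs and power
#' exponents of the cost function, and the budget. All arguments are
#' recycled to a common length, so a single call can describe a whole
#' parameter sweep.
#'
#' The two-stage model works with `s2_mu_wd`, the variance of the exposure
#' estimate obtained at one measurement occasion. If raw three-stage
#' parameters are available (within-occasion variance `s2_q`, quantum unit
#' cost `pi_q`, exponent `gamma`, and a fixed number of quanta `n_q`), use
#' [reduce_stages()] to fold them into `s2_mu_wd` and `c_q` first.
#'
#' @param s2_bs Between-subjects variance (exposure units squared).
#' @param s2_bd Between-occasions-within-subject variance.
#' @param s2_mu_wd Variance of a single-occasion exposure estimate
#'   (`s2_q / n_q` in three-stage terms).
#' @param pi_s Unit cost of recruiting one subject.
#' @param pi_d Unit cost of setting up one measurement occasion.
#' @param c_q Cost of collecting the within-occasion data for one occasion
#'   (`pi_q * n_q^gamma` in three-stage terms).
#' @param alpha,beta Power exponents of the subject and occasion cost
#'   stages; 1 means constant marginal cost, above 1 increasing, below 1
#'   decreasing.
#' @param budget Variable-cost budget (fixed costs already deducted).
#'
#' @return A tibble with one row per scenario and columns named as the
#'   arguments.
#' @examples
#' scenario_tbl(s2_bs = 2, s2_bd = 10, s2_mu_wd = 10,
#'              pi_s = 20, pi_d = 1, c_q = 1,
#'              alpha = 1.5, beta = 1.5, budget = 500)
#' @export
scenario_tbl <- function(s2_bs, s2_bd, s2_mu_wd, pi_s, pi_d, c_q,
                         alpha = 1, beta = 1, budget) {
  df <- tibble::tibble(
    s2_bs = as.numeric(s2_bs), s2_bd = as.numeric(s2_bd),
    s2_mu_wd = as.numeric(s2_mu_wd),
    pi_s = as.numeric(pi_s), pi_d = as.numeric(pi_d), c_q = as.numeric(c_q),
    alpha = as.numeric(alpha), beta = as.numeric(beta),
    budget = as.numeric(budget)
  )
  validate_scenarios(df)
}

scenario_cols <- c("s2_bs", "s2_bd", "s2_mu_wd", "pi_s", "pi_d", "c_q",
                   "alpha", "beta", "budget")

#' Validate a scenario tibble
#'
#' Checks the invariants every optimizer in the package relies on:
#' non-negative variance components with a positive total, non-negative
#' unit costs with a positive total, strictly positive exponents, and a
#' positive budget.
#'
#' @param scenarios A data frame with the columns of [scenario_tbl()].
#' @return The input as a tibble, invisibly unchanged, or an error naming
#'   the offending column.
#' @export
validate_scenarios <- function(scenarios) {
  stopifnot(is.data.frame(scenarios))
  missing <- setdiff(scenario_cols, names(scenarios))
  if (length(missing) > 0) {
    stop("scenario table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(scenarios)
  chk <- function(ok, what) {
    if (!all(ok)) {
      stop("invalid scenario(s) at row(s) ",
           paste(utils::head(which(!ok), 5), collapse = ", "),
           ": ", what, call. = FALSE)
    }
  }
  for (v in scenario_cols) chk(is.finite(df[[v]]), paste(v, "must be finite"))
  chk(df$s2_bs >= 0 & df$s2_bd >= 0 & df$s2_mu_wd >= 0,
      "variance components must be >= 0")
  chk(df$s2_bs + df$s2_bd + df$s2_mu_wd > 0,
      "total exposure variance must be > 0")
  chk(df$pi_s >= 0 & df$pi_d >= 0 & df$c_q >= 0, "unit costs must be >= 0")
  chk(df$pi_s + df$pi_d + df$c_q > 0, "total unit cost must be > 0")
  chk(df$alpha > 0 & df$beta > 0, "alpha and beta must be > 0")
  chk(df$budget > 0, "budget must be > 0")
  df
}

#' Fold a three-stage design problem into its two-stage form
#'
#' With a fixed number of quanta per occasion the three-stage problem
#' reduces exactly to a two-stage one: the single-occasion estimate has
#' variance `s2_mu_wd = s2_q / n_q`, and the within-occasion data cost a
#' fixed `c_q = pi_q * n_q^gamma` per occasion. Variance and cost of every
#' allocation are preserved by the reduction.
#'
#' @param scenarios A data frame with three-stage columns `s2_bs`, `s2_bd`,
#'   `s2_q`, `pi_s`, `pi_d`, `pi_q`, `alpha`, `beta`, `gamma`, `budget`.
#' @param n_q Number of quanta per occasion (integer, >= 1); recycled.
#'
#' @return A validated two-stage scenario tibble; the three-stage columns
#'   `s2_q`, `pi_q`, `gamma` and the chosen `n_q` are retained for
#'   reference.
#' @examples
#' three <- tibble::tibble(s2_bs = 2, s2_bd = 10, s2_q = 40,
#'                         pi_s = 20, pi_d = 1, pi_q = 2.5,
#'                         alpha = 1, beta = 1, gamma = 1, budget = 500)
#' reduce_stages(three, n_q = 4)   # s2_mu_wd = 10, c_q = 10
#' @export
reduce_stages <- function(scenarios, n_q = 1) {
  stopifnot(is.data.frame(scenarios))
  need <- c("s2_bs", "s2_bd", "s2_q", "pi_s", "pi_d", "pi_q",
            "alpha", "beta", "gamma", "budget")
  missing <- setdiff(need, names(scenarios))
  if (length(missing) > 0) {
    stop("three-stage table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(n_q < 1 | n_q != floor(n_q))) {
    stop("n_q must be an integer >= 1", call. = FALSE)
  }
  out <- tibble::as_tibble(scenarios)
  out$n_q <- as.integer(rep_len(n_q, nrow(out)))
  out$s2_mu_wd <- out$s2_q / out$n_q
  out$c_q <- out$pi_q * out$n_q^out$gamma
  validate_scenarios(out)
}
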