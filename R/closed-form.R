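# Analytic screening for the linear and semi-linear cost cases. Throughout,
# W = s2_bd + s2_mu_wd (within-subject variance seen by the two-stage model)
# and P = pi_d + c_q (full marginal cost of one more occasion when beta = 1).
# These rules govern the continuous relaxation; the integer optimum is always
# confirmed by enumeration (see optimize_design).

require_exponents <- function(df, alpha = NULL, beta = NULL, what) {
  if (!is.null(alpha) && any(df$alpha != alpha)) {
    stop(what, " requires alpha = ", alpha, call. = FALSE)
  }
  if (!is.null(beta) && any(df$beta != beta)) {
    stop(what, " requires beta = ", beta, call. = FALSE)
  }
  invisible(TRUE)
}

#' Linear-cost condition for the single-subject boundary
#'
#' With linear costs (`alpha = beta = 1`) the substituted one-variable
#' objective `f(n_s) = s2_bs/n_s + W*P/(budget - pi_s*n_s)` has a positive
#' derivative at `n_s = 1` exactly when
#' `s2_bs * (budget - pi_s)^2 < W * P * pi_s`. If true, the continuous
#' optimum is one subject measured on `(budget - pi_s)/P` occasions.
#'
#' @param scenarios A scenario tibble with `alpha = beta = 1` rows.
#' @return Logical vector, one element per scenario.
#' @export
case_a_lower_condition <- function(scenarios) {
  df <- validate_scenarios(scenarios)
  require_exponents(df, 1, 1, "case_a_lower_condition")
  W <- df$s2_bd + df$s2_mu_wd
  P <- df$pi_d + df$c_q
  df$s2_bs * (df$budget - df$pi_s)^2 < W * P * df$pi_s
}

#' Linear-cost condition for the maximal-subjects boundary
#'
#' With linear costs the optimum is `n_d = 1` with as many subjects as the
#' budget buys if and only if `s2_bs * P >= pi_s * W`. The condition does
#' not involve the budget. The knife-edge equality counts as
#' boundary-optimal: the reference study contains a scenario sitting
#' exactly on it whose printed optimum is the boundary design.
#'
#' @inheritParams case_a_lower_condition
#' @return Logical vector, one element per scenario.
#' @export
case_a_upper_condition <- function(scenarios) {
  df <- validate_scenarios(scenarios)
  require_exponents(df, 1, 1, "case_a_upper_condition")
  W <- df$s2_bd + df$s2_mu_wd
  P <- df$pi_d + df$c_q
  df$s2_bs * P >= df$pi_s * W
}

#' Closed-form interior optimum for linear costs
#'
#' Setting the derivative of the substituted objective to zero gives
#' `n_s_star = budget / (pi_s + sqrt(pi_s * P * W / s2_bs))` and
#' `n_d_star = sqrt(pi_s * W / (P * s2_bs))`. The pair satisfies the budget
#' with equality, and `n_d_star` does not depend on the budget. Both are
#' generally non-integer; use [optimize_design()] for the integer optimum.
#'
#' @inheritParams case_a_lower_condition
#' @return A tibble with columns `n_s_star`, `n_d_star`, `locus` ("I1") and
#'   `case` ("A").
#' @export
case_a_interior <- function(scenarios) {
  df <- validate_scenarios(scenarios)
  require_exponents(df, 1, 1, "case_a_interior")
  if (any(df$s2_bs == 0 | df$pi_s == 0)) {
    stop("s2_bs = 0 or pi_s = 0 has no interior optimum; ",
         "use the boundary conditions", call. = FALSE)
  }
  W <- df$s2_bd + df$s2_mu_wd
  P <- df$pi_d + df$c_q
  tibble::tibble(
    n_s_star = df$budget / (df$pi_s + sqrt(df$pi_s * P * W / df$s2_bs)),
    n_d_star = sqrt(df$pi_s * W / (P * df$s2_bs)),
    locus = "I1",
    case = "A"
  )
}

# One-variable objective and derivative for alpha = 1, beta != 1, in n_d:
# f(n_d) = (s2_bs + W/n_d) * (pi_s + pi_d*n_d^beta + c_q*n_d) / budget
case_b_objective <- function(n_d, df) {
  W <- df$s2_bd + df$s2_mu_wd
  (df$s2_bs + W / n_d) *
    (df$pi_s + df$pi_d * n_d^df$beta + df$c_q * n_d) / df$budget
}

case_b_derivative <- function(n_d, df) {
  W <- df$s2_bd + df$s2_mu_wd
  (-W / n_d^2 * (df$pi_s + df$pi_d * n_d^df$beta + df$c_q * n_d) +
     (df$s2_bs + W / n_d) *
       (df$beta * df$pi_d * n_d^(df$beta - 1) + df$c_q)) / df$budget
}

#' Single-occasion boundary condition when only occasion costs are non-linear
#'
#' For `alpha = 1` the substituted objective in `n_d` has a positive
#' derivative at `n_d = 1` exactly when
#' `s2_bs * (beta*pi_d + c_q) + W * beta * pi_d > W * (pi_s + pi_d)`.
#' If true, the optimum is one occasion per subject with
#' `floor(budget / (pi_s + pi_d + c_q))` subjects. At `beta = 1` the rule
#' reduces to the linear-cost maximal-subjects condition.
#'
#' @param scenarios A scenario tibble with `alpha = 1` rows.
#' @return Logical vector, one element per scenario.
#' @export
case_b_lower_condition <- function(scenarios) {
  df <- validate_scenarios(scenarios)
  require_exponents(df, alpha = 1, what = "case_b_lower_condition")
  W <- df$s2_bd + df$s2_mu_wd
  df$s2_bs * (df$beta * df$pi_d + df$c_q) + W * df$beta * df$pi_d >=
    W * (df$pi_s + df$pi_d)
}

#' Convexity of the occasion-substituted objective
#'
#' The one-variable objective in `n_d` is always convex for `beta >= 2`.
#' For other exponents convexity over the given integer range is decided
#' numerically by the sign of the second differences
#' `f(n-1) - 2 f(n) + f(n+1)`, with a relative tolerance of `1e-9` so that
#' floating-point noise is not mistaken for concavity.
#'
#' @param scenarios A single-row scenario tibble with `alpha = 1`.
#' @param nd_range Integer range `c(lo, hi)` of occasion counts to inspect
#'   (usually `c(1, nd_max)`).
#' @return `TRUE` if the objective is convex on the range.
#' @export
case_b_convex <- function(scenarios, nd_range) {
  df <- validate_scenarios(scenarios)
  stopifnot(nrow(df) == 1)
  require_exponents(df, alpha = 1, what = "case_b_convex")
  convex_on_range(function(n) case_b_objective(n, df), nd_range,
                  analytic = df$beta >= 2)
}

convex_on_range <- function(f, range, analytic = FALSE) {
  lo <- as.integer(range[1]); hi <- as.integer(range[2])
  if (hi < lo) stop("empty range", call. = FALSE)
  if (analytic) return(TRUE)
  if (hi - lo < 2) return(TRUE)  # too short to bend
  n <- (lo + 1):(hi - 1)
  d2 <- f(n - 1) - 2 * f(n) + f(n + 1)
  all(d2 >= -1e-9 * abs(f(n)))
}

# One-variable objective and derivative for beta = 1, alpha != 1, in n_s:
# f(n_s) = s2_bs/n_s + W*P / (budget - pi_s*n_s^alpha)
case_c_objective <- function(n_s, df) {
  W <- df$s2_bd + df$s2_mu_wd
  P <- df$pi_d + df$c_q
  df$s2_bs / n_s + W * P / (df$budget - df$pi_s * n_s^df$alpha)
}

case_c_derivative <- function(n_s, df) {
  W <- df$s2_bd + df$s2_mu_wd
  P <- df$pi_d + df$c_q
  -df$s2_bs / n_s^2 +
    W * P * df$pi_s * df$alpha * n_s^(df$alpha - 1) /
      (df$budget - df$pi_s * n_s^df$alpha)^2
}

#' Single-subject boundary condition when only subject costs are non-linear
#'
#' For `beta = 1` the substituted objective in `n_s` has a positive
#' derivative at `n_s = 1` exactly when
#' `s2_bs * (budget - pi_s)^2 < W * P * pi_s * alpha`. If true the optimum
#' is one subject with `floor((budget - pi_s) / P)` occasions. At
#' `alpha = 1` the rule reduces to the linear-cost single-subject
#' condition.
#'
#' @param scenarios A scenario tibble with `beta = 1` rows.
#' @return Logical vector, one element per scenario.
#' @export
case_c_lower_condition <- function(scenarios) {
  df <- validate_scenarios(scenarios)
  require_exponents(df, beta = 1, what = "case_c_lower_condition")
  W <- df$s2_bd + df$s2_mu_wd
  P <- df$pi_d + df$c_q
  df$s2_bs * (df$budget - df$pi_s)^2 < W * P * df$pi_s * df$alpha
}

#' Classify where the optimum of the one-variable objective sits
#'
#' Maps the boundary-derivative signs and the convexity of the substituted
#' objective to the four solution loci: `E1` (lower boundary), `E2` (upper
#' boundary), `I1` (interior minimum of a convex objective), `I2` (concave
#' objective, optimum at whichever boundary wins the comparison).
#'
#' @param lower Logical: derivative positive at the lower boundary (the
#'   lower-boundary condition holds).
#' @param upper Logical: derivative negative at the upper boundary.
#' @param convex Logical: objective convex over the choice set.
#' @return Character vector of locus labels.
#' @export
classify_locus <- function(lower, upper, convex = TRUE) {
  n <- max(length(lower), length(upper), length(convex))
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  convex <- rep_len(convex, n)
  dplyr::case_when(
    !convex ~ "I2",
    lower   ~ "E1",
    upper   ~ "E2",
    TRUE    ~ "I1"
  )
}
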