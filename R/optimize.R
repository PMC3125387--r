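# Integer search machinery. Costs are strictly increasing in n_d (when
# pi_d + c_q > 0) and in n_s, and the variance is non-increasing in n_d for
# fixed n_s, so only budget-saturating pairs (n_s, nd_max(n_s)) need to be
# scanned. Searches use doubling plus bisection on exact integer arguments;
# no continuous root-finding is involved.

SAFETY_CAP <- 1e7  # candidate evaluations per scenario

cost_one <- function(n_s, n_d, df) {
  df$pi_s * n_s^df$alpha + n_s * df$pi_d * n_d^df$beta + n_s * n_d * df$c_q
}

var_one <- function(n_s, n_d, df) {
  df$s2_bs / n_s + (df$s2_bd + df$s2_mu_wd) / (n_s * n_d)
}

# largest integer n with f(n) <= lim, given f(1) <= lim and f increasing
grow_and_bisect <- function(f, lim) {
  hi <- 1L
  while (f(hi * 2L) <= lim) {
    hi <- hi * 2L
    if (hi > SAFETY_CAP) {
      stop("search exceeded the safety cap of ", format(SAFETY_CAP, scientific = FALSE),
           " candidates", call. = FALSE)
    }
  }
  lo <- hi; hi <- hi * 2L
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (f(mid) <= lim) lo <- mid else hi <- mid
  }
  lo
}

max_occasions_one <- function(n_s, df) {
  lim <- budget_limit(df$budget)
  f <- function(n_d) cost_one(n_s, n_d, df)
  if (f(1L) > lim) return(NA_integer_)
  if (df$pi_d + df$c_q <= 0) {
    stop("occasions are free (pi_d + c_q = 0); the occasion count is unbounded",
         call. = FALSE)
  }
  if (df$beta == 1) {
    # closed form, then a float-safety nudge in both directions
    n <- max(1, floor((lim - df$pi_s * n_s^df$alpha) / (n_s * (df$pi_d + df$c_q))))
    while (f(n + 1) <= lim) n <- n + 1
    while (n > 1 && f(n) > lim) n <- n - 1
    return(as.integer(n))
  }
  as.integer(grow_and_bisect(f, lim))
}

max_subjects_one <- function(df) {
  lim <- budget_limit(df$budget)
  f <- function(n_s) cost_one(n_s, 1L, df)
  if (f(1L) > lim) {
    stop("budget insufficient for a single observation", call. = FALSE)
  }
  if (df$alpha == 1) {
    n <- max(1, floor(lim / (df$pi_s + df$pi_d + df$c_q)))
    while (f(n + 1) <= lim) n <- n + 1
    while (n > 1 && f(n) > lim) n <- n - 1
    return(as.integer(n))
  }
  as.integer(grow_and_bisect(f, lim))
}

#' Largest affordable number of occasions for a given subject count
#'
#' @param scenarios A scenario tibble; rows are recycled against `n_s`.
#' @param n_s Subject count(s) to probe.
#' @return Integer vector: the largest `n_d >= 1` whose design cost stays
#'   within the budget, or `NA` when even a single occasion is unaffordable
#'   at that subject count.
#' @examples
#' scn <- scenario_tbl(2, 10, 10, 20, 1, 1, alpha = 1.5, beta = 1.5, budget = 500)
#' max_occasions(scn, n_s = 5)  # 12
#' @export
max_occasions <- function(scenarios, n_s) {
  df <- validate_scenarios(scenarios)
  n <- max(nrow(df), length(n_s))
  idx <- rep_len(seq_len(nrow(df)), n)
  n_s <- rep_len(as.integer(n_s), n)
  check_alloc(n_s, 1L)
  vapply(seq_len(n), function(i) max_occasions_one(n_s[i], df[idx[i], ]),
         integer(1))
}

#' Largest affordable number of subjects (at one occasion each)
#'
#' @param scenarios A scenario tibble.
#' @return Integer vector: the largest `n_s` with the cost of `(n_s, 1)`
#'   within the budget. Errors if not even `(1, 1)` is affordable.
#' @examples
#' max_subjects(scenario_tbl(20, 1, 1, 20, 1, 1, alpha = 0.5, budget = 500))  # 134
#' @export
max_subjects <- function(scenarios) {
  df <- validate_scenarios(scenarios)
  vapply(seq_len(nrow(df)), function(i) max_subjects_one(df[i, ]), integer(1))
}

# strictly-better comparison with the documented tie-break:
# ties in variance (1e-12 relative) prefer more subjects, then lower cost
better_than <- function(v, n_s, cost, best) {
  if (is.null(best)) return(TRUE)
  tol <- TIE_TOL * max(abs(best$variance), .Machine$double.xmin)
  if (v < best$variance - tol) return(TRUE)
  if (abs(v - best$variance) <= tol) {
    if (n_s > best$n_s) return(TRUE)
    if (n_s == best$n_s && cost < best$cost) return(TRUE)
  }
  FALSE
}

profile_one <- function(df) {
  ns_top <- max_subjects_one(df)
  if (ns_top > SAFETY_CAP) {
    stop("search exceeded the safety cap of ",
         format(SAFETY_CAP, scientific = FALSE), " candidates", call. = FALSE)
  }
  n_s <- seq_len(ns_top)
  n_d <- vapply(n_s, function(s) max_occasions_one(s, df), integer(1))
  keep <- !is.na(n_d)
  n_s <- n_s[keep]; n_d <- n_d[keep]
  if (df$s2_bd + df$s2_mu_wd == 0) n_d[] <- 1L  # occasions add nothing
  tibble::tibble(
    n_s = n_s, n_d = n_d,
    cost = cost_one(n_s, n_d, df),
    variance = var_one(n_s, n_d, df),
    utilization_pct = 100 * cost_one(n_s, n_d, df) / df$budget
  )
}

pick_best <- function(profile) {
  best <- NULL
  for (i in seq_len(nrow(profile))) {
    if (better_than(profile$variance[i], profile$n_s[i], profile$cost[i], best)) {
      best <- list(n_s = profile$n_s[i], n_d = profile$n_d[i],
                   variance = profile$variance[i], cost = profile$cost[i])
    }
  }
  best
}

enumerate_one <- function(df) {
  best <- pick_best(profile_one(df))
  best$method <- "enumeration"
  best
}

refine_one <- function(n_s_star, n_d_star, df) {
  # The continuous optimum can sit far from the integer one, so the
  # neighborhood is every budget-saturating candidate from just below
  # floor(n_s_star) up to the subject boundary, plus the four rounded
  # corners of (n_s_star, n_d_star).
  ns_top <- max_subjects_one(df)
  lo <- max(1L, as.integer(floor(n_s_star)) - 1L)
  cand_s <- lo:ns_top
  cand_d <- vapply(cand_s, function(s) max_occasions_one(s, df), integer(1))
  corners_s <- as.integer(c(floor(n_s_star), ceiling(n_s_star)))
  corners_d <- as.integer(c(floor(n_d_star), ceiling(n_d_star)))
  extra <- expand.grid(n_s = pmax(corners_s, 1L), n_d = pmax(corners_d, 1L))
  all_s <- c(cand_s, extra$n_s)
  all_d <- c(cand_d, extra$n_d)
  keep <- !is.na(all_d) &
    cost_one(all_s, all_d, df) <= budget_limit(df$budget)
  all_s <- all_s[keep]; all_d <- all_d[keep]
  if (length(all_s) == 0) return(enumerate_one(df))
  prof <- tibble::tibble(
    n_s = all_s, n_d = all_d,
    cost = cost_one(all_s, all_d, df),
    variance = var_one(all_s, all_d, df)
  )
  best <- pick_best(prof)
  best$method <- "closed_form_refined"
  best
}

dispatch_case <- function(alpha, beta) {
  dplyr::case_when(
    alpha == 1 & beta == 1 ~ "A",
    alpha == 1             ~ "B",
    beta == 1              ~ "C",
    TRUE                   ~ "D"
  )
}

optimize_one <- function(df) {
  lim <- budget_limit(df$budget)
  if (cost_one(1L, 1L, df) > lim) {
    stop("budget insufficient for a single observation", call. = FALSE)
  }
  case <- dispatch_case(df$alpha, df$beta)
  W <- df$s2_bd + df$s2_mu_wd

  # enumeration over budget-saturating pairs is the authority
  authoritative <- enumerate_one(df)
  res <- authoritative

  if (case == "A" && df$s2_bs > 0 && df$pi_s > 0 && W > 0) {
    lower <- case_a_lower_condition(df)
    upper <- case_a_upper_condition(df)
    locus <- classify_locus(lower, upper, convex = TRUE)
    if (locus == "I1") {
      cont <- case_a_interior(df)
      refined <- refine_one(cont$n_s_star, cont$n_d_star, df)
      if (abs(refined$variance - authoritative$variance) <=
          TIE_TOL * abs(authoritative$variance)) {
        res <- refined
      }
    } else {
      res$method <- "boundary"
    }
  } else if (case == "B") {
    nd_top <- max_occasions_one(1L, df)
    convex <- case_b_convex(df, c(1L, nd_top))
    lower <- case_b_lower_condition(df)
    upper <- nd_top > 1 && case_b_derivative(nd_top, df) < 0
    locus <- classify_locus(lower, upper, convex)
    if (locus %in% c("E1", "E2")) res$method <- "boundary"
  } else if (case == "C") {
    ns_top <- max_subjects_one(df)
    convex <- convex_on_range(function(n) case_c_objective(n, df),
                              c(1L, ns_top))
    lower <- case_c_lower_condition(df)
    upper <- ns_top > 1 && case_c_derivative(ns_top, df) < 0
    locus <- classify_locus(lower, upper, convex)
    if (locus %in% c("E1", "E2")) res$method <- "boundary"
  } else {
    # Case A degenerate corners fall through to here as pure enumeration.
    # No substituted one-variable objective exists in case D; read the
    # locus off the saturating profile in n_s instead.
    prof <- profile_one(df)
    convex <- nrow(prof) < 3 ||
      all(diff(prof$variance, differences = 2) >= -1e-9 * abs(prof$variance[-c(1, nrow(prof))]))
    at_lower <- res$n_s == prof$n_s[1]
    at_upper <- res$n_s == prof$n_s[nrow(prof)]
    locus <- if (!convex && (at_lower || at_upper)) "I2"
             else if (at_lower) "E1" else if (at_upper) "E2" else "I1"
    case <- dispatch_case(df$alpha, df$beta)
  }

  tibble::tibble(
    n_s = res$n_s, n_d = res$n_d,
    variance = res$variance, cost = res$cost,
    utilization_pct = 100 * res$cost / df$budget,
    case = case, locus = locus, method = res$method
  )
}

#' Find the cost-optimal allocation for each scenario
#'
#' For every scenario row, returns the integer design `(n_s, n_d)` that
#' minimizes the variance of the estimated group mean exposure subject to
#' the budget. The search scans budget-saturating pairs
#' `(n_s, max_occasions(n_s))`, which is sufficient because variance never
#' increases with `n_d`; with linear costs the closed-form interior
#' solution is used for screening and then integer-refined, and boundary
#' rules decide the degenerate cases. Enumeration remains the authority:
#' every reported optimum equals the enumerated one.
#'
#' Ties in variance (at relative tolerance 1e-12) are broken in favour of
#' more subjects, then lower cost.
#'
#' @param scenarios A scenario tibble, see [scenario_tbl()].
#' @param method `"auto"` (default) uses closed-form screening where
#'   available; `"enumerate"` forces pure enumeration. The returned optimum
#'   is identical either way.
#' @return The scenario tibble plus columns `n_s`, `n_d`, `variance`,
#'   `cost`, `utilization_pct`, `case` (A: both cost stages linear, B: only
#'   subjects linear, C: only occasions linear, D: neither), `locus`
#'   (E1/E2/I1/I2 position of the continuous optimum in its choice set) and
#'   `method`. Class `"expo_results"`, which has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @examples
#' scenario_tbl(2, 10, 10, 20, 1, 1, alpha = 1.5, beta = 1.5, budget = 500) |>
#'   optimize_design()
#' @export
optimize_design <- function(scenarios, method = c("auto", "enumerate")) {
  method <- match.arg(method)
  df <- validate_scenarios(scenarios)
  solver <- if (method == "auto") {
    function(row) optimize_one(row)
  } else {
    function(row) {
      lim <- budget_limit(row$budget)
      if (cost_one(1L, 1L, row) > lim) {
        stop("budget insufficient for a single observation", call. = FALSE)
      }
      best <- enumerate_one(row)
      tibble::tibble(n_s = best$n_s, n_d = best$n_d,
                     variance = best$variance, cost = best$cost,
                     utilization_pct = 100 * best$cost / row$budget,
                     case = dispatch_case(row$alpha, row$beta),
                     locus = NA_character_, method = best$method)
    }
  }
  sol <- purrr::map(seq_len(nrow(df)), function(i) solver(df[i, ])) |>
    purrr::list_rbind()
  out <- dplyr::bind_cols(df, sol)
  out$variance_2dp <- round_half_away(out$variance, 2)
  class(out) <- c("expo_results", class(out))
  out
}

#' Budget-saturating sensitivity profile of a scenario
#'
#' For each affordable subject count, the largest affordable occasion
#' count and the resulting cost, variance and utilization: the full
#' candidate table behind the optimizer, useful for judging how much
#' statistical performance is lost by deviating from the optimum.
#'
#' @param scenarios A scenario tibble; one profile is computed per row.
#' @return A tibble of class `"expo_profile"` with columns `scenario`
#'   (row index), `n_s`, `n_d` (largest affordable), `cost`, `variance`,
#'   `utilization_pct`. Has an [autoplot()] method.
#' @examples
#' scenario_tbl(2, 10, 10, 20, 1, 1, alpha = 0.75, beta = 0.75, budget = 500) |>
#'   design_profile()
#' @export
design_profile <- function(scenarios) {
  df <- validate_scenarios(scenarios)
  out <- purrr::map(seq_len(nrow(df)), function(i) {
    dplyr::mutate(profile_one(df[i, ]), scenario = i, .before = 1)
  }) |>
    purrr::list_rbind()
  class(out) <- c("expo_profile", class(out))
  out
}
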