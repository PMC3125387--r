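test_that("occasion boundary search finds the largest affordable n_d", {
  scn <- scenario_tbl(2, 10, 10, 2, 10, 10, alpha = 1, beta = 0.5, budget = 500)
  got <- max_occasions(scn, 1)
  # cross-check by direct scan
  costs <- 2 + 10 * (1:100)^0.5 + 10 * (1:100)
  expect_equal(got, max(which(costs <= 500)))
  expect_equal(got, 43L)

  we <- worked_example()
  expect_equal(max_occasions(we, 5), 12L)
  # budget saturation: one more occasion would overshoot
  expect_lte(design_cost(5, 12, 20, 1, 1, 1.5, 1.5), 500)
  expect_gt(design_cost(5, 13, 20, 1, 1, 1.5, 1.5), 500)
  # unaffordable subject count
  expect_true(is.na(max_occasions(we, 50)))
})

test_that("subject boundary search matches the reference scenarios", {
  ns_for <- function(cst, alpha) {
    max_subjects(scenario_tbl(2, 10, 10, cst[1], cst[2], cst[3],
                              alpha = alpha, beta = 1, budget = 500))
  }
  expect_equal(ns_for(c(2, 10, 10), 0.5), 24L)
  expect_equal(ns_for(c(20, 1, 1), 0.5), 134L)
  expect_equal(ns_for(c(11, 5.5, 5.5), 1), 22L)
  expect_error(
    max_subjects(scenario_tbl(2, 10, 10, 11, 5.5, 5.5, budget = 10)),
    "budget insufficient"
  )
})

test_that("optimizer reproduces the worked examples", {
  res <- optimize_design(worked_example())
  expect_equal(c(res$n_s, res$n_d), c(5, 12))
  expect_equal(res$variance_2dp, 0.73)
  expect_equal(round(res$utilization_pct, 1), 98.3)
  expect_equal(res$case, "D")

  lin <- optimize_design(scenario_tbl(2, 10, 10, 20, 1, 1, budget = 500))
  expect_equal(c(lin$n_s, lin$n_d), c(13, 9))
  expect_equal(lin$case, "A")
  expect_equal(lin$locus, "I1")
  expect_equal(lin$method, "closed_form_refined")
})

test_that("dominant between-subjects variance pins optima to one occasion", {
  for (a in c(0.5, 1, 1.5)) {
    for (b in c(0.5, 1, 1.5)) {
      res <- optimize_design(
        scenario_tbl(20, 1, 1, 2, 10, 10, alpha = a, beta = b, budget = 500)
      )
      expect_equal(res$n_d, 1L)
    }
  }
})

test_that("optimize agrees with the brute-force rectangle oracle", {
  scns <- random_scenarios(60, 11)
  res <- optimize_design(scns)
  for (i in seq_len(nrow(scns))) {
    expect_equal(res$variance[i], oracle_min_variance(scns[i, ]),
                 tolerance = 1e-12)
  }
  # forcing pure enumeration returns the same optima
  res2 <- optimize_design(scns, method = "enumerate")
  expect_equal(res$n_s, res2$n_s)
  expect_equal(res$n_d, res2$n_d)
  expect_equal(res$variance, res2$variance)
})

test_that("integer refinement handles exact and distant continuous optima", {
  # continuous optimum (10, 2) is integral and budget-exact; returned as is
  scn <- scenario_tbl(1, 1, 1, 4, 1, 1, budget = 80)
  cont <- case_a_interior(scn)
  expect_equal(c(cont$n_s_star, cont$n_d_star), c(10, 2))
  res <- optimize_design(scn)
  expect_equal(c(res$n_s, res$n_d), c(10, 2))
  # continuous (12.5, 10) but integer optimum (13, 9): the neighborhood
  # must extend along the budget boundary
  res2 <- optimize_design(scenario_tbl(2, 10, 10, 20, 1, 1, budget = 500))
  expect_equal(c(res2$n_s, res2$n_d), c(13, 9))
  expect_equal(res2$variance, oracle_min_variance(res2[, 1:9]))
})

test_that("ties in variance prefer more subjects, then lower cost", {
  # s2_bs = 0, free recruitment, linear costs: variance depends only on
  # n_s * n_d, so every saturating design with the same product ties
  scn <- scenario_tbl(0, 10, 10, 0, 1, 1, budget = 24)
  res <- optimize_design(scn)
  expect_equal(res$variance, 20 / 12)
  expect_equal(res$n_s, 12L)  # the most-subjects member of the tie class
  expect_equal(res$n_d, 1L)
})

test_that("degenerate variance structures short-circuit correctly", {
  # no within-subject variance: occasions are worthless, spend on subjects
  res <- optimize_design(scenario_tbl(10, 0, 0, 2, 1, 1, budget = 100))
  expect_equal(res$n_d, 1L)
  expect_equal(res$n_s, max_subjects(scenario_tbl(10, 0, 0, 2, 1, 1, budget = 100)))
  # free occasions with within-subject variance present: no finite optimum
  expect_error(
    optimize_design(scenario_tbl(2, 10, 10, 5, 0, 0, budget = 100)),
    "unbounded"
  )
})

test_that("optimal variance responds monotonically to budget and scaling", {
  base <- scenario_tbl(2, 10, 10, 11, 5.5, 5.5, alpha = 1.25, beta = 0.75,
                       budget = 100)
  ladder <- seq(50, 800, by = 50)
  vars <- vapply(ladder, function(R) {
    optimize_design(dplyr::mutate(base, budget = R))$variance
  }, numeric(1))
  expect_true(all(diff(vars) <= 1e-12))
  # joint scaling of unit costs and budget leaves the optimum unchanged
  res <- optimize_design(base |> dplyr::mutate(budget = 500))
  for (k in c(0.25, 3, 17)) {
    scaled <- dplyr::mutate(base, pi_s = pi_s * k, pi_d = pi_d * k,
                            c_q = c_q * k, budget = 500 * k)
    res_k <- optimize_design(scaled)
    expect_equal(c(res_k$n_s, res_k$n_d), c(res$n_s, res$n_d))
  }
})

test_that("infeasible scenarios and runaway searches raise explicit errors", {
  expect_error(optimize_design(scenario_tbl(2, 10, 10, 11, 5.5, 5.5, budget = 10)),
               "budget insufficient")
  # near-zero occasion cost with beta < 1: the occasion boundary explodes
  runaway <- scenario_tbl(2, 10, 10, 1, 1e-8, 0, alpha = 1, beta = 0.5,
                          budget = 1000)
  expect_error(optimize_design(runaway), "safety cap")
})

test_that("sensitivity profile exposes the deviation trade-offs", {
  scn <- scenario_tbl(2, 10, 10, 20, 1, 1, alpha = 0.75, beta = 0.75,
                      budget = 500)
  prof <- design_profile(scn)
  best <- prof[which.min(prof$variance), ]
  expect_equal(c(best$n_s, best$n_d), c(21, 9))
  expect_equal(round_half_away(best$variance), 0.20)
  # near-optimal plateau: n_s from 15 to 32, occasion boundary from 15 to 4
  mid <- prof[prof$n_s %in% 15:32, ]
  expect_equal(range(mid$n_d), c(4, 15))
  expect_equal(mid$n_d[mid$n_s == 30], 4)
  expect_equal(round_half_away(mid$variance[mid$n_s == 30]), 0.23)
  expect_equal(round(mid$utilization_pct[mid$n_s == 30]), 92)
  expect_equal(mid$n_s[which.max(mid$variance)], 30)
  expect_true(all(mid$variance[mid$n_s != 30] < mid$variance[mid$n_s == 30]))
  # profile minimum agrees with the optimizer
  opt <- optimize_design(scn)
  expect_equal(best$variance, opt$variance)
  # scenario affordable only at a single subject count has a one-row profile
  tight <- scenario_tbl(2, 10, 10, 10, 5, 5, budget = 22)
  expect_equal(nrow(design_profile(tight)), 1)
})
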