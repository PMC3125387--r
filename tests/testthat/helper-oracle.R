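# Independent brute-force oracle: scans the complete feasible integer
# rectangle with its own cost/variance arithmetic, deliberately sharing no
# code with the package's optimizer.

oracle_cost <- function(n_s, n_d, row) {
  row$pi_s * n_s^row$alpha + n_s * row$pi_d * n_d^row$beta + n_s * n_d * row$c_q
}

oracle_variance <- function(n_s, n_d, row) {
  row$s2_bs / n_s + (row$s2_bd + row$s2_mu_wd) / (n_s * n_d)
}

# minimum variance over every feasible (n_s, n_d), full rectangle
oracle_min_variance <- function(row, lim = row$budget * (1 + 1e-12) + 1e-9) {
  best <- Inf
  n_s <- 1
  while (oracle_cost(n_s, 1, row) <= lim) {
    n_d_hi <- 1
    while (oracle_cost(n_s, n_d_hi + 1, row) <= lim) n_d_hi <- n_d_hi + 1
    nd <- seq_len(n_d_hi)
    feas <- oracle_cost(n_s, nd, row) <= lim
    best <- min(best, min(oracle_variance(n_s, nd[feas], row)))
    n_s <- n_s + 1
  }
  best
}

# reference scenario used across tests: the fully non-linear worked example
worked_example <- function() {
  scenario_tbl(s2_bs = 2, s2_bd = 10, s2_mu_wd = 10,
               pi_s = 20, pi_d = 1, c_q = 1,
               alpha = 1.5, beta = 1.5, budget = 500)
}
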