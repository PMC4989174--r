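# Shared fixtures and independent oracles used across the suite.

# Parameter set of the analytic relative-time experiment.
fig2_params <- function(alpha = 1) {
  game_params(M = 100, N = 5, c = 1, r = 3, alpha = alpha,
              delta = 1, gamma = 0.3, omega = 0.1, mu = 0)
}

# Parameter set of the agent-based trace/sweep experiments.
fig_sim_params <- function(alpha = 1) {
  game_params(M = 100, N = 5, c = 1, r = 3, alpha = alpha,
              delta = 1, gamma = 0.3, omega = 0.5, mu = 0.001)
}

# Independent payoff formula (deliberately restated, not group_payoffs).
oracle_payoff <- function(focal, x, y, z, p) {
  share <- p$c * p$r * (x + z)^p$alpha / p$N
  switch(focal,
         C = share - p$c,
         D = share - p$delta * z,
         P = share - p$c - p$gamma * y)
}

# Brute-force expected payoff: enumerate every unordered co-player subset
# of size N-1 from a labelled population of M individuals (m_focal of the
# focal type, the rest of the opponent type) and average the focal payoff.
# Independent of dhyper and of the package's composition assembly.
oracle_expected_payoff <- function(params, focal, opponent, m_focal) {
  types <- c(rep(focal, m_focal), rep(opponent, params$M - m_focal))
  combos <- utils::combn(params$M, params$N - 1)
  vals <- apply(combos, 2, function(idx) {
    n <- table(factor(types[idx], levels = c("C", "D", "P")))
    n[[focal]] <- n[[focal]] + 1L
    oracle_payoff(focal, n[["C"]], n[["D"]], n[["P"]], params)
  })
  mean(vals)
}

# Absorbing birth-death chain oracle: solve the linear system for the
# probability x_1 of reaching state M from a single mutant, using the
# transition rates directly (tridiagonal solve over interior states).
oracle_fixation_solve <- function(params, mutant, resident) {
  M <- params$M
  n <- M - 1
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (k in seq_len(n)) {
    tr <- moran_transition_probs(params, mutant, resident, k)
    tp <- tr[["T_plus"]]; tm <- tr[["T_minus"]]
    A[k, k] <- tp + tm
    if (k > 1) A[k, k - 1] <- -tm
    if (k < n) A[k, k + 1] <- -tp
    if (k == n) b[k] <- tp   # x_M = 1
  }
  solve(A, b)[1]
}

# Memoized analytic scan at the fig2 parameter set (reused by several
# tests to keep the suite fast).
fig2_scan_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- alpha_scan(fig2_params(), seq(1, 2, by = 0.1))
    cache
  }
})
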