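test_that("group sampling pmf matches direct enumeration and normalizes", {
  expect_equal(group_sampling_pmf(M = 100, m_i = 100, N = 5, k = 5), 1)
  expect_equal(sum(group_sampling_pmf(M = 100, m_i = 30, N = 5, k = 0:5)), 1)
  # C(4,2) * C(6,1) / C(10,3) = 36/120
  expect_equal(group_sampling_pmf(M = 10, m_i = 4, N = 3, k = 2), 0.30)
  expect_equal(group_sampling_pmf(M = 10, m_i = 4, N = 3, k = 3),
               choose(4, 3) * choose(6, 0) / choose(10, 3))
  expect_equal(group_sampling_pmf(M = 10, m_i = 2, N = 3, k = 3), 0)
  # stable at large population sizes
  expect_true(is.finite(group_sampling_pmf(M = 10000, m_i = 5000,
                                           N = 100, k = 50)))
  expect_error(group_sampling_pmf(M = 10, m_i = 11, N = 3, k = 1), "m_i")
  expect_error(group_sampling_pmf(M = 10, m_i = 4, N = 3, k = 4), "k must")
})

test_that("expected pairwise payoff matches the brute-force enumeration oracle", {
  p <- game_params(M = 10, N = 3, c = 1, r = 3, alpha = 1.8,
                   delta = 1, gamma = 0.3, omega = 0.1)
  for (m in c(1, 5, 9)) {
    for (pair in list(c("C", "D"), c("D", "C"), c("P", "D"),
                      c("D", "P"), c("C", "P"), c("P", "C"))) {
      expect_equal(expected_payoff_pair(p, pair[1], pair[2], m),
                   oracle_expected_payoff(p, pair[1], pair[2], m),
                   tolerance = 1e-12,
                   info = paste(pair[1], "vs", pair[2], "m =", m))
    }
  }
})

test_that("expected payoff of a homogeneous population is the full-group payoff", {
  p <- game_params(M = 100, N = 5, c = 1, r = 3, alpha = 1)
  expect_equal(expected_payoff_pair(p, "C", "D", 100), 2)
  expect_error(expected_payoff_pair(p, "C", "D", 0), "m_focal")
  expect_error(expected_payoff_pair(p, "C", "C", 5), "distinct")
})

test_that("free, costless punishment makes the C/P pairing symmetric", {
  p <- game_params(M = 30, N = 5, delta = 0, gamma = 0, alpha = 1.4)
  for (m in c(1, 10, 29))
    expect_equal(expected_payoff_pair(p, "C", "P", m),
                 expected_payoff_pair(p, "P", "C", m))
})

test_that("exponential fitness map behaves as exp(omega * payoff)", {
  expect_equal(fitness(game_params(omega = 0.1), 0), 1)
  expect_equal(fitness(game_params(omega = 0.5), 2), exp(1))
  p <- game_params(omega = 0.3)
  expect_gt(fitness(p, 1.01), fitness(p, 1.00))
  expect_gt(fitness(p, -50), 0)
})

test_that("Moran transition rates have the frequency-dependent form", {
  # equal fitness: T+ = T- = (m_i/M) * (m_j/M)
  p <- game_params(M = 4, N = 2, delta = 0, gamma = 0, alpha = 1)
  tr <- moran_transition_probs(p, "C", "P", 2)
  expect_equal(tr[["T_plus"]], 0.25)
  expect_equal(tr[["T_minus"]], 0.25)
  # absorbing boundaries
  expect_equal(moran_transition_probs(p, "C", "P", 0),
               c(T_plus = 0, T_minus = 0))
  expect_equal(moran_transition_probs(p, "C", "P", 4),
               c(T_plus = 0, T_minus = 0))
  # algebraic identity theta = T-/T+ = exp(-omega * (P_i - P_j))
  q <- fig2_params(alpha = 1.5)
  for (m in c(1, 25, 60, 99)) {
    tr <- moran_transition_probs(q, "P", "D", m)
    d <- expected_payoff_pair(q, "P", "D", m) -
         expected_payoff_pair(q, "D", "P", q$M - m)
    expect_equal(tr[["T_minus"]] / tr[["T_plus"]], exp(-q$omega * d),
                 tolerance = 1e-12)
    expect_lte(tr[["T_plus"]] + tr[["T_minus"]], 1)
  }
})

test_that("fixation probability equals the absorbing-chain linear solve", {
  for (setup in list(list(M = 10, N = 3, alpha = 1.8),
                     list(M = 20, N = 4, alpha = 1.2),
                     list(M = 20, N = 4, alpha = 1.0))) {
    p <- game_params(M = setup$M, N = setup$N, c = 1, r = 3,
                     alpha = setup$alpha, delta = 1, gamma = 0.3,
                     omega = 0.1)
    for (pair in list(c("C", "D"), c("P", "D"), c("D", "P"), c("C", "P"))) {
      expect_equal(fixation_probability(p, pair[1], pair[2]),
                   oracle_fixation_solve(p, pair[1], pair[2]),
                   tolerance = 1e-10,
                   info = sprintf("M=%d %s into %s", setup$M, pair[1],
                                  pair[2]))
    }
  }
})

test_that("neutral and payoff-identical pairs fix at 1/M", {
  p <- game_params(M = 100, N = 5, delta = 0, gamma = 0, alpha = 1.3,
                   omega = 0.2)
  expect_equal(fixation_probability(p, "C", "P"), 1 / 100, tolerance = 1e-12)
  expect_equal(fixation_probability(p, "P", "C"), 1 / 100, tolerance = 1e-12)
})

test_that("fixation stays finite and inside (0,1) under strong selection", {
  p <- game_params(M = 1000, N = 5, c = 1, r = 3, alpha = 1.8,
                   delta = 1, gamma = 0.3, omega = 5)
  for (pair in list(c("P", "D"), c("D", "P"), c("C", "D"))) {
    rho <- fixation_probability(p, pair[1], pair[2])
    expect_true(is.finite(rho))
    expect_gte(rho, 0)
    expect_lte(rho, 1)
  }
  # a lone invader of either type sits in a deep fitness valley (a rare
  # punisher is fined-free but pays c and gamma*y; a rare defector among
  # punishers is fined delta*z), so both invasions are vanishingly rare
  expect_lt(fixation_probability(p, "P", "D"), 1e-10)
  expect_lt(fixation_probability(p, "D", "P"), 1e-10)
  # cooperators and punishers are payoff-identical in a defector-free
  # pairing, so even at omega = 5 their mutual fixation is neutral: 1/M
  expect_equal(fixation_probability(p, "C", "P"), 1 / 1000,
               tolerance = 1e-12)
})

test_that("embedded chain is row-stochastic with rho/2 off-diagonals", {
  p <- game_params(M = 20, N = 4, c = 1, r = 3, alpha = 1.4, delta = 1,
                   gamma = 0.3, omega = 0.1)
  A <- embedded_transition_matrix(p)
  expect_equal(rowSums(A), c(C = 1, D = 1, P = 1))
  expect_equal(A["D", "C"], fixation_probability(p, "C", "D") / 2)
  expect_equal(A["C", "P"], fixation_probability(p, "P", "C") / 2)
  # payoff-identical world: all six fixation probabilities are 1/M
  q <- game_params(M = 50, N = 5, delta = 0, gamma = 0, alpha = 1,
                   omega = 1e-9)
  Aq <- embedded_transition_matrix(q)
  off <- Aq[row(Aq) != col(Aq)]
  expect_equal(off, rep(1 / (2 * 50), 6), tolerance = 1e-6)
  expect_equal(unname(diag(Aq)), rep(1 - 1 / 50, 3), tolerance = 1e-6)
})

test_that("stationary distribution solves pi^T A = pi^T by both routes", {
  # uniform law for a symmetric doubly stochastic matrix
  A <- matrix(c(0.8, 0.1, 0.1,
                0.1, 0.8, 0.1,
                0.1, 0.1, 0.8), 3, 3, byrow = TRUE)
  expect_equal(unname(stationary_distribution(A)), rep(1 / 3, 3))
  # random stochastic matrices: fixed-point residual at machine precision
  set.seed(42)
  for (i in 1:20) {
    A <- matrix(stats::rexp(9), 3, 3)
    A <- A / rowSums(A)
    pi <- stationary_distribution(A)
    expect_lt(max(abs(pi %*% A - pi)), 1e-12)
    expect_equal(sum(pi), 1, tolerance = 1e-12)
  }
  # reducible chain: stationary vector is not unique
  expect_error(stationary_distribution(diag(3)), "not unique")
  expect_error(stationary_distribution(matrix(1, 3, 3)), "row-stochastic")
})

test_that("alpha scan reproduces the relative-time picture", {
  scan <- fig2_scan_cached()
  expect_equal(nrow(scan), 11)
  expect_equal(rowSums(scan[, c("pi_C", "pi_D", "pi_P")]),
               rep(1, 11), tolerance = 1e-12)
  # defectors lose ground monotonically as returns to scale increase
  expect_true(all(diff(scan$pi_D) < 0))
  # cooperators and punishers both hold at least the defectors' share
  # from alpha = 1.3 onwards
  hi <- scan[scan$alpha >= 1.3 - 1e-9, ]
  expect_true(all(pmin(hi$pi_C, hi$pi_P) >= hi$pi_D))
  # single-point grid degenerates to one stationary law
  one <- alpha_scan(fig2_params(), 1.0)
  expect_equal(nrow(one), 1)
  expect_equal(unlist(one[1, -1]), unlist(scan[1, -1]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(alpha_scan(fig2_params(), c(1, -2)), "positive")
})

test_that("free and costless punishment equalizes the C and P states", {
  p <- game_params(M = 100, N = 5, c = 1, r = 3, alpha = 1.2,
                   delta = 0, gamma = 0, omega = 0.1)
  pi <- stationary_distribution(embedded_transition_matrix(p))
  expect_equal(pi[["pi_C"]], pi[["pi_P"]], tolerance = 1e-10)
})

test_that("alpha scan CSV round-trips at full precision", {
  scan <- alpha_scan(game_params(M = 20, N = 4, omega = 0.1),
                     c(1.0, 1.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_alpha_scan(scan, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("alpha", "pi_C", "pi_D", "pi_P"))
  expect_equal(back$pi_D, scan$pi_D, tolerance = 1e-14)
})
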