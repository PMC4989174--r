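#' Hypergeometric group-sampling probability
#'
#' Probability of drawing `k` individuals of a focal type when `N` players
#' are sampled without replacement from a two-type population of size `M`
#' containing `m_i` individuals of that type:
#' `choose(m_i, k) * choose(M - m_i, N - k) / choose(M, N)`.
#' Delegates to [stats::dhyper()], which evaluates the ratio through
#' log-gamma terms and is stable for populations of at least `1e4`.
#'
#' @param M Population size.
#' @param m_i Number of focal-type individuals, `0 <= m_i <= M`.
#' @param N Sample size, `0 <= N <= M`.
#' @param k Number of focal-type draws (vectorized); probability is 0
#'   when `k > m_i` or `N - k > M - m_i`.
#' @return Probability (vector over `k`).
#' @examples
#' group_sampling_pmf(M = 10, m_i = 4, N = 3, k = 2)  # 36/120
#' @export
group_sampling_pmf <- function(M, m_i, N, k) {
  if (!(M >= 1 && m_i >= 0 && m_i <= M && N >= 0 && N <= M))
    stop("require 0 <= m_i <= M and 0 <= N <= M", call. = FALSE)
  if (any(k < 0) || any(k > N))
    stop("k must lie in [0, N]", call. = FALSE)
  stats::dhyper(k, m_i, M - m_i, N)
}

check_pair <- function(focal, opponent) {
  if (!(focal %in% STRATEGIES) || !(opponent %in% STRATEGIES) ||
      focal == opponent)
    stop("focal and opponent must be two distinct strategies among C, D, P",
         call. = FALSE)
}

#' Expected payoff in a two-strategy population
#'
#' Expected one-shot payoff of a focal player of type `focal` in a
#' population holding `m_focal` players of the focal type and
#' `M - m_focal` players of type `opponent` (the two-type regime of the
#' small-mutation limit). The focal player occupies one group slot; the
#' number of focal-type co-players among the remaining `N - 1` slots
#' follows the same hypergeometric sampling law as the group draw itself,
#' `k ~ Hyper(m_focal, M - m_focal, N - 1)`. All six ordered pairings
#' (C/D, D/C, P/D, D/P, C/P, P/C) are covered by choosing `focal` and
#' `opponent`.
#'
#' @param params A [game_params()] object.
#' @param focal Strategy label of the focal player.
#' @param opponent The other strategy present in the population.
#' @param m_focal Count of focal-type players in the population,
#'   `1 <= m_focal <= M`.
#' @return Expected payoff of the focal player, in payoff units.
#' @export
expected_payoff_pair <- function(params, focal, opponent, m_focal) {
  stopifnot(inherits(params, "game_params"))
  check_pair(focal, opponent)
  if (!(m_focal >= 1 && m_focal <= params$M))
    stop("focal type must be present: 1 <= m_focal <= M", call. = FALSE)
  N <- params$N
  k <- 0:(N - 1)
  w <- group_sampling_pmf(params$M, m_focal, N - 1, k)
  vals <- vapply(k, function(kk) {
    n <- c(C = 0L, D = 0L, P = 0L)
    n[[focal]] <- kk + 1L
    n[[opponent]] <- N - 1L - kk
    group_payoffs(params, n)[[match(focal, STRATEGIES)]]
  }, numeric(1))
  sum(w * vals)
}

#' Exponential payoff-to-fitness map
#'
#' `F = exp(omega * P)`: strictly positive for payoffs of any sign, which
#' is why it is preferred over the linear baseline-plus-payoff map under
#' strong selection.
#'
#' @param params A [game_params()] object (only `omega` is used).
#' @param payoff Payoff value(s), finite.
#' @return Fitness value(s), `> 0`.
#' @export
fitness <- function(params, payoff) {
  stopifnot(inherits(params, "game_params"))
  if (any(!is.finite(payoff))) stop("payoff must be finite", call. = FALSE)
  exp(params$omega * payoff)
}

#' Moran birth-death transition probabilities in a two-strategy population
#'
#' Frequency-dependent Moran rates for the number `m_i` of mutants of type
#' `mutant` among residents of type `resident`:
#' \deqn{T^+ = \frac{m_i F_i}{m_i F_i + m_j F_j} \cdot \frac{m_j}{M},
#'   \qquad
#'   T^- = \frac{m_j F_j}{m_i F_i + m_j F_j} \cdot \frac{m_i}{M},}
#' with fitnesses from the expected payoffs of the two types at this
#' state. The ratio `T^-/T^+ = F_j/F_i` is what makes the fixation
#' probability reduce to the classical birth-death product formula.
#' Boundary states (`m_i` of 0 or `M`) are absorbing: both rates 0.
#'
#' @param params A [game_params()] object.
#' @param mutant,resident The two distinct strategies.
#' @param m_i Mutant count, `0 <= m_i <= M`.
#' @return Named numeric `c(T_plus = , T_minus = )`.
#' @export
moran_transition_probs <- function(params, mutant, resident, m_i) {
  stopifnot(inherits(params, "game_params"))
  check_pair(mutant, resident)
  M <- params$M
  if (!(m_i >= 0 && m_i <= M))
    stop("m_i must lie in [0, M]", call. = FALSE)
  if (m_i == 0 || m_i == M)
    return(c(T_plus = 0, T_minus = 0))
  m_j <- M - m_i
  F_i <- fitness(params, expected_payoff_pair(params, mutant, resident, m_i))
  F_j <- fitness(params, expected_payoff_pair(params, resident, mutant, m_j))
  denom <- m_i * F_i + m_j * F_j
  c(T_plus  = (m_i * F_i / denom) * (m_j / M),
    T_minus = (m_j * F_j / denom) * (m_i / M))
}

# log(theta_l) = log(T_l^- / T_l^+) = -omega * (P_i(l) - P_j(l)) for
# l = 1..M-1; shared by fixation_probability and its documentation of the
# birth-death product structure.
log_theta_profile <- function(params, mutant, resident) {
  M <- params$M
  m <- seq_len(M - 1L)
  P_i <- vapply(m, function(mm)
    expected_payoff_pair(params, mutant, resident, mm), numeric(1))
  P_j <- vapply(m, function(mm)
    expected_payoff_pair(params, resident, mutant, M - mm), numeric(1))
  -params$omega * (P_i - P_j)
}

#' Fixation probability of a single mutant
#'
#' Probability that one mutant of type `mutant` takes over a resident
#' population of type `resident` before going extinct, for the
#' birth-death chain defined by [moran_transition_probs()]:
#' \deqn{\rho_{ij} = \left(1 + \sum_{k=1}^{M-1} \prod_{l=1}^{k}
#'   \theta_l\right)^{-1}, \qquad \theta_l = T_l^-/T_l^+.}
#' The products are accumulated as sums of `log(theta)` and the outer sum
#' is evaluated by log-sum-exp, so the result stays finite and inside
#' `(0, 1)` even when the product spans hundreds of orders of magnitude
#' (strong selection, large `M`). Under neutrality (`theta = 1`
#' throughout) the formula gives `1/M`.
#'
#' @param params A [game_params()] object.
#' @param mutant,resident The two distinct strategies.
#' @return Fixation probability in `(0, 1)`.
#' @export
fixation_probability <- function(params, mutant, resident) {
  stopifnot(inherits(params, "game_params"))
  check_pair(mutant, resident)
  log_terms <- c(0, cumsum(log_theta_profile(params, mutant, resident)))
  mx <- max(log_terms)
  exp(-(mx + log(sum(exp(log_terms - mx)))))
}

#' Embedded Markov chain over homogeneous states
#'
#' In the small-mutation limit the population is monomorphic almost
#' always; transitions between the three homogeneous states (all-C,
#' all-D, all-P) occur when a single mutant appears and fixes. Each of
#' the two possible mutant types arises with probability 1/2, so the
#' transition probability from resident state `j` to state `i` is
#' `rho_ij / 2`, with the diagonal absorbing the remainder.
#'
#' @param params A [game_params()] object.
#' @return A row-stochastic 3x3 matrix with dimnames `C`, `D`, `P`
#'   (rows: current resident state; columns: next state).
#' @export
embedded_transition_matrix <- function(params) {
  stopifnot(inherits(params, "game_params"))
  A <- matrix(0, 3, 3, dimnames = list(STRATEGIES, STRATEGIES))
  for (j in STRATEGIES) for (i in STRATEGIES) if (i != j)
    A[j, i] <- fixation_probability(params, mutant = i, resident = j) / 2
  diag(A) <- 1 - rowSums(A)
  A
}

#' Stationary distribution of the embedded chain
#'
#' Long-run probabilities of finding the population in each homogeneous
#' state ("relative time in homogeneous states"). The vector `pi`
#' satisfies `pi^T A = pi^T` with components summing to 1. It is computed
#' by two independent routes and cross-validated:
#' the normalized eigenvector of `t(A)` for the eigenvalue nearest 1, and
#' the closed-form solve of the homogeneous linear system
#' `(t(A) - I) pi = 0` with one equation replaced by the normalization
#' identity. The two must agree to `1e-10`, otherwise an error is raised;
#' likewise if the unit eigenvalue is (numerically) non-simple, in which
#' case the stationary vector is not unique.
#'
#' @param A A row-stochastic 3x3 matrix, e.g. from
#'   [embedded_transition_matrix()].
#' @return Named numeric `c(pi_C = , pi_D = , pi_P = )` summing to 1.
#' @export
stationary_distribution <- function(A) {
  if (!is.matrix(A) || any(dim(A) != c(3L, 3L)))
    stop("A must be a 3x3 matrix", call. = FALSE)
  if (any(A < -1e-12) || any(abs(rowSums(A) - 1) > 1e-9))
    stop("A must be row-stochastic", call. = FALSE)

  # eigen route
  e <- eigen(t(A))
  ord <- order(abs(e$values - 1))
  if (length(ord) > 1 && abs(abs(e$values[ord[2]]) - 1) < 1e-12)
    stop("stationary distribution is not unique (reducible or periodic chain)",
         call. = FALSE)
  v <- Re(e$vectors[, ord[1]])
  v <- v / sum(v)
  if (any(v < -1e-9))
    stop("eigenvector normalization produced negative components", call. = FALSE)

  # closed-form route: homogeneous system plus normalization identity
  B <- t(A) - diag(3)
  B[3, ] <- 1
  w <- solve(B, c(0, 0, 1))

  if (max(abs(v - w)) > 1e-10)
    stop("eigen and closed-form stationary solutions disagree", call. = FALSE)

  pi <- pmax(v, 0)
  pi <- pi / sum(pi)
  c(pi_C = pi[1], pi_D = pi[2], pi_P = pi[3])
}

#' Stationary distribution as a function of the scale coefficient
#'
#' Recomputes the full small-mutation analysis (expected payoffs, fixation
#' probabilities, embedded chain, stationary distribution) for each value
#' of the scale coefficient `alpha` on a grid. This is the scan behind the
#' relative-time-in-homogeneous-states picture: as `alpha` grows past a
#' threshold, the defector state loses mass to the cooperator and punisher
#' states.
#'
#' @param params A [game_params()] object; its `alpha` entry is replaced
#'   by each grid value in turn.
#' @param alpha_grid Numeric vector of scale coefficients, all `> 0`.
#' @return A data frame with columns `alpha`, `pi_C`, `pi_D`, `pi_P`
#'   (one row per grid value; each row sums to 1).
#' @examples
#' \donttest{
#' scan <- alpha_scan(game_params(M = 100, N = 5, omega = 0.1),
#'                    alpha_grid = seq(1, 2, by = 0.5))
#' }
#' @export
alpha_scan <- function(params, alpha_grid) {
  stopifnot(inherits(params, "game_params"))
  if (length(alpha_grid) < 1 || any(!is.finite(alpha_grid)) ||
      any(alpha_grid <= 0))
    stop("alpha_grid values must be positive", call. = FALSE)
  rows <- lapply(alpha_grid, function(a) {
    p <- params; p$alpha <- a
    pi <- stationary_distribution(embedded_transition_matrix(p))
    data.frame(alpha = a, pi_C = pi[["pi_C"]], pi_D = pi[["pi_D"]],
               pi_P = pi[["pi_P"]])
  })
  do.call(rbind, rows)
}

#' Write an alpha scan to CSV
#'
#' Full double precision, header `alpha,pi_C,pi_D,pi_P`.
#'
#' @param scan Data frame from [alpha_scan()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_alpha_scan <- function(scan, path) {
  stopifnot(is.data.frame(scan),
            identical(names(scan), c("alpha", "pi_C", "pi_D", "pi_P")))
  utils::write.csv(format(scan, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
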