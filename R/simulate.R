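#' Population state
#'
#' Strategy counts at the population scale.
#'
#' @param X,Y,Z Counts of cooperators, defectors and punishers; their sum
#'   is the population size `M`.
#' @return Named integer vector of class `population_state`.
#' @export
population_state <- function(X, Y, Z) {
  v <- c(X, Y, Z)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    stop("population counts must be non-negative integers", call. = FALSE)
  structure(as.integer(v), names = c("X", "Y", "Z"),
            class = "population_state")
}

check_state <- function(state, params) {
  if (!inherits(state, "population_state"))
    state <- population_state(state[[1]], state[[2]], state[[3]])
  if (sum(state) != params$M)
    stop("population counts must sum to M = ", params$M, call. = FALSE)
  state
}

#' Simulation configuration
#'
#' Run-length, seeding and recording settings for [run_simulation()].
#' `mean_frequencies` are averaged over every period after `burn_in`,
#' regardless of the recording cadence.
#'
#' @param periods Number of birth-death periods to simulate.
#' @param seed Integer RNG seed; a run is fully reproducible from it.
#' @param initial_state A [population_state()].
#' @param burn_in Periods excluded from the time averages
#'   (default: 10% of `periods`; set 0 to average the whole run).
#' @param record_every Cadence at which states are stored in the trace.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(periods, seed, initial_state,
                       burn_in = floor(0.1 * periods), record_every = 1L) {
  stopifnot(is.numeric(periods), length(periods) == 1L, periods >= 1,
            periods == round(periods))
  stopifnot(is.numeric(seed), length(seed) == 1L, seed == round(seed))
  if (!inherits(initial_state, "population_state"))
    stop("initial_state must be a population_state()", call. = FALSE)
  if (!(burn_in >= 0 && burn_in < periods))
    stop("burn_in must satisfy 0 <= burn_in < periods", call. = FALSE)
  if (record_every < 1 || record_every != round(record_every))
    stop("record_every must be a positive integer", call. = FALSE)
  structure(list(periods = as.integer(periods), seed = as.integer(seed),
                 initial_state = initial_state,
                 burn_in = as.integer(burn_in),
                 record_every = as.integer(record_every)),
            class = "sim_config")
}

#' Play one period of the sampled public goods game
#'
#' Draws the `N` group members without replacement from the population
#' (multivariate hypergeometric over the three strategy counts, realized
#' as nested univariate hypergeometric draws) and computes the one-shot
#' payoff each sampled member receives. Individuals left out of this
#' period's group earn payoff 0.
#'
#' Uses the current R RNG stream; seed via [set.seed()].
#'
#' @param state A [population_state()].
#' @param params A [game_params()] object.
#' @return List with `sampled` (named counts of sampled C/D/P, summing to
#'   `N`) and `payoffs` (named per-strategy payoff earned by this
#'   period's sampled members of that strategy).
#' @export
play_one_period <- function(state, params) {
  stopifnot(inherits(params, "game_params"))
  state <- check_state(state, params)
  N <- params$N
  xs <- stats::rhyper(1, state[["X"]], state[["Y"]] + state[["Z"]], N)
  ds <- stats::rhyper(1, state[["Y"]], state[["Z"]], N - xs)
  zs <- N - xs - ds
  pay <- group_payoffs(params, c(xs, ds, zs))
  list(sampled = c(C = xs, D = ds, P = zs),
       payoffs = c(C = pay[["P_x"]], D = pay[["P_y"]], P = pay[["P_z"]]))
}

#' Mutate a newborn's strategy
#'
#' With probability `1 - mu` the strategy is inherited unchanged; with
#' probability `mu` it switches to one of the two other strategies,
#' chosen uniformly.
#'
#' @param strategy One of `"C"`, `"D"`, `"P"`.
#' @param mu Mutation probability in `[0, 1)`.
#' @return A strategy label.
#' @export
mutate_strategy <- function(strategy, mu) {
  if (!(strategy %in% STRATEGIES)) stop("unknown strategy", call. = FALSE)
  if (!(mu >= 0 && mu < 1)) stop("mu must be in [0, 1)", call. = FALSE)
  if (stats::runif(1) < mu) {
    others <- setdiff(STRATEGIES, strategy)
    if (stats::runif(1) < 0.5) others[1] else others[2]
  } else strategy
}

#' One genetic-pool Moran update
#'
#' One individual, chosen uniformly, dies; the replacing offspring's type
#' is drawn with probability proportional to the total fitness mass of
#' each type (sampled members contribute `exp(omega * payoff)`, everyone
#' else the baseline `exp(0) = 1`), then passes through
#' [mutate_strategy()]. The default `"weighted"` draw is distributionally
#' identical to literally materializing a pool of `M` fitness-chosen
#' offspring and picking one uniformly; the `"literal"` pool is kept for
#' verification.
#'
#' @param state A [population_state()].
#' @param params A [game_params()] object.
#' @param sampled Named sampled counts from [play_one_period()].
#' @param payoffs Named per-strategy payoffs from [play_one_period()].
#' @param pool `"weighted"` (default) or `"literal"`.
#' @return The next [population_state()].
#' @export
genetic_pool_update <- function(state, params, sampled, payoffs,
                                pool = c("weighted", "literal")) {
  stopifnot(inherits(params, "game_params"))
  pool <- match.arg(pool)
  state <- check_state(state, params)
  counts <- as.integer(state)
  f <- exp(params$omega * payoffs[STRATEGIES])
  mass <- (counts - sampled[STRATEGIES]) + sampled[STRATEGIES] * f
  if (!all(is.finite(mass)) || sum(mass) <= 0)
    stop("invalid fitness mass", call. = FALSE)

  u <- stats::runif(1)
  M <- params$M
  die <- if (u < counts[1] / M) 1L else if (u < (counts[1] + counts[2]) / M) 2L else 3L

  if (pool == "weighted") {
    v <- stats::runif(1) * sum(mass)
    born <- if (v < mass[1]) 1L else if (v < mass[1] + mass[2]) 2L else 3L
  } else {
    offspring <- sample.int(3L, M, replace = TRUE, prob = mass / sum(mass))
    born <- offspring[sample.int(M, 1L)]
  }
  born <- match(mutate_strategy(STRATEGIES[born], params$mu), STRATEGIES)

  counts[die] <- counts[die] - 1L
  counts[born] <- counts[born] + 1L
  population_state(counts[1], counts[2], counts[3])
}

#' Run the agent-based Moran simulation
#'
#' Iterates [play_one_period()] and [genetic_pool_update()] for
#' `config$periods` periods from `config$initial_state`, recording states
#' at the configured cadence and accumulating time-averaged strategy
#' frequencies over the post-burn-in periods. Deterministic given the
#' seed. The default engine is a compiled loop; `engine = "r"` runs the
#' step-by-step R reference, which consumes the RNG stream identically
#' and therefore yields a bit-identical trace.
#'
#' @param params A [game_params()] object.
#' @param config A [sim_config()].
#' @param engine `"cpp"` (default) or `"r"`.
#' @param corner_margin Distance from a monomorphic corner within which a
#'   period counts as "near" that corner (used by the
#'   simulation-vs-analytics occupancy cross-check).
#' @return An object of class `sim_trace`: list with `trace` (data frame
#'   `period, X, Y, Z`), `mean_frequencies` (named `C`, `D`, `P`,
#'   summing to 1), `corner_time` (fraction of post-burn-in periods spent
#'   within `corner_margin` of each corner), plus the `params` and
#'   `config` used.
#' @examples
#' p <- game_params(M = 50, N = 5, alpha = 1.8, omega = 0.5, mu = 0.001)
#' cfg <- sim_config(periods = 2000, seed = 1,
#'                   initial_state = population_state(15, 20, 15))
#' tr <- run_simulation(p, cfg)
#' tr$mean_frequencies
#' @export
run_simulation <- function(params, config, engine = c("cpp", "r"),
                           corner_margin = 2L) {
  stopifnot(inherits(params, "game_params"), inherits(config, "sim_config"))
  engine <- match.arg(engine)
  init <- check_state(config$initial_state, params)
  set.seed(config$seed)

  if (engine == "cpp") {
    res <- sim_loop_cpp(params$M, params$N, params$c, params$r, params$alpha,
                        params$delta, params$gamma, params$omega, params$mu,
                        init[["X"]], init[["Y"]], init[["Z"]],
                        config$periods, config$burn_in, config$record_every,
                        as.integer(corner_margin))
    trace <- data.frame(period = res$period, X = res$X, Y = res$Y, Z = res$Z)
    mean_freq <- stats::setNames(res$mean_freq, STRATEGIES)
    corner <- stats::setNames(res$corner_time, STRATEGIES)
  } else {
    state <- init
    M <- params$M
    n_rec <- config$periods %/% config$record_every + 1L
    rec <- matrix(0L, n_rec, 4L)
    rec[1L, ] <- c(0L, state)
    ri <- 1L
    sums <- c(0, 0, 0)
    corner_hits <- c(0, 0, 0)
    for (t in seq_len(config$periods)) {
      period <- play_one_period(state, params)
      state <- genetic_pool_update(state, params, period$sampled,
                                   period$payoffs)
      if (t %% config$record_every == 0L) {
        ri <- ri + 1L
        rec[ri, ] <- c(t, state)
      }
      if (t > config$burn_in) {
        sums <- sums + as.integer(state)
        corner_hits <- corner_hits + (as.integer(state) >= M - corner_margin)
      }
    }
    span <- config$periods - config$burn_in
    trace <- data.frame(period = rec[, 1], X = rec[, 2], Y = rec[, 3],
                        Z = rec[, 4])
    mean_freq <- stats::setNames(sums / (span * M), STRATEGIES)
    corner <- stats::setNames(corner_hits / span, STRATEGIES)
  }

  structure(list(trace = trace, mean_frequencies = mean_freq,
                 corner_time = corner, params = params, config = config),
            class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("Moran PGG simulation: %d periods, M = %d, seed = %d\n",
              x$config$periods, x$params$M, x$config$seed))
  cat("  mean frequencies (post burn-in):\n")
  print(round(x$mean_frequencies, 4))
  invisible(x)
}

#' Write a simulation trace to CSV
#'
#' Header `period,X,Y,Z`, one row per recorded period.
#'
#' @param trace A `sim_trace` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sim_trace"))
  utils::write.csv(trace$trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

SWEEPABLE <- c("alpha", "r", "c", "delta", "gamma", "omega", "mu", "initial")

# Documented seed-derivation scheme: the run for grid point g (1-based)
# and replicate s uses seed  base + 10007 * (g - 1) + (s - 1).
derive_seed <- function(base, grid_index, replicate) {
  as.integer(base + 10007L * (grid_index - 1L) + (replicate - 1L))
}

#' Replicated parameter sweep of the agent-based simulation
#'
#' Runs `replicates` independent simulations (seeds derived from
#' `config$seed` as `seed + 10007 * (grid_index - 1) + (replicate - 1)`)
#' at each grid value of one parameter, and summarizes the long-run mean
#' strategy frequencies.
#'
#' @param params Base [game_params()].
#' @param varying Name of the swept parameter: one of
#'   `"alpha", "r", "c", "delta", "gamma", "omega", "mu"`, or
#'   `"initial"` (initial composition; then `grid` is a list of
#'   [population_state()] objects).
#' @param grid Numeric vector of parameter values (or list of states for
#'   `"initial"`).
#' @param config A [sim_config()]; its `initial_state` and `seed` are the
#'   sweep-wide bases.
#' @param replicates Independent replicate runs per grid point.
#' @return Data frame with columns `param_name`, `param_value`,
#'   `mean_freq_C/D/P`, `sd_freq_C/D/P`, `replicates`; one row per grid
#'   point. Mean frequencies within a row sum to 1.
#' @export
parameter_sweep <- function(params, varying, grid, config, replicates = 20L) {
  stopifnot(inherits(params, "game_params"), inherits(config, "sim_config"))
  if (!(is.character(varying) && length(varying) == 1L &&
        varying %in% SWEEPABLE))
    stop("varying must be one of: ", paste(SWEEPABLE, collapse = ", "),
         call. = FALSE)
  stopifnot(replicates >= 1, length(grid) >= 1)

  rows <- lapply(seq_along(grid), function(g) {
    p <- params
    init <- config$initial_state
    if (varying == "initial") {
      init <- grid[[g]]
      value <- paste(init, collapse = "/")
    } else {
      p[[varying]] <- grid[[g]]
      p <- params_from_list(unclass(p))   # re-validate
      value <- grid[[g]]
    }
    freqs <- t(vapply(seq_len(replicates), function(s) {
      cfg <- sim_config(config$periods, derive_seed(config$seed, g, s),
                        init, burn_in = config$burn_in,
                        record_every = config$record_every)
      run_simulation(p, cfg)$mean_frequencies
    }, numeric(3)))
    data.frame(param_name = varying, param_value = value,
               mean_freq_C = mean(freqs[, 1]), mean_freq_D = mean(freqs[, 2]),
               mean_freq_P = mean(freqs[, 3]),
               sd_freq_C = stats::sd(freqs[, 1]),
               sd_freq_D = stats::sd(freqs[, 2]),
               sd_freq_P = stats::sd(freqs[, 3]),
               replicates = as.integer(replicates))
  })
  do.call(rbind, rows)
}

#' Write a parameter sweep to CSV
#'
#' Header `param_name,param_value,mean_freq_C,mean_freq_D,mean_freq_P,`
#' `sd_freq_C,sd_freq_D,sd_freq_P,replicates`.
#'
#' @param sweep Data frame from [parameter_sweep()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(is.data.frame(sweep), "param_name" %in% names(sweep))
  utils::write.csv(sweep, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
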