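#' Group composition
#'
#' Counts of the three strategies inside one sampled game group.
#'
#' @param cooperators,defectors,punishers Non-negative integer counts.
#' @return A named integer vector of class `group_comp` with entries
#'   `C`, `D`, `P`.
#' @export
group_composition <- function(cooperators, defectors, punishers) {
  v <- c(C = cooperators, D = defectors, P = punishers)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    stop("group composition counts must be non-negative integers", call. = FALSE)
  structure(as.integer(v), names = STRATEGIES, class = "group_comp")
}

as_group_comp <- function(comp) {
  if (inherits(comp, "group_comp")) return(comp)
  if (is.numeric(comp) && length(comp) == 3L)
    return(group_composition(comp[[1]], comp[[2]], comp[[3]]))
  stop("composition must be a group_composition() or a length-3 numeric vector",
       call. = FALSE)
}

#' Total production of the joint project
#'
#' Cobb-Douglas production with defector productivity fixed at zero:
#' `c * r * contributors^alpha`. For `alpha > 1` production is superlinear
#' in the number of contributors (increasing returns to scale). Zero
#' contributors produce nothing (`0^alpha = 0` for `alpha > 0`).
#'
#' @param params A [game_params()] object.
#' @param contributors Number of contributing group members (cooperators
#'   plus punishers), `0 <= contributors <= N`. Vectorized.
#' @return Total production, in payoff units.
#' @examples
#' p <- game_params(c = 1, r = 3, alpha = 1.8, N = 5)
#' total_production(p, 0:5)
#' @export
total_production <- function(params, contributors) {
  stopifnot(inherits(params, "game_params"))
  if (any(!is.finite(contributors)) || any(contributors < 0) ||
      any(contributors > params$N) || any(contributors != round(contributors)))
    stop("contributors must be integers in [0, N]", call. = FALSE)
  params$c * params$r * contributors ^ params$alpha
}

#' Per-strategy payoffs for one group composition
#'
#' Production is divided equally among all `N` group members (defectors
#' included). On top of the equal share:
#' a cooperator pays the contribution cost `c`; a defector is fined
#' `delta` by each punisher present (total `delta * z`); a punisher pays
#' the contribution cost plus `gamma` per defector fined (total
#' `gamma * y`).
#'
#' All three entries are always returned. An entry for a strategy absent
#' from the composition is the counterfactual payoff a hypothetical member
#' of that type would receive in that group; this is exactly what the
#' focal-player expected-payoff construction of the analytic module needs.
#' Payoffs may be negative (e.g. heavily fined defectors); the exponential
#' fitness map handles any sign.
#'
#' @param params A [game_params()] object.
#' @param comp A [group_composition()] (or length-3 numeric `c(x, y, z)`)
#'   summing to `N`.
#' @return Named numeric vector `c(P_x = , P_y = , P_z = )`: payoffs of a
#'   cooperator, a defector and a punisher in this group.
#' @examples
#' p <- game_params(M = 100, N = 5, c = 1, r = 3, alpha = 1)
#' group_payoffs(p, group_composition(5, 0, 0))  # all-cooperator group
#' @export
group_payoffs <- function(params, comp) {
  stopifnot(inherits(params, "game_params"))
  comp <- as_group_comp(comp)
  if (sum(comp) != params$N)
    stop("composition must sum to N = ", params$N, call. = FALSE)
  x <- comp[["C"]]; y <- comp[["D"]]; z <- comp[["P"]]
  share <- total_production(params, x + z) / params$N
  c(P_x = share - params$c,
    P_y = share - params$delta * z,
    P_z = share - params$c - params$gamma * y)
}
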