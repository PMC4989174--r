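#' Strategy labels
#'
#' The three behavioural strategies of the game, in canonical order:
#' cooperators contribute to the common pool, defectors free-ride,
#' punishers contribute and additionally fine defectors at a personal cost.
#'
#' @format Character vector `c("C", "D", "P")`.
#' @export
STRATEGIES <- c("C", "D", "P")

#' Parameters of the increasing-returns public goods game
#'
#' Bundles all model constants and validates them. The game is played in
#' groups of `N` players sampled from a well-mixed population of constant
#' size `M`. Each contributor (cooperator or punisher) pays cost `c` into a
#' joint project whose total production is `c * r * n_contributors^alpha`
#' (a Cobb-Douglas technology with defector productivity fixed at zero);
#' `alpha > 1` gives increasing returns to scale. Production is shared
#' equally among all `N` group members. Each punisher fines every defector
#' in its group by `delta` and pays `gamma` per defector fined. Payoff `P`
#' maps to reproductive fitness as `exp(omega * P)`, and offspring mutate
#' to another strategy with probability `mu`.
#'
#' @param M Population size (integer, `M >= N`).
#' @param N Group (sample) size (integer, `2 <= N <= M`).
#' @param c Contribution cost per contributor, `> 0`.
#' @param r Return multiplier, `> 1`.
#' @param alpha Scale coefficient (production exponent), `> 0`; values
#'   above 1 mean increasing returns to scale.
#' @param delta Punishment strength: fine imposed on a defector per
#'   punisher in its group, `>= 0`.
#' @param gamma Punishment cost: amount a punisher pays per defector in
#'   its group, `>= 0`.
#' @param omega Selection strength of the exponential fitness map, `> 0`.
#' @param mu Mutation rate per reproduction event, in `[0, 1)`.
#'
#' @return An object of class `game_params`.
#' @examples
#' p <- game_params(M = 100, N = 5, c = 1, r = 3, alpha = 1.8)
#' p
#' @export
game_params <- function(M = 100, N = 5, c = 1, r = 3, alpha = 1,
                        delta = 1, gamma = 0.3, omega = 0.1, mu = 0) {
  stop_unless <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  stop_unless(num1(M) && M >= 1 && M == round(M), "M must be a positive integer")
  stop_unless(num1(N) && N == round(N) && N >= 2 && N <= M,
              "N must be an integer with 2 <= N <= M")
  stop_unless(num1(c) && c > 0, "c must be > 0")
  stop_unless(num1(r) && r > 1, "r must be > 1")
  stop_unless(num1(alpha) && alpha > 0, "alpha must be > 0")
  stop_unless(num1(delta) && delta >= 0, "delta must be >= 0")
  stop_unless(num1(gamma) && gamma >= 0, "gamma must be >= 0")
  stop_unless(num1(omega) && omega > 0, "omega must be > 0")
  stop_unless(num1(mu) && mu >= 0 && mu < 1, "mu must be in [0, 1)")
  structure(
    list(M = as.integer(M), N = as.integer(N), c = c, r = r, alpha = alpha,
         delta = delta, gamma = gamma, omega = omega, mu = mu),
    class = "game_params"
  )
}

#' @export
print.game_params <- function(x, ...) {
  cat("Public goods game parameters\n")
  cat(sprintf("  population M = %d, group size N = %d\n", x$M, x$N))
  cat(sprintf("  cost c = %g, multiplier r = %g, scale alpha = %g\n",
              x$c, x$r, x$alpha))
  cat(sprintf("  punishment delta = %g, gamma = %g\n", x$delta, x$gamma))
  cat(sprintf("  selection omega = %g, mutation mu = %g\n", x$omega, x$mu))
  invisible(x)
}

.PARAM_KEYS <- c("M", "N", "c", "r", "alpha", "delta", "gamma", "omega", "mu")

#' Convert game parameters to a flat named list
#'
#' @param params A `game_params` object.
#' @return A plain named list with keys
#'   `M, N, c, r, alpha, delta, gamma, omega, mu`.
#' @export
params_to_list <- function(params) {
  stopifnot(inherits(params, "game_params"))
  out <- unclass(params)[.PARAM_KEYS]
  out$M <- as.integer(out$M); out$N <- as.integer(out$N)
  out
}

#' Build game parameters from a flat key-value list
#'
#' Unknown keys are ignored (so a full run config can be passed through);
#' missing keys fall back to the `game_params()` defaults.
#'
#' @param x A named list, e.g. parsed from YAML or JSON.
#' @return A `game_params` object.
#' @export
params_from_list <- function(x) {
  stopifnot(is.list(x))
  args <- x[intersect(names(x), .PARAM_KEYS)]
  do.call(game_params, args)
}

#' Read game parameters from a YAML or JSON config file
#'
#' The format is chosen by file extension (`.yaml`/`.yml` vs `.json`).
#' The file is a flat mapping using the keys
#' `M, N, c, r, alpha, delta, gamma, omega, mu`; extra run keys
#' (`periods`, `seed`, ...) are tolerated and ignored here.
#'
#' @param path Path to the config file.
#' @return A `game_params` object.
#' @export
read_params_config <- function(path) {
  x <- read_flat_config(path)
  params_from_list(x)
}

# Parse a flat YAML/JSON mapping; shared by parameter and run configs.
read_flat_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("config must be .yaml, .yml or .json, got: ", ext, call. = FALSE)
  )
  if (!is.list(x)) stop("config must be a flat key-value mapping", call. = FALSE)
  x
}

#' Write game parameters (plus optional run keys) to a config file
#'
#' @param params A `game_params` object.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @param extra Named list of additional run keys (e.g. `seed`, `periods`)
#'   merged alongside the parameter keys.
#' @return `path`, invisibly.
#' @export
write_params_config <- function(params, path, extra = list()) {
  x <- c(params_to_list(params), extra)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml = yaml::write_yaml(x, path),
    stop("config must be .yaml, .yml or .json, got: ", ext, call. = FALSE)
  )
  invisible(path)
}
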