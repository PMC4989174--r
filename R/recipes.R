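#' @section Canned experiment recipes:
#' The package ships named recipes reproducing the three headline
#' experiments: the analytic scan of the stationary distribution against
#' the scale coefficient (`fig2`), two long agent-based traces at
#' constant (`fig3a`) and strongly increasing (`fig3b`) returns to scale,
#' and nine replicated parameter sweeps (`fig4_a` ... `fig4_i`).
#' @name pggirs-recipes
#' @keywords internal
NULL

# Baseline parameter set shared by the headline experiments.
.BASE_ANALYTIC <- list(M = 100L, N = 5L, c = 1, r = 3, alpha = 1,
                       delta = 1, gamma = 0.3, omega = 0.1, mu = 0)
.BASE_SIM <- list(M = 100L, N = 5L, c = 1, r = 3, alpha = 1,
                  delta = 1, gamma = 0.3, omega = 0.5, mu = 0.001)
.BASE_INIT <- c(X = 30L, Y = 40L, Z = 30L)

# Recipe registry. Sweep grids are package defaults (the figure captions
# fix the non-swept parameters but not the grids). Panel d sweeps the
# return multiplier at constant returns (alpha = 1); panels e-i sweep
# their parameter in the increasing-returns regime (alpha = 1.8); panels
# a-c sweep alpha itself from monomorphic initial compositions.
recipe_registry <- function() {
  sweep_recipe <- function(varying, grid, overrides = list(),
                           init = .BASE_INIT) {
    list(kind = "sweep", params = utils::modifyList(.BASE_SIM, overrides),
         varying = varying, grid = grid, init = init,
         periods = 100000L, replicates = 20L, burn_in = 0L)
  }
  list(
    fig2 = list(kind = "scan", params = .BASE_ANALYTIC,
                grid = seq(1, 2, by = 0.1)),
    fig3a = list(kind = "trace",
                 params = utils::modifyList(.BASE_SIM, list(alpha = 1.0)),
                 init = .BASE_INIT, periods = 100000L, burn_in = 0L,
                 record_every = 10L),
    fig3b = list(kind = "trace",
                 params = utils::modifyList(.BASE_SIM, list(alpha = 1.8)),
                 init = .BASE_INIT, periods = 100000L, burn_in = 0L,
                 record_every = 10L),
    fig4_a = sweep_recipe("alpha", seq(1.0, 1.5, by = 0.1),
                          init = c(X = 100L, Y = 0L, Z = 0L)),
    fig4_b = sweep_recipe("alpha", seq(1.0, 1.5, by = 0.1),
                          init = c(X = 0L, Y = 100L, Z = 0L)),
    fig4_c = sweep_recipe("alpha", seq(1.0, 1.5, by = 0.1),
                          init = c(X = 0L, Y = 0L, Z = 100L)),
    fig4_d = sweep_recipe("r", seq(1.5, 5, by = 0.5),
                          overrides = list(alpha = 1.0)),
    fig4_e = sweep_recipe("c", seq(0.5, 2, by = 0.25),
                          overrides = list(alpha = 1.8)),
    fig4_f = sweep_recipe("delta", seq(0, 2, by = 0.25),
                          overrides = list(alpha = 1.8)),
    fig4_g = sweep_recipe("gamma", seq(0, 1, by = 0.1),
                          overrides = list(alpha = 1.8)),
    fig4_h = sweep_recipe("omega", c(0.1, 0.25, 0.5, 0.75, 1),
                          overrides = list(alpha = 1.8)),
    fig4_i = sweep_recipe("mu", c(1e-4, 3e-4, 1e-3, 3e-3, 1e-2),
                          overrides = list(alpha = 1.8))
  )
}

#' List the available experiment recipes
#'
#' @return Character vector of recipe names.
#' @export
list_recipes <- function() names(recipe_registry())

.RUN_KEYS <- c("periods", "replicates", "burn_in", "record_every",
               "X", "Y", "Z", "grid", "varying")

#' Run a canned experiment recipe
#'
#' Executes one registered recipe (see [list_recipes()]) with optional
#' overrides, writes its CSV output and a JSON run manifest into
#' `out_dir`, and returns the computed result. The manifest is flat and
#' can be re-fed as a `--config` file to reproduce the run exactly.
#'
#' @param name Recipe name, e.g. `"fig2"`, `"fig3b"`, `"fig4_a"`.
#' @param overrides Named list overriding parameter keys
#'   (`M, N, c, r, alpha, delta, gamma, omega, mu`) or run keys
#'   (`periods, replicates, burn_in, record_every, X, Y, Z, grid,
#'   varying`).
#' @param out_dir Output directory (created if missing).
#' @param seed Base RNG seed (ignored by the deterministic `fig2` scan).
#' @param scale Speed factor for scaled-down runs: periods and replicates
#'   are divided by `scale` (floors of 1000 periods / 1 replicate);
#'   recorded in the manifest.
#' @param quiet Suppress progress messages.
#' @return The result object (scan data frame, `sim_trace`, or sweep
#'   data frame) with attribute `files` naming the written outputs.
#' @export
run_recipe <- function(name, overrides = list(), out_dir = ".", seed = 1L,
                       scale = 1, quiet = FALSE) {
  reg <- recipe_registry()
  if (!(is.character(name) && length(name) == 1L && name %in% names(reg)))
    stop("unknown recipe '", name, "'; see list_recipes()", call. = FALSE)
  bad <- setdiff(names(overrides), c(.PARAM_KEYS, .RUN_KEYS))
  if (length(bad))
    stop("invalid override keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)

  rec <- reg[[name]]
  rec$params <- utils::modifyList(rec$params,
                                  overrides[intersect(names(overrides),
                                                      .PARAM_KEYS)])
  for (k in intersect(names(overrides), .RUN_KEYS)) {
    if (k %in% c("X", "Y", "Z")) rec$init[[k]] <- overrides[[k]]
    else rec[[k]] <- overrides[[k]]
  }
  if (scale != 1) {
    rec$periods <- max(1000L, as.integer(rec$periods / scale))
    if (!is.null(rec$replicates))
      rec$replicates <- max(1L, as.integer(rec$replicates / scale))
  }
  params <- params_from_list(rec$params)
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (!quiet) message(sprintf(...))

  if (rec$kind == "scan") {
    say("[%s] analytic scan over %d grid points", name, length(rec$grid))
    result <- alpha_scan(params, rec$grid)
    out_csv <- file.path(out_dir, paste0(name, "_scan.csv"))
    write_alpha_scan(result, out_csv)
  } else if (rec$kind == "trace") {
    say("[%s] simulating %d periods (seed %d)", name, rec$periods, seed)
    cfg <- sim_config(rec$periods, seed,
                      population_state(rec$init[["X"]], rec$init[["Y"]],
                                       rec$init[["Z"]]),
                      burn_in = rec$burn_in,
                      record_every = rec$record_every)
    result <- run_simulation(params, cfg)
    out_csv <- file.path(out_dir, paste0(name, "_trace.csv"))
    write_trace(result, out_csv)
  } else {
    say("[%s] sweeping %s over %d grid points x %d replicates x %d periods",
        name, rec$varying, length(rec$grid), rec$replicates, rec$periods)
    cfg <- sim_config(rec$periods, seed,
                      population_state(rec$init[["X"]], rec$init[["Y"]],
                                       rec$init[["Z"]]),
                      burn_in = rec$burn_in, record_every = rec$periods)
    result <- parameter_sweep(params, rec$varying, rec$grid, cfg,
                              replicates = rec$replicates)
    out_csv <- file.path(out_dir, paste0(name, "_sweep.csv"))
    write_sweep(result, out_csv)
  }

  manifest <- c(list(recipe = name), params_to_list(params),
                rec[intersect(names(rec),
                              c("periods", "replicates", "burn_in",
                                "record_every", "varying", "grid"))],
                if (!is.null(rec$init))
                  list(X = rec$init[["X"]], Y = rec$init[["Y"]],
                       Z = rec$init[["Z"]]),
                list(seed = as.integer(seed), scale = scale,
                     code_version =
                       as.character(utils::packageVersion("pggirs")),
                     wall_time_s = proc.time()[["elapsed"]] - t0,
                     outputs = basename(out_csv)))
  out_json <- file.path(out_dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, out_json, auto_unbox = TRUE, digits = NA)
  say("[%s] wrote %s and %s (%.1f s)", name, basename(out_csv),
      basename(out_json), manifest$wall_time_s)

  attr(result, "files") <- c(csv = out_csv, manifest = out_json)
  invisible(result)
}
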