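# Simulation scenarios and parameter-space exploration.
#
# Three biological scenarios are encoded: basal production throughout the
# tissue with no initial auxin; a basal initial auxin pool with no
# production; and an auxin source confined to the Frankia compartment of
# infected cells (the Frankia-source scenario is run at a low and a high
# source strength).

SCENARIO_NAMES <- c("production_only", "initial_pool",
                    "frankia_source_low", "frankia_source_high")

#' Define a simulation scenario
#'
#' A scenario is a named set of overrides of the source-related parameters
#' (`sigma`, `a0`, `s_frankia`) with invariants: `production_only` has
#' production but no initial auxin and no Frankia source; `initial_pool` has
#' only an initial pool (its observable is the normalized concentration
#' profile, since the absolute level decays to zero); the `frankia_source_*`
#' scenarios have only the Frankia-compartment source, at strength 1 (low)
#' or 10 (high).
#'
#' @param name one of `"production_only"`, `"initial_pool"`,
#'   `"frankia_source_low"`, `"frankia_source_high"`.
#' @param sigma,a0,s_frankia optional non-default magnitudes for the
#'   scenario's active knob(s); inactive knobs are pinned to zero.
#' @return a `scenario` list with `name` and `overrides`.
#' @export
scenario <- function(name = SCENARIO_NAMES, sigma = NULL, a0 = NULL, s_frankia = NULL) {
  name <- match.arg(name)
  ov <- switch(name,
    production_only = list(sigma = if (is.null(sigma)) 0.1 else sigma,
                           a0 = 0, s_frankia = 0),
    initial_pool = list(sigma = 0, a0 = if (is.null(a0)) 1 else a0, s_frankia = 0),
    frankia_source_low = list(sigma = 0, a0 = 0,
                              s_frankia = if (is.null(s_frankia)) 1 else s_frankia),
    frankia_source_high = list(sigma = 0, a0 = 0,
                               s_frankia = if (is.null(s_frankia)) 10 else s_frankia))
  sc <- structure(list(name = name, overrides = ov), class = "scenario")
  check_scenario(sc)
  sc
}

check_scenario <- function(sc) {
  ov <- sc$overrides
  ok <- switch(sc$name,
    production_only = ov$a0 == 0 && ov$sigma > 0 && ov$s_frankia == 0,
    initial_pool = ov$a0 > 0 && ov$sigma == 0 && ov$s_frankia == 0,
    frankia_source_low = ,
    frankia_source_high = ov$s_frankia > 0 && ov$a0 == 0 && ov$sigma == 0)
  if (!ok) stopf("scenario '%s' violates its invariants", sc$name)
  invisible(sc)
}

#' Run one scenario on a tissue and carrier layout
#'
#' Applies the scenario overrides to `base_params` and integrates to steady
#' state with [simulate_fluxes()] (`method = "simulate"`), or solves directly
#' (`method = "direct"`, using [steady_state_direct()] for sourced scenarios
#' and [quasi_stationary_profile()] for `initial_pool`). For `initial_pool`
#' the captured result is the quasi-stationary normalized profile: the
#' absolute level decays to zero and only the pattern is meaningful.
#'
#' @param tissue a `nodule_tissue`.
#' @param layout a matching `carrier_layout` (or preset name).
#' @param base_params a [model_params()].
#' @param sc a [scenario()] or scenario name.
#' @param method `"simulate"` (explicit integration) or `"direct"` (linear
#'   solve / eigenmode; fast path).
#' @return a `simulation_result` with `$scenario` set.
#' @export
run_scenario <- function(tissue, layout, base_params = model_params(),
                         sc = scenario("production_only"),
                         method = c("simulate", "direct")) {
  method <- match.arg(method)
  if (is.character(sc)) sc <- scenario(sc)
  check_scenario(sc)
  layout <- place_carriers(tissue, layout)
  params <- do.call(update_params, c(list(base_params), sc$overrides))
  if (method == "simulate") {
    res <- simulate_fluxes(tissue, layout, params,
                           stop_on = if (sc$name == "initial_pool") "profile" else "rate")
  } else {
    st <- if (sc$name == "initial_pool") {
      quasi_stationary_profile(tissue, layout, params)
    } else {
      steady_state_direct(tissue, layout, params)
    }
    res <- structure(list(final_state = st, converged = TRUE, n_steps = 0L,
                          time = Inf, dt_used = NA_real_,
                          stop_on = if (sc$name == "initial_pool") "profile" else "rate",
                          params = params, tissue_cells = nrow(tissue$cells)),
                     class = "simulation_result")
  }
  res$scenario <- sc$name
  res
}

#' Run the full virtual-nodule experiment
#'
#' Generates one synthetic nodule tissue per seed, applies a carrier layout
#' preset, runs every scenario, and classifies each steady-state pattern.
#'
#' @param tissue_seeds integer seeds for [generate_nodule_tissue()] (default
#'   `c(1, 2, 3)`, i.e. three independent virtual nodules).
#' @param params base [model_params()].
#' @param layout carrier-layout preset (default `"discaria"`).
#' @param scenarios character vector of scenario names (default all four).
#' @param gen_spec base [nodule_spec()]; its `seed` field is replaced by
#'   each entry of `tissue_seeds`.
#' @param method passed to [run_scenario()].
#' @param epsilon relative margin for [classify_pattern()].
#' @return list with `tissues`, `results` (nested by seed then scenario),
#'   `calls` (list of `pattern_call`) and `summary` (one row per run:
#'   seed, scenario, layout, label, margin, per-type means, converged).
#' @export
run_figure7 <- function(tissue_seeds = c(1, 2, 3), params = model_params(),
                        layout = "discaria", scenarios = SCENARIO_NAMES,
                        gen_spec = nodule_spec(), method = c("simulate", "direct"),
                        epsilon = 0.01) {
  method <- match.arg(method)
  tissues <- lapply(tissue_seeds, function(s) {
    sp <- gen_spec
    sp$seed <- as.integer(s)
    generate_nodule_tissue(sp)
  })
  names(tissues) <- paste0("seed", tissue_seeds)
  results <- list()
  calls <- list()
  rows <- list()
  for (ti in seq_along(tissues)) {
    tissue <- tissues[[ti]]
    lay <- place_carriers(tissue, layout)
    for (scn in scenarios) {
      res <- run_scenario(tissue, lay, params, scenario(scn), method = method)
      call <- classify_pattern(res, tissue, epsilon = epsilon)
      call$scenario <- scn
      call$layout <- if (is.character(layout)) layout else "custom"
      call$tissue_seed <- tissue_seeds[ti]
      key <- sprintf("seed%s_%s", tissue_seeds[ti], scn)
      results[[key]] <- res
      calls[[key]] <- call
      rows[[key]] <- data.frame(tissue_seed = tissue_seeds[ti], scenario = scn,
                                layout = call$layout, label = call$label,
                                margin = call$margin,
                                mean_infected = call$mean_by_type[["infected"]],
                                mean_uninfected = call$mean_by_type[["uninfected"]],
                                mean_meristem = call$mean_by_type[["meristematic"]],
                                converged = res$converged)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(tissues = tissues, results = results, calls = calls, summary = summary)
}

#' Specification of a parameter-space sweep
#'
#' The default grid spans two decades around each transport parameter
#' (passive wall permeability, PIN and AUX1 coefficients) plus a source
#' scale, 4 values each, 256 configurations, on the *D. trinervis* layout
#' under the Frankia-source scenario (the biologically motivated source of
#' auxin in infected cells).
#'
#' @param grid named list of parameter values: `d_wall`, `p_pin`, `p_aux`,
#'   `source_scale` (the latter multiplies the scenario's active source
#'   knob). Duplicate values are removed.
#' @param layouts character vector of layout presets.
#' @param scenarios character vector of scenario names.
#' @param delta decay rate (fixed > 0 across the sweep).
#' @param seed tissue-generation seed used when [sweep_parameters()] has to
#'   generate its own tissue.
#' @return a `sweep_spec`.
#' @export
sweep_spec <- function(grid = list(d_wall = c(0.1, 0.3, 1, 3),
                                   p_pin = c(0.1, 1, 10, 100),
                                   p_aux = c(0.1, 1, 10, 100),
                                   source_scale = c(0.1, 1, 10, 100)),
                       layouts = "discaria",
                       scenarios = "frankia_source_low",
                       delta = 0.1, seed = 1L) {
  stopifnot(length(grid) > 0)
  need <- c("d_wall", "p_pin", "p_aux", "source_scale")
  missing <- setdiff(need, names(grid))
  for (nm in missing) grid[[nm]] <- 1
  grid <- lapply(grid[need], function(v) sort(unique(as.numeric(v))))
  if (any(unlist(grid) < 0)) stopf("grid values must be nonnegative")
  if (delta <= 0) stopf("delta must stay positive across the sweep")
  stopifnot(all(scenarios %in% SCENARIO_NAMES))
  structure(list(grid = grid, layouts = layouts, scenarios = scenarios,
                 delta = delta, seed = as.integer(seed)),
            class = "sweep_spec")
}

#' Exhaustive grid evaluation of the transport model
#'
#' Evaluates every configuration of the sweep grid x layouts x scenarios on
#' one tissue, using the direct solve (fast path), classifies each
#' steady-state pattern, and returns one row per configuration in
#' deterministic order. Per-row failures are recorded in the `error` column
#' and never abort the sweep.
#'
#' @param sweep a [sweep_spec()].
#' @param tissue a `nodule_tissue`; if `NULL`, one nodule tissue is
#'   generated from `nodule_spec(seed = sweep$seed)`.
#' @param base_params template [model_params()] (its `delta` is replaced by
#'   the sweep's).
#' @param epsilon relative margin for [classify_pattern()].
#' @return data.frame with columns `config_id`, `d_wall`, `p_pin`, `p_aux`,
#'   `source_scale`, `scenario`, `layout`, `pattern`, `margin`,
#'   `mean_infected`, `mean_uninfected`, `mean_meristem`, `converged`,
#'   `error`.
#' @export
sweep_parameters <- function(sweep = sweep_spec(), tissue = NULL,
                             base_params = model_params(), epsilon = 0.01) {
  stopifnot(inherits(sweep, "sweep_spec"))
  if (is.null(tissue)) tissue <- generate_nodule_tissue(nodule_spec(seed = sweep$seed))
  configs <- expand.grid(d_wall = sweep$grid$d_wall, p_pin = sweep$grid$p_pin,
                         p_aux = sweep$grid$p_aux,
                         source_scale = sweep$grid$source_scale,
                         scenario = sweep$scenarios, layout = sweep$layouts,
                         stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  layouts <- lapply(stats::setNames(sweep$layouts, sweep$layouts),
                    function(l) place_carriers(tissue, l))
  rows <- vector("list", nrow(configs))
  for (i in seq_len(nrow(configs))) {
    cf <- configs[i, ]
    row <- data.frame(config_id = i, d_wall = cf$d_wall, p_pin = cf$p_pin,
                      p_aux = cf$p_aux, source_scale = cf$source_scale,
                      scenario = cf$scenario, layout = cf$layout,
                      pattern = NA_character_, margin = NA_real_,
                      mean_infected = NA_real_, mean_uninfected = NA_real_,
                      mean_meristem = NA_real_, converged = NA, error = "")
    out <- tryCatch({
      sc <- switch(cf$scenario,
                   production_only = scenario("production_only", sigma = 0.1 * cf$source_scale),
                   initial_pool = scenario("initial_pool", a0 = cf$source_scale),
                   frankia_source_low = scenario("frankia_source_low", s_frankia = 1 * cf$source_scale),
                   frankia_source_high = scenario("frankia_source_high", s_frankia = 10 * cf$source_scale))
      params <- update_params(base_params, d_wall = cf$d_wall, p_pin = cf$p_pin,
                              p_aux = cf$p_aux, delta = sweep$delta)
      res <- run_scenario(tissue, layouts[[cf$layout]], params, sc, method = "direct")
      call <- classify_pattern(res, tissue, epsilon = epsilon)
      row$pattern <- call$label
      row$margin <- call$margin
      row$mean_infected <- call$mean_by_type[["infected"]]
      row$mean_uninfected <- call$mean_by_type[["uninfected"]]
      row$mean_meristem <- call$mean_by_type[["meristematic"]]
      row$converged <- res$converged
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    rows[[i]] <- out
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "sweep_spec") <- sweep
  out
}

#' Filter a sweep table for configurations matching a target pattern
#'
#' @param table a [sweep_parameters()] result.
#' @param target_pattern a pattern label (e.g. `"infected_and_meristem"`).
#' @return the matching rows.
#' @export
find_reproducing_configs <- function(table, target_pattern) {
  table[!is.na(table$pattern) & table$pattern == target_pattern, , drop = FALSE]
}
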