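# Carrier-mediated auxin transport dynamics.
#
# The model is linear in the per-cell auxin concentration a (amount per unit
# area, nondimensional). For cells i, j sharing a wall, the flux per unit
# wall length, positive from i to j, is
#
#   J(i->j) = [d_wall + p_pin * pin(i-side)] * a_i
#           - [d_wall + p_pin * pin(j-side)] * a_j
#           + p_aux * aux(j-side) * a_i
#           - p_aux * aux(i-side) * a_j
#
# Efflux carriers on a membrane push auxin out of their cell; influx carriers
# pull auxin into their cell from the neighbor (the carrier model stands in
# for the apoplast pool, which is not an explicit compartment). Each cell
# then obeys
#
#   da_i/dt = (1/area_i) * sum_j wall_length(ij) * J(j->i)
#           + sigma + s_frankia * [has_frankia_i] - delta * a_i
#
# The dynamics are affine, da/dt = M a + c, with M a Metzler matrix whose
# transport part conserves area-weighted total amount; delta > 0 makes M
# strictly stable so the steady state exists, is unique, nonnegative, and
# solvable directly (steady_state_direct), which is the precision reference
# for the explicit-Euler integrator (simulate_fluxes).

#' Transport-model parameters
#'
#' All quantities are nondimensional; geometry is in pixel units of the
#' digitized tissue. Defaults make carrier-mediated transport dominate
#' passive wall permeability tenfold.
#'
#' @param d_wall background (passive) wall permeability per unit wall length
#'   (default 1).
#' @param p_aux influx-carrier permeability coefficient, multiplies the
#'   membrane `aux` density (default 10).
#' @param p_pin efflux-carrier permeability coefficient, multiplies the
#'   membrane `pin` density (default 10).
#' @param sigma basal auxin production rate per unit area in every cell
#'   (default 0.1; scenario-dependent).
#' @param delta first-order auxin decay rate (default 0.1). Strict
#'   positivity guarantees a unique bounded steady state and is required by
#'   [steady_state_direct()]; `delta = 0` is allowed for closed-tissue
#'   conservation runs of the integrator.
#' @param s_frankia extra source rate in cells with a Frankia compartment
#'   (default 1; scenario-dependent).
#' @param a0 initial uniform auxin level (default 1; scenario-dependent).
#' @param dt requested integration step (default 0.05). The integrator
#'   enforces the explicit-step stability bound
#'   `dt * max_i(total outflow rate per unit area + delta) < 1` by reducing
#'   dt when necessary, which also preserves nonnegativity.
#' @param t_max integration horizon (default 2000).
#' @param steady_tol relative steady-state tolerance (default 1e-8; 0 turns
#'   early stopping off, so integration always runs to `t_max`).
#' @return a `model_params` list.
#' @export
model_params <- function(d_wall = 1, p_aux = 10, p_pin = 10, sigma = 0.1,
                         delta = 0.1, s_frankia = 1, a0 = 1,
                         dt = 0.05, t_max = 2000, steady_tol = 1e-8) {
  p <- list(d_wall = d_wall, p_aux = p_aux, p_pin = p_pin, sigma = sigma,
            delta = delta, s_frankia = s_frankia, a0 = a0, dt = dt,
            t_max = t_max, steady_tol = steady_tol)
  for (nm in c("d_wall", "p_aux", "p_pin", "sigma", "s_frankia", "a0", "delta",
               "steady_tol")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) || p[[nm]] < 0) {
      stopf("%s must be a nonnegative finite scalar", nm)
    }
  }
  for (nm in c("dt", "t_max")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) || p[[nm]] <= 0) {
      stopf("%s must be a positive finite scalar", nm)
    }
  }
  structure(p, class = "model_params")
}

#' Update selected fields of a parameter set
#'
#' @param params a `model_params`.
#' @param ... fields to override (revalidated).
#' @return a `model_params`.
#' @export
update_params <- function(params, ...) {
  dots <- list(...)
  bad <- setdiff(names(dots), names(params))
  if (length(bad) > 0) stopf("unknown parameter(s): %s", paste(bad, collapse = ", "))
  p <- unclass(params)
  p[names(dots)] <- dots
  do.call(model_params, p)
}

check_sim_inputs <- function(tissue, layout, params) {
  stopifnot(inherits(params, "model_params"))
  bad <- validate_layout(layout, tissue)
  if (length(bad) > 0) stopf("mismatched tissue/layout: %s", paste(bad, collapse = "; "))
}

#' Assemble the affine rate operator of the transport model
#'
#' Returns `M` (dense matrix) and `c` (source vector) such that the per-cell
#' rate of change is exactly `M %*% a + c` for any concentration vector `a`
#' ordered as `tissue$cells`. The transport part of `M` has area-weighted
#' column sums of zero (amount conservation); the diagonal additionally
#' carries the decay `-delta`.
#'
#' @param tissue a `nodule_tissue`.
#' @param layout a matching `carrier_layout`.
#' @param params a [model_params()].
#' @return list with `M`, `c`, `cell_id`, and `max_outflow` (the stability
#'   bound `max_i |M_ii|`).
#' @export
build_rate_operator <- function(tissue, layout, params) {
  check_sim_inputs(tissue, layout, params)
  n <- nrow(tissue$cells)
  ids <- tissue$cells$cell_id
  area <- tissue$cells$area
  M <- matrix(0, n, n)
  ifs <- tissue$interfaces
  if (nrow(ifs) > 0) {
    ia <- match(ifs$cell_a, ids)
    ib <- match(ifs$cell_b, ids)
    w <- ifs$wall_length
    # J(a->b) = coef_a * x_a + coef_b * x_b  (per unit wall length)
    coef_a <- params$d_wall + params$p_pin * layout$pin_a + params$p_aux * layout$aux_b
    coef_b <- -(params$d_wall + params$p_pin * layout$pin_b + params$p_aux * layout$aux_a)
    for (k in seq_len(nrow(ifs))) {
      i <- ia[k]; j <- ib[k]
      M[i, i] <- M[i, i] - w[k] * coef_a[k] / area[i]
      M[i, j] <- M[i, j] - w[k] * coef_b[k] / area[i]
      M[j, i] <- M[j, i] + w[k] * coef_a[k] / area[j]
      M[j, j] <- M[j, j] + w[k] * coef_b[k] / area[j]
    }
  }
  diag(M) <- diag(M) - params$delta
  cvec <- rep(params$sigma, n) + params$s_frankia * as.numeric(tissue$cells$has_frankia)
  list(M = M, c = cvec, cell_id = ids, max_outflow = max(abs(diag(M))))
}

#' Per-cell rate of change of auxin concentration
#'
#' The definitional interface-by-interface evaluation of the flux law (see
#' the package vignette); [build_rate_operator()] is verified against it.
#'
#' @param state numeric vector of concentrations ordered as `tissue$cells`.
#' @param tissue a `nodule_tissue`.
#' @param layout a matching `carrier_layout`.
#' @param params a [model_params()].
#' @return numeric rate vector (same order), with attribute `bookkeeping`
#'   holding total production, decay and net transport for conservation
#'   checks.
#' @export
cell_dynamics_rate <- function(state, tissue, layout, params) {
  check_sim_inputs(tissue, layout, params)
  n <- nrow(tissue$cells)
  if (length(state) != n) stopf("state length %d != %d cells", length(state), n)
  ids <- tissue$cells$cell_id
  area <- tissue$cells$area
  rate <- rep(params$sigma, n) +
    params$s_frankia * as.numeric(tissue$cells$has_frankia) -
    params$delta * state
  ifs <- tissue$interfaces
  transport <- numeric(n)
  for (k in seq_len(nrow(ifs))) {
    i <- match(ifs$cell_a[k], ids)
    j <- match(ifs$cell_b[k], ids)
    J_ij <- (params$d_wall + params$p_pin * layout$pin_a[k]) * state[i] -
      (params$d_wall + params$p_pin * layout$pin_b[k]) * state[j] +
      params$p_aux * layout$aux_b[k] * state[i] -
      params$p_aux * layout$aux_a[k] * state[j]
    flow <- ifs$wall_length[k] * J_ij
    transport[i] <- transport[i] - flow / area[i]
    transport[j] <- transport[j] + flow / area[j]
  }
  out <- rate + transport
  attr(out, "bookkeeping") <- list(
    production = sum(area * (params$sigma + params$s_frankia * tissue$cells$has_frankia)),
    decay = sum(area * params$delta * state),
    net_transport = sum(area * transport))
  out
}

#' Steady state by direct linear solve
#'
#' Solves `M a + c = 0` for the unique steady state (requires `delta > 0`,
#' which makes `M` nonsingular and stable). This is the independent
#' precision reference for [simulate_fluxes()].
#'
#' @inheritParams build_rate_operator
#' @return an `auxin_state`: named concentration vector with attribute
#'   `time = Inf`.
#' @export
steady_state_direct <- function(tissue, layout, params) {
  if (params$delta <= 0) stopf("steady_state_direct requires delta > 0")
  op <- build_rate_operator(tissue, layout, params)
  a <- tryCatch(solve(op$M, -op$c),
                error = function(e) stopf("singular transport system: %s", conditionMessage(e)))
  # round-off can leave tiny negative entries in an exactly-zero component
  a[a < 0 & a > -1e-12 * max(abs(a), 1)] <- 0
  new_auxin_state(a, op$cell_id, time = Inf)
}

#' Quasi-stationary normalized concentration profile
#'
#' For source-free decaying dynamics (`sigma = s_frankia = 0`) the absolute
#' steady state is zero, but the shape `a / sum(a)` converges to the dominant
#' eigenvector of the transport operator (uniform decay does not affect the
#' shape). This computes that limit directly by eigendecomposition.
#'
#' @inheritParams build_rate_operator
#' @return an `auxin_state` normalized to `sum(a) == 1`.
#' @export
quasi_stationary_profile <- function(tissue, layout, params) {
  op <- build_rate_operator(tissue, layout, params)
  eg <- eigen(op$M)
  k <- which.max(Re(eg$values))
  v <- Re(eg$vectors[, k])
  if (sum(v) < 0) v <- -v
  v[v < 0 & abs(v) < 1e-10 * max(abs(v))] <- 0
  if (any(v < 0)) stopf("dominant mode is not nonnegative; tissue may be degenerate")
  new_auxin_state(v / sum(v), op$cell_id, time = Inf)
}

new_auxin_state <- function(a, cell_id, time) {
  structure(stats::setNames(as.numeric(a), cell_id), time = time,
            class = "auxin_state")
}

#' Integrate the transport dynamics to steady state
#'
#' Explicit Euler integration of `da/dt = M a + c` from the uniform initial
#' state `a0`. The step size is capped at the stability bound
#' `0.9 / max_i |M_ii|`, which keeps the update matrix `I + dt M`
#' nonnegative and hence preserves nonnegativity of the state without any
#' clipping. Integration stops when the convergence criterion falls below
#' `params$steady_tol` or `t_max` is reached.
#'
#' Two stopping modes: `"rate"` (default) monitors
#' `max_i |da_i/dt| / max(max_i a_i, 1e-12)`; `"profile"` monitors the
#' change per unit time of the normalized profile `a / sum(a)` and is meant
#' for source-free decaying scenarios where only the pattern converges.
#'
#' @inheritParams build_rate_operator
#' @param a0 optional initial concentration vector (default: uniform
#'   `params$a0`).
#' @param stop_on `"rate"` or `"profile"`.
#' @param record_trajectory if `TRUE`, sample the state every
#'   `trajectory_every` steps into `result$trajectory`.
#' @param trajectory_every sampling stride (default 100 steps).
#' @return a `simulation_result`: list with `final_state` (an
#'   `auxin_state`; normalized to total 1 in profile mode), `converged`,
#'   `n_steps`, `time`, `dt_used`, and optionally `trajectory` (data.frame
#'   time, cell_id, concentration).
#' @export
simulate_fluxes <- function(tissue, layout, params, a0 = NULL,
                            stop_on = c("rate", "profile"),
                            record_trajectory = FALSE, trajectory_every = 100L) {
  stop_on <- match.arg(stop_on)
  op <- build_rate_operator(tissue, layout, params)
  n <- length(op$cell_id)
  a <- if (is.null(a0)) rep(params$a0, n) else {
    if (length(a0) != n) stopf("a0 length %d != %d cells", length(a0), n)
    as.numeric(a0)
  }
  dt <- params$dt
  dt_cap <- 0.9 / max(op$max_outflow, .Machine$double.eps)
  if (dt > dt_cap) {
    dt <- dt_cap
    message(sprintf("simulate_fluxes: dt reduced to %.3g to satisfy the stability bound", dt))
  }
  check_every <- 25L
  n_max <- ceiling(params$t_max / dt)
  traj <- if (record_trajectory) list() else NULL
  converged <- FALSE
  step <- 0L
  prev_profile <- if (stop_on == "profile") a / max(sum(a), .Machine$double.eps) else NULL
  prev_profile_step <- 0L
  while (step < n_max) {
    rate <- drop(op$M %*% a) + op$c
    a_new <- a + dt * rate
    if (any(!is.finite(a_new))) {
      stopf("divergence: non-finite concentration at step %d (t = %g)", step + 1L, (step + 1L) * dt)
    }
    a <- a_new
    step <- step + 1L
    if (record_trajectory && (step %% trajectory_every == 0L || step == 1L)) {
      traj[[length(traj) + 1L]] <- data.frame(time = step * dt,
                                              cell_id = op$cell_id,
                                              concentration = a)
    }
    if (step %% check_every == 0L) {
      if (stop_on == "rate") {
        crit <- max(abs(drop(op$M %*% a) + op$c)) / max(max(a), 1e-12)
        if (crit < params$steady_tol) { converged <- TRUE; break }
      } else {
        profile <- a / max(sum(a), .Machine$double.eps)
        dcrit <- max(abs(profile - prev_profile)) / ((step - prev_profile_step) * dt)
        prev_profile <- profile
        prev_profile_step <- step
        if (dcrit < params$steady_tol) { converged <- TRUE; break }
      }
    }
  }
  final <- if (stop_on == "profile") a / max(sum(a), .Machine$double.eps) else a
  res <- list(final_state = new_auxin_state(final, op$cell_id, time = step * dt),
              converged = converged, n_steps = step, time = step * dt,
              dt_used = dt, stop_on = stop_on,
              params = params,
              tissue_cells = n)
  if (record_trajectory) res$trajectory <- do.call(rbind, traj)
  class(res) <- "simulation_result"
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d cells, %d steps (dt %.3g, t %.4g), %s\n",
              x$tissue_cells, x$n_steps, x$dt_used, x$time,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
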