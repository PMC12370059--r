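#' Simulate one trajectory of the bundled feedback module
#'
#' Two-phase protocol: phase 1 relaxes the model to its steady state with
#' zero stimulus input (under the regime-modified parameters, so treated and
#' untreated conditions each equilibrate to their own baseline); phase 2
#' integrates over the sampling grid with the IKK input curve applied.
#' Integration is fixed-step RK4 with step `h` (minutes); the model is
#' non-stiff at the bundled parameterization and results are step-converged
#' at the default (see the package vignette).
#'
#' @param params `core_params` (after any [apply_regime()])
#' @param input IKK activity curve on `grid$t`, from [ikk_input_curve()]
#' @param grid [time_grid()]
#' @param h RK4 step, minutes
#' @param ss_tol phase-1 max-norm convergence tolerance
#' @param ss_block phase-1 comparison block length, minutes
#' @param ss_max_time phase-1 cap on simulated time, minutes
#' @param stimulus optional (ligand, dose) label attached to the result
#' @param regime_id optional regime label attached to the result
#' @param baseline optional pre-computed phase-1 state from
#'   [steady_state()]; phase 1 depends only on the parameters, so it can be
#'   shared across the stimuli of one regime
#' @return object of class `trajectory`: `values` (nuclear NFkB activity on
#'   the grid), `grid`, `stimulus`, `regime_id`, `states` (grid x 4 matrix of
#'   IkBa mRNA, free IkBa, nuclear NFkB, complex), `baseline` (phase-1 state)
#' @export
simulate_trajectory <- function(params, input, grid, h = 0.05,
                                ss_tol = 1e-8, ss_block = 100,
                                ss_max_time = 1e6,
                                stimulus = NULL, regime_id = NULL,
                                baseline = NULL) {
  validate_core_params(params)
  stopifnot(inherits(grid, "time_grid"))
  if (length(input) != grid$n_points)
    stop("`input` length must match the grid", call. = FALSE)
  pvec <- as.numeric(params[.core_param_order])
  ss <- if (is.null(baseline))
    steady_state(params, h, ss_tol, ss_block, ss_max_time)
  else baseline
  st <- .cpp_simulate(pvec, ss$state, as.numeric(input), grid$t, h)
  if (any(!is.finite(st)))
    stop("integration produced non-finite state values", call. = FALSE)
  colnames(st) <- c("mrna", "ikba", "nfkbn", "complex")
  structure(
    list(values = st[, "nfkbn"], grid = grid, stimulus = stimulus,
         regime_id = regime_id, states = st, baseline = ss$state,
         ss_delta = ss$delta),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s / %s: %d points, peak %.4g\n",
              x$regime_id %||% "?",
              paste(x$stimulus, collapse = "_") %||% "?",
              x$grid$n_points, max(x$values)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Phase-1 steady state of the model under zero stimulus
#'
#' Long integration with zero input until the state moves less than
#' `ss_tol` (max-norm) over a whole comparison block.
#'
#' @inheritParams simulate_trajectory
#' @return list with `state` (m, IkBa, nuclear NFkB, complex), `converged`,
#'   `delta` (last block-to-block max-norm change), `time`
#' @export
steady_state <- function(params, h = 0.05, ss_tol = 1e-8, ss_block = 100,
                         ss_max_time = 1e6) {
  validate_core_params(params)
  pvec <- as.numeric(params[.core_param_order])
  ss <- .cpp_steady_state(pvec, h, ss_block, ss_tol, ss_max_time)
  if (!ss$converged)
    stop(sprintf(
      "phase-1 steady state did not converge (delta %.3g after %.0f min)",
      ss$delta, ss$time), call. = FALSE)
  ss
}

#' Assemble a trajectory set container
#'
#' @param values numeric matrix, one row per trajectory, `grid$n_points`
#'   columns
#' @param meta data.frame with columns `regime_id`, `drug`, `dd`, `ligand`,
#'   `ligand_dose`, `stimulus` (one row per trajectory, aligned with
#'   `values`)
#' @param grid [time_grid()]
#' @return object of class `trajectory_set`
#' @export
trajectory_set <- function(values, meta, grid) {
  stopifnot(is.matrix(values), nrow(values) == nrow(meta),
            ncol(values) == grid$n_points)
  need <- c("regime_id", "drug", "dd", "ligand", "ligand_dose", "stimulus")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("meta is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("trajectory values must be finite", call. = FALSE)
  structure(list(values = values, meta = as.data.frame(meta), grid = grid),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf(
    "<trajectory_set> %d trajectories x %d timepoints, %d regime(s)\n",
    nrow(x$values), ncol(x$values), length(unique(x$meta$regime_id))))
  invisible(x)
}

#' Number of trajectories in a set
#' @param x `trajectory_set`
#' @return integer count
#' @export
n_trajectories <- function(x) nrow(x$values)

#' Simulate the full stimulus x regime grid
#'
#' Runs [simulate_trajectory()] for every (ligand, ligand dose) condition
#' under every regime. The phase-1 steady state depends only on the regime's
#' parameters, so simulation is grouped by regime. Deterministic: no
#' randomness anywhere in the simulator.
#'
#' @param regimes list of `drug_regime` (include [untreated_regime()] to get
#'   the untreated 15-trajectory set)
#' @param ligands named list of [ligand_input_spec()], default
#'   [ligand_library()]
#' @param params base `core_params`
#' @param grid [time_grid()]
#' @param model plug-in simulator: a function `(params, input, grid)`
#'   returning a numeric activity vector on the grid. Defaults to the bundled
#'   module. Substituting a published full model here reuses the rest of the
#'   workflow unchanged.
#' @param ... passed to [simulate_trajectory()] when the bundled model is
#'   used
#' @return [trajectory_set()] ordered regimes-major, stimuli in canonical
#'   order within each regime
#' @export
simulate_grid <- function(regimes, ligands = ligand_library(),
                          params = core_params(), grid = time_grid(),
                          model = NULL, ...) {
  if (inherits(regimes, "drug_regime")) regimes <- list(regimes)
  stopifnot(length(regimes) >= 1L, length(ligands) >= 1L)
  n <- length(regimes) * length(ligands)
  values <- matrix(NA_real_, n, grid$n_points)
  meta <- data.frame(
    regime_id = character(n), drug = character(n), dd = integer(n),
    ligand = character(n), ligand_dose = character(n), stimulus = character(n),
    stringsAsFactors = FALSE
  )
  row <- 0L
  for (rg in regimes) {
    p <- apply_regime(params, rg)
    base <- if (is.null(model)) steady_state(p, ...) else NULL
    drug <- if (length(rg$components)) {
      paste(vapply(rg$components, `[[`, "", "drug"), collapse = "+")
    } else "none"
    dd <- if (length(rg$components)) rg$components[[1]]$dd else 0L
    for (s in names(ligands)) {
      row <- row + 1L
      u <- ikk_input_curve(ligands[[s]], grid, p)
      values[row, ] <- if (is.null(model)) {
        simulate_trajectory(p, u, grid, stimulus = s,
                            regime_id = rg$regime_id, baseline = base,
                            ...)$values
      } else {
        as.numeric(model(p, u, grid))
      }
      meta$regime_id[row] <- rg$regime_id
      meta$drug[row] <- drug
      meta$dd[row] <- dd
      meta$ligand[row] <- ligands[[s]]$ligand
      meta$ligand_dose[row] <- ligands[[s]]$dose_level
      meta$stimulus[row] <- s
    }
  }
  trajectory_set(values, meta, grid)
}
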