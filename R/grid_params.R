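#' Uniform sampling grid for trajectories
#'
#' The default grid has 481 points at 1-minute spacing, spanning 0--480 min
#' with t = 0 at stimulation onset.
#'
#' @param n_points number of samples (>= 2)
#' @param dt sampling interval in minutes (> 0)
#' @param t_start time of the first sample, minutes
#' @return an object of class `time_grid` with fields `n_points`, `dt`,
#'   `t_start` and the sample times `t`
#' @export
time_grid <- function(n_points = 481L, dt = 1, t_start = 0) {
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L)
    stop("`n_points` must be an integer >= 2", call. = FALSE)
  if (!is.finite(dt) || dt <= 0)
    stop("`dt` must be a positive number of minutes", call. = FALSE)
  structure(
    list(n_points = n_points, dt = dt, t_start = t_start,
         t = t_start + dt * (seq_len(n_points) - 1)),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %d points, dt = %g min, span %g-%g min\n",
              x$n_points, x$dt, x$t[1], x$t[x$n_points]))
  invisible(x)
}

# Canonical parameter order shared with the compiled integrator.
.core_param_order <- c(
  "tot_nfkb", "ikk_gain", "ikk_basal", "txn_basal", "txn_induced",
  "txn_khalf", "mrna_decay", "translation", "deg_free_basal", "deg_free_ikk",
  "deg_bound_basal", "deg_bound_ikk", "assoc", "nuc_export", "nuc_import"
)

# Parameters that shape the IKK input curve rather than the core ODEs; they
# are regime targets too (phosphatase / lysosome inhibitors act upstream).
.input_param_names <- c("input_decay_rate", "input_plateau_loss")

#' Default rate constants of the bundled feedback module
#'
#' A 4-variable mass-action model of the IkBa-NFkB negative feedback loop
#' (IkBa mRNA, free cytoplasmic IkBa, free nuclear NFkB, cytoplasmic
#' NFkB:IkBa complex) driven by an IKK activity input. Units: minutes and
#' arbitrary concentration units with total NFkB = 1. The defaults give a
#' resting nuclear fraction well below the 0.05 non-responder cutoff and
#' damped oscillations with a period of roughly 90 minutes under a sustained
#' input, the hallmark dynamics of this feedback.
#'
#' `input_decay_rate` and `input_plateau_loss` shape the IKK input curve
#' (see [ikk_input_curve()]); they are listed here so drug regimes can target
#' upstream processes with the same multiplier mechanism.
#'
#' @param ... name = value overrides of individual parameters
#' @return named numeric vector of class `core_params`
#' @export
core_params <- function(...) {
  p <- c(
    tot_nfkb        = 1.0,
    ikk_gain        = 1.0,
    ikk_basal       = 0.01,
    txn_basal       = 2e-4,
    txn_induced     = 0.06,
    txn_khalf       = 0.25,
    mrna_decay      = 0.02,
    translation     = 0.10,
    deg_free_basal  = 0.18,
    deg_free_ikk    = 0.13,
    deg_bound_basal = 2e-4,
    deg_bound_ikk   = 0.11,
    assoc           = 30.0,
    nuc_export      = 30.0,
    nuc_import      = 0.16,
    input_decay_rate   = 1.0,
    input_plateau_loss = 1.0
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad))
      stop("unknown core parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    p[names(dots)] <- unlist(dots)
  }
  validate_core_params(p)
  class(p) <- "core_params"
  p
}

validate_core_params <- function(p) {
  need <- c(.core_param_order, .input_param_names)
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("missing core parameter(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0))
    stop("all core parameters must be finite and >= 0", call. = FALSE)
  if (p[["tot_nfkb"]] <= 0)
    stop("`tot_nfkb` must be > 0", call. = FALSE)
  invisible(p)
}
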