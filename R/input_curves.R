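#' Ligand input specification
#'
#' A six-parameter stand-in for the receptor modules: each (ligand, dose)
#' condition is an IKK activity curve with a characteristic rise, a decay
#' toward a sustained late-phase plateau, and a peak amplitude expressed as a
#' fraction of maximal IKK activity.
#'
#' @param ligand ligand label (TNF, LPS, CpG, PolyIC, Pam3CSK)
#' @param dose_level dose label (Low/Medium/High); metadata only
#' @param amplitude peak IKK activity fraction in `[0, 1]`
#' @param rise_time characteristic rise time, minutes (> 0)
#' @param decay_time characteristic decay time, minutes (> 0)
#' @param plateau_fraction late-phase sustained fraction in `[0, 1]`
#' @param dose_label physical dose string (metadata, e.g. "33 ng/mL")
#' @return object of class `ligand_input_spec`
#' @export
ligand_input_spec <- function(ligand, dose_level, amplitude, rise_time,
                              decay_time, plateau_fraction,
                              dose_label = NA_character_) {
  if (!is.finite(amplitude) || amplitude < 0 || amplitude > 1)
    stop("`amplitude` must lie in [0, 1]", call. = FALSE)
  if (!is.finite(rise_time) || rise_time <= 0)
    stop("`rise_time` must be > 0", call. = FALSE)
  if (!is.finite(decay_time) || decay_time <= 0)
    stop("`decay_time` must be > 0", call. = FALSE)
  if (!is.finite(plateau_fraction) || plateau_fraction < 0 ||
      plateau_fraction > 1)
    stop("`plateau_fraction` must lie in [0, 1]", call. = FALSE)
  structure(
    list(ligand = ligand, dose_level = dose_level, amplitude = amplitude,
         rise_time = rise_time, decay_time = decay_time,
         plateau_fraction = plateau_fraction, dose_label = dose_label),
    class = "ligand_input_spec"
  )
}

#' IKK activity curve for one stimulus condition
#'
#' Deterministic curve `A * (1 - exp(-t/tau_r)) * (p + (1-p) exp(-r t/tau_d))`
#' on the sampling grid: zero at t = 0, rising with time constant
#' `rise_time`, decaying with `decay_time` toward the sustained fraction
#' `plateau_fraction` of the peak. Two regime-targetable parameters reshape
#' the curve: `input_decay_rate` scales the decay rate r (phosphatase
#' inhibition slows IKK inactivation) and `input_plateau_loss` scales the
#' lost late-phase fraction `1 - p` (lysosome inhibition spares receptors, so
#' a small multiplier pushes the plateau toward 1).
#'
#' @param spec [ligand_input_spec()]
#' @param grid [time_grid()]
#' @param params `core_params` supplying `input_decay_rate` and
#'   `input_plateau_loss` (default 1, i.e. the unperturbed curve)
#' @return numeric vector of IKK activity fractions on `grid$t`
#' @export
ikk_input_curve <- function(spec, grid, params = core_params()) {
  stopifnot(inherits(spec, "ligand_input_spec"), inherits(grid, "time_grid"))
  t <- grid$t - grid$t_start
  p_eff <- 1 - params[["input_plateau_loss"]] * (1 - spec$plateau_fraction)
  p_eff <- min(max(p_eff, 0), 1)
  rate <- params[["input_decay_rate"]] / spec$decay_time
  u <- spec$amplitude * (1 - exp(-t / spec$rise_time)) *
    (p_eff + (1 - p_eff) * exp(-rate * t))
  pmax(u, 0)
}

#' Bundled 15-condition stimulus library
#'
#' Five ligands at three doses each, in canonical order (TNF L/M/H, LPS
#' L/M/H, CpG L/M/H, PolyIC L/M/H, Pam3CSK L/M/H). Curve parameters are
#' calibrated qualitatively against the published taxonomy of the untreated
#' responses: TNF is fast and oscillation-prone with dose-graded late
#' activity, low-dose LPS is a complete non-responder, PolyIC rises slowly,
#' and high-dose CpG and high-dose Pam3CSK are nearly indistinguishable.
#'
#' @return named list of 15 [ligand_input_spec()] objects; names are
#'   `"<ligand>_<L|M|H>"`
#' @export
ligand_library <- function() {
  spec <- function(...) ligand_input_spec(...)
  list(
    TNF_L = spec("TNF", "Low",  0.30,  4,  35, 0.02, "0.3 ng/mL"),
    TNF_M = spec("TNF", "Medium", 0.55, 4,  45, 0.06, "3.3 ng/mL"),
    TNF_H = spec("TNF", "High", 0.85,  4,  55, 0.16, "33 ng/mL"),
    LPS_L = spec("LPS", "Low",  0.015, 14, 80, 0.25, "0.33 ng/mL"),
    LPS_M = spec("LPS", "Medium", 0.28, 14, 80, 0.30, "3.3 ng/mL"),
    LPS_H = spec("LPS", "High", 0.60, 13, 90, 0.35, "33 ng/mL"),
    CpG_L = spec("CpG", "Low",  0.09, 32, 220, 0.72, "33 nM"),
    CpG_M = spec("CpG", "Medium", 0.32, 30, 230, 0.75, "100 nM"),
    CpG_H = spec("CpG", "High", 0.66, 28, 240, 0.78, "330 nM"),
    PolyIC_L = spec("PolyIC", "Low",  0.10, 95, 300, 0.80, "3.3 ug/mL"),
    PolyIC_M = spec("PolyIC", "Medium", 0.24, 90, 300, 0.82, "33 ug/mL"),
    PolyIC_H = spec("PolyIC", "High", 0.46, 85, 300, 0.84, "100 ug/mL"),
    Pam3CSK_L = spec("Pam3CSK", "Low",  0.11, 7,  45, 0.06, "10 ng/mL"),
    Pam3CSK_M = spec("Pam3CSK", "Medium", 0.36, 14, 120, 0.40, "33 ng/mL"),
    Pam3CSK_H = spec("Pam3CSK", "High", 0.72, 26, 235, 0.76, "100 ng/mL")
  )
}

#' Canonical stimulus ordering
#' @return character vector of the 15 stimulus names
#' @export
stimulus_order <- function() names(ligand_library())
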