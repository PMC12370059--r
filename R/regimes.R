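#' Log-linear drug dose ladder
#'
#' Multipliers 10^e with exponents linearly spaced from `exp_start` to
#' `exp_stop` inclusive. The default ladder is the 20-step scan from
#' 10^-0.15 (DD1, a mild ~29% reduction) down to 10^-3 (DD20, a 1000-fold
#' reduction).
#'
#' @param n_steps number of dose steps (>= 1)
#' @param exp_start,exp_stop first and last base-10 exponents
#' @return numeric vector of multipliers, length `n_steps`
#' @export
build_dose_ladder <- function(n_steps = 20L, exp_start = -0.15, exp_stop = -3) {
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L)
    stop("`n_steps` must be a positive integer", call. = FALSE)
  if (!is.finite(exp_start) || !is.finite(exp_stop))
    stop("ladder exponents must be finite", call. = FALSE)
  if (n_steps == 1L) return(10 ^ exp_start)
  10 ^ seq(exp_start, exp_stop, length.out = n_steps)
}

#' Bundled compound library
#'
#' Ten compounds acting on the NFkB network, each mapped to the model
#' parameters it scales. `targets` is the remap onto the bundled minimal
#' module; `reference_params` records the kinetic-parameter indices of the
#' full published receptor+core model for users substituting their own model
#' via the plug-in interface.
#'
#' Attenuating compounds scale core rates down; PDTC/CHX act on the negative
#' feedback itself (so attenuation of the target enhances NFkB activity), and
#' PP2Ai/CHL scale the input-curve decay/plateau-loss parameters (slower IKK
#' decay, retained late-phase input).
#'
#' @return named list; each element has `targets` (character vector of core
#'   parameter names) and `reference_params` (character vector of k-indices
#'   in the full published model)
#' @export
drug_library <- function() {
  list(
    IKKi   = list(targets = "ikk_gain",
                  reference_params = c("k3", "k25", "k26")),
    TAK1i  = list(targets = "ikk_gain",
                  reference_params = "k67"),
    BTRCPi = list(targets = "deg_bound_ikk",
                  reference_params = c("k25", "k26")),
    PP2Ai  = list(targets = "input_decay_rate",
                  reference_params = "k4"),
    TSA    = list(targets = "txn_basal",
                  reference_params = "k5"),
    PDTC   = list(targets = "txn_induced",
                  reference_params = "k6"),
    CHX    = list(targets = "translation",
                  reference_params = "k8"),
    Sel    = list(targets = "nuc_export",
                  reference_params = c("k11", "k12", "k14")),
    MG132  = list(targets = c("deg_bound_ikk", "deg_free_ikk"),
                  reference_params = c("k15", "k16", "k26", "k53", "k58",
                                       "k61", "k64", "k69", "k73", "k75")),
    CHL    = list(targets = "input_plateau_loss",
                  reference_params = c("k30", "k42", "k43", "k44", "k78",
                                       "k83", "k86", "k87", "k92", "k93"))
  )
}

#' Construct a drug regime
#'
#' A regime is one compound (or several, for combinations) at a dose index on
#' the multiplier ladder, realized as a map from parameter names to
#' multipliers. Combination regimes compose multiplicatively per parameter.
#'
#' @param drug compound name present in `library`
#' @param dd dose index into `ladder` (DD1 = mildest)
#' @param ladder multiplier ladder from [build_dose_ladder()]
#' @param library compound library, default [drug_library()]
#' @return object of class `drug_regime` with `regime_id`, `components`,
#'   `multiplier_map`
#' @export
drug_regime <- function(drug, dd, ladder = build_dose_ladder(),
                        library = drug_library()) {
  if (!drug %in% names(library))
    stop("unknown compound: ", drug, call. = FALSE)
  dd <- as.integer(dd)
  if (is.na(dd) || dd < 1L || dd > length(ladder))
    stop("`dd` must index the ladder (1..", length(ladder), ")", call. = FALSE)
  mult <- ladder[dd]
  map <- setNames(rep(mult, length(library[[drug]]$targets)),
                  library[[drug]]$targets)
  structure(
    list(regime_id = sprintf("%s_DD%02d", drug, dd),
         components = list(list(drug = drug, dd = dd)),
         multiplier_map = map),
    class = "drug_regime"
  )
}

#' The identity (untreated) regime
#' @return `drug_regime` with an empty multiplier map
#' @export
untreated_regime <- function() {
  structure(
    list(regime_id = "untreated", components = list(),
         multiplier_map = setNames(numeric(0), character(0))),
    class = "drug_regime"
  )
}

#' Compose two regimes into a combination regime
#'
#' Per-parameter multipliers from both components are multiplied.
#'
#' @param a,b `drug_regime` objects
#' @return combined `drug_regime`
#' @export
combine_regimes <- function(a, b) {
  stopifnot(inherits(a, "drug_regime"), inherits(b, "drug_regime"))
  keys <- union(names(a$multiplier_map), names(b$multiplier_map))
  map <- setNames(rep(1, length(keys)), keys)
  map[names(a$multiplier_map)] <- a$multiplier_map
  map[names(b$multiplier_map)] <- map[names(b$multiplier_map)] * b$multiplier_map
  structure(
    list(regime_id = paste(a$regime_id, b$regime_id, sep = "+"),
         components = c(a$components, b$components),
         multiplier_map = map),
    class = "drug_regime"
  )
}

#' Apply a regime's multipliers to model parameters
#'
#' @param params `core_params`
#' @param regime `drug_regime`
#' @return modified copy of `params`; untouched parameters are identical
#' @export
apply_regime <- function(params, regime) {
  validate_core_params(params)
  stopifnot(inherits(regime, "drug_regime"))
  map <- regime$multiplier_map
  if (!length(map)) return(params)
  bad <- setdiff(names(map), names(params))
  if (length(bad))
    stop("regime `", regime$regime_id, "` targets unknown parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(map <= 0))
    stop("regime multipliers must be > 0", call. = FALSE)
  params[names(map)] <- params[names(map)] * map
  params
}

#' Enumerate the single-drug regime collection
#'
#' @param drugs compound names (default: all ten in [drug_library()])
#' @param dds dose indices (default: the full ladder)
#' @inheritParams drug_regime
#' @return list of `drug_regime`, drugs varying slowest
#' @export
single_drug_regimes <- function(drugs = names(drug_library()),
                                dds = seq_along(ladder),
                                ladder = build_dose_ladder(),
                                library = drug_library()) {
  out <- list()
  for (drug in drugs)
    for (dd in dds)
      out[[length(out) + 1L]] <- drug_regime(drug, dd, ladder, library)
  out
}

#' Enumerate pairwise drug-combination regimes
#'
#' All unordered compound pairs, each at every combination of the given dose
#' indices. The default two dose levels over ten compounds give the
#' 45 pairs x 4 dose combinations = 180 regimes of the combination scan.
#'
#' @param drugs compound names
#' @param dds dose indices used for both components (default DD5 and DD10)
#' @inheritParams drug_regime
#' @return list of combination `drug_regime`s
#' @export
combination_regimes <- function(drugs = names(drug_library()),
                                dds = c(5L, 10L),
                                ladder = build_dose_ladder(),
                                library = drug_library()) {
  out <- list()
  nd <- length(drugs)
  for (i in seq_len(nd - 1L)) {
    for (j in seq((i + 1L), nd)) {
      for (d1 in dds) for (d2 in dds) {
        out[[length(out) + 1L]] <- combine_regimes(
          drug_regime(drugs[i], d1, ladder, library),
          drug_regime(drugs[j], d2, ladder, library))
      }
    }
  }
  out
}
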