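#' Load and validate a pipeline configuration
#'
#' JSON config with sections `grid`, `model`, `ligands`, `compounds`,
#' `ladder`, `analysis`, `combinations`. Every section is optional; defaults
#' reproduce the bundled study design (481-point 1-min grid, 15 stimuli, 10
#' compounds on the 20-step 10^-0.15..10^-3 ladder, 0.05 duration threshold
#' and non-responder cutoff). Unknown section or parameter names are
#' rejected with their key paths.
#'
#' @param path JSON file path, or NULL for the all-defaults config
#' @return object of class `pipeline_config`
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  known <- c("grid", "model", "ligands", "compounds", "ladder", "analysis",
             "combinations")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  errs <- character(0)
  gdef <- list(n_points = 481L, dt = 1, t_start = 0)
  g <- utils::modifyList(gdef, as.list(raw$grid %||% list()))
  bad <- setdiff(names(g), names(gdef))
  if (length(bad)) errs <- c(errs, paste0("grid.", bad, ": unknown key"))

  model <- tryCatch(do.call(core_params, as.list(raw$model %||% list())),
                    error = function(e) {
                      errs <<- c(errs, paste0("model: ", conditionMessage(e)))
                      core_params()
                    })
  if (!is.null(raw$model)) {
    vals <- unlist(raw$model)
    neg <- names(vals)[!is.finite(vals) | vals < 0]
    if (length(neg))
      errs <- c(errs, paste0("model.", neg, ": must be finite and >= 0"))
  }

  ldef <- list(n_steps = 20L, exp_start = -0.15, exp_stop = -3)
  lad <- utils::modifyList(ldef, as.list(raw$ladder %||% list()))
  bad <- setdiff(names(lad), names(ldef))
  if (length(bad)) errs <- c(errs, paste0("ladder.", bad, ": unknown key"))
  if (!is.null(lad$n_steps) && lad$n_steps < 1)
    errs <- c(errs, "ladder.n_steps: must be >= 1")

  ligands <- if (is.null(raw$ligands)) ligand_library() else {
    lapply(raw$ligands, function(sp) do.call(ligand_input_spec, sp))
  }

  compounds <- if (is.null(raw$compounds)) drug_library() else {
    lapply(raw$compounds, function(cp)
      if (is.list(cp)) cp else list(targets = cp, reference_params = NULL))
  }
  for (nm in names(compounds)) {
    bad <- setdiff(compounds[[nm]]$targets, names(model))
    if (length(bad))
      errs <- c(errs, paste0("compounds.", nm, ": unknown target parameter ",
                             paste(bad, collapse = ", ")))
  }

  adef <- list(threshold = 0.05, cutoff = 0.05, eps = NULL,
               eps_grid_size = 200L, seed = 0L,
               spaces = "codon", expert_dir = NULL)
  an <- utils::modifyList(adef, as.list(raw$analysis %||% list()))
  bad <- setdiff(names(an), names(adef))
  if (length(bad)) errs <- c(errs, paste0("analysis.", bad, ": unknown key"))

  cdef <- list(enabled = FALSE, dds = c(5L, 10L))
  cmb <- utils::modifyList(cdef, as.list(raw$combinations %||% list()))
  bad <- setdiff(names(cmb), names(cdef))
  if (length(bad))
    errs <- c(errs, paste0("combinations.", bad, ": unknown key"))

  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  structure(
    list(grid = time_grid(g$n_points, g$dt, g$t_start), model = model,
         ligands = ligands, compounds = compounds,
         ladder = do.call(build_dose_ladder, lad),
         ladder_spec = lad, analysis = an, combinations = cmb),
    class = "pipeline_config"
  )
}

.stim_suffix <- c(Low = "L", Medium = "M", High = "H")

#' Write / read trajectory tables
#'
#' Long dialect: columns `regime_id,drug,dd,ligand,ligand_dose,t_min,value`.
#' Wide dialect: the metadata columns followed by `t0,t1,...`. Values are
#' rendered with 17 significant digits so a write/read round trip is
#' bit-identical. UTF-8, '.' decimal.
#'
#' @param set [trajectory_set()]
#' @param path CSV path
#' @param format `"long"` or `"wide"`
#' @return `path`, invisibly (write); a [trajectory_set()] (read)
#' @export
write_trajectories <- function(set, path, format = c("wide", "long")) {
  format <- match.arg(format)
  stopifnot(inherits(set, "trajectory_set"))
  meta <- set$meta[, c("regime_id", "drug", "dd", "ligand", "ligand_dose")]
  fmt <- function(x) sub("^\\s+", "", sprintf("%.17g", x))  # round-trip safe
  if (format == "wide") {
    vals <- as.data.frame(matrix(fmt(set$values), nrow(set$values)))
    names(vals) <- paste0("t", set$grid$t)
    dt <- data.table::as.data.table(cbind(meta, vals))
  } else {
    n <- nrow(set$values); Tn <- ncol(set$values)
    dt <- data.table::data.table(
      meta[rep(seq_len(n), each = Tn), ],
      t_min = rep(set$grid$t, times = n),
      value = fmt(as.vector(t(set$values)))
    )
  }
  data.table::fwrite(dt, path, sep = ",", dec = ".", quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path, format = NULL) {
  hdr <- names(data.table::fread(path, nrows = 0L))
  if (is.null(format))
    format <- if ("t_min" %in% hdr) "long" else "wide"
  dt <- data.table::fread(path, sep = ",", dec = ".")
  meta_cols <- c("regime_id", "drug", "dd", "ligand", "ligand_dose")
  miss <- setdiff(meta_cols, names(dt))
  if (length(miss))
    stop("trajectory table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (format == "long") {
    if (!all(c("t_min", "value") %in% names(dt)))
      stop("long dialect requires `t_min` and `value` columns",
           call. = FALSE)
    key <- do.call(paste, c(dt[, meta_cols, with = FALSE], sep = "\r"))
    ukey <- unique(key)
    tvals <- sort(unique(dt$t_min))
    if (length(tvals) < 2L)
      stop("need at least two timepoints", call. = FALSE)
    dtv <- diff(tvals)
    if (max(dtv) - min(dtv) > 1e-9)
      stop("non-uniform time column", call. = FALSE)
    grid <- time_grid(length(tvals), dtv[1], tvals[1])
    values <- matrix(NA_real_, length(ukey), length(tvals))
    ridx <- match(key, ukey)
    cidx <- match(dt$t_min, tvals)
    values[cbind(ridx, cidx)] <- dt$value
    if (anyNA(values))
      stop("missing timepoints for some trajectories", call. = FALSE)
    first <- !duplicated(key)
    meta <- as.data.frame(dt[first, meta_cols, with = FALSE])
  } else {
    tcols <- grep("^t[0-9]", names(dt), value = TRUE)
    if (length(tcols) < 2L)
      stop("wide dialect requires t<minute> columns", call. = FALSE)
    tvals <- as.numeric(sub("^t", "", tcols))
    if (is.unsorted(tvals, strictly = TRUE))
      stop("non-monotone time columns", call. = FALSE)
    grid <- time_grid(length(tvals), diff(tvals)[1], tvals[1])
    values <- as.matrix(dt[, tcols, with = FALSE])
    dimnames(values) <- NULL
    meta <- as.data.frame(dt[, meta_cols, with = FALSE])
  }
  meta$stimulus <- paste0(meta$ligand, "_",
                          .stim_suffix[as.character(meta$ligand_dose)])
  meta$stimulus[is.na(meta$stimulus)] <-
    paste0(meta$ligand, "_", meta$ligand_dose)[is.na(meta$stimulus)]
  trajectory_set(values, meta, grid)
}
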