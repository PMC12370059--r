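#' Cluster and score every regime of a trajectory set in codon space
#'
#' Computes the codon table for the whole set, min-max normalizes it jointly
#' (one scale across all regimes, untreated included), then for each regime
#' builds the 15-stimulus codon feature matrix, removes the regime's
#' non-responders, clusters the rest with the epsilon network, and scores
#' the partition.
#'
#' @param set [trajectory_set()] containing one or more regimes
#' @param eps linking radius in normalized codon space
#' @param threshold Duration threshold
#' @param cutoff non-responder peak cutoff
#' @param bounds optional codon normalization bounds to reuse
#' @return list: `scorecards` (per regime), `scores` (data.frame), `codons`
#'   (normalized codon object), `eps`
#' @export
score_regimes <- function(set, eps, threshold = 0.05, cutoff = 0.05,
                          bounds = NULL) {
  stopifnot(inherits(set, "trajectory_set"))
  tab <- codon_table(set, threshold, cutoff)
  norm <- normalize_codons(tab, bounds)
  regimes <- unique(tab$regime_id)
  scorecards <- lapply(regimes, function(rid) {
    F <- feature_matrix(rid, "codon", codons = norm)
    sub <- norm$table[norm$table$regime_id == rid, ]
    nr <- sub$stimulus[sub$is_nonresponder]
    p <- epsilon_cluster(pairwise_distances(F), eps, nr)
    compute_scores(p, rid)
  })
  names(scorecards) <- regimes
  list(scorecards = scorecards, scores = scores_table(scorecards),
       codons = norm, eps = eps)
}

#' Bundled synthetic expert partitions
#'
#' Expert consensus partitions for the five calibration regimes of the
#' bundled model (CHL DD8, IKKi DD11, MG132 DD6, Sel DD15, TAK1i DD14),
#' shipped as JSON fixtures. They are synthetic: they describe the bundled
#' minimal module's trajectories, not the published full model's, and were
#' curated by inspecting the bundled simulations.
#'
#' @return named list of [partition()] objects keyed by regime id
#' @export
expert_partitions_synthetic <- function() {
  dir <- system.file("extdata", "expert_synthetic", package = "tempocode")
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  if (!length(files)) stop("bundled expert partitions not found",
                           call. = FALSE)
  parts <- lapply(files, read_partition)
  names(parts) <- sub("\\.json$", "", basename(files))
  parts
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(config[setdiff(names(config), "grid")]),
                   collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}

.file_digest <- function(path) unname(tools::md5sum(path))

#' Run the full workflow
#'
#' Stages: simulate (untreated + single-drug scan, plus pairwise
#' combinations when enabled) -> featurize (codon tables) -> calibrate
#' epsilon (against expert partitions, unless `analysis$eps` is fixed in the
#' config) -> score every regime -> tally pairwise robustness. Outputs are
#' CSV/JSON files under `out_dir` plus a run manifest; re-running with an
#' unchanged config skips stages whose outputs are present with matching
#' digests.
#'
#' @param config [load_config()] result (NULL for defaults)
#' @param out_dir output directory, created if needed
#' @param experts named list of expert [partition()]s keyed by regime id;
#'   default: the bundled synthetic set
#' @param quiet suppress stage logging
#' @return the run manifest, invisibly
#' @export
run_pipeline <- function(config = NULL, out_dir, experts = NULL,
                         quiet = FALSE) {
  if (is.null(config)) config <- load_config()
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) if (!quiet) message(sprintf(...))
  hash <- .config_hash(config)
  manifest_path <- file.path(out_dir, "manifest.json")
  prev <- if (file.exists(manifest_path))
    tryCatch(jsonlite::fromJSON(manifest_path), error = function(e) NULL)
  else NULL
  reuse <- !is.null(prev) && identical(prev$config_hash, hash)
  manifest <- list(config_hash = hash,
                   package_version = as.character(
                     utils::packageVersion("tempocode")),
                   seed = config$analysis$seed,
                   started = format(Sys.time(), tz = "UTC"),
                   stages = list())

  fresh <- function(stage, files) {
    ok <- reuse && all(file.exists(files)) &&
      identical(unname(unlist(prev$stages[[stage]]$digests)),
                unname(vapply(files, .file_digest, "")))
    ok
  }
  record <- function(stage, files, t0, cached = FALSE) {
    manifest$stages[[stage]] <<- list(
      outputs = basename(files),
      digests = vapply(files, .file_digest, ""),
      seconds = round(as.numeric(Sys.time()) - t0, 2),
      cached = cached)
  }

  traj_file <- file.path(out_dir, "trajectories.csv")
  t0 <- as.numeric(Sys.time())
  if (fresh("simulate", traj_file)) {
    log_stage("simulate: cached")
    set <- read_trajectories(traj_file)
    record("simulate", traj_file, t0, cached = TRUE)
  } else {
    regimes <- c(list(untreated_regime()),
                 single_drug_regimes(names(config$compounds),
                                     seq_along(config$ladder),
                                     config$ladder, config$compounds))
    if (isTRUE(config$combinations$enabled))
      regimes <- c(regimes,
                   combination_regimes(names(config$compounds),
                                       as.integer(config$combinations$dds),
                                       config$ladder, config$compounds))
    set <- simulate_grid(regimes, config$ligands, config$model, config$grid)
    write_trajectories(set, traj_file)
    record("simulate", traj_file, t0)
    log_stage("simulate: %d trajectories (%d regimes)",
              n_trajectories(set), length(regimes))
  }

  t0 <- as.numeric(Sys.time())
  tab <- codon_table(set, config$analysis$threshold, config$analysis$cutoff)
  norm <- normalize_codons(tab)
  codon_file <- file.path(out_dir, "codons.csv")
  codon_norm_file <- file.path(out_dir, "codons_norm.csv")
  data.table::fwrite(tab, codon_file)
  data.table::fwrite(norm$table, codon_norm_file)
  record("featurize", c(codon_file, codon_norm_file), t0)
  log_stage("featurize: %d codon vectors", nrow(tab))

  t0 <- as.numeric(Sys.time())
  if (!is.null(config$analysis$eps)) {
    eps <- config$analysis$eps
    calib <- NULL
    log_stage("epsilon: fixed at %.4g from config", eps)
  } else {
    if (is.null(experts)) experts <- expert_partitions_synthetic()
    have <- intersect(names(experts), unique(tab$regime_id))
    if (!length(have))
      stop("no expert partition matches a simulated regime; set",
           " analysis$eps or provide `experts`", call. = FALSE)
    feats <- lapply(have, feature_matrix, space = "codon", codons = norm)
    calib <- optimize_epsilon(feats, experts[have])
    eps <- calib$eps
    log_stage("epsilon: optimized to %.4g (mean MR %.3f over %d regimes)",
              eps, calib$mean_mr, length(have))
  }

  res <- score_regimes(set, eps, config$analysis$threshold,
                       config$analysis$cutoff)
  scores_file <- file.path(out_dir, "scores.csv")
  data.table::fwrite(res$scores, scores_file)
  eps_file <- file.path(out_dir, "epsilon.json")
  jsonlite::write_json(
    list(eps = eps,
         calibration = if (!is.null(calib))
           list(grid = calib$grid, mean_mr_curve = calib$mr_curve,
                per_regime_mr = calib$per_regime_mr)),
    eps_file, auto_unbox = TRUE, digits = NA, null = "null")
  record("score", c(scores_file, eps_file), t0)
  log_stage("score: %d regimes", nrow(res$scores))

  t0 <- as.numeric(Sys.time())
  treated <- res$scorecards[names(res$scorecards) != "untreated"]
  tally <- tally_pairwise(unname(treated))
  tally_file <- file.path(out_dir, "tally.csv")
  data.table::fwrite(data.table::as.data.table(tally$counts,
                                               keep.rownames = "stimulus"),
                     tally_file)
  record("robustness", tally_file, t0)

  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
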