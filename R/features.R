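#' Feature matrix of one regime in a chosen space
#'
#' Returns the 15 stimulus conditions of one regime as rows of a feature
#' matrix, in canonical stimulus order:
#' * `"trajectory"`: the raw sampled values (15 x T),
#' * `"codon"`: normalized codon vectors (15 x 6),
#' * `"cpd"`: CPD component weights (15 x rank),
#' * `"fpca"`: fPCA scores (15 x components).
#'
#' @param regime_id regime label as in the set's metadata
#' @param space one of `"trajectory"`, `"codon"`, `"cpd"`, `"fpca"`
#' @param set [trajectory_set()] (required for trajectory and fpca spaces)
#' @param codons normalized codon object from [normalize_codons()] (codon
#'   space)
#' @param cpd `cpd_model` fitted on the set's tensor (cpd space)
#' @param fpca `fpca_model` fitted on the set's value matrix (fpca space)
#' @return numeric matrix with 15 rows named by stimulus
#' @export
feature_matrix <- function(regime_id,
                           space = c("trajectory", "codon", "cpd", "fpca"),
                           set = NULL, codons = NULL, cpd = NULL,
                           fpca = NULL) {
  space <- match.arg(space)
  canon <- stimulus_order()
  if (space == "codon") {
    if (is.null(codons))
      stop("codon space requires `codons` from normalize_codons()",
           call. = FALSE)
    tab <- codons$table
    rows <- tab[tab$regime_id == regime_id, , drop = FALSE]
    if (!nrow(rows)) stop("regime not found: ", regime_id, call. = FALSE)
    rows <- rows[match(canon, rows$stimulus), , drop = FALSE]
    if (anyNA(rows$stimulus))
      stop("regime ", regime_id, " is missing stimulus conditions",
           call. = FALSE)
    F <- as.matrix(rows[, .codon_names])
  } else if (space == "trajectory") {
    if (is.null(set)) stop("trajectory space requires `set`", call. = FALSE)
    sel <- which(set$meta$regime_id == regime_id)
    if (!length(sel)) stop("regime not found: ", regime_id, call. = FALSE)
    sel <- sel[match(canon, set$meta$stimulus[sel])]
    F <- set$values[sel, , drop = FALSE]
  } else if (space == "fpca") {
    if (is.null(set) || is.null(fpca))
      stop("fpca space requires `set` and `fpca`", call. = FALSE)
    sel <- which(set$meta$regime_id == regime_id)
    if (!length(sel)) stop("regime not found: ", regime_id, call. = FALSE)
    sel <- sel[match(canon, set$meta$stimulus[sel])]
    F <- fpca_scores(fpca, set$values[sel, , drop = FALSE])
  } else {
    if (is.null(cpd) || is.null(set))
      stop("cpd space requires `cpd` and `set`", call. = FALSE)
    meta1 <- set$meta[set$meta$regime_id == regime_id, , drop = FALSE]
    if (!nrow(meta1)) stop("regime not found: ", regime_id, call. = FALSE)
    dn <- lapply(cpd$factors[1:4], rownames)
    ligs <- dimnames_or(cpd, 1L)
    doses <- dimnames_or(cpd, 2L)
    drugs <- dimnames_or(cpd, 3L)
    dds <- dimnames_or(cpd, 4L)
    k <- match(meta1$drug[1], drugs)
    l <- match(as.character(meta1$dd[1]), dds)
    if (is.na(k) || is.na(l))
      stop("regime ", regime_id, " not present in the CPD tensor",
           call. = FALSE)
    meta1 <- meta1[match(canon, meta1$stimulus), , drop = FALSE]
    F <- t(vapply(seq_len(nrow(meta1)), function(r) {
      i <- match(meta1$ligand[r], ligs)
      j <- match(meta1$ligand_dose[r], doses)
      cpd_weights(cpd, i, j, k, l)
    }, numeric(cpd$rank)))
  }
  rownames(F) <- canon
  if (any(!is.finite(F)))
    stop("non-finite feature values for regime ", regime_id, call. = FALSE)
  F
}

# dimension labels stored on the model's factors (set by the pipeline);
# fall back to index strings
dimnames_or <- function(cpd, n) {
  lb <- attr(cpd$factors[[n]], "labels")
  if (is.null(lb)) as.character(seq_len(nrow(cpd$factors[[n]]))) else lb
}

#' Attach dimension labels from a tensor to a fitted CPD model
#' @param model `cpd_model`
#' @param A the tensor it was fitted on (with dimnames)
#' @return model with labeled factors
#' @export
label_cpd <- function(model, A) {
  dn <- dimnames(A)
  for (n in seq_along(model$factors))
    if (!is.null(dn[[n]])) attr(model$factors[[n]], "labels") <- dn[[n]]
  model
}
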