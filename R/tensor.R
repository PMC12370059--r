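#' Arrange a trajectory set as a fifth-order tensor
#'
#' Dimensions: ligand (I) x ligand dose (J) x drug (K) x drug dose (L) x
#' time (T). Requires a complete grid: every (ligand, dose, drug, dd)
#' combination present exactly once. The untreated regime (drug "none") is
#' excluded -- the tensor covers the treated scan only.
#'
#' @param set [trajectory_set()]
#' @return 5-D array with dimnames; attribute `grid` carries the time grid
#' @export
as_tensor <- function(set) {
  stopifnot(inherits(set, "trajectory_set"))
  meta <- set$meta
  keep <- meta$drug != "none"
  meta <- meta[keep, , drop = FALSE]
  vals <- set$values[keep, , drop = FALSE]
  ligands <- unique(meta$ligand)
  doses <- unique(meta$ligand_dose)
  drugs <- unique(meta$drug)
  dds <- sort(unique(meta$dd))
  I <- length(ligands); J <- length(doses); K <- length(drugs)
  L <- length(dds); Tn <- ncol(vals)
  if (nrow(meta) != I * J * K * L)
    stop("trajectory set is not a complete ligand x dose x drug x dd grid",
         call. = FALSE)
  A <- array(NA_real_, dim = c(I, J, K, L, Tn),
             dimnames = list(ligand = ligands, ligand_dose = doses,
                             drug = drugs, dd = as.character(dds),
                             time = NULL))
  ii <- match(meta$ligand, ligands)
  jj <- match(meta$ligand_dose, doses)
  kk <- match(meta$drug, drugs)
  ll <- match(meta$dd, dds)
  for (r in seq_len(nrow(meta)))
    A[ii[r], jj[r], kk[r], ll[r], ] <- vals[r, ]
  if (anyNA(A))
    stop("duplicate or missing grid cells in trajectory set", call. = FALSE)
  attr(A, "grid") <- set$grid
  A
}

#' Normalize a tensor per drug
#'
#' Divides each drug slab (fixed index on the drug mode) by its own global
#' maximum, decoupling the scale of compounds with different mechanisms so
#' the decomposition weighs them in a balanced manner. Each slab's maximum
#' becomes exactly 1.
#'
#' @param A 5-D array from [as_tensor()] (drug on mode 3)
#' @param drug_mode which mode indexes drugs, default 3
#' @return normalized array; attribute `drug_max` stores the divisors
#' @export
normalize_tensor_per_drug <- function(A, drug_mode = 3L) {
  stopifnot(is.array(A))
  K <- dim(A)[drug_mode]
  mx <- numeric(K)
  idx <- rep(list(quote(expr = )), length(dim(A)))
  for (k in seq_len(K)) {
    idx[[drug_mode]] <- k
    slab <- do.call(`[`, c(list(A), idx, list(drop = FALSE)))
    mx[k] <- max(slab)
    if (mx[k] <= 0) {
      nm <- dimnames(A)[[drug_mode]]
      stop("all-zero slab for drug ",
           if (!is.null(nm)) nm[k] else k, call. = FALSE)
    }
    A <- do.call(`[<-`, c(list(A), idx, list(value = slab / mx[k])))
  }
  names(mx) <- dimnames(A)[[drug_mode]]
  attr(A, "drug_max") <- mx
  A
}

# mode-n unfolding (Kolda convention: remaining indices ordered with the
# lowest original mode varying fastest)
.unfold <- function(A, n) {
  d <- dim(A)
  perm <- c(n, seq_along(d)[-n])
  m <- aperm(A, perm)
  dim(m) <- c(d[n], prod(d[-n]))
  m
}

# Khatri-Rao product of a list of factor matrices; the FIRST matrix in the
# list indexes the fastest-varying mode of the corresponding unfolding.
.khatri_rao <- function(mats) {
  Z <- mats[[1L]]
  for (k in seq_along(mats)[-1L]) {
    M <- mats[[k]]
    Z <- Z[rep(seq_len(nrow(Z)), nrow(M)), , drop = FALSE] *
      M[rep(seq_len(nrow(M)), each = nrow(Z)), , drop = FALSE]
  }
  Z
}
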