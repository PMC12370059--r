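#' Non-negative canonical polyadic decomposition
#'
#' Factorizes a non-negative tensor as a sum of `rank` rank-1 components,
#' `A ~ sum_r lambda_r a1_r o a2_r o ... o aN_r`, by multiplicative updates
#' from random non-negative initialization. Several random restarts are run
#' and the fit with the best R2X is kept; R2X is reported as
#' `1 - Var(reconstruction - A) / Var(A)` over all tensor entries.
#'
#' @param A non-negative array (any number of modes >= 2)
#' @param rank number of components (>= 1)
#' @param seed integer seed; restart `s` uses `seed + s - 1`
#' @param max_iter maximum update sweeps per restart
#' @param restarts number of random restarts
#' @param tol stop when R2X improves by less than `tol` between checks
#' @return object of class `cpd_model`: `factors` (named list of mode
#'   matrices, columns unit-norm except the time mode after rescaling),
#'   `lambda`, `rho` (all 1 until [rescale_temporal()]), `r2x`, `rank`,
#'   `seed`, `iterations`, `converged`, `dims`, `grid` (when the input
#'   carries one)
#' @export
cpd_fit <- function(A, rank, seed = 0L, max_iter = 900L, restarts = 5L,
                    tol = 1e-9) {
  stopifnot(is.array(A))
  rank <- as.integer(rank)
  if (is.na(rank) || rank < 1L)
    stop("`rank` must be a positive integer", call. = FALSE)
  if (any(A < 0)) stop("tensor must be non-negative", call. = FALSE)
  d <- dim(A)
  N <- length(d)
  unfolds <- lapply(seq_len(N), .unfold, A = A)
  varA <- stats::var(as.numeric(A))
  if (varA == 0) stop("tensor is constant; nothing to decompose",
                      call. = FALSE)
  best <- NULL
  for (s in seq_len(restarts)) {
    set.seed(as.integer(seed) + s - 1L)
    U <- lapply(d, function(I) matrix(stats::runif(I * rank, 0.1, 1), I, rank))
    r2x_prev <- -Inf
    converged <- FALSE
    it_done <- max_iter
    for (it in seq_len(max_iter)) {
      for (n in seq_len(N)) {
        others <- U[-n]                      # modes 1..N without n, ascending
        V <- Reduce(`*`, lapply(others, crossprod))
        Z <- .khatri_rao(others)
        num <- unfolds[[n]] %*% Z
        den <- U[[n]] %*% V
        U[[n]] <- U[[n]] * num / pmax(den, 1e-300)
      }
      if (it %% 10L == 0L || it == max_iter) {
        r2x <- 1 - stats::var(as.numeric(.cp_recon_factors(U, d))
                              - as.numeric(A)) / varA
        if (is.finite(r2x) && r2x - r2x_prev < tol) {
          converged <- TRUE
          it_done <- it
          break
        }
        r2x_prev <- r2x
      }
    }
    # pull column norms out into lambda; order components by weight
    norms <- lapply(U, function(M) {
      nn <- sqrt(colSums(M ^ 2))
      nn[nn == 0] <- 1
      nn
    })
    lambda <- Reduce(`*`, norms)
    U <- Map(function(M, nn) sweep(M, 2, nn, "/"), U, norms)
    ord <- order(lambda, decreasing = TRUE)
    lambda <- lambda[ord]
    U <- lapply(U, function(M) M[, ord, drop = FALSE])
    r2x <- 1 - stats::var(as.numeric(.cp_recon(U, lambda, rep(1, rank), d))
                          - as.numeric(A)) / varA
    if (is.null(best) || r2x > best$r2x) {
      best <- list(factors = U, lambda = lambda, r2x = r2x,
                   seed = as.integer(seed) + s - 1L,
                   iterations = it_done, converged = converged)
    }
  }
  if (!best$converged)
    warning("CPD did not converge within max_iter; returning partial fit")
  nm <- names(dimnames(A))
  if (!is.null(nm) && all(nzchar(nm))) names(best$factors) <- nm
  structure(
    list(factors = best$factors, lambda = best$lambda,
         rho = rep(1, rank), rank = rank, r2x = best$r2x,
         seed = best$seed, iterations = best$iterations,
         converged = best$converged, dims = d,
         grid = attr(A, "grid")),
    class = "cpd_model"
  )
}

.cp_recon_factors <- function(U, d) {
  N <- length(U)
  M <- U[[1L]] %*% t(.khatri_rao(U[-1L]))
  array(M, dim = d)
}

.cp_recon <- function(U, lambda, rho, d) {
  U1 <- sweep(U[[1L]], 2, lambda * rho, "*")
  array(U1 %*% t(.khatri_rao(U[-1L])), dim = d)
}

#' Reconstruct the tensor from a CPD model
#' @param model `cpd_model`
#' @return array of the model's dimensions
#' @export
cp_reconstruct <- function(model) {
  stopifnot(inherits(model, "cpd_model"))
  .cp_recon(model$factors, model$lambda, model$rho, model$dims)
}

#' @export
print.cpd_model <- function(x, ...) {
  cat(sprintf("<cpd_model> rank %d, R2X = %.4f (seed %d, %d iterations%s)\n",
              x$rank, x$r2x, x$seed, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Rescale temporal factors to a fixed area
#'
#' CPD is scale-invariant per component; to make components comparable the
#' temporal pattern of each is rescaled to a fixed trapezoidal area (time in
#' hours) and the inverse scale is stored in `rho`, so the reconstruction is
#' unchanged.
#'
#' @param model `cpd_model` with a `time` factor (last mode by default)
#' @param target_area target trapezoidal area, default 20
#' @param time_mode index of the time mode, default the last
#' @param dt_hours grid spacing in hours; taken from the model's grid when
#'   present, else required
#' @return rescaled `cpd_model`
#' @export
rescale_temporal <- function(model, target_area = 20, time_mode = NULL,
                             dt_hours = NULL) {
  stopifnot(inherits(model, "cpd_model"))
  if (is.null(time_mode)) time_mode <- length(model$factors)
  if (is.null(dt_hours)) {
    if (is.null(model$grid))
      stop("`dt_hours` is required when the model carries no grid",
           call. = FALSE)
    dt_hours <- model$grid$dt / 60
  }
  Ft <- model$factors[[time_mode]]
  Tn <- nrow(Ft)
  w <- dt_hours * c(0.5, rep(1, Tn - 2L), 0.5)     # trapezoid weights
  areas <- as.numeric(crossprod(Ft, w))
  if (any(areas <= 0))
    stop("temporal factor with non-positive area; cannot rescale",
         call. = FALSE)
  scale <- target_area / areas
  model$factors[[time_mode]] <- sweep(Ft, 2, scale, "*")
  model$rho <- model$rho * (1 / scale)
  model$time_mode <- time_mode
  model
}

#' Component weights of one trajectory
#'
#' `omega_r = lambda_r * rho_r * a_ligand[i,r] * a_dose[j,r] * a_drug[k,r] *
#' a_dd[l,r]`: the weighted sum of the temporal patterns with these weights
#' approximates trajectory (i, j, k, l) up to the fit residual.
#'
#' @param model `cpd_model` fitted on a 5-mode tensor (time last)
#' @param i,j,k,l ligand, ligand-dose, drug, drug-dose indices
#' @return numeric weight vector of length `rank`
#' @export
cpd_weights <- function(model, i, j, k, l) {
  stopifnot(inherits(model, "cpd_model"), length(model$factors) == 5L)
  idx <- c(i, j, k, l)
  for (n in 1:4)
    if (idx[n] < 1 || idx[n] > nrow(model$factors[[n]]))
      stop("index out of range on mode ", n, call. = FALSE)
  model$lambda * model$rho *
    model$factors[[1L]][i, ] * model$factors[[2L]][j, ] *
    model$factors[[3L]][k, ] * model$factors[[4L]][l, ]
}
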