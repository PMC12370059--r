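#' Functional principal component analysis on a dense grid
#'
#' Mean-centered fPCA by eigendecomposition of the empirical covariance
#' under trapezoid quadrature on the sampling grid: eigenfunctions are
#' orthonormal with respect to the quadrature inner product
#' `<f, g> = sum_t f(t) g(t) w_t`, and each trajectory is approximated as
#' `X_m(t) ~ mu(t) + sum_r xi_r(m) phi_r(t)`.
#'
#' Sign convention: each eigenfunction is oriented so that its
#' largest-magnitude value is positive.
#'
#' @param X numeric matrix, trajectories in rows, timepoints in columns
#' @param n_components number of components to retain
#' @param grid [time_grid()] matching the columns (only `dt` is used, for
#'   the quadrature weights); defaults to unit spacing
#' @return object of class `fpca_model`: `mean` (length T), `phi`
#'   (T x R eigenfunctions), `scores` (rows x R), `evr` (explained-variance
#'   fractions, non-increasing), `eigenvalues` (all), `weights`, `grid`
#' @export
fpca_fit <- function(X, n_components, grid = NULL) {
  stopifnot(is.matrix(X), nrow(X) >= 2L)
  Tn <- ncol(X)
  n_components <- as.integer(n_components)
  if (is.na(n_components) || n_components < 1L ||
      n_components > min(nrow(X), Tn))
    stop("`n_components` must be in 1..min(rows, timepoints)", call. = FALSE)
  dt <- if (is.null(grid)) 1 else grid$dt
  w <- dt * c(0.5, rep(1, Tn - 2L), 0.5)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (nrow(X) - 1L)
  sw <- sqrt(w)
  Cw <- C * tcrossprod(sw)               # W^1/2 C W^1/2
  eig <- eigen(Cw, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  phi_all <- eig$vectors / sw            # back-transform: orthonormal under w
  R <- n_components
  phi <- phi_all[, seq_len(R), drop = FALSE]
  # orient: largest-magnitude value positive
  for (r in seq_len(R)) {
    v <- phi[, r]
    if (v[which.max(abs(v))] < 0) phi[, r] <- -v
  }
  scores <- Xc %*% (phi * w)
  tot <- sum(vals)
  structure(
    list(mean = mu, phi = phi, scores = scores,
         evr = if (tot > 0) vals[seq_len(R)] / tot else rep(0, R),
         eigenvalues = vals, weights = w, grid = grid,
         n_components = R),
    class = "fpca_model"
  )
}

#' @export
print.fpca_model <- function(x, ...) {
  cat(sprintf("<fpca_model> %d components, %.1f%% variance explained\n",
              x$n_components, 100 * sum(x$evr)))
  invisible(x)
}

#' Project new trajectories onto fitted eigenfunctions
#' @param model `fpca_model`
#' @param X matrix of trajectories (rows), same grid as the fit
#' @return scores matrix (rows x components)
#' @export
fpca_scores <- function(model, X) {
  stopifnot(inherits(model, "fpca_model"), ncol(X) == length(model$mean))
  sweep(X, 2, model$mean) %*% (model$phi * model$weights)
}
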