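#' Misclustering rate between two partitions
#'
#' Aligns the clusters of `A` one-to-one with the clusters of `B` so as to
#' maximize the number of matched elements (an assignment problem on the
#' cluster-overlap count matrix, padded square with zeros when the cluster
#' counts differ), then returns the fraction of elements left unmatched.
#' Symmetric, zero iff the partitions are identical.
#'
#' @param A,B [partition()] objects over the same element set
#' @return fraction in `[0, 1]`
#' @export
misclustering_rate <- function(A, B) {
  stopifnot(inherits(A, "partition"), inherits(B, "partition"))
  if (!setequal(A$elements, B$elements))
    stop("partitions are over different element sets", call. = FALSE)
  n <- length(A$elements)
  ka <- length(A$clusters); kb <- length(B$clusters)
  O <- matrix(0, ka, kb)
  for (i in seq_len(ka))
    for (j in seq_len(kb))
      O[i, j] <- length(intersect(A$clusters[[i]], B$clusters[[j]]))
  m <- max(ka, kb)
  Osq <- matrix(0, m, m)
  Osq[seq_len(ka), seq_len(kb)] <- O
  assign <- .hungarian_min(max(Osq) - Osq)   # maximize overlap
  matched <- sum(Osq[cbind(seq_len(m), assign)])
  (n - matched) / n
}

# Square min-cost assignment (Hungarian with potentials, O(n^3)).
# Returns, for each row, its assigned column.
.hungarian_min <- function(cost) {
  n <- nrow(cost)
  if (n == 1L) return(1L)
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L); way <- integer(n + 1L)  # index j+1 holds column j
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          if (p[j + 1L] > 0L) u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) assign[p[j + 1L]] <- j
  assign
}

#' Optimize the epsilon linking radius against expert partitions
#'
#' For each candidate epsilon, clusters every calibration regime with
#' [epsilon_cluster()] and averages the misclustering rate against the
#' corresponding expert partition; returns the smallest epsilon attaining
#' the minimum mean MR.
#'
#' @param features list of feature matrices (one per calibration regime,
#'   rows = stimulus conditions)
#' @param experts list of expert [partition()]s, aligned with `features`
#' @param eps_grid strictly increasing vector of candidate radii; default
#'   [eps_grid_from_features()] over the calibration regimes
#' @param nonresponders list of non-responder label vectors per regime
#'   (default: each expert's designated non-responder cluster)
#' @return object of class `epsilon_calibration`: `eps`, `mean_mr`,
#'   `per_regime_mr` (at the optimum), `grid`, `mr_curve`
#' @export
optimize_epsilon <- function(features, experts, eps_grid = NULL,
                             nonresponders = NULL) {
  stopifnot(length(features) >= 1L, length(features) == length(experts))
  if (is.null(eps_grid)) eps_grid <- eps_grid_from_features(features)
  if (!length(eps_grid)) stop("empty epsilon grid", call. = FALSE)
  if (is.unsorted(eps_grid, strictly = TRUE))
    stop("`eps_grid` must be strictly increasing", call. = FALSE)
  if (is.null(nonresponders)) {
    nonresponders <- lapply(experts, function(ex) {
      if (is.null(ex$nonresponder_cluster)) character(0)
      else ex$clusters[[ex$nonresponder_cluster]]
    })
  }
  Ds <- lapply(features, pairwise_distances)
  mr_mat <- vapply(eps_grid, function(eps) {
    vapply(seq_along(Ds), function(g) {
      cl <- epsilon_cluster(Ds[[g]], eps, nonresponders[[g]])
      misclustering_rate(cl, experts[[g]])
    }, numeric(1))
  }, numeric(length(Ds)))
  mr_mat <- matrix(mr_mat, nrow = length(Ds))
  mean_mr <- colMeans(mr_mat)
  best <- which(mean_mr == min(mean_mr))[1L]   # tie -> smallest eps
  structure(
    list(eps = eps_grid[best], mean_mr = mean_mr[best],
         per_regime_mr = mr_mat[, best], grid = eps_grid,
         mr_curve = mean_mr),
    class = "epsilon_calibration"
  )
}

#' @export
print.epsilon_calibration <- function(x, ...) {
  cat(sprintf("<epsilon_calibration> eps = %.4g, mean MR = %.4g over %d regime(s)\n",
              x$eps, x$mean_mr, length(x$per_regime_mr)))
  invisible(x)
}

#' Default epsilon search grid
#'
#' 200 log-spaced values between the 1st and 99th percentile of the pooled
#' non-zero pairwise distances of the given feature matrices.
#'
#' @param features list of feature matrices
#' @param n grid size
#' @return numeric vector
#' @export
eps_grid_from_features <- function(features, n = 200L) {
  d <- unlist(lapply(features, function(F) {
    D <- pairwise_distances(F)
    D[upper.tri(D)]
  }))
  d <- d[d > 0]
  if (!length(d)) stop("all pairwise distances are zero", call. = FALSE)
  q <- stats::quantile(d, c(0.01, 0.99), names = FALSE)
  if (q[1] <= 0) q[1] <- min(d)
  exp(seq(log(q[1]), log(q[2]), length.out = n))
}

#' Read / write partition JSON
#'
#' Format: `{"elements": [...], "clusters": [[...], ...],
#' "nonresponder_cluster": 1-based index or null}`.
#'
#' @param path file path
#' @return [partition()]
#' @export
read_partition <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyMatrix = FALSE)
  cl <- obj$clusters
  if (!is.list(cl)) cl <- list(cl)
  partition(cl, elements = obj$elements,
            nonresponder_cluster = obj$nonresponder_cluster)
}

#' @rdname read_partition
#' @param p [partition()]
#' @export
write_partition <- function(p, path) {
  stopifnot(inherits(p, "partition"))
  obj <- list(elements = p$elements, clusters = p$clusters,
              nonresponder_cluster = p$nonresponder_cluster)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}
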