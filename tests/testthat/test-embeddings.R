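test_that("per-drug tensor normalization decouples compound scales", {
  A <- rank1_tensor(c(3, 2, 2, 2, 10), seed = 3)
  A[, , 1, , ] <- A[, , 1, , ] * 2 / max(A[, , 1, , ])   # slab max 2
  A[, , 2, , ] <- A[, , 2, , ] * 10 / max(A[, , 2, , ])  # slab max 10
  Ah <- normalize_tensor_per_drug(A)
  expect_equal(max(Ah[, , 1, , ]), 1)
  expect_equal(max(Ah[, , 2, , ]), 1)
  expect_equal(Ah[, , 1, , ], A[, , 1, , ] / 2)
  # already-normalized slab is unchanged
  expect_equal(normalize_tensor_per_drug(Ah)[, , 2, , ], Ah[, , 2, , ])
  A0 <- A
  A0[, , 2, , ] <- 0
  expect_error(normalize_tensor_per_drug(A0), "all-zero slab")
})

test_that("CPD recovers an exact rank-1 tensor and improves with rank", {
  A <- rank1_tensor(c(4, 3, 3, 3, 15), seed = 5)
  m1 <- cpd_fit(A, rank = 1, seed = 0, max_iter = 500, restarts = 2)
  expect_gte(m1$r2x, 0.999)
  m2 <- cpd_fit(A, rank = 2, seed = 0, max_iter = 500, restarts = 2)
  expect_gte(m2$r2x, m1$r2x - 1e-9)
  expect_error(cpd_fit(A, rank = 0), "positive integer")
  expect_error(cpd_fit(-A, rank = 1), "non-negative")
})

test_that("temporal rescaling sets area 20 and preserves reconstruction", {
  A <- rank1_tensor(c(3, 2, 2, 2, 25), seed = 9)
  m <- cpd_fit(A, rank = 2, seed = 1, max_iter = 400, restarts = 2)
  dt_hours <- 0.5
  before <- cp_reconstruct(m)
  r2x_before <- m$r2x
  rs <- rescale_temporal(m, target_area = 20, dt_hours = dt_hours)
  Tn <- nrow(rs$factors[[5]])
  w <- dt_hours * c(0.5, rep(1, Tn - 2), 0.5)
  areas <- as.numeric(crossprod(rs$factors[[5]], w))
  expect_equal(areas, rep(20, 2), tolerance = 1e-6)
  after <- cp_reconstruct(rs)
  expect_lt(max(abs(after - before)), 1e-10)
  # R2X is invariant to the rescaling
  r2x_after <- 1 - stats::var(as.numeric(after) - as.numeric(A)) /
    stats::var(as.numeric(A))
  expect_equal(r2x_after, r2x_before, tolerance = 1e-9)
  # worked factor-scaling example: area 40 halves to 20 with rho = 2
  m40 <- m
  w0 <- rep(1, 2)
  a0 <- as.numeric(crossprod(m40$factors[[5]], w))
  m40$factors[[5]] <- sweep(m40$factors[[5]], 2, 40 / a0, "*")
  rs40 <- rescale_temporal(m40, 20, dt_hours = dt_hours)
  expect_equal(rs40$rho, rep(2, 2), tolerance = 1e-9)
})

test_that("component weights are the stated products", {
  fac <- lapply(c(2, 2, 2, 2, 6), function(d) matrix(1, d, 1))
  model <- structure(
    list(factors = fac, lambda = 2, rho = 0.5, rank = 1L,
         r2x = 1, dims = c(2, 2, 2, 2, 6), grid = NULL),
    class = "cpd_model")
  expect_equal(cpd_weights(model, 1, 1, 1, 1), 1)   # 2 * 0.5 * 1^4
  model$factors[[2]][1, 1] <- 0
  expect_equal(cpd_weights(model, 1, 1, 2, 2), 0)
  expect_error(cpd_weights(model, 3, 1, 1, 1), "out of range")

  # on an exact rank-1 tensor the single weighted temporal pattern
  # reproduces each trajectory
  A <- rank1_tensor(c(3, 2, 2, 2, 12), seed = 13)
  m <- cpd_fit(A, rank = 1, seed = 0, max_iter = 500, restarts = 2)
  for (idx in list(c(1, 1, 1, 1), c(3, 2, 2, 2), c(2, 1, 2, 1))) {
    w <- cpd_weights(m, idx[1], idx[2], idx[3], idx[4])
    traj <- A[idx[1], idx[2], idx[3], idx[4], ]
    expect_equal(as.numeric(w * m$factors[[5]]), traj, tolerance = 1e-4)
  }
})

test_that("fPCA satisfies its spectral contracts", {
  g <- time_grid(60, 8)
  tt <- g$t
  mu <- 0.3 * exp(-tt / 200)
  phi1 <- sin(pi * tt / max(tt))
  set.seed(21)
  X1 <- t(vapply(stats::rnorm(40), function(c) mu + c * phi1, tt))
  f1 <- fpca_fit(X1, 2, g)
  expect_gte(f1$evr[1], 0.999)

  # richer data: orthonormality, declining residuals, full-rank variance sum
  X <- t(vapply(seq_len(50), function(i)
    mu + stats::rnorm(1) * phi1 + stats::rnorm(1, sd = 0.5) * cos(pi * tt / 240) +
      stats::rnorm(1, sd = 0.2) * sin(2 * pi * tt / 300) +
      stats::rnorm(length(tt), sd = 0.05), tt))
  f <- fpca_fit(X, 5, g)
  G <- t(f$phi) %*% (f$phi * f$weights)
  expect_equal(G, diag(5), tolerance = 1e-6)
  expect_true(all(diff(f$evr) <= 1e-12))
  expect_lte(sum(f$evr), 1 + 1e-9)
  resid <- vapply(1:5, function(r) {
    recon <- matrix(f$mean, nrow(X), ncol(X), byrow = TRUE) +
      f$scores[, 1:r, drop = FALSE] %*% t(f$phi[, 1:r, drop = FALSE])
    sum((X - recon) ^ 2)
  }, numeric(1))
  expect_true(all(diff(resid) < 0))

  ffull <- fpca_fit(X, min(nrow(X), ncol(X)), g)
  expect_equal(sum(ffull$eigenvalues) / sum(ffull$eigenvalues), 1)
  nz <- ffull$eigenvalues > 1e-10 * max(ffull$eigenvalues)
  expect_equal(sum(ffull$evr[seq_len(sum(nz))]), 1, tolerance = 1e-6)

  # scores of the mean trajectory are zero
  expect_equal(as.numeric(fpca_scores(f, matrix(f$mean, 1))),
               rep(0, 5), tolerance = 1e-8)
  expect_error(fpca_fit(X, 1000, g), "n_components")
})

# flatten the 5-mode tensor to trajectories x time
.unfold_for_test <- function(A) {
  d <- dim(A)
  t(apply(array(A, c(prod(d[1:4]), d[5])), 1, identity))
}

test_that("CPD ignores time order while fPCA does not", {
  A <- rank1_tensor(c(3, 2, 2, 2, 24), seed = 31)
  # add a second component so the tensor is not trivially symmetric
  A <- A + rank1_tensor(c(3, 2, 2, 2, 24), seed = 32) / 2
  perm <- c(13:24, 1:12)
  Ap <- A[, , , , perm]
  m <- cpd_fit(A, rank = 2, seed = 2, max_iter = 400, restarts = 3)
  mp <- cpd_fit(Ap, rank = 2, seed = 2, max_iter = 400, restarts = 3)
  expect_equal(m$r2x, mp$r2x, tolerance = 1e-4)

  X <- .unfold_for_test(A)
  fp <- fpca_fit(X, 2)
  fpp <- fpca_fit(X[, perm], 2)
  expect_gt(max(abs(fp$phi[, 1] - fpp$phi[, 1])), 0.01)
})

test_that("feature_matrix returns canonical 15-row matrices per space", {
  g <- time_grid(41, 12)
  regimes <- c(list(untreated_regime()), single_drug_regimes("IKKi", 1:2))
  set <- simulate_grid(regimes, grid = g)
  tab <- codon_table(set)
  norm <- normalize_codons(tab)

  Fc <- feature_matrix("untreated", "codon", codons = norm)
  expect_equal(dim(Fc), c(15L, 6L))
  expect_identical(rownames(Fc), stimulus_order())

  Ft <- feature_matrix("IKKi_DD01", "trajectory", set = set)
  expect_equal(dim(Ft), c(15L, g$n_points))

  fp <- fpca_fit(set$values, 5, g)
  Ff <- feature_matrix("IKKi_DD01", "fpca", set = set, fpca = fp)
  expect_equal(dim(Ff), c(15L, 5L))

  A <- normalize_tensor_per_drug(as_tensor(set))
  m <- label_cpd(suppressWarnings(
    cpd_fit(A, 2, seed = 0, max_iter = 150, restarts = 1, tol = 1e-6)), A)
  Fw <- feature_matrix("IKKi_DD02", "cpd", set = set, cpd = m)
  expect_equal(dim(Fw), c(15L, 2L))
  expect_error(feature_matrix("untreated", "cpd", set = set, cpd = m),
               "not present")
  expect_error(feature_matrix("nope", "codon", codons = norm), "not found")
})
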