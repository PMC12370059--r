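# Independent oracles used across the suite. These deliberately use a
# different algorithmic route than the implementation they check.

# Transitive-closure clustering oracle: boolean powering of the threshold
# adjacency matrix until fixpoint, then row-pattern grouping.
oracle_closure_clusters <- function(D, eps) {
  A <- D <= eps
  diag(A) <- TRUE
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  comp <- match(apply(A, 1, paste, collapse = ""),
                unique(apply(A, 1, paste, collapse = "")))
  comp
}

# Exhaustive misclustering-rate oracle: enumerate all injective alignments
# of the smaller partition's clusters onto the larger's.
oracle_mr <- function(A, B) {
  n <- length(A$elements)
  ka <- length(A$clusters); kb <- length(B$clusters)
  if (ka > kb) return(oracle_mr(B, A))
  overlap <- function(i, j)
    length(intersect(A$clusters[[i]], B$clusters[[j]]))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- 0L
  for (cols in combn(kb, ka, simplify = FALSE))
    for (p in perms(cols)) {
      m <- sum(vapply(seq_len(ka), function(i) overlap(i, p[i]), 0L))
      if (m > best) best <- m
    }
  (n - best) / n
}

# Random partition of elements 1..n into at most kmax clusters
random_partition <- function(n, kmax, nonresp_prob = 0) {
  k <- sample(seq_len(min(kmax, n)), 1L)
  memb <- sample(seq_len(k), n, replace = TRUE)
  memb <- match(memb, unique(memb))          # drop empty clusters
  cl <- split(seq_len(n), memb)
  nr <- if (nonresp_prob > 0 && stats::runif(1) < nonresp_prob)
    sample(seq_along(cl), 1L) else NULL
  partition(unname(cl), elements = seq_len(n), nonresponder_cluster = nr)
}

# Direct-sum discrete Fourier oracle for the oscillatory band power:
# explicit exponential sums, no fft().
oracle_band_power <- function(x, dt, band = c(0.33, 1)) {
  n <- length(x)
  ks <- seq_len(floor(n / 2))
  freq <- ks / (n * dt / 60)
  ks <- ks[freq >= band[1] & freq <= band[2]]
  sum(vapply(ks, function(k) {
    ang <- -2 * pi * k * (seq_len(n) - 1) / n
    Mod(sum(x * complex(real = cos(ang), imaginary = sin(ang)))) ^ 2
  }, numeric(1)))
}

# Small non-negative rank-1 five-mode tensor from fixed positive vectors
rank1_tensor <- function(dims, seed = 1) {
  set.seed(seed)
  vecs <- lapply(dims, function(d) stats::runif(d, 0.2, 1))
  A <- array(Reduce(function(a, b) outer(a, b), vecs), dim = dims)
  A
}

# A tiny trajectory set (2 ligands x 2 doses x 2 drugs x 2 dds) built from
# deterministic waveforms -- no ODE involved.
toy_trajectory_set <- function(n_points = 61, dt = 8) {
  g <- time_grid(n_points, dt)
  combos <- expand.grid(dd = 1:2, drug = c("A", "B"),
                        ligand_dose = c("Low", "High"),
                        ligand = c("L1", "L2"), stringsAsFactors = FALSE)
  vals <- t(vapply(seq_len(nrow(combos)), function(r) {
    amp <- 0.2 + 0.2 * (combos$ligand[r] == "L2") +
      0.3 * (combos$ligand_dose[r] == "High")
    dec <- 0.004 * combos$dd[r] + 0.002 * (combos$drug[r] == "B")
    generate_waveform(g, amp, onset = 10, rise_time = 25,
                      decay_rate = dec)$values
  }, numeric(n_points)))
  meta <- data.frame(
    regime_id = paste0(combos$drug, "_DD", combos$dd),
    drug = combos$drug, dd = combos$dd, ligand = combos$ligand,
    ligand_dose = combos$ligand_dose,
    stimulus = paste0(combos$ligand, "_",
                      substr(combos$ligand_dose, 1, 1)),
    stringsAsFactors = FALSE
  )
  trajectory_set(vals, meta, g)
}
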