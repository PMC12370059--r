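#' Signaling codons
#'
#' Six interpretable dynamic features of a signaling trajectory
#' `x = (x_1, ..., x_N)` sampled every `dt` minutes: activation Speed, Peak
#' amplitude, Duration above a low threshold, total activity (AUC),
#' early-vs-late activity timing (EvL), and oscillatory band power (Osc).
#' Timing codons are reported in minutes from the first sample; the sample at
#' index i (1-based) sits at time `(i - 1) * dt`.
#'
#' @name codons
#' @param x numeric trajectory values, or a `trajectory` object
#' @param dt sampling interval in minutes (taken from the object when `x` is
#'   a `trajectory`)
NULL

.traj_values <- function(x) if (inherits(x, "trajectory")) x$values else x
.traj_dt <- function(x, dt) if (inherits(x, "trajectory")) x$grid$dt else dt

# Largest attainable timing on the grid, used as the sentinel for degenerate
# Speed/EvL and the non-responder correction: (N - 1) * dt (480 min on the
# default grid).
.t_max <- function(n, dt) (n - 1) * dt

#' @describeIn codons time of the first qualifying local maximum: the
#'   smallest interior index i > 3 with `x_i > x_{i-1}`, `x_i >= x_{i+1}`
#'   and `x_i > 0` (plateaus admitted on the right). Returns the sentinel
#'   `(N-1)*dt` when no such peak exists.
#' @export
codon_speed <- function(x, dt = 1) {
  v <- .traj_values(x); dt <- .traj_dt(x, dt)
  n <- length(v)
  stopifnot(n >= 5L)
  i <- 2:(n - 1L)
  is_peak <- v[i] > v[i - 1L] & v[i] >= v[i + 1L] & v[i] > 0
  cand <- i[is_peak & i > 3L]
  if (!length(cand)) return(.t_max(n, dt))
  (cand[1L] - 1L) * dt
}

#' @describeIn codons maximal trajectory value
#' @export
codon_peak <- function(x, dt = 1) max(.traj_values(x))

#' @describeIn codons total time spent above `threshold`:
#'   `|{i : x_i > threshold}| * dt`
#' @param threshold activity threshold (a.u.) for Duration
#' @export
codon_duration <- function(x, threshold = 0.05, dt = 1) {
  v <- .traj_values(x); dt <- .traj_dt(x, dt)
  stopifnot(threshold >= 0)
  sum(v > threshold) * dt
}

#' @describeIn codons trapezoidal integral over the grid
#' @export
codon_auc <- function(x, dt = 1) {
  v <- .traj_values(x); dt <- .traj_dt(x, dt)
  n <- length(v)
  stopifnot(n >= 2L)
  sum((v[-n] + v[-1L]) * dt / 2)
}

# cumulative trapezoid through sample i (c_1 = 0, c_N = AUC)
.cumtrapz <- function(v, dt) c(0, cumsum((v[-length(v)] + v[-1L]) * dt / 2))

#' @describeIn codons time at which the cumulative activity first best
#'   approximates half the total (ties to the smallest index)
#' @export
codon_evl <- function(x, dt = 1) {
  v <- .traj_values(x); dt <- .traj_dt(x, dt)
  stopifnot(length(v) >= 2L)
  cc <- .cumtrapz(v, dt)
  (which.min(abs(cc - max(cc) / 2)) - 1L) * dt
}

#' @describeIn codons summed power spectral density `|fft(x)|^2` over
#'   positive frequencies in the band 0.33--1 cycles/hour (inclusive); the
#'   frequency of bin k is `k / (N * dt)` with `dt` in hours, so the DC bin
#'   is never in band
#' @param band frequency band in cycles/hour, default `c(0.33, 1)`
#' @export
codon_osc <- function(x, dt = 1, band = c(0.33, 1)) {
  v <- .traj_values(x); dt <- .traj_dt(x, dt)
  n <- length(v)
  xf <- stats::fft(v)
  k <- seq_len(floor(n / 2))          # positive frequencies only
  freq <- k / (n * dt / 60)           # cycles per hour
  inband <- freq >= band[1] & freq <= band[2]
  sum(Mod(xf[k + 1L])[inband] ^ 2)
}

#' Extract all six codons from one trajectory
#'
#' Trajectories whose peak falls below `nonresponder_cutoff` (strictly) are
#' flagged as non-responders and their Speed and EvL are corrected to the
#' maximal timing `(N-1)*dt`, placing them far from fast early responders in
#' feature space.
#'
#' @inheritParams codons
#' @param threshold Duration threshold (a.u.)
#' @param nonresponder_cutoff peak cutoff below which a trajectory is a
#'   non-responder (default 0.05, strict `<`)
#' @return named list: `speed`, `peak`, `duration`, `auc`, `evl`, `osc`,
#'   `is_nonresponder`
#' @export
extract_codons <- function(x, threshold = 0.05, nonresponder_cutoff = 0.05,
                           dt = 1) {
  v <- .traj_values(x); dt <- .traj_dt(x, dt)
  pk <- codon_peak(v)
  nr <- pk < nonresponder_cutoff
  tmax <- .t_max(length(v), dt)
  list(
    speed = if (nr) tmax else codon_speed(v, dt),
    peak = pk,
    duration = codon_duration(v, threshold, dt),
    auc = codon_auc(v, dt),
    evl = if (nr) tmax else codon_evl(v, dt),
    osc = codon_osc(v, dt),
    is_nonresponder = nr
  )
}

.codon_names <- c("speed", "peak", "duration", "auc", "evl", "osc")

#' Codon table for a trajectory set
#'
#' One row per trajectory: the set's metadata columns followed by the six
#' raw codon values and the non-responder flag.
#'
#' @param set [trajectory_set()]
#' @inheritParams extract_codons
#' @return data.frame
#' @export
codon_table <- function(set, threshold = 0.05, nonresponder_cutoff = 0.05) {
  stopifnot(inherits(set, "trajectory_set"))
  dt <- set$grid$dt
  rows <- lapply(seq_len(nrow(set$values)), function(i)
    extract_codons(set$values[i, ], threshold, nonresponder_cutoff, dt))
  out <- cbind(
    set$meta,
    do.call(rbind, lapply(rows, function(r)
      as.data.frame(r[c(.codon_names, "is_nonresponder")])))
  )
  rownames(out) <- NULL
  out
}

#' Min-max normalize codon columns
#'
#' Per-codon min-max scaling to `[0, 1]`, with bounds computed jointly over
#' the whole analyzed collection (all regimes share one scale so distances
#' are comparable across regimes). Constant columns map to 0. Pass
#' previously computed `bounds` to place new data on an existing scale.
#'
#' @param tab codon data.frame from [codon_table()] (any extra columns are
#'   carried through)
#' @param bounds optional bounds object from a previous call
#' @return list with `table` (codon columns replaced by normalized values)
#'   and `bounds` (2 x 6 matrix, rows `min`/`max`)
#' @export
normalize_codons <- function(tab, bounds = NULL) {
  stopifnot(all(.codon_names %in% names(tab)))
  if (is.null(bounds)) {
    bounds <- sapply(.codon_names, function(cn) range(tab[[cn]]))
    rownames(bounds) <- c("min", "max")
  }
  out <- tab
  for (cn in .codon_names) {
    lo <- bounds["min", cn]; hi <- bounds["max", cn]
    out[[cn]] <- if (hi > lo) (tab[[cn]] - lo) / (hi - lo) else
      rep(0, nrow(tab))
  }
  list(table = out, bounds = bounds)
}
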