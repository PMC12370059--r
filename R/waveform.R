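#' Parametric waveform generator with known codon values
#'
#' Generates deterministic test waveforms whose codon values are known from
#' the continuous-time form, independently of the discrete codon
#' implementation. Two families:
#'
#' * `"damped"`: `A * (1 - exp(-s/tau_r)) * exp(-lambda s) *
#'   (1 - depth * cos(2 pi f s))` for `s = t - onset >= 0`, clipped at 0.
#' * `"triangle"`: symmetric triangular pulse rising from `onset` to apex
#'   `A` at `onset + rise_time` and back to 0.
#'
#' For oscillation-free waveforms (`osc_depth = 0`) the expected Speed,
#' Peak, Duration, AUC and EvL are derived from the continuous envelope
#' (calculus for the peak and area, root-finding on the closed-form
#' cumulative integral for EvL and the threshold crossings for Duration).
#' With `osc_depth > 0` no expected values are returned (the discrete
#' Fourier oracle in the test suite covers the oscillatory codon).
#'
#' @param grid [time_grid()]
#' @param amplitude envelope scale, >= 0
#' @param onset delay before the waveform starts, minutes
#' @param rise_time rise time constant (damped) or time to apex (triangle)
#' @param decay_rate exponential decay rate, 1/min (damped family; > 0 for
#'   expected-codon computation)
#' @param osc_freq oscillation frequency, 1/hour
#' @param osc_depth oscillation depth in `[0, 1]`
#' @param shape `"damped"` or `"triangle"`
#' @param threshold Duration threshold used for the expected value
#' @return list with `values` (waveform on the grid) and `expected` (named
#'   list of codon values, or NULL when `osc_depth > 0`)
#' @export
generate_waveform <- function(grid, amplitude, onset = 0, rise_time = 20,
                              decay_rate = 0.01, osc_freq = 0, osc_depth = 0,
                              shape = c("damped", "triangle"),
                              threshold = 0.05) {
  shape <- match.arg(shape)
  stopifnot(inherits(grid, "time_grid"), amplitude >= 0, osc_freq >= 0,
            osc_depth >= 0, osc_depth <= 1, rise_time > 0)
  t <- grid$t - grid$t_start
  s <- pmax(t - onset, 0)
  if (shape == "triangle") {
    env <- amplitude * pmax(0, 1 - abs(s - rise_time) / rise_time)
    env[t < onset] <- 0
  } else {
    env <- amplitude * (1 - exp(-s / rise_time)) * exp(-decay_rate * s)
    env[t < onset] <- 0
  }
  x <- env
  if (osc_depth > 0 && osc_freq > 0) {
    x <- env * (1 - osc_depth * cos(2 * pi * osc_freq / 60 * s))
    x[t < onset] <- 0
  }
  x <- pmax(x, 0)
  expected <- NULL
  if (osc_depth == 0 && amplitude > 0) {
    expected <- if (shape == "triangle") {
      .triangle_expected(amplitude, onset, rise_time, threshold, grid)
    } else if (decay_rate > 0) {
      .damped_expected(amplitude, onset, rise_time, decay_rate, threshold,
                       grid)
    }
  }
  list(values = x, expected = expected)
}

.triangle_expected <- function(A, onset, w, thr, grid) {
  span <- grid$t[grid$n_points] - grid$t[1]
  apex <- onset + w
  dur <- if (thr >= A) 0 else 2 * w * (1 - thr / A)
  list(speed = apex, peak = A, duration = dur, auc = A * w, evl = apex)
}

.damped_expected <- function(A, onset, tau, lam, thr, grid) {
  Send <- grid$t[grid$n_points] - grid$t[1] - onset
  g <- function(s) (1 - exp(-s / tau)) * exp(-lam * s)
  # cumulative integral of g from 0 to s, closed form
  G <- function(s) (1 - exp(-lam * s)) / lam -
    (1 - exp(-(lam + 1 / tau) * s)) / (lam + 1 / tau)
  s_peak <- tau * log(1 + 1 / (lam * tau))
  peak <- A * g(min(s_peak, Send))
  total <- A * G(Send)
  evl_s <- stats::uniroot(function(s) A * G(s) - total / 2,
                          c(0, Send), tol = 1e-10)$root
  dur <- 0
  if (thr < peak) {
    sp <- min(s_peak, Send)
    lo <- if (A * g(1e-12) >= thr) 0 else
      stats::uniroot(function(s) A * g(s) - thr, c(1e-12, sp),
                     tol = 1e-10)$root
    hi <- if (A * g(Send) > thr) Send else
      stats::uniroot(function(s) A * g(s) - thr, c(sp, Send),
                     tol = 1e-10)$root
    dur <- hi - lo
  }
  list(speed = onset + min(s_peak, Send), peak = peak, duration = dur,
       auc = total, evl = onset + evl_s)
}
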