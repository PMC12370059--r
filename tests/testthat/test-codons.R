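test_that("Speed finds the first qualifying local maximum", {
  x <- rep(0.1, 481)
  x[25] <- 0.5                              # peak at 1-based index 25
  expect_equal(codon_speed(x, 1), 24)

  expect_equal(codon_speed(seq(1, 0, length.out = 481), 1), 480)  # no peak

  # plateau peak: rises into index 10, flat at 10..11, then falls
  x <- c(seq(0, 0.9, length.out = 10), 0.9, seq(0.8, 0, length.out = 470))
  expect_equal(codon_speed(x, 1), 9)

  # peaks at i <= 3 are ignored
  x <- rep(0.1, 481); x[2] <- 0.9; x[50] <- 0.5
  expect_equal(codon_speed(x, 1), 49)
})

test_that("Peak, Duration and AUC follow their definitions", {
  x <- rep(0.3, 481)
  expect_equal(codon_peak(x), 0.3)
  expect_equal(codon_peak(2 * x), 0.6)
  expect_equal(codon_peak(rep(0, 481)), 0)

  y <- c(rep(1, 100), rep(0, 381))
  expect_equal(codon_duration(y, 0.5, 1), 100)
  expect_equal(codon_duration(y, 2, 1), 0)
  thr <- seq(0, 1, by = 0.1)
  durs <- vapply(thr, function(th) codon_duration(y, th, 1), numeric(1))
  expect_true(all(diff(durs) <= 0))          # non-increasing in threshold

  expect_equal(codon_auc(rep(0.25, 481), 1), 480 * 0.25)
  ramp <- seq(0, 1, length.out = 481)
  expect_equal(codon_auc(ramp, 1), 240)      # triangle, exact for trapezoid
  z <- stats::runif(481)
  expect_equal(codon_auc(ramp + z, 1), codon_auc(ramp, 1) + codon_auc(z, 1))
})

test_that("EvL finds the half-activity time", {
  expect_equal(codon_evl(rep(0.2, 481), 1), 240, tolerance = 1.0001)
  g <- time_grid(481, 1)
  tri <- generate_waveform(g, 1, onset = 60, rise_time = 60,
                           shape = "triangle")
  expect_lte(abs(codon_evl(tri$values, 1) - 120), 1)
  expect_equal(codon_evl(rep(0, 481), 1), 0)  # degenerate: smallest index
})

test_that("Osc sums in-band spectral power only", {
  expect_equal(codon_osc(rep(0, 481), 1), 0)
  t_min <- 0:480
  # bin-aligned frequencies (k cycles per record) to avoid leakage:
  # k = 4 -> 0.499/hr (in band), k = 16 -> 1.995/hr (out of band)
  inband <- 0.3 * cos(2 * pi * 4 * t_min / 481)
  outband <- 0.3 * cos(2 * pi * 16 * t_min / 481)
  expect_gt(codon_osc(inband, 1), codon_osc(outband, 1))
  expect_lt(codon_osc(outband, 1), 1e-6 * codon_osc(inband, 1))
  # DC offset never in band
  expect_equal(codon_osc(inband + 5, 1), codon_osc(inband, 1),
               tolerance = 1e-9)
  # agrees with the direct-sum Fourier oracle
  x <- generate_waveform(time_grid(241, 2), 0.6, rise_time = 20,
                         decay_rate = 0.01, osc_freq = 0.6,
                         osc_depth = 0.7)$values
  expect_equal(codon_osc(x, 2), oracle_band_power(x, 2), tolerance = 1e-9)
})

test_that("extract_codons applies the non-responder rules", {
  z <- extract_codons(rep(0, 481), dt = 1)
  expect_true(z$is_nonresponder)
  expect_equal(z$speed, 480)
  expect_equal(z$evl, 480)
  expect_equal(z$peak, 0)
  expect_equal(z$auc, 0)
  expect_equal(z$duration, 0)
  expect_equal(z$osc, 0)

  # the cutoff is strict: peak exactly 0.05 responds
  x <- rep(0.01, 481); x[30:40] <- 0.05
  expect_false(extract_codons(x, dt = 1)$is_nonresponder)
  x[30:40] <- 0.049999
  expect_true(extract_codons(x, dt = 1)$is_nonresponder)
})

test_that("codons scale correctly with trajectory amplitude", {
  g <- time_grid(241, 2)
  set.seed(7)
  for (i in 1:20) {
    x <- generate_waveform(g, stats::runif(1, 0.2, 1), onset = runif(1, 0, 30),
                           rise_time = runif(1, 8, 40),
                           decay_rate = runif(1, 0.004, 0.03),
                           osc_freq = runif(1, 0.3, 0.9),
                           osc_depth = runif(1, 0, 0.9))$values
    c1 <- extract_codons(x, threshold = 0.02, dt = 2)
    c2 <- extract_codons(3 * x, threshold = 0.06, dt = 2)
    expect_equal(c2$peak, 3 * c1$peak)
    expect_equal(c2$auc, 3 * c1$auc)
    expect_equal(c2$osc, 9 * c1$osc, tolerance = 1e-9)
    expect_equal(c2$speed, c1$speed)
    expect_equal(c2$evl, c1$evl)
    expect_equal(c2$duration, c1$duration)   # threshold scaled with x
    # timings quantized to dt and within range
    expect_true(all(c(c1$speed, c1$evl, c1$duration) %% 2 == 0))
    expect_true(all(c(c1$speed, c1$evl) <= 480))
  }
})

test_that("extracted codons recover closed-form waveform values", {
  g <- time_grid(481, 1)
  set.seed(11)
  n_ok <- 0
  while (n_ok < 100) {
    wf <- generate_waveform(g, stats::runif(1, 0.15, 1),
                            onset = stats::runif(1, 0, 60),
                            rise_time = stats::runif(1, 6, 60),
                            decay_rate = stats::runif(1, 0.003, 0.04))
    ex <- wf$expected
    if (ex$peak < 0.1 || ex$speed < 6 || ex$speed > 450) next
    n_ok <- n_ok + 1
    got <- extract_codons(wf$values, threshold = 0.05, dt = 1)
    expect_false(got$is_nonresponder)
    expect_lte(abs(got$speed - ex$speed), 1)
    expect_lte(abs(got$evl - ex$evl), 1)
    expect_lte(abs(got$duration - ex$duration), 1)
    expect_equal(got$peak, ex$peak, tolerance = 0.01)
    expect_equal(got$auc, ex$auc, tolerance = 0.01)
  }
})

test_that("codon normalization is a guarded global min-max", {
  set <- toy_trajectory_set()
  tab <- codon_table(set, threshold = 0.02)
  norm <- normalize_codons(tab)
  for (cn in c("speed", "peak", "duration", "auc", "evl", "osc")) {
    v <- norm$table[[cn]]
    expect_true(all(v >= 0 & v <= 1))
    if (norm$bounds["max", cn] > norm$bounds["min", cn]) {
      expect_equal(min(v), 0)
      expect_equal(max(v), 1)
    }
  }
  # constant column maps to zero
  tab2 <- tab
  tab2$duration <- 5
  norm2 <- normalize_codons(tab2)
  expect_true(all(norm2$table$duration == 0))
  # idempotent: renormalizing with its own bounds reproduces the table
  renorm <- normalize_codons(norm$table,
                             bounds = rbind(min = rep(0, 6), max = rep(1, 6),
                                            deparse.level = 0) |>
                               `colnames<-`(c("speed", "peak", "duration",
                                              "auc", "evl", "osc")))
  expect_equal(renorm$table, norm$table)
})
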