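test_that("dose ladder matches the printed design", {
  lad <- build_dose_ladder(20, -0.15, -3)
  expect_length(lad, 20)
  expect_equal(lad[20], 1e-3)
  expect_equal(lad[1], 10 ^ -0.15, tolerance = 1e-12)  # ~0.70795
  expect_true(all(diff(lad) < 0))
  expect_true(all(lad > 0 & lad < 1))
  expect_equal(build_dose_ladder(1, -2, -2), 0.01)
  expect_error(build_dose_ladder(0), "positive integer")
})

test_that("apply_regime scales targeted parameters and only those", {
  p <- core_params()
  expect_identical(apply_regime(p, untreated_regime()), p)

  lad <- build_dose_ladder()
  rg <- drug_regime("IKKi", 20, lad)
  p2 <- apply_regime(p, rg)
  expect_equal(p2[["ikk_gain"]], p[["ikk_gain"]] * 1e-3)
  untouched <- setdiff(names(p), names(rg$multiplier_map))
  expect_identical(p2[untouched], p[untouched])

  # multiplicative composition of combinations
  a <- drug_regime("CHX", 5, lad)
  b <- drug_regime("CHX", 5, lad)
  ab <- combine_regimes(a, b)
  p3 <- apply_regime(p, ab)
  expect_equal(p3[["translation"]], p[["translation"]] * lad[5] ^ 2)

  bad <- drug_regime("IKKi", 1, lad)
  bad$multiplier_map <- c(no_such_rate = 0.5)
  expect_error(apply_regime(p, bad), "no_such_rate")
})

test_that("combination builder yields the 45 x 4 = 180 regime design", {
  combos <- combination_regimes()
  expect_length(combos, 180)
  expect_length(unique(vapply(combos, `[[`, "", "regime_id")), 180)
  # every combination has two components and a positive multiplier map
  expect_true(all(vapply(combos, function(r) length(r$components) == 2L,
                         TRUE)))
  expect_true(all(vapply(combos, function(r) all(r$multiplier_map > 0),
                         TRUE)))
})

test_that("IKK input curves behave as specified", {
  g <- time_grid(241, 2)
  zero <- ligand_input_spec("TNF", "Low", 0, 5, 60, 0.1)
  expect_identical(ikk_input_curve(zero, g), rep(0, g$n_points))

  sustained <- ligand_input_spec("LPS", "High", 0.6, 20, 100, 1)
  u <- ikk_input_curve(sustained, g)
  expect_true(all(diff(u) >= -1e-12))          # no decay phase
  expect_identical(u[1], 0)

  lo <- ligand_input_spec("TNF", "Low", 0.3, 5, 60, 0.1)
  hi <- ligand_input_spec("TNF", "High", 0.6, 5, 60, 0.1)
  expect_true(all(ikk_input_curve(hi, g) >= ikk_input_curve(lo, g)))
  expect_equal(ikk_input_curve(hi, g), 2 * ikk_input_curve(lo, g))
})

test_that("zero input stays at the pre-equilibrated baseline", {
  g <- time_grid(121, 4)
  tr <- simulate_trajectory(core_params(), rep(0, g$n_points), g)
  expect_lt(max(tr$values) - min(tr$values), 1e-6)
  expect_lt(max(tr$values), 0.05)              # below non-responder cutoff
  expect_lt(tr$ss_delta, 1e-8)                 # phase-1 convergence
})

test_that("states stay non-negative and the NFkB pool is conserved", {
  g <- time_grid(481, 1)
  p <- core_params()
  u <- ikk_input_curve(ligand_library()$TNF_H, g, p)
  tr <- simulate_trajectory(p, u, g)
  st <- tr$states
  expect_true(all(st >= 0))
  bound_pool <- st[, "nfkbn"] + st[, "complex"]
  expect_true(all(bound_pool <= p[["tot_nfkb"]] * (1 + 1e-6)))
  free_cyt <- p[["tot_nfkb"]] - bound_pool
  expect_equal(max(abs(st[, "nfkbn"] + st[, "complex"] + free_cyt -
                         p[["tot_nfkb"]])), 0, tolerance = 1e-6)
})

test_that("integration is step-converged at the default RK4 step", {
  g <- time_grid(161, 3)
  p <- core_params()
  u <- ikk_input_curve(ligand_library()$LPS_H, g, p)
  coarse <- simulate_trajectory(p, u, g, h = 0.05)$values
  fine <- simulate_trajectory(p, u, g, h = 0.01)$values
  expect_lt(max(abs(coarse - fine)), 1e-6)
})

test_that("removing the feedback (CHX-like) enhances late activity", {
  g <- time_grid(241, 2)
  p <- core_params()
  u <- ikk_input_curve(ligand_library()$TNF_H, g, p)
  untr <- simulate_trajectory(p, u, g)$values
  chx <- apply_regime(p, drug_regime("CHX", 20))
  trt <- simulate_trajectory(chx, u, g)$values
  late <- g$t > 240
  expect_gte(mean(trt[late]), mean(untr[late]))
})

test_that("simulate_grid is complete, deterministic, and counts match", {
  g <- time_grid(41, 12)
  lig1 <- ligand_library()["TNF_H"]
  one <- simulate_grid(list(drug_regime("IKKi", 1)), lig1, grid = g)
  expect_equal(n_trajectories(one), 1L)

  regimes <- c(list(untreated_regime()),
               single_drug_regimes(c("IKKi", "CHX"), c(1L, 10L)))
  set1 <- simulate_grid(regimes, ligand_library(), grid = g)
  expect_equal(n_trajectories(set1), 5L * 15L)
  set2 <- simulate_grid(regimes, ligand_library(), grid = g)
  expect_identical(set1$values, set2$values)   # bit-identical re-run
})

test_that("a pure IKK inhibitor attenuates peaks monotonically in dose", {
  g <- time_grid(97, 5)
  dds <- c(1L, 4L, 7L, 10L, 14L, 20L)
  sets <- lapply(dds, function(dd)
    simulate_grid(list(drug_regime("IKKi", dd)), grid = g))
  peaks <- vapply(sets, function(s) apply(s$values, 1, max),
                  numeric(15L))
  for (i in seq_len(15L))
    expect_true(all(diff(peaks[i, ]) <= 1e-9),
                info = sprintf("stimulus %d", i))
})

test_that("plug-in models are honoured by simulate_grid", {
  g <- time_grid(31, 16)
  fake <- function(params, input, grid) input * params[["tot_nfkb"]]
  set <- simulate_grid(list(untreated_regime()), ligand_library()["TNF_M"],
                       grid = g, model = fake)
  expect_equal(set$values[1, ],
               ikk_input_curve(ligand_library()$TNF_M, g))
})

test_that("waveform generator reproduces its stated shapes", {
  g <- time_grid(481, 1)
  flat <- generate_waveform(g, 0)
  expect_identical(flat$values, rep(0, 481))

  tri <- generate_waveform(g, 0.8, onset = 60, rise_time = 60,
                           shape = "triangle")
  expect_equal(tri$expected$evl, 120)
  expect_equal(codon_evl(tri$values, 1), 120, tolerance = 1.000001)

  env <- generate_waveform(g, 0.5, rise_time = 15, decay_rate = 0.01)
  osc <- generate_waveform(g, 0.5, rise_time = 15, decay_rate = 0.01,
                           osc_freq = 0.5, osc_depth = 0.8)
  expect_gt(codon_osc(osc$values, 1), codon_osc(env$values, 1))
  expect_gt(oracle_band_power(osc$values, 1),
            oracle_band_power(env$values, 1))
})
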