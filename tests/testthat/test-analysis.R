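test_that("a constant probe is classified as non-oscillatory", {
  tr <- fake_trajectory(seq(0, 400, by = 0.5), probe = rep(5, 801))
  osc <- detect_oscillation(tr)
  expect_false(osc$oscillating)
  expect_true(is.na(osc$period))
})

test_that("a synthetic 40 s sinusoid is recovered to half a second", {
  tt <- seq(0, 400, by = 0.5)
  tr <- fake_trajectory(tt, probe = 10 + 3 * sin(2 * pi * tt / 40))
  osc <- detect_oscillation(tr)
  expect_true(osc$oscillating)
  expect_equal(osc$period, 40, tolerance = 0.5 / 40)
  expect_equal(osc$amplitude, 3, tolerance = 0.01)
})

test_that("a decaying ring-down is not a sustained oscillation", {
  tt <- seq(0, 400, by = 0.5)
  probe <- 10 + 3 * exp(-tt / 40) * sin(2 * pi * tt / 40)
  tr <- fake_trajectory(tt, probe = probe)
  expect_false(detect_oscillation(tr)$oscillating)
})

test_that("the default parameter set oscillates with a ~40 s period", {
  osc <- detect_oscillation(default_run())
  expect_true(osc$oscillating)
  expect_equal(osc$period, 40, tolerance = 0.15)
})

test_that("performance scores synthetic profiles by their h/w geometry", {
  tt <- seq(0, 100, by = 0.5)
  flat <- fake_trajectory(tt, probe = rep(1, length(tt)),
                          profile = rep(2, 65))
  pf <- performance(flat)
  expect_equal(pf$h, 0)
  expect_equal(pf$score, 0)

  # symmetric V: poles at twice the mid-cell value, half-depth width 1/2
  z <- (seq_len(65) - 0.5) / 65  # odd count: one center at exactly mid-cell
  vee <- fake_trajectory(tt, probe = rep(1, length(tt)),
                         profile = 3 * (1 + 2 * abs(z - 0.5)))
  pf <- performance(vee)
  expect_equal(pf$h, 1, tolerance = 0.02)
  expect_equal(pf$w, 0.5, tolerance = 0.02)
  expect_equal(pf$score, 2, tolerance = 0.05)

  # inverted profile: mid-cell is the maximum, score negative
  dome <- fake_trajectory(tt, probe = rep(1, length(tt)),
                          profile = 5 * (1 - 0.4 * abs(z - 0.5)))
  pf <- performance(dome)
  expect_equal(pf$h, -0.2, tolerance = 0.02)
  expect_lt(pf$score, 0)
  expect_equal(sign(pf$score), sign(pf$h))
})

test_that("an oscillatory run scores positive, a stationary one negative", {
  expect_gt(performance(default_run())$score, 0)
  # cell-end effect: caps absorb MinD:ATP, mid-cell slightly enriched
  expect_lt(performance(stable_run())$score, 0)
})

test_that("bifurcation search needs a straddling bracket", {
  p <- min_params()
  g <- coarse_geometry(p)
  expect_error(
    find_bifurcation(p, "k_minus_1", 0.3, 0.9, g = g, t_end = 300),
    "no bifurcation in range")
  expect_warning(
    res <- find_bifurcation(p, "k_minus_1", 0.6, 0.6, g = g),
    "degenerate")
  expect_equal(res$critical_value, 0.6)
  expect_equal(res$n_runs, 0L)
})

test_that("scan rows carry analytic gamma and the full parameter set", {
  p <- min_params()
  g <- coarse_geometry(p)
  sc <- scan_plane(p, "k_minus_1", c(0.6, 6, 30, 60), g = g, t_end = 400)
  expect_equal(nrow(sc), 4L)
  for (i in seq_len(nrow(sc))) {
    pp <- update_params(p, k_minus_1 = sc$k_minus_1[i])
    expect_equal(sc$gamma[i], gamma_factor(pp), tolerance = 1e-12)
  }
  # performance > 0 exactly on the oscillatory points
  expect_equal(sc$score > 0, sc$oscillating)
  # MinE sequestration marks the oscillatory side of the bifurcation
  expect_true(all(sc$cytoplasm_MinE[sc$oscillating] < 0.1 * p$N_E))
  expect_true(all(sc$cytoplasm_MinE[!sc$oscillating] > 0.1 * p$N_E))
  # a 1x1 grid reduces to a single run
  sc1 <- scan_plane(p, "k_minus_1", 0.6, g = g, t_end = 400)
  expect_equal(nrow(sc1), 1L)
  expect_true(sc1$oscillating)
})

test_that("scan survives a failing grid point", {
  p <- min_params()
  g <- coarse_geometry(p)
  sc <- scan_plane(p, "k_minus_1", c(-1, 0.6), g = g, t_end = 200)
  expect_false(is.na(sc$error[1]))
  expect_true(is.na(sc$error[2]))
  expect_true(sc$oscillating[2])
})
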