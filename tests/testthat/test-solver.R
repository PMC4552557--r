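test_that("the step initial condition carries the exact copy numbers", {
  p <- min_params()
  g <- build_geometry(p$R, p$L)
  s0 <- default_initial_state(p, g)
  tot <- species_totals(s0, g)
  expect_equal(tot$MinD_total, 2000, tolerance = 1e-9)
  expect_equal(tot$MinE_total, 700, tolerance = 1e-9)
  # MinE uniform at N_E / (pi R^2 L)
  expect_equal(unique(s0$rho_E), 700 / (pi * 0.25 * 4), tolerance = 1e-12)
  expect_equal(unique(s0$rho_E), 222.8, tolerance = 1e-3)
  # all MinD:ADP mass in z < L/2
  half <- rep(g$z_centers < g$L / 2, each = g$Nr)
  expect_true(all(s0$rho_DD[!half] == 0))
  expect_true(all(s0$rho_DT == 0) && all(s0$rho_d == 0))
})

test_that("the detailed-balance uniform state is stationary", {
  p <- db_params()
  g <- coarse_geometry(p)
  fp <- uniform_fixed_point(p, g)
  s <- min_state(g, rho_DD = fp$rho_DD, rho_DT = fp$rho_DT,
                 rho_E = fp$rho_E, rho_d = fp$rho_d, rho_de = fp$rho_de)
  # oracle root satisfies the mass constraints
  tot <- species_totals(s, g)
  expect_equal(tot$MinD_total, p$N_D, tolerance = 1e-10)
  expect_equal(tot$MinE_total, p$N_E, tolerance = 1e-10)
  # every flux vanishes at the root
  fl <- reaction_fluxes(p, fp)
  expect_equal(fl$j_net, rep(0, 5), tolerance = 1e-12)
  ds <- state_derivative(s, p, g)
  expect_lt(max(abs(unlist(ds[c("rho_DD", "rho_DT", "rho_E",
                                "rho_d", "rho_de")]))), 1e-10)
  # perturbing one rate moves the system off the old root
  p2 <- update_params(p, k_minus_3 = p$k_minus_3 * 1.01)
  expect_gt(max(abs(reaction_fluxes(p2, fp)$j_net)), 0)
})

test_that("spontaneous binding seeds empty membrane at k_plus_2 * rho_DT", {
  p <- min_params()
  g <- coarse_geometry(p)
  s <- min_state(g, rho_DT = 3)
  ds <- state_derivative(s, p, g)
  expect_equal(ds$rho_d, rep(p$k_plus_2 * 3, g$n_mem), tolerance = 1e-12)
  expect_equal(ds$rho_de, rep(0, g$n_mem))
})

test_that("the right-hand side conserves total mass exactly", {
  p <- min_params()
  g <- coarse_geometry(p)
  set.seed(42)
  s <- min_state(g,
                 rho_DD = stats::runif(g$n_vol, 1, 100),
                 rho_DT = stats::runif(g$n_vol, 1, 100),
                 rho_E = stats::runif(g$n_vol, 1, 100),
                 rho_d = stats::runif(g$n_mem, 1, 100),
                 rho_de = stats::runif(g$n_mem, 1, 100))
  ds <- state_derivative(s, p, g)
  dD <- sum((ds$rho_DD + ds$rho_DT) * g$cell_volumes) +
    sum((ds$rho_d + ds$rho_de) * g$patch_area)
  dE <- sum(ds$rho_E * g$cell_volumes) + sum(ds$rho_de * g$patch_area)
  scale <- max(abs(ds$rho_DD)) * max(g$cell_volumes)
  expect_lt(abs(dD) / scale, 1e-10)
  expect_lt(abs(dE) / scale, 1e-10)
})

test_that("negative densities are rejected with a location diagnostic", {
  p <- min_params()
  g <- coarse_geometry(p)
  s <- min_state(g, rho_DD = 1)
  s$rho_DT[3] <- -1
  expect_error(state_derivative(s, p, g), "negative density")
})

test_that("an equilibrium start yields a constant trajectory", {
  p <- db_params()
  g <- coarse_geometry(p)
  fp <- uniform_fixed_point(p, g)
  s <- min_state(g, rho_DD = fp$rho_DD, rho_DT = fp$rho_DT,
                 rho_E = fp$rho_E, rho_d = fp$rho_d, rho_de = fp$rho_de)
  tr <- simulate_min(p, g, init = s, t_end = 50)
  expect_equal(stats::sd(tr$probe), 0, tolerance = 1e-8 * mean(tr$probe))
  osc <- detect_oscillation(tr)
  expect_false(osc$oscillating)
})

test_that("mass is conserved through a long oscillatory run", {
  tr <- default_run()
  expect_lt(diff(range(tr$counts$MinD_total)) / 2000, 1e-6)
  expect_lt(diff(range(tr$counts$MinE_total)) / 700, 1e-6)
  expect_gte(min(tr$states), 0)  # no clipping anywhere in the solver
})

test_that("flux balance holds on period average but not instantaneously", {
  tr <- default_run()
  bud <- period_averaged_budget(tr)
  expect_lt(glance(bud)$flux_balance, 0.01)
  inst <- abs(tr$fluxes$J_1 - tr$fluxes$J_4)
  expect_gt(max(inst) / abs(bud$J_avg), 0.1)
})

test_that("halving the axial grid changes the period by less than 2%", {
  p1 <- detect_oscillation(default_run())$period      # dz = 0.1
  p2 <- detect_oscillation(coarse_run())$period       # dz = 0.2
  expect_lt(abs(p1 - p2) / p1, 0.02)
})

test_that("a symmetric initial condition preserves axial symmetry", {
  p <- min_params()
  g <- coarse_geometry(p)
  s <- min_state(g, rho_DD = p$N_D / g$total_volume,
                 rho_E = p$N_E / g$total_volume)
  tr <- simulate_min(p, g, init = s, t_end = 40)
  final <- tr$kymograph[nrow(tr$kymograph), ]
  expect_equal(final, rev(final), tolerance = 1e-6)
  # while the step condition breaks it
  tr2 <- coarse_run()
  final2 <- tr2$kymograph[nrow(tr2$kymograph), ]
  expect_gt(max(abs(final2 - rev(final2))) / mean(final2), 0.1)
})

test_that("a geometry mismatched to the cell dimensions is rejected", {
  p <- min_params()
  g <- build_geometry(0.4, 4, 0.1, 0.1)
  expect_error(simulate_min(p, g, t_end = 1), "does not match")
})
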