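test_that("reaction dissipation density has its closed form and symmetry", {
  expect_equal(reaction_dissipation_density(3, 3), 0)
  expect_equal(reaction_dissipation_density(2, 1), log(2))
  expect_equal(reaction_dissipation_density(1, 2),
               reaction_dissipation_density(2, 1))
  expect_equal(reaction_dissipation_density(0, 0), 0)
  expect_warning(v <- reaction_dissipation_density(1, 0), "irreversible")
  expect_identical(v, Inf)
  set.seed(3)
  jp <- stats::runif(100, 1e-6, 10)
  jm <- stats::runif(100, 1e-6, 10)
  expect_true(all(reaction_dissipation_density(jp, jm) >= 0))
})

test_that("diffusion dissipation density matches |j|^2 / (D rho)", {
  expect_equal(diffusion_dissipation_density(0, 0, 0, rho = 5, D = 16), 0)
  expect_equal(diffusion_dissipation_density(1, rho = 1, D = 16), 1 / 16)
  expect_equal(diffusion_dissipation_density(1, 2, 2, rho = 3, D = 10),
               9 / 30)
  expect_error(diffusion_dissipation_density(1, rho = 0, D = 16),
               "unphysical")
})

test_that("continuum formula is the small-dx limit of lattice hopping", {
  # smooth positive profile on [0, 1]; D fixed, hop rate a = D / dx^2
  D <- 16
  rho_fun <- function(x) 2 + sin(2 * pi * x)
  drho_fun <- function(x) 2 * pi * cos(2 * pi * x)
  exact <- continuum_diffusion_dissipation(rho_fun, drho_fun, D, 0, 1)
  err <- vapply(c(50, 100, 200, 400), function(n) {
    dx <- 1 / n
    x <- (seq_len(n) - 0.5) * dx
    abs(lattice_diffusion_dissipation(rho_fun(x), dx, D / dx^2) - exact)
  }, numeric(1))
  expect_equal(lattice_diffusion_dissipation(rep(4, 10), 0.1, 100), 0)
  order <- log2(err[-4] / err[-1])
  expect_true(all(order >= 1))  # at least first-order convergence
  expect_lt(err[4] / exact, 0.01)
})

test_that("two-cell lattice bond approaches the continuum face formula", {
  D <- 10
  grad <- -1  # fixed density gradient rho(x) = 2 + grad * x
  ratio <- vapply(c(0.1, 0.05, 0.025, 0.0125), function(dx) {
    rho <- 2 + grad * c(0, dx)
    latt <- lattice_diffusion_dissipation(rho, dx, D / dx^2)
    cont <- dx * diffusion_dissipation_density(-D * grad, rho = mean(rho),
                                               D = D)
    latt / cont
  }, numeric(1))
  expect_equal(ratio[4], 1, tolerance = 1e-4)
  expect_true(all(diff(abs(ratio - 1)) < 0))  # error shrinks with dx
})

test_that("sigma_ATP is J_1 ln(gamma) and vanishes at detailed balance", {
  tr <- coarse_run()
  sa <- sigma_atp(tr)
  expect_equal(sa$sigma_atp, tr$fluxes$J_1 * log(1e8), tolerance = 1e-12)

  p <- db_params()
  g <- coarse_geometry(p)
  fp <- uniform_fixed_point(p, g)
  s <- min_state(g, rho_DD = fp$rho_DD, rho_DT = fp$rho_DT,
                 rho_E = fp$rho_E, rho_d = fp$rho_d, rho_de = fp$rho_de)
  tr_eq <- simulate_min(p, g, init = s, t_end = 20)
  expect_equal(sigma_atp(tr_eq)$sigma_atp, rep(0, length(tr_eq$times)))
  # the equilibrium state is non-dissipative in every channel
  expect_lt(max(tr_eq$sigma$sigma_tot), 1e-6)
  bud <- period_averaged_budget(tr_eq)
  expect_lt(abs(bud$sigma_tot), 1e-6)
})

test_that("a stationary dissipative run has sigma_ATP = sigma_tot pointwise", {
  tr <- stable_run()
  n <- length(tr$times)
  late <- seq(floor(0.9 * n), n)
  expect_equal(tr$sigma$sigma_atp[late], tr$sigma$sigma_tot[late],
               tolerance = 1e-3)
})

test_that("every dissipation channel is nonnegative along a run", {
  tr <- default_run()
  sig <- tr$sigma
  for (col in c("sigma_1", "sigma_2", "sigma_3", "sigma_4",
                "sigma_diff_DD", "sigma_diff_DT", "sigma_diff_E")) {
    expect_gte(min(sig[[col]]), 0)
  }
})

test_that("the period-averaged budget closes its bookkeeping", {
  tr <- default_run()
  bud <- period_averaged_budget(tr)
  gl <- glance(bud)
  expect_true(gl$oscillating)
  expect_lt(gl$closure_atp_tot, 0.01)
  expect_equal(bud$sigma_tot, sum(bud$sigma) + bud$sigma_diff,
               tolerance = 0.01)
  expect_equal(bud$sigma_atp, bud$J_avg * bud$ln_gamma, tolerance = 0.01)
  td <- tidy(bud)
  expect_equal(sum(td$fraction, na.rm = TRUE), 1, tolerance = 1e-9)
})

test_that("average dissipation approaches the kinetic ceiling when oscillating", {
  tr <- default_run()
  bud <- period_averaged_budget(tr)
  ceiling <- dissipation_ceiling(tr$params)  # k_plus_4 * N_E * ln(gamma)
  expect_equal(bud$sigma_tot, ceiling, tolerance = 0.1)
})

test_that("dissipation grows with ln(gamma) once the oscillator is on", {
  # along the k_minus_1 axis: smaller k_minus_1 -> larger gamma
  p <- min_params()
  g <- coarse_geometry(p)
  km1 <- c(6, 0.6, 0.06)
  sig <- vapply(km1, function(v) {
    tr <- simulate_min(update_params(p, k_minus_1 = v), g, t_end = 400)
    period_averaged_budget(tr)$sigma_tot
  }, numeric(1))
  expect_true(all(diff(sig) > 0))
  # and is roughly proportional to ln(gamma) in the saturated regime
  lg <- log(1e8) + log(0.6 / km1)
  expect_equal(sig[2] / sig[1], lg[2] / lg[1], tolerance = 0.1)
  expect_equal(sig[3] / sig[2], lg[3] / lg[2], tolerance = 0.1)
})
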