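zero_d <- list(rho_DD = 0, rho_DT = 0, rho_E = 0, rho_d = 0, rho_de = 0)

test_that("flux laws reproduce direct substitutions", {
  p <- min_params()
  fl <- reaction_fluxes(p, zero_d)
  expect_equal(fl$j_plus, rep(0, 5))
  expect_equal(fl$j_minus, rep(0, 5))

  d1 <- utils::modifyList(zero_d, list(rho_DD = 1))
  fl <- reaction_fluxes(p, d1)
  expect_equal(fl$j_plus[fl$step == "1"], 6)
  expect_equal(sum(abs(fl$j_plus[fl$step != "1"])), 0)
  expect_equal(fl$j_minus[fl$step == "4"], p$k_minus_4 * 1 * 0)

  d2 <- utils::modifyList(zero_d, list(rho_DT = 1, rho_d = 1, rho_de = 1))
  fl <- reaction_fluxes(p, d2)
  expect_equal(fl$j_plus[fl$step == "2"], 0.1)
  expect_equal(fl$j_plus[fl$step == "2c"], 0.02)  # 0.01 * 1 * (1 + 1)
})

test_that("net flux is forward minus backward and fluxes are nonnegative", {
  p <- min_params()
  set.seed(11)
  for (rep in 1:20) {
    d <- as.list(stats::setNames(stats::runif(5, 0, 50), names(zero_d)))
    fl <- reaction_fluxes(p, d)
    expect_equal(fl$j_net, fl$j_plus - fl$j_minus)
    expect_true(all(fl$j_plus >= 0) && all(fl$j_minus >= 0))
  }
})

test_that("negative densities are rejected with the species named", {
  expect_error(
    reaction_fluxes(min_params(), utils::modifyList(zero_d,
                                                    list(rho_de = -1))),
    "rho_de")
})

test_that("gamma is the forward/backward rate-product around the cycle", {
  expect_equal(gamma_factor(db_params()), 1)
  p <- min_params()
  expect_equal(gamma_factor(p), 1e8)
  expect_equal(log(gamma_factor(p)), log(1e8), tolerance = 1e-12)
  p10 <- update_params(p, k_minus_1 = p$k_minus_1 * 10)
  expect_equal(gamma_factor(p10), 1e7)
  p_irr <- p
  p_irr$k_minus_2 <- 0  # irreversible limit cannot pass the constructor
  expect_error(gamma_factor(p_irr), "irreversible")
})

test_that("per-step free energies sum to -ln(gamma)", {
  expect_equal(delta_g(db_params())$delta_g, rep(0, 4))
  p <- min_params()
  expect_equal(sum(delta_g(p)$delta_g), -log(1e8), tolerance = 1e-12)
  set.seed(7)
  for (rep in 1:10) {
    pp <- update_params(p,
      k_minus_1 = stats::runif(1, 0.01, 10),
      k_minus_3 = stats::runif(1, 0.01, 10),
      k_minus_4 = stats::runif(1, 1e-6, 1))
    expect_equal(gamma_factor(pp), exp(-sum(delta_g(pp)$delta_g)),
                 tolerance = 1e-12)
  }
})

test_that("a free-energy allocation closes the budget through step 2", {
  p <- params_from_delta_g(-1, -3, -8, delta_g_total = -18)
  dg <- delta_g(p)$delta_g
  expect_equal(dg, c(-1, -18 - (-1) - (-3) - (-8), -3, -8))
  expect_equal(log(gamma_factor(p)), 18, tolerance = 1e-12)
  # cooperative channel inherits the same drop, keeping the invariant
  expect_equal(p$k_plus_2 / p$k_minus_2, p$k_plus_2c / p$k_minus_2c)
})

test_that("the cooperative-consistency invariant is enforced", {
  expect_error(min_params(k_minus_2c = 0.005), "cooperative-consistency")
  expect_silent(min_params(k_plus_2c = 0, k_minus_2c = 0))  # non-coop variant
})
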