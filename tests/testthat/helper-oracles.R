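# Independent brute-force references used only by the tests. These share
# no numerics with the package beyond elementary arithmetic.

# Entropy production of hopping on a 1D chain of cells of width dx with
# symmetric hop rate a: sum over bonds of (j+ - j-) ln(j+/j-), with
# j+ = a rho(x) dx and j- = a rho(x+dx) dx per unit cross-section area.
lattice_diffusion_dissipation <- function(rho, dx, a, area = 1) {
  stopifnot(all(rho > 0))
  i <- seq_len(length(rho) - 1)
  jp <- a * rho[i] * dx
  jm <- a * rho[i + 1] * dx
  sum((jp - jm) * log(jp / jm)) * area
}

# Continuum dissipation integral int |j|^2/(D rho) dx for a smooth 1D
# profile, via quadrature on the analytic flux j = -D rho'.
continuum_diffusion_dissipation <- function(rho_fun, drho_fun, D, lo, hi,
                                            area = 1) {
  f <- function(x) D * drho_fun(x)^2 / rho_fun(x)
  area * stats::integrate(f, lo, hi, rel.tol = 1e-10)$value
}

# Spatially uniform detailed-balance fixed point of the well-mixed model
# at gamma = 1, satisfying both mass constraints. Detailed balance fixes
# every ratio, leaving (rho_DD, rho_E); rho_E is eliminated analytically
# and rho_DD found with uniroot.
uniform_fixed_point <- function(p, g) {
  stopifnot(abs(gamma_factor(p) - 1) < 1e-9)
  V <- g$total_volume
  A <- g$lateral_area + 2 * g$cap_area
  r1 <- p$k_plus_1 / p$k_minus_1     # rho_DT / rho_DD
  r2 <- p$k_plus_2 / p$k_minus_2     # rho_d / rho_DT
  r3 <- p$k_plus_3 / p$k_minus_3     # rho_de / (rho_E rho_d)
  f <- function(rho_DD) {
    rho_DT <- r1 * rho_DD
    rho_d <- r2 * rho_DT
    rho_E <- p$N_E / (V + r3 * rho_d * A)
    rho_de <- r3 * rho_E * rho_d
    (rho_DD + rho_DT) * V + (rho_d + rho_de) * A - p$N_D
  }
  hi <- p$N_D / V
  root <- stats::uniroot(f, c(1e-12, hi), tol = 1e-14)$root
  rho_DT <- r1 * root
  rho_d <- r2 * rho_DT
  rho_E <- p$N_E / (V + r3 * rho_d * A)
  list(rho_DD = root, rho_DT = rho_DT, rho_E = rho_E,
       rho_d = rho_d, rho_de = r3 * rho_E * rho_d)
}

# parameter set at detailed balance (gamma = 1), matched unit magnitudes
db_params <- function() {
  min_params(k_minus_1 = 6, k_minus_2 = 0.1, k_minus_2c = 0.01,
             k_minus_3 = 0.4, k_minus_4 = 1)
}
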