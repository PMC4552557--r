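#' Dissipation rate density of a reversible reaction
#'
#' For forward and backward flux densities `j_plus` and `j_minus` at one
#' location, the local free-energy dissipation rate density is
#' `(j_plus - j_minus) * ln(j_plus / j_minus)`, which is nonnegative for
#' any pair of positive fluxes and symmetric under swapping the
#' arguments. Units follow the fluxes: kBT per unit volume (or area) per
#' second. Both fluxes zero gives 0; exactly one flux zero is the
#' irreversible limit, for which the dissipation diverges and `Inf` is
#' returned with a warning.
#'
#' @param j_plus,j_minus forward and backward flux densities (vectorized)
#' @return numeric vector of dissipation rate densities
#' @examples
#' reaction_dissipation_density(2, 1)  # log(2)
#' @export
reaction_dissipation_density <- function(j_plus, j_minus) {
  stopifnot(length(j_plus) == length(j_minus), all(j_plus >= 0),
            all(j_minus >= 0))
  out <- numeric(length(j_plus))
  both <- j_plus > 0 & j_minus > 0
  out[both] <- (j_plus[both] - j_minus[both]) * log(j_plus[both] / j_minus[both])
  one <- xor(j_plus > 0, j_minus > 0)
  if (any(one)) {
    warning("irreversible limit (one flux is zero): dissipation divergent")
    out[one] <- Inf
  }
  out
}

#' Dissipation rate density of diffusion
#'
#' `|j|^2 / (D * rho)` in kBT per unit volume per second, the continuum
#' limit of the entropy production of hopping on a lattice. The total
#' diffusive dissipation of a trajectory is the volume integral summed
#' over the three cytoplasmic species; membrane-bound species do not
#' diffuse in this model.
#'
#' @param jx,jy,jz components of the diffusive flux (1/(um^2 s)); omit
#'   `jy`/`jz` for lower-dimensional fluxes
#' @param rho local density (1/um^3), strictly positive where the flux is
#'   nonzero
#' @param D diffusion constant (um^2/s)
#' @return dissipation rate density (kBT/(um^3 s))
#' @examples
#' diffusion_dissipation_density(1, rho = 1, D = 16)  # 1/16
#' @export
diffusion_dissipation_density <- function(jx, jy = 0, jz = 0, rho, D) {
  j2 <- jx^2 + jy^2 + jz^2
  if (any(rho <= 0 & j2 > 0)) {
    stop("unphysical state: zero density with nonzero diffusive flux")
  }
  out <- numeric(length(j2))
  ok <- rho > 0
  out[ok] <- j2[ok] / (D * rho[ok])
  out
}

#' Chemical free-energy uptake rate sigma_ATP
#'
#' The ATP free-energy deposit rate `J_1(t) * ln(gamma)`, with `J_1(t)`
#' the volume-integrated net nucleotide-exchange flux. At detailed
#' balance (`gamma = 1`) this vanishes identically; a configuration with
#' `gamma < 1` is thermodynamically inverted and is flagged.
#'
#' @param tr a [simulate_min()] trajectory
#' @return a tibble with columns `time` and `sigma_atp` (kBT/s)
#' @export
sigma_atp <- function(tr) {
  stopifnot(inherits(tr, "min_trajectory"))
  gam <- gamma_factor(tr$params)
  if (gam < 1) {
    warning("gamma < 1: negative 'dissipation' - thermodynamically ",
            "inverted configuration")
  }
  tibble::tibble(time = tr$fluxes$time,
                 sigma_atp = tr$fluxes$J_1 * log(gam))
}

#' Period-averaged free-energy dissipation budget
#'
#' Averages every dissipation channel and integrated flux over an
#' integer number of detected oscillation periods taken from the end of
#' the trajectory (default: the last 5 whole periods). For
#' non-oscillatory trajectories the long-time instantaneous values are
#' used. The bookkeeping identities of a sustained oscillation -
#' `<sigma_ATP> = <sigma_tot> = sum_i <sigma_i> + <sigma_diff> =
#' <J> ln(gamma)` and `<J_1> = <J_2 + J_2'> = <J_3> = <J_4>` - are
#' computed and reported; they should close within about 1% when the
#' averaging window covers whole periods of a converged run.
#'
#' @param tr a [simulate_min()] trajectory
#' @param n_periods number of whole periods to average over
#' @param ... passed to [detect_oscillation()]
#' @return an object of class `min_budget`; see [tidy.min_budget()] and
#'   [glance.min_budget()]
#' @export
period_averaged_budget <- function(tr, n_periods = 5, ...) {
  stopifnot(inherits(tr, "min_trajectory"))
  win <- averaging_window(tr, n_periods)
  avg <- function(x, tvec = tr$sigma$time) {
    if (win$periods > 0) {
      time_average(tvec, x, win$t1, win$t2)
    } else {
      x[length(x)]
    }
  }
  s <- tr$sigma
  f <- tr$fluxes
  sig <- c(sigma_1 = avg(s$sigma_1), sigma_2 = avg(s$sigma_2),
           sigma_3 = avg(s$sigma_3), sigma_4 = avg(s$sigma_4))
  sdiff <- avg(s$sigma_diff)
  stot <- avg(s$sigma_tot)
  satp <- avg(s$sigma_atp)
  J <- c(J_1 = avg(f$J_1), J_2 = avg(f$J_2) + avg(f$J_2c),
         J_3 = avg(f$J_3), J_4 = avg(f$J_4))
  out <- list(sigma = sig, sigma_diff = sdiff, sigma_tot = stot,
              sigma_atp = satp, J = J, J_avg = mean(J),
              ln_gamma = log(gamma_factor(tr$params)),
              period = win$osc$period, periods_averaged = win$periods,
              oscillating = win$osc$oscillating)
  class(out) <- "min_budget"
  out
}

#' @export
print.min_budget <- function(x, ...) {
  cat("<min_budget> period-averaged dissipation (kBT/s)\n")
  if (x$periods_averaged > 0) {
    cat(sprintf("  averaged over %d period(s) of %.4g s\n",
                x$periods_averaged, x$period))
  } else {
    cat("  non-oscillatory: long-time instantaneous values\n")
  }
  print(generics::tidy(x))
  cat(sprintf("  <sigma_ATP> = %.6g, <sigma_tot> = %.6g, <J> ln(gamma) = %.6g\n",
              x$sigma_atp, x$sigma_tot, x$J_avg * x$ln_gamma))
  invisible(x)
}

#' Tidy a dissipation budget
#'
#' @param x a [period_averaged_budget()] result
#' @param ... unused
#' @return a tibble with columns `quantity`, `step`, `value_kBT_per_s`,
#'   `fraction` (of the total dissipation rate)
#' @method tidy min_budget
#' @export
tidy.min_budget <- function(x, ...) {
  vals <- c(x$sigma, sigma_diff = x$sigma_diff)
  tot <- sum(vals)
  tibble::tibble(
    quantity = c(rep("reaction", 4), "diffusion", "total", "atp_uptake"),
    step = c("1", "2", "3", "4", NA, NA, NA),
    value_kBT_per_s = c(vals, x$sigma_tot, x$sigma_atp),
    fraction = c(vals / tot, NA, NA))
}

#' One-row summary of a dissipation budget
#'
#' @param x a [period_averaged_budget()] result
#' @param ... unused
#' @return a one-row tibble including the closure discrepancies
#'   `closure_atp_tot` (relative difference between `<sigma_ATP>` and
#'   `<sigma_tot>`) and `flux_balance` (max relative spread of the four
#'   period-averaged fluxes)
#' @method glance min_budget
#' @export
glance.min_budget <- function(x, ...) {
  tibble::tibble(
    oscillating = x$oscillating, period = x$period,
    periods_averaged = x$periods_averaged,
    sigma_1 = x$sigma[["sigma_1"]], sigma_2 = x$sigma[["sigma_2"]],
    sigma_3 = x$sigma[["sigma_3"]], sigma_4 = x$sigma[["sigma_4"]],
    sigma_diff = x$sigma_diff, sigma_tot = x$sigma_tot,
    sigma_atp = x$sigma_atp, J_avg = x$J_avg, ln_gamma = x$ln_gamma,
    closure_atp_tot = abs(x$sigma_atp - x$sigma_tot) /
      max(abs(x$sigma_tot), .Machine$double.eps),
    flux_balance = (max(x$J) - min(x$J)) /
      max(abs(x$J_avg), .Machine$double.eps))
}
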