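#' Integrate the reversible MinDE reaction-diffusion system
#'
#' Runs the stiff method-of-lines system (cytoplasmic diffusion plus
#' reversible reactions, membrane species on the boundary patches) with
#' the sparse implicit integrator `deSolve::lsodes` and adaptive steps.
#' The dynamics are fully deterministic. At every sample time the
#' integrated reaction fluxes `J_i(t)`, the per-step reaction dissipation
#' rates, the diffusion dissipation and the species bookkeeping are
#' recorded, together with a kymograph of membrane-bound MinD along the
#' long axis and a probe time series of membrane MinD at the `z = 0`
#' pole cap.
#'
#' @param p a [min_params()] object
#' @param g a [build_geometry()] mesh; defaults to the cell geometry in
#'   `p` at 0.1 um spacing
#' @param init initial `min_state`; defaults to
#'   [default_initial_state()]
#' @param t_end integration end time (s)
#' @param sample_dt output sampling interval (s)
#' @param rtol,atol relative and absolute solver tolerances
#' @return an object of class `min_trajectory`
#' @examples
#' \donttest{
#' p <- min_params()
#' g <- build_geometry(p$R, p$L, dr = 0.25, dz = 0.2)
#' tr <- simulate_min(p, g, t_end = 120)
#' detect_oscillation(tr)
#' }
#' @export
simulate_min <- function(p, g = build_geometry(p$R, p$L),
                         init = default_initial_state(p, g),
                         t_end = 600, sample_dt = 0.5,
                         rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(p, "min_params"), inherits(g, "min_geometry"),
            inherits(init, "min_state"), t_end > 0)
  if (abs(g$R - p$R) > 1e-9 || abs(g$L - p$L) > 1e-9) {
    stop("geometry (R=", g$R, ", L=", g$L,
         ") does not match parameters (R=", p$R, ", L=", p$L, ")")
  }
  y0 <- state_to_vector(init)
  kvec <- rate_vector(p)
  gg <- unclass(g)
  times <- seq(init$time, init$time + t_end, by = sample_dt)
  rhs <- function(t, y, parms) list(min_rhs_cpp(y, gg, kvec))
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsodes", rtol = rtol, atol = atol,
                      maxsteps = 50000)
  if (anyNA(sol)) {
    ok <- !apply(is.na(sol), 1, any)
    last <- if (any(ok)) max(sol[ok, 1]) else NA_real_
    stop("integrator failed after t = ", last,
         " s; last good state retained up to that time")
  }
  tt <- sol[, 1]
  states <- sol[, -1, drop = FALSE]
  dimnames(states) <- NULL

  nv <- g$n_vol
  nm <- g$n_mem
  lat_d <- 3 * nv + seq_len(g$Nz)
  lat_de <- 3 * nv + nm + seq_len(g$Nz)
  kymo <- states[, lat_d, drop = FALSE] + states[, lat_de, drop = FALSE]

  cap0 <- c(3 * nv + g$Nz + seq_len(g$Nr), 3 * nv + nm + g$Nz + seq_len(g$Nr))
  wA <- g$patch_area[g$Nz + seq_len(g$Nr)]
  probe <- (states[, cap0[seq_len(g$Nr)], drop = FALSE] +
              states[, cap0[g$Nr + seq_len(g$Nr)], drop = FALSE]) %*%
    (wA / sum(wA))
  probe <- as.numeric(probe)

  diag <- lapply(seq_along(tt), function(i) {
    min_diag_cpp(states[i, ], gg, kvec)
  })
  pick <- function(part, name) {
    vapply(diag, function(d) d[[part]][[name]], numeric(1))
  }
  ln_gamma <- tryCatch(log(gamma_factor(p)), error = function(e) NA_real_)
  fluxes <- tibble::tibble(
    time = tt,
    J_1 = pick("J", "J_1"), J_2 = pick("J", "J_2"),
    J_2c = pick("J", "J_2c"), J_3 = pick("J", "J_3"),
    J_4 = pick("J", "J_4"))
  sdd <- pick("sigma_diff", "DD")
  sdt <- pick("sigma_diff", "DT")
  sde <- pick("sigma_diff", "E")
  sigma <- tibble::tibble(
    time = tt,
    sigma_1 = pick("sigma_react", "sigma_1"),
    sigma_2 = pick("sigma_react", "sigma_2"),
    sigma_3 = pick("sigma_react", "sigma_3"),
    sigma_4 = pick("sigma_react", "sigma_4"),
    sigma_diff_DD = sdd, sigma_diff_DT = sdt, sigma_diff_E = sde,
    sigma_diff = sdd + sdt + sde,
    sigma_tot = sigma_1 + sigma_2 + sigma_3 + sigma_4 + sigma_diff,
    sigma_atp = fluxes$J_1 * ln_gamma)
  counts <- tibble::tibble(
    time = tt,
    cytoplasm_MinD = pick("counts", "cytoplasm_MinD"),
    cytoplasm_MinE = pick("counts", "cytoplasm_MinE"),
    membrane_MinD = pick("counts", "membrane_MinD"),
    membrane_MinE = pick("counts", "membrane_MinE"),
    MinD_total = cytoplasm_MinD + membrane_MinD,
    MinE_total = cytoplasm_MinE + membrane_MinE)

  out <- list(params = p, geometry = g, times = tt, states = states,
              probe = probe, kymograph = kymo,
              fluxes = fluxes, sigma = sigma, counts = counts,
              solver = list(method = "lsodes", rtol = rtol, atol = atol,
                            sample_dt = sample_dt, t_end = t_end))
  class(out) <- "min_trajectory"
  out
}

#' @export
print.min_trajectory <- function(x, ...) {
  cat(sprintf(
    "<min_trajectory> %d samples over %.4g s on a %d x %d mesh\n",
    length(x$times), max(x$times) - min(x$times), x$geometry$Nr,
    x$geometry$Nz))
  osc <- tryCatch(detect_oscillation(x), error = function(e) NULL)
  if (!is.null(osc)) {
    if (osc$oscillating) {
      cat(sprintf("  oscillating, period %.3g s\n", osc$period))
    } else {
      cat("  non-oscillatory (stationary within threshold)\n")
    }
  }
  invisible(x)
}

#' Extract one sampled field state from a trajectory
#'
#' @param tr a `min_trajectory`
#' @param i sample index (default: last sample)
#' @return a `min_state`
#' @export
trajectory_state <- function(tr, i = length(tr$times)) {
  stopifnot(inherits(tr, "min_trajectory"))
  vector_to_state(tr$states[i, ], tr$geometry, time = tr$times[i])
}
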