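#' Assemble a field state from per-species density vectors
#'
#' @param g a [build_geometry()] mesh
#' @param rho_DD,rho_DT,rho_E cytoplasmic densities (1/um^3), length
#'   `g$n_vol` or scalar
#' @param rho_d,rho_de membrane densities (1/um^2), length `g$n_mem` or
#'   scalar
#' @param time time stamp (s)
#' @return an object of class `min_state`
#' @export
min_state <- function(g, rho_DD = 0, rho_DT = 0, rho_E = 0,
                      rho_d = 0, rho_de = 0, time = 0) {
  stopifnot(inherits(g, "min_geometry"))
  vol <- function(x) {
    if (length(x) == 1) x <- rep(x, g$n_vol)
    stopifnot(length(x) == g$n_vol)
    x
  }
  mem <- function(x) {
    if (length(x) == 1) x <- rep(x, g$n_mem)
    stopifnot(length(x) == g$n_mem)
    x
  }
  s <- list(time = time,
            rho_DD = vol(rho_DD), rho_DT = vol(rho_DT), rho_E = vol(rho_E),
            rho_d = mem(rho_d), rho_de = mem(rho_de))
  class(s) <- "min_state"
  s
}

state_to_vector <- function(s) {
  c(s$rho_DD, s$rho_DT, s$rho_E, s$rho_d, s$rho_de)
}

vector_to_state <- function(y, g, time = 0) {
  nv <- g$n_vol
  nm <- g$n_mem
  min_state(g,
            rho_DD = y[seq_len(nv)],
            rho_DT = y[nv + seq_len(nv)],
            rho_E = y[2 * nv + seq_len(nv)],
            rho_d = y[3 * nv + seq_len(nm)],
            rho_de = y[3 * nv + nm + seq_len(nm)],
            time = time)
}

#' Default symmetry-breaking initial condition
#'
#' All MinD mass is placed as cytoplasmic MinD:ADP in the half of the cell
#' with `z < L/2` (a step function along the long axis), MinE is uniform
#' in the cytoplasm, and the remaining species start at zero. The uniform
#' state is an unstable solution of the deterministic equations, so the
#' step is needed to break the symmetry and select the pole-to-pole limit
#' cycle. Discrete species totals equal `N_D` and `N_E` exactly.
#'
#' @param p a [min_params()] object
#' @param g a [build_geometry()] mesh
#' @return a `min_state`
#' @export
default_initial_state <- function(p, g) {
  stopifnot(inherits(p, "min_params"), inherits(g, "min_geometry"))
  half <- g$z_centers < g$L / 2
  v_half <- sum(g$cell_volumes[rep(half, each = g$Nr)])
  rho_DD <- ifelse(rep(half, each = g$Nr), p$N_D / v_half, 0)
  min_state(g,
            rho_DD = rho_DD,
            rho_E = p$N_E / g$total_volume)
}

#' Total molecule counts carried by a field state
#'
#' @param s a `min_state`
#' @param g the matching `min_geometry`
#' @return a tibble with per-compartment species counts and `MinD_total`,
#'   `MinE_total`
#' @export
species_totals <- function(s, g) {
  stopifnot(inherits(s, "min_state"), inherits(g, "min_geometry"))
  V <- g$cell_volumes
  A <- g$patch_area
  tibble::tibble(
    cytoplasm_MinD_ADP = sum(s$rho_DD * V),
    cytoplasm_MinD_ATP = sum(s$rho_DT * V),
    cytoplasm_MinE = sum(s$rho_E * V),
    membrane_MinD = sum(s$rho_d * A),
    membrane_MinDE = sum(s$rho_de * A),
    MinD_total = cytoplasm_MinD_ADP + cytoplasm_MinD_ATP +
      membrane_MinD + membrane_MinDE,
    MinE_total = cytoplasm_MinE + membrane_MinDE
  )
}

rate_vector <- function(p) {
  c(p$k_plus_1, p$k_minus_1, p$k_plus_2, p$k_minus_2,
    p$k_plus_2c, p$k_minus_2c, p$k_plus_3, p$k_minus_3,
    p$k_plus_4, p$k_minus_4, p$D_D, p$D_E)
}

#' Time derivative of a field state
#'
#' Evaluates the full right-hand side of the reaction-diffusion system:
#' axisymmetric finite-volume diffusion of the three cytoplasmic species,
#' the volumetric nucleotide-exchange source, the membrane reaction ODEs
#' and the membrane/cytoplasm boundary exchange (MinD release injects
#' MinD:ADP, attachment removes MinD:ATP, MinE recruitment/release
#' exchanges MinE).
#'
#' @param s a `min_state` (all densities nonnegative)
#' @param p a `min_params`
#' @param g the matching `min_geometry`
#' @return a `min_state` holding d(density)/dt
#' @export
state_derivative <- function(s, p, g) {
  stopifnot(inherits(s, "min_state"))
  y <- state_to_vector(s)
  if (any(y < 0)) {
    idx <- which(y < 0)[1]
    stop("negative density in state at component ", idx)
  }
  dy <- min_rhs_cpp(y, unclass(g), rate_vector(p))
  vector_to_state(dy, g, time = s$time)
}
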