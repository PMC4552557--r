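#' Model parameters for the reversible MinDE oscillator
#'
#' Builds and validates the full parameter set of the microscopically
#' reversible MinDE reaction-diffusion model: four reversible reaction
#' steps (nucleotide exchange, MinD membrane immobilization with a
#' spontaneous and a cooperative channel, MinE recruitment, MinE-aided
#' MinD release), cytoplasmic diffusion constants, total copy numbers and
#' the cylindrical cell geometry.
#'
#' Units follow the micrometre/second system used throughout the package:
#' first-order rates in 1/s, the spontaneous attachment rate in um/s, the
#' cooperative attachment rates in um^3/s (forward) and um^2/s (backward),
#' MinE recruitment in um^3/s, MinD rebinding in um^4/s. The spontaneous
#' and cooperative attachment channels are two routes over the same
#' free-energy drop, so `k_plus_2/k_minus_2` must equal
#' `k_plus_2c/k_minus_2c`; setting both cooperative rates to zero selects
#' the non-cooperative model variant.
#'
#' @param k_plus_1,k_minus_1 nucleotide exchange MinD:ADP <-> MinD:ATP (1/s)
#' @param k_plus_2,k_minus_2 spontaneous membrane attachment (um/s, 1/s)
#' @param k_plus_2c,k_minus_2c cooperative attachment (um^3/s, um^2/s)
#' @param k_plus_3,k_minus_3 MinE recruitment (um^3/s, 1/s)
#' @param k_plus_4,k_minus_4 MinE-aided release / rebinding (1/s, um^4/s)
#' @param D_D,D_E cytoplasmic diffusion constants of MinD and MinE (um^2/s)
#' @param N_D,N_E total MinD molecules and MinE dimers (counts)
#' @param R,L cell radius and length (um)
#' @return an object of class `min_params` (a validated named list)
#' @examples
#' p <- min_params()
#' gamma_factor(p)
#' @export
min_params <- function(k_plus_1 = 6, k_minus_1 = 0.6,
                       k_plus_2 = 0.1, k_minus_2 = 0.01,
                       k_plus_2c = 0.01, k_minus_2c = 0.001,
                       k_plus_3 = 0.4, k_minus_3 = 0.04,
                       k_plus_4 = 1, k_minus_4 = 1e-5,
                       D_D = 16, D_E = 10,
                       N_D = 2000, N_E = 700,
                       R = 0.5, L = 4) {
  p <- list(
    k_plus_1 = k_plus_1, k_minus_1 = k_minus_1,
    k_plus_2 = k_plus_2, k_minus_2 = k_minus_2,
    k_plus_2c = k_plus_2c, k_minus_2c = k_minus_2c,
    k_plus_3 = k_plus_3, k_minus_3 = k_minus_3,
    k_plus_4 = k_plus_4, k_minus_4 = k_minus_4,
    D_D = D_D, D_E = D_E, N_D = N_D, N_E = N_E, R = R, L = L
  )
  class(p) <- "min_params"
  validate_min_params(p)
  p
}

#' Canonical unit strings for every model parameter
#' @return named character vector, one unit string per parameter
#' @export
param_units <- function() {
  c(k_plus_1 = "1/s", k_minus_1 = "1/s",
    k_plus_2 = "um/s", k_minus_2 = "1/s",
    k_plus_2c = "um^3/s", k_minus_2c = "um^2/s",
    k_plus_3 = "um^3/s", k_minus_3 = "1/s",
    k_plus_4 = "1/s", k_minus_4 = "um^4/s",
    D_D = "um^2/s", D_E = "um^2/s",
    N_D = "1", N_E = "1", R = "um", L = "um")
}

validate_min_params <- function(p) {
  num <- unlist(p[names(param_units())])
  bad <- names(num)[!is.finite(num)]
  if (length(bad)) {
    stop("non-finite parameter value(s): ", paste(bad, collapse = ", "))
  }
  noncoop <- p$k_plus_2c == 0 && p$k_minus_2c == 0
  must_pos <- setdiff(names(num), if (noncoop) c("k_plus_2c", "k_minus_2c"))
  bad <- must_pos[num[must_pos] <= 0]
  if (length(bad)) {
    stop("parameter(s) must be strictly positive: ", paste(bad, collapse = ", "))
  }
  for (n in c("N_D", "N_E")) {
    if (abs(p[[n]] - round(p[[n]])) > 1e-9) {
      stop(n, " must be a positive integer copy number, got ", p[[n]])
    }
  }
  if (!noncoop) {
    r1 <- p$k_plus_2 / p$k_minus_2
    r2 <- p$k_plus_2c / p$k_minus_2c
    if (abs(r1 - r2) > 1e-9 * abs(r1)) {
      stop("cooperative-consistency violated: k_plus_2/k_minus_2 = ",
           format(r1), " but k_plus_2c/k_minus_2c = ", format(r2),
           "; the two attachment channels must share one free-energy drop")
    }
  }
  invisible(p)
}

#' @export
print.min_params <- function(x, ...) {
  u <- param_units()
  cat("<min_params> reversible MinDE model parameters\n")
  for (n in names(u)) {
    cat(sprintf("  %-11s %-12g %s\n", n, x[[n]], u[[n]]))
  }
  lg <- tryCatch(log(gamma_factor(x)), error = function(e) NA_real_)
  cat(sprintf("  ln(gamma) = %.4g kBT per cycle\n", lg))
  invisible(x)
}

#' Update parameters, revalidating
#'
#' @param p a `min_params` object
#' @param ... named parameter replacements
#' @return a new validated `min_params` object
#' @export
update_params <- function(p, ...) {
  stopifnot(inherits(p, "min_params"))
  repl <- list(...)
  unknown <- setdiff(names(repl), names(param_units()))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  p[names(repl)] <- repl
  validate_min_params(p)
  p
}

#' Nonequilibrium parameter gamma of the reaction cycle
#'
#' The product of forward over backward rate constants around the
#' four-step futile cycle. `gamma = 1` is detailed balance; `ln(gamma)` is
#' the chemical free energy (in kBT) dissipated per completed cycle,
#' i.e. per ATP hydrolysed.
#'
#' @param p a `min_params` object
#' @return dimensionless scalar
#' @export
gamma_factor <- function(p) {
  stopifnot(inherits(p, "min_params"))
  km <- c(p$k_minus_1, p$k_minus_2, p$k_minus_3, p$k_minus_4)
  if (any(km == 0)) {
    stop("irreversible model (a backward rate is zero): gamma undefined")
  }
  (p$k_plus_1 * p$k_plus_2 * p$k_plus_3 * p$k_plus_4) /
    (p$k_minus_1 * p$k_minus_2 * p$k_minus_3 * p$k_minus_4)
}

#' Standard free-energy change of each reaction step
#'
#' `delta_g_i = ln(k_minus_i / k_plus_i)` in kBT, under the convention of
#' unit Min concentrations and fixed physiological nucleotide pools (ATP,
#' ADP and Pi are folded into the rate constants, so these values are
#' meaningful relative to that reference, not as absolute standard-state
#' energies). The four steps sum to `-ln(gamma)`.
#'
#' @param p a `min_params` object
#' @return a tibble with columns `step` (1:4) and `delta_g` (kBT)
#' @export
delta_g <- function(p) {
  stopifnot(inherits(p, "min_params"))
  kp <- c(p$k_plus_1, p$k_plus_2, p$k_plus_3, p$k_plus_4)
  km <- c(p$k_minus_1, p$k_minus_2, p$k_minus_3, p$k_minus_4)
  if (any(km == 0)) {
    stop("irreversible model (a backward rate is zero): delta_g undefined")
  }
  tibble::tibble(step = 1:4, delta_g = log(km / kp))
}

#' Build a parameter set from a free-energy allocation
#'
#' Fixes the forward rates and derives every backward rate from the
#' per-step standard free-energy changes, `k_minus_i =
#' k_plus_i * exp(delta_g_i)`. If `dg2` is omitted it is closed by the
#' total budget `delta_g_total = sum(dg_i) = -ln(gamma)`. The cooperative
#' backward rate is derived from the same `dg2`, which preserves the
#' shared-free-energy-drop invariant by construction.
#'
#' @param dg1,dg3,dg4 per-step free-energy changes (kBT, usually negative)
#' @param dg2 free-energy change of the attachment step; default closes the
#'   budget
#' @param delta_g_total total free-energy drop per cycle (kBT, negative)
#' @param base a `min_params` carrying the forward rates and all
#'   non-rate parameters
#' @return a validated `min_params` object
#' @export
params_from_delta_g <- function(dg1, dg3, dg4,
                                dg2 = delta_g_total - dg1 - dg3 - dg4,
                                delta_g_total = -18,
                                base = min_params()) {
  update_params(base,
    k_minus_1 = base$k_plus_1 * exp(dg1),
    k_minus_2 = base$k_plus_2 * exp(dg2),
    k_minus_2c = base$k_plus_2c * exp(dg2),
    k_minus_3 = base$k_plus_3 * exp(dg3),
    k_minus_4 = base$k_plus_4 * exp(dg4))
}

#' Kinetic ceiling on the average dissipation rate of the oscillator
#'
#' In the sustained-oscillation regime almost all MinE dimers are
#' membrane-bound, so the cycle flux saturates at `k_plus_4 * N_E` and the
#' average dissipation rate approaches `k_plus_4 * N_E * ln(gamma)` kBT/s.
#'
#' @param p a `min_params` object supplying `k_plus_4` and `N_E`
#' @param ln_gamma optional override of `log(gamma_factor(p))`
#' @return scalar, kBT per second
#' @export
dissipation_ceiling <- function(p = min_params(), ln_gamma = NULL) {
  if (is.null(ln_gamma)) ln_gamma <- log(gamma_factor(p))
  p$k_plus_4 * p$N_E * ln_gamma
}
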