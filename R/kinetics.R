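#' Forward, backward and net reaction flux densities at one location
#'
#' Evaluates the mass-action flux laws of the five reaction channels
#' (nucleotide exchange; spontaneous and cooperative membrane attachment;
#' MinE recruitment; MinE-aided release) for given local densities.
#' Cytoplasmic densities are volume densities (1/um^3) taken at the
#' membrane-adjacent position for the surface reactions; membrane
#' densities are surface densities (1/um^2). Step 1 fluxes are volumetric
#' (1/(um^3 s)); steps 2, 2c, 3 and 4 are surface fluxes (1/(um^2 s)).
#'
#' @param p a [min_params()] object
#' @param d local densities: a named list, one-row data frame or named
#'   numeric vector with entries `rho_DD`, `rho_DT`, `rho_E` (cytoplasmic
#'   MinD:ADP, MinD:ATP, MinE dimer) and `rho_d`, `rho_de` (membrane-bound
#'   MinD:ATP and MinE:MinD:ATP)
#' @return a tibble with columns `step` ("1","2","2c","3","4"), `j_plus`,
#'   `j_minus`, `j_net` and `units`
#' @examples
#' reaction_fluxes(min_params(),
#'   list(rho_DD = 1, rho_DT = 0, rho_E = 0, rho_d = 0, rho_de = 0))
#' @export
reaction_fluxes <- function(p, d) {
  stopifnot(inherits(p, "min_params"))
  if (is.data.frame(d)) {
    stopifnot(nrow(d) == 1)
    d <- as.list(d)
  }
  d <- as.list(d)
  need <- c("rho_DD", "rho_DT", "rho_E", "rho_d", "rho_de")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("missing density component(s): ", paste(missing, collapse = ", "))
  }
  vals <- unlist(d[need])
  if (any(vals < 0)) {
    bad <- need[vals < 0]
    stop("negative density for ", paste(bad, collapse = ", "),
         " (", paste(format(vals[vals < 0]), collapse = ", "), ")")
  }
  dsum <- d$rho_d + d$rho_de
  jp <- c(p$k_plus_1 * d$rho_DD,
          p$k_plus_2 * d$rho_DT,
          p$k_plus_2c * d$rho_DT * dsum,
          p$k_plus_3 * d$rho_E * d$rho_d,
          p$k_plus_4 * d$rho_de)
  jm <- c(p$k_minus_1 * d$rho_DT,
          p$k_minus_2 * d$rho_d,
          p$k_minus_2c * d$rho_d * dsum,
          p$k_minus_3 * d$rho_de,
          p$k_minus_4 * d$rho_DD * d$rho_E)
  tibble::tibble(
    step = c("1", "2", "2c", "3", "4"),
    j_plus = jp, j_minus = jm, j_net = jp - jm,
    units = c("1/(um^3 s)", rep("1/(um^2 s)", 4))
  )
}
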