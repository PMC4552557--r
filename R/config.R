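#' Load and validate an experiment configuration
#'
#' Reads a YAML experiment description with optional blocks `params`,
#' `geometry`, `solver`, `analysis`, `scan`, `optimize` and `output`.
#' Parameter entries may be bare numbers or `"value unit"` strings; unit
#' strings, when given, must match the canonical micrometre/second units
#' of [param_units()] exactly (no SI prefixes). Missing parameters are
#' filled with the package defaults. All validation failures are
#' collected and reported together.
#'
#' @param path path to a YAML file
#' @return an object of class `min_config`
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  config_from_list(raw, source = path)
}

config_from_list <- function(raw, source = "<list>") {
  if (is.null(raw)) raw <- list()
  known_blocks <- c("params", "geometry", "solver", "analysis", "scan",
                    "optimize", "output", "preset")
  failures <- character()
  unknown <- setdiff(names(raw), known_blocks)
  if (length(unknown)) {
    failures <- c(failures, paste0("unknown top-level block(s): ",
                                   paste(unknown, collapse = ", ")))
  }
  units <- param_units()
  pvals <- list()
  praw <- raw$params
  if (!is.null(praw)) {
    unknown_p <- setdiff(names(praw), names(units))
    if (length(unknown_p)) {
      failures <- c(failures, paste0("unknown parameter(s): ",
                                     paste(unknown_p, collapse = ", ")))
    }
    for (n in intersect(names(praw), names(units))) {
      v <- praw[[n]]
      if (is.character(v)) {
        parts <- strsplit(trimws(v), "\\s+")[[1]]
        num <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(num)) {
          failures <- c(failures, paste0(n, ": cannot parse value from '",
                                         v, "'"))
          next
        }
        if (length(parts) > 1) {
          unit <- paste(parts[-1], collapse = " ")
          if (unit != units[[n]]) {
            failures <- c(failures,
                          paste0(n, ": unit '", unit, "' does not match ",
                                 "canonical '", units[[n]], "'"))
            next
          }
        }
        pvals[[n]] <- num
      } else if (is.numeric(v)) {
        pvals[[n]] <- v
      } else {
        failures <- c(failures, paste0(n, ": value must be numeric or ",
                                       "'value unit' string"))
      }
    }
  }
  params <- tryCatch(do.call(min_params, pvals),
                     error = function(e) {
                       failures <<- c(failures, conditionMessage(e))
                       NULL
                     })
  geometry <- utils::modifyList(list(dr = 0.1, dz = 0.1),
                                as.list(raw$geometry))
  solver <- utils::modifyList(
    list(t_end = 600, sample_dt = 0.5, rtol = 1e-6, atol = 1e-9),
    as.list(raw$solver))
  analysis <- utils::modifyList(
    list(threshold = 1e-3, transient_frac = 0.5, n_periods = 5),
    as.list(raw$analysis))
  if (length(failures)) {
    stop("invalid configuration (", source, "):\n  - ",
         paste(failures, collapse = "\n  - "))
  }
  cfg <- list(params = params, geometry = geometry, solver = solver,
              analysis = analysis, scan = raw$scan,
              optimize = raw$optimize,
              output = raw$output, preset = raw$preset)
  class(cfg) <- "min_config"
  cfg
}

#' Serialize a configuration back to YAML
#'
#' Writes every parameter as a `"value unit"` string so that a dumped
#' configuration reloads to an identical object (round-trip property).
#'
#' @param cfg a `min_config`
#' @param path output path; a connection-free character path
#' @return `path`, invisibly
#' @export
dump_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "min_config"))
  units <- param_units()
  pl <- lapply(names(units), function(n) {
    paste(format(cfg$params[[n]], digits = 17), units[[n]])
  })
  names(pl) <- names(units)
  out <- list(params = pl, geometry = cfg$geometry, solver = cfg$solver,
              analysis = cfg$analysis)
  for (blk in c("scan", "optimize", "output", "preset")) {
    if (!is.null(cfg[[blk]])) out[[blk]] <- cfg[[blk]]
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Named experiment presets
#'
#' One configuration per canonical experiment of the study conditions:
#' \describe{
#'   \item{default / fig2}{the reference oscillatory parameter set
#'     (backward rates `k_minus_2 = 0.01/s`, `k_minus_2c = 0.001
#'     um^2/s`, `k_minus_3 = 0.04/s`, `k_minus_4 = 1e-5 um^4/s` with
#'     `k_minus_1 = 0.6/s`, giving `gamma = 1e8`); the dissipation-axis
#'     experiment sweeps `k_minus_1`}
#'   \item{fig3_ac}{the same backward rates, intended for plane scans in
#'     `(k_minus_1, k_plus_1)` or `(k_minus_4, k_plus_4)`}
#'   \item{fig4_strategy}{strategy optimization at total budget -18 kBT}
#'   \item{s4}{`k_minus_1 = 0.06/s`; the `k_plus_4` oscillation-window
#'     axis}
#'   \item{s6_stable}{`k_minus_1 = 30/s`, the stationary cell-end-effect
#'     regime}
#'   \item{s1_noncoop}{the non-cooperative variant (`k_plus_2 = 1 um/s`,
#'     `k_minus_2 = 0.1/s`, cooperative channel removed), which never
#'     oscillates}
#' }
#'
#' @return a named list of `min_config` objects
#' @export
presets <- function() {
  mk <- function(pars = list(), extra = list(), name) {
    config_from_list(c(list(params = pars, preset = name), extra),
                     source = paste0("preset '", name, "'"))
  }
  list(
    default = mk(name = "default"),
    fig2 = mk(name = "fig2",
              extra = list(scan = list(axis1 = "k_minus_1",
                                       from = 0.06, to = 60, n = 13,
                                       log = TRUE))),
    fig3_ac = mk(name = "fig3_ac",
                 extra = list(scan = list(axis1 = "k_minus_1",
                                          axis2 = "k_plus_1",
                                          from = 0.06, to = 60, n = 7,
                                          log = TRUE))),
    fig4_strategy = mk(name = "fig4_strategy",
                       extra = list(optimize = list(total_dg = -18,
                                                    n_grid = 13))),
    s4 = mk(pars = list(k_minus_1 = 0.06), name = "s4",
            extra = list(scan = list(axis1 = "k_plus_4",
                                     from = 0.1, to = 5, n = 13,
                                     log = TRUE))),
    s6_stable = mk(pars = list(k_minus_1 = 30), name = "s6_stable"),
    s1_noncoop = mk(pars = list(k_plus_2 = 1, k_minus_2 = 0.1,
                                k_plus_2c = 0, k_minus_2c = 0),
                    name = "s1_noncoop")
  )
}

#' Run the simulation described by a configuration
#'
#' @param cfg a `min_config` (from [load_config()] or [presets()])
#' @return a `min_trajectory`
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "min_config"))
  p <- cfg$params
  g <- build_geometry(p$R, p$L, dr = cfg$geometry$dr, dz = cfg$geometry$dz)
  simulate_min(p, g, t_end = cfg$solver$t_end,
               sample_dt = cfg$solver$sample_dt,
               rtol = cfg$solver$rtol, atol = cfg$solver$atol)
}

#' Persist a trajectory as a structured plain-text container
#'
#' Writes a directory holding the echoed configuration
#' (`config.yaml`), the kymograph (`kymograph.csv`: time by axial
#' position), the integrated fluxes (`fluxes.csv`), the dissipation time
#' series (`sigma.csv`), species counts (`counts.csv`) and the pole
#' probe (`probe.csv`).
#'
#' @param tr a `min_trajectory`
#' @param dir output directory (created if missing)
#' @param cfg optional `min_config` echoed alongside the results
#' @return `dir`, invisibly
#' @export
write_trajectory <- function(tr, dir, cfg = NULL) {
  stopifnot(inherits(tr, "min_trajectory"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cfg)) {
    cfg <- config_from_list(list(
      params = as.list(unlist(tr$params[names(param_units())])),
      geometry = list(dr = tr$geometry$dr, dz = tr$geometry$dz),
      solver = tr$solver[c("t_end", "sample_dt", "rtol", "atol")]))
  }
  dump_config(cfg, file.path(dir, "config.yaml"))
  ky <- as.data.frame(tr$kymograph)
  names(ky) <- sprintf("z_%0.4f", tr$geometry$z_centers)
  utils::write.csv(cbind(time = tr$times, ky),
                   file.path(dir, "kymograph.csv"), row.names = FALSE)
  utils::write.csv(tr$fluxes, file.path(dir, "fluxes.csv"),
                   row.names = FALSE)
  utils::write.csv(tr$sigma, file.path(dir, "sigma.csv"), row.names = FALSE)
  utils::write.csv(tr$counts, file.path(dir, "counts.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(time = tr$times, pole_MinD = tr$probe),
                   file.path(dir, "probe.csv"), row.names = FALSE)
  invisible(dir)
}
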