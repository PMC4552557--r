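#' Detect sustained oscillation and estimate the period
#'
#' Classifies a trajectory from the pole-membrane MinD probe series: the
#' leading transient (default: first half of the run) is discarded, and
#' the system is regarded as oscillating when the coefficient of
#' variation (sd/mean) of the remaining series exceeds `threshold` and
#' the amplitude is sustained rather than decaying (the cv of the last
#' half of the analysis window must not have fallen below `decay_min`
#' times the cv of the first half, which separates a limit cycle from a
#' slowly decaying spiral near the bifurcation). The period is estimated
#' from the spacing of successive probe maxima and cross-checked against
#' the first autocorrelation peak.
#'
#' @param tr a [simulate_min()] trajectory
#' @param threshold relative-variance (sd/mean) cutoff for oscillation
#' @param transient_frac fraction of the run discarded as transient
#' @param decay_min minimum allowed amplitude-decay ratio for an
#'   oscillation to count as sustained
#' @return a one-row tibble with `oscillating`, `period` (s, NA when not
#'   oscillating or undetermined), `amplitude`, `cv`, `decay_ratio`,
#'   `n_peaks`; the analysed probe window is attached as attribute
#'   `"probe"`
#' @export
detect_oscillation <- function(tr, threshold = 1e-3, transient_frac = 0.5,
                               decay_min = 0.3) {
  stopifnot(inherits(tr, "min_trajectory"))
  n <- length(tr$probe)
  i0 <- max(1L, floor(n * transient_frac))
  x <- tr$probe[i0:n]
  tt <- tr$times[i0:n]
  m <- mean(x)
  cv <- if (m > 0) stats::sd(x) / m else 0
  half <- length(x) %/% 2
  cv1 <- if (mean(x[1:half]) > 0) stats::sd(x[1:half]) / mean(x[1:half]) else 0
  cv2 <- if (mean(x[(half + 1):length(x)]) > 0) {
    stats::sd(x[(half + 1):length(x)]) / mean(x[(half + 1):length(x)])
  } else 0
  decay_ratio <- if (cv1 > 0) cv2 / cv1 else 1
  oscillating <- is.finite(cv) && cv > threshold && decay_ratio > decay_min

  period <- NA_real_
  amplitude <- NA_real_
  n_peaks <- 0L
  if (oscillating) {
    pk <- which(diff(sign(diff(x))) == -2) + 1L
    n_peaks <- length(pk)
    if (n_peaks >= 3) {
      period <- mean(diff(tt[pk]))
      # cross-check against the first autocorrelation maximum
      ac <- stats::acf(x - mean(x), lag.max = length(x) - 2, plot = FALSE)$acf
      apk <- which(diff(sign(diff(ac))) == -2)
      if (length(apk)) {
        p_acf <- apk[1] * (tt[2] - tt[1])
        if (is.finite(p_acf) && abs(p_acf - period) / period > 0.2) {
          warning("period estimates disagree: maxima spacing ",
                  format(period), " s vs autocorrelation ", format(p_acf),
                  " s; reporting maxima-based value")
        }
      }
      amplitude <- (max(x) - min(x)) / 2
    } else {
      warning("fewer than 3 probe maxima in the analysis window; ",
              "period undetermined - extend the run")
    }
  }
  out <- tibble::tibble(oscillating = oscillating, period = period,
                        amplitude = amplitude, cv = cv,
                        decay_ratio = decay_ratio, n_peaks = n_peaks)
  attr(out, "probe") <- tibble::tibble(time = tt, value = x)
  out
}

time_average <- function(t, x, t1, t2) {
  sel <- t >= t1 - 1e-9 & t <= t2 + 1e-9
  t <- t[sel]
  x <- x[sel]
  if (length(t) < 2) return(mean(x))
  sum(diff(t) * (utils::head(x, -1) + utils::tail(x, -1)) / 2) / (t[length(t)] - t[1])
}

averaging_window <- function(tr, n_periods = 5) {
  osc <- detect_oscillation(tr)
  t2 <- max(tr$times)
  if (isTRUE(osc$oscillating) && is.finite(osc$period)) {
    span <- t2 - tr$times[max(1L, floor(length(tr$times) * 0.5))]
    k <- max(1L, min(n_periods, floor(span / osc$period)))
    list(t1 = t2 - k * osc$period, t2 = t2, periods = k, osc = osc)
  } else {
    list(t1 = t2, t2 = t2, periods = 0L, osc = osc)
  }
}

#' Mid-cell marking performance (h/w score)
#'
#' Computes the time-averaged profile of membrane-bound MinD
#' (`rho_d + rho_de`) along the lateral membrane, with the axial
#' coordinate normalized to `[0, 1]` and the concentration rescaled by
#' its mid-cell value. The depth `h` is the rescaled profile's maximum
#' minus one; when the mid-cell is itself the profile maximum (the
#' stationary cell-end-effect regime) `h` is the minimum minus one and
#' the score is negative. The width `w` is the distance between the
#' half-depth crossings (level `1 + h/2`) on either side of mid-cell,
#' and the performance score is `h/w`. Oscillatory trajectories are
#' averaged over an integer number of detected periods from the end of
#' the run; stationary ones use the final profile. End caps participate
#' in the dynamics but are excluded from the axial profile.
#'
#' @param tr a [simulate_min()] trajectory
#' @param n_periods number of whole periods to average over
#' @return a one-row tibble with `h`, `w`, `score`, `oscillating`,
#'   `period`, `periods_averaged`; the rescaled profile is attached as
#'   attribute `"profile"`
#' @export
performance <- function(tr, n_periods = 5) {
  stopifnot(inherits(tr, "min_trajectory"))
  win <- averaging_window(tr, n_periods)
  z <- tr$geometry$z_centers / tr$geometry$L
  if (win$periods > 0) {
    prof <- vapply(seq_len(ncol(tr$kymograph)), function(j) {
      time_average(tr$times, tr$kymograph[, j], win$t1, win$t2)
    }, numeric(1))
  } else {
    prof <- tr$kymograph[nrow(tr$kymograph), ]
  }
  mid <- stats::approx(z, prof, xout = 0.5)$y
  if (!is.finite(mid) || mid <= 0) {
    out <- tibble::tibble(h = NA_real_, w = NA_real_, score = NA_real_,
                          oscillating = win$osc$oscillating,
                          period = win$osc$period,
                          periods_averaged = win$periods)
    attr(out, "profile") <- tibble::tibble(z = z, value = prof)
    warning("mid-cell concentration is zero or undefined; score undefined")
    return(out)
  }
  f <- prof / mid
  tol <- 1e-6
  if (max(f) - 1 > tol) {
    h <- max(f) - 1            # poles above mid-cell: valley at mid-cell
  } else if (1 - min(f) > tol) {
    h <- min(f) - 1            # mid-cell is the maximum: negative score
  } else {
    out <- tibble::tibble(h = 0, w = NA_real_, score = 0,
                          oscillating = win$osc$oscillating,
                          period = win$osc$period,
                          periods_averaged = win$periods)
    attr(out, "profile") <- tibble::tibble(z = z, value = prof, rescaled = f)
    return(out)
  }
  level <- 1 + h / 2
  zl <- profile_crossing(z, f, level, side = "left")
  zr <- profile_crossing(z, f, level, side = "right")
  w <- zr - zl
  out <- tibble::tibble(h = h, w = w, score = h / w,
                        oscillating = win$osc$oscillating,
                        period = win$osc$period,
                        periods_averaged = win$periods)
  attr(out, "profile") <- tibble::tibble(z = z, value = prof, rescaled = f)
  out
}

# first crossing of `level` moving outward from mid-cell; falls back to the
# position of the outermost extremum if the level is never crossed
profile_crossing <- function(z, f, level, side) {
  if (side == "left") {
    idx <- rev(which(z < 0.5))
  } else {
    idx <- which(z > 0.5)
  }
  sgn <- sign(f[idx] - level)
  start_sgn <- sign(stats::approx(z, f, xout = 0.5)$y - level)
  for (j in seq_along(idx)[-1]) {
    a <- idx[j - 1]
    b <- idx[j]
    if ((f[a] - level) * (f[b] - level) <= 0 && f[a] != f[b]) {
      return(z[a] + (level - f[a]) * (z[b] - z[a]) / (f[b] - f[a]))
    }
  }
  # check the segment adjacent to mid-cell
  a <- idx[1]
  fmid <- stats::approx(z, f, xout = 0.5)$y
  if ((fmid - level) * (f[a] - level) <= 0 && f[a] != fmid) {
    return(0.5 + (level - fmid) * (z[a] - 0.5) / (f[a] - fmid))
  }
  z[idx[length(idx)]]
}

#' Locate an oscillation bifurcation along one parameter axis
#'
#' Bisects (on a log scale) a single rate constant between a
#' non-oscillatory and an oscillatory endpoint, classifying each run with
#' [detect_oscillation()], until the bracket's relative width falls below
#' `rel_width`. Returns the critical parameter value (the geometric
#' midpoint of the final bracket) and the corresponding nonequilibrium
#' parameter `gamma_c`.
#'
#' @param p base [min_params()]
#' @param param name of the parameter to bisect (e.g. `"k_minus_1"`)
#' @param lower,upper bracket endpoints (must straddle the bifurcation)
#' @param g mesh; defaults to 0.1 um spacing
#' @param t_end run length per classification (s); long runs sharpen the
#'   boundary because near-critical transients decay slowly
#' @param rel_width stop when `upper/lower - 1 < rel_width`
#' @param ... further arguments to [detect_oscillation()]
#' @return a one-row tibble: `param`, `critical_value`, `gamma_c`,
#'   `lower`, `upper`, `n_runs`
#' @export
find_bifurcation <- function(p, param, lower, upper,
                             g = build_geometry(p$R, p$L),
                             t_end = 1200, rel_width = 0.05, ...) {
  stopifnot(inherits(p, "min_params"), lower > 0, upper >= lower)
  classify <- function(val) {
    pp <- do.call(update_params, stats::setNames(list(p, val), c("p", param)))
    tr <- simulate_min(pp, g, t_end = t_end)
    isTRUE(detect_oscillation(tr, ...)$oscillating)
  }
  result <- function(lo, hi, n) {
    crit <- sqrt(lo * hi)
    pc <- do.call(update_params, stats::setNames(list(p, crit), c("p", param)))
    tibble::tibble(param = param, critical_value = crit,
                   gamma_c = gamma_factor(pc), lower = lo, upper = hi,
                   n_runs = n)
  }
  if (upper == lower) {
    warning("degenerate bracket of width zero; returning the endpoint")
    return(result(lower, upper, 0L))
  }
  s_lo <- classify(lower)
  s_hi <- classify(upper)
  n <- 2L
  if (s_lo == s_hi) {
    stop("no bifurcation in range: oscillation status is ",
         if (s_lo) "oscillatory" else "stationary", " at both endpoints")
  }
  lo <- lower
  hi <- upper
  while (hi / lo - 1 > rel_width) {
    mid <- sqrt(lo * hi)
    s_mid <- classify(mid)
    n <- n + 1L
    if (s_mid == s_lo) lo <- mid else hi <- mid
  }
  result(lo, hi, n)
}

#' Scan a plane (or line) of parameter space
#'
#' Runs an independent simulation at every grid point, classifies it,
#' scores it, and computes the period-averaged dissipation budget. A
#' failed point is recorded in the `error` column and the scan continues.
#'
#' @param p base [min_params()]
#' @param axis1,axis2 parameter names; `axis2 = NULL` scans a line
#' @param values1,values2 grid values for each axis
#' @param g mesh
#' @param t_end run length per point (s)
#' @param n_periods periods averaged for the dissipation budget
#' @param ... further arguments to [detect_oscillation()]
#' @return a tibble (class `min_scan`) with one row per grid point:
#'   the axis values, `gamma`, `oscillating`, `period`, `score`,
#'   `sigma_avg`, `sigma_1 ... sigma_4`, `sigma_diff`, `J_avg`,
#'   `cytoplasm_MinE`, `error`, plus the full parameter set per row
#' @export
scan_plane <- function(p, axis1, values1, axis2 = NULL, values2 = NULL,
                       g = build_geometry(p$R, p$L), t_end = 600,
                       n_periods = 5, ...) {
  stopifnot(inherits(p, "min_params"))
  grid <- if (is.null(axis2)) {
    tibble::tibble(v1 = values1)
  } else {
    tidyr::expand_grid(v1 = values1, v2 = values2)
  }
  rows <- purrr::pmap(grid, function(v1, v2 = NULL) {
    repl <- stats::setNames(list(v1), axis1)
    if (!is.null(v2)) repl[[axis2]] <- v2
    tryCatch({
      pp <- do.call(update_params, c(list(p), repl))
      tr <- simulate_min(pp, g, t_end = t_end)
      bud <- period_averaged_budget(tr, n_periods = n_periods, ...)
      perf <- performance(tr, n_periods = n_periods)
      gl <- generics::glance(bud)
      tibble::tibble(
        gamma = gamma_factor(pp),
        oscillating = gl$oscillating, period = gl$period,
        score = perf$score, h = perf$h, w = perf$w,
        sigma_avg = gl$sigma_tot, sigma_1 = gl$sigma_1,
        sigma_2 = gl$sigma_2, sigma_3 = gl$sigma_3, sigma_4 = gl$sigma_4,
        sigma_diff = gl$sigma_diff, J_avg = gl$J_avg,
        cytoplasm_MinE = time_average(
          tr$counts$time, tr$counts$cytoplasm_MinE,
          averaging_window(tr, n_periods)$t1, max(tr$counts$time)),
        error = NA_character_,
        !!!stats::setNames(as.list(unlist(pp[names(param_units())])),
                           names(param_units())))
    }, error = function(e) {
      tibble::tibble(!!!tibble::as_tibble(repl),
                     gamma = NA_real_, oscillating = NA, period = NA_real_,
                     score = NA_real_, h = NA_real_, w = NA_real_,
                     sigma_avg = NA_real_, sigma_1 = NA_real_,
                     sigma_2 = NA_real_, sigma_3 = NA_real_,
                     sigma_4 = NA_real_, sigma_diff = NA_real_,
                     J_avg = NA_real_, cytoplasm_MinE = NA_real_,
                     error = conditionMessage(e))
    })
  })
  out <- dplyr::bind_rows(rows)
  axes <- c(axis1, axis2)
  out <- dplyr::relocate(out, dplyr::all_of(axes))
  class(out) <- c("min_scan", class(out))
  out
}

#' Search for the optimal free-energy dissipation strategy
#'
#' Grid search over the per-step standard free-energy allocation
#' `(dg1, dg3, dg4)` at a fixed total budget `total_dg = -ln(gamma)`;
#' `dg2` is closed by the budget constraint and the backward rates are
#' derived as `k_minus_i = k_plus_i * exp(dg_i)`. Each point is an
#' independent deterministic run scored with [performance()]. Ties on
#' the score are broken toward the smaller average dissipation rate.
#' An optional single local refinement pass halves the grid spacing
#' around the best point.
#'
#' @param total_dg total free-energy budget per cycle (kBT, negative)
#' @param dg1,dg3,dg4 grids over the per-step allocations (kBT)
#' @param base base [min_params()] supplying forward rates
#' @param g mesh
#' @param t_end run length per point (s)
#' @param refine logical: run one local refinement pass
#' @param ... passed to [detect_oscillation()] via the scan machinery
#' @return a list of class `min_strategy`: `map` (tibble of all points),
#'   `best` (one-row tibble), `budget` (the [period_averaged_budget()]
#'   of the best point, NULL when nothing oscillates), `all_stationary`
#' @export
optimize_strategy <- function(total_dg = -18,
                              dg1 = seq(-12, 0, length.out = 13),
                              dg3 = seq(-12, 0, length.out = 13),
                              dg4 = seq(-12, 0, length.out = 13),
                              base = min_params(),
                              g = build_geometry(base$R, base$L),
                              t_end = 600, refine = TRUE, ...) {
  eval_grid <- function(g1, g3, g4) {
    grid <- tidyr::expand_grid(dg1 = g1, dg3 = g3, dg4 = g4)
    purrr::pmap_dfr(grid, function(dg1, dg3, dg4) {
      dg2 <- total_dg - dg1 - dg3 - dg4
      tryCatch({
        pp <- params_from_delta_g(dg1, dg3, dg4, delta_g_total = total_dg,
                                  base = base)
        tr <- simulate_min(pp, g, t_end = t_end)
        perf <- performance(tr)
        bud <- period_averaged_budget(tr, ...)
        gl <- generics::glance(bud)
        tibble::tibble(dg1 = dg1, dg2 = dg2, dg3 = dg3, dg4 = dg4,
                       oscillating = gl$oscillating, period = gl$period,
                       score = perf$score, sigma_avg = gl$sigma_tot,
                       sigma_1 = gl$sigma_1, sigma_2 = gl$sigma_2,
                       sigma_3 = gl$sigma_3, sigma_4 = gl$sigma_4,
                       sigma_diff = gl$sigma_diff,
                       error = NA_character_)
      }, error = function(e) {
        tibble::tibble(dg1 = dg1, dg2 = dg2, dg3 = dg3, dg4 = dg4,
                       oscillating = NA, period = NA_real_,
                       score = NA_real_, sigma_avg = NA_real_,
                       sigma_1 = NA_real_, sigma_2 = NA_real_,
                       sigma_3 = NA_real_, sigma_4 = NA_real_,
                       sigma_diff = NA_real_,
                       error = conditionMessage(e))
      })
    })
  }
  map <- eval_grid(dg1, dg3, dg4)
  pickable <- dplyr::filter(map, !is.na(score), isTRUE(oscillating) |
                              oscillating %in% TRUE)
  all_stationary <- nrow(pickable) == 0
  best <- NULL
  if (!all_stationary) {
    best <- dplyr::slice(dplyr::arrange(pickable, dplyr::desc(score),
                                        sigma_avg), 1)
    if (refine) {
      step <- function(grid) if (length(grid) > 1) min(diff(sort(grid))) else 1
      local <- function(center, h) center + c(-h, 0, h) / 2
      map2 <- eval_grid(local(best$dg1, step(dg1)),
                        local(best$dg3, step(dg3)),
                        local(best$dg4, step(dg4)))
      map <- dplyr::bind_rows(map, map2)
      pickable <- dplyr::filter(map, !is.na(score), oscillating %in% TRUE)
      best <- dplyr::slice(dplyr::arrange(pickable, dplyr::desc(score),
                                          sigma_avg), 1)
    }
  }
  budget <- NULL
  if (!all_stationary) {
    pp <- params_from_delta_g(best$dg1, best$dg3, best$dg4,
                              delta_g_total = total_dg, base = base)
    tr <- simulate_min(pp, g, t_end = t_end)
    budget <- period_averaged_budget(tr)
  }
  out <- list(map = map, best = best, budget = budget,
              all_stationary = all_stationary, total_dg = total_dg)
  class(out) <- "min_strategy"
  out
}

#' @export
print.min_strategy <- function(x, ...) {
  cat(sprintf("<min_strategy> budget %.3g kBT, %d grid points\n",
              x$total_dg, nrow(x$map)))
  if (x$all_stationary) {
    cat("  no oscillatory point on the grid (budget below threshold?)\n")
  } else {
    cat(sprintf("  best score %.4g at dg = (%.3g, %.3g, %.3g, %.3g)\n",
                x$best$score, x$best$dg1, x$best$dg2, x$best$dg3,
                x$best$dg4))
  }
  invisible(x)
}
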