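# Shared simulation runs, computed once per test session. The reference
# run uses the production mesh (0.1 um); the coarse mesh (dr 0.25, dz
# 0.2) is used where many runs are needed.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

coarse_geometry <- function(p = min_params()) {
  build_geometry(p$R, p$L, dr = 0.25, dz = 0.2)
}

default_run <- function() {
  cached("default", {
    p <- min_params()
    simulate_min(p, build_geometry(p$R, p$L), t_end = 600)
  })
}

coarse_run <- function() {
  cached("coarse", {
    p <- min_params()
    simulate_min(p, coarse_geometry(p), t_end = 600)
  })
}

stable_run <- function() {
  cached("stable", {
    p <- update_params(min_params(), k_minus_1 = 30)
    simulate_min(p, coarse_geometry(p), t_end = 400)
  })
}

# synthetic trajectory carrying only what the analysis layer reads
fake_trajectory <- function(times, probe, profile = NULL, L = 4) {
  nz <- if (is.null(profile)) 40L else length(profile)
  z <- (seq_len(nz) - 0.5) * L / nz
  kymo <- if (is.null(profile)) {
    matrix(rep(probe, nz), ncol = nz)
  } else {
    matrix(rep(profile, each = length(times)), ncol = nz)
  }
  structure(list(
    times = times, probe = probe, kymograph = kymo,
    geometry = structure(list(z_centers = z, L = L), class = "min_geometry"),
    params = min_params()), class = "min_trajectory")
}
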