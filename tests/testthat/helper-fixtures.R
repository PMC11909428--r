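# Shared fixtures. Small grids (scale-8 presets) keep unit tests fast; the
# acceptance tests use the default quarter-scale (scale-4) experiment, run
# once and memoised here.

fixture_env <- new.env(parent = emptyenv())

small_profile <- function(name = "spectralis_like") device_preset(name, scale = 8)

small_phantom <- function(severity = 5, seed = 3) {
  prof <- small_profile()
  params <- params_for_severity(severity, seed = seed)
  surfaces <- generate_surfaces(params, prof$grid)
  list(profile = prof, params = params, surfaces = surfaces,
       labels = rasterize_labels(surfaces),
       volume = render_volume(surfaces, prof, seed = seed + 1))
}

# Labels object with given channel arrays on a matching ad-hoc grid
labels_from_arrays <- function(ilm, rpe, rpedc,
                               dz = 3.91, dx = 11.7, dy = 47.2) {
  d <- dim(ilm)
  oct_labels(ilm, rpe, rpedc, grid_spec(d[1], d[2], d[3], dz, dx, dy))
}

empty_labels <- function(n_rows, n_cols, n_bscans, ...) {
  z <- array(0L, c(n_rows, n_cols, n_bscans))
  labels_from_arrays(z, z, z, ...)
}

# The default quarter-scale experiment (both architectures), run once per
# test session and shared by the end-to-end validation tests.
default_acceptance_run <- function() {
  if (is.null(fixture_env$acc_run)) {
    cfg <- experiment_config(n_train = 5L, n_test = 6L, seed = 1L)
    fixture_env$acc_run <- run_experiment(cfg)
  }
  fixture_env$acc_run
}
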