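# Shared fixtures. The full reference-configuration sweep is expensive, so it
# is computed once per test run and reused by the design and acceptance
# tests.

.fixture_env <- new.env(parent = emptyenv())

get_default_sweep <- function() {
  if (is.null(.fixture_env$sweep)) {
    .fixture_env$sweep <- suppressWarnings(
      sweep_flow_rates(cfg = default_config()))
  }
  .fixture_env$sweep
}

get_op5 <- function() { # the 5 uL/min operating point of the default sweep
  sw <- get_default_sweep()
  sw$points[[which(sw$table$Q_uL_min == 5)[1]]]
}

# small flat (array-free) chamber grid for solver checks
flat_grid <- function(nx = 24, ny = 12, nz = 20, half_model = TRUE,
                      height = 0.5e-3, width = 3e-3, length = 6e-3) {
  ch <- chamber_spec(length_x = length, width_y = width, height_z = height,
                     half_model = half_model)
  W <- if (half_model) width / 2 else width
  build_chamber_grid(ch, scaffold_array_spec(n_rows = 0L, n_cols = 0L),
                     grid_control(dx = length / nx, dy = W / ny,
                                  dz_fine = height / nz,
                                  fine_height = height, growth = 1))
}

# coarse default-geometry grid (array included) for oxygen property tests
coarse_array_grid <- function() {
  build_chamber_grid(chamber_spec(), scaffold_array_spec(),
                     grid_control(dx = 250e-6, dy = 250e-6, dz_fine = 10e-6,
                                  fine_height = 50e-6, growth = 2))
}
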