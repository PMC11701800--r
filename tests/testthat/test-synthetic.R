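test_that("reference configuration carries the study constants", {
  cfg <- default_config()
  expect_equal(cfg$chamber$length_x, 6e-3)
  expect_equal(cfg$chamber$inlet_diameter, 0.76e-3)
  expect_equal(cfg$array$n_rows * cfg$array$n_cols, 16)
  expect_equal(cfg$oxygen$Km / cfg$oxygen$C0, 2.75e-3)
  expect_equal(config_chamber(cfg)$A_in, 4.5365e-7, tolerance = 1e-4)
  expect_equal(cfg$loading$n_array + cfg$loading$n_flat,
               cfg$loading$n_total)
  expect_equal(cfg$sweep$rates_uL_min, c(1, 3, 5, 10))
  # every section instantiates its domain object
  expect_s3_class(config_array(cfg), "scaffold_array_spec")
  expect_s3_class(config_oxygen(cfg), "oxygen_params")
  expect_s3_class(config_ranges(cfg), "physiological_ranges")
})

test_that("random configurations are deterministic and valid", {
  c1 <- random_config(42)
  c2 <- random_config(42)
  expect_identical(c1, c2)
  c3 <- random_config(43)
  expect_false(identical(c1$chamber$length_x, c3$chamber$length_x))
  for (seed in 1:10) {
    cfg <- random_config(seed)
    expect_s3_class(config_chamber(cfg), "chamber_spec")
    expect_true(cfg$loading$n_array + cfg$loading$n_flat ==
                  cfg$loading$n_total)
    g <- build_chamber_grid(config_chamber(cfg), config_array(cfg),
                            config_grid_control(cfg))
    expect_gt(region_volume(g, "POROUS_ARRAY"), 0)
  }
})

test_that("conservation, boundedness and linearity hold on random
          configurations at coarse resolution", {
  for (seed in c(7, 19, 53)) {
    cfg <- random_config(seed)
    cfg$grid <- list(dx = cfg$chamber$length_x / 32,
                     dy = cfg$chamber$width_y / 2 / 8,
                     dz_fine = 10e-6, fine_height = 50e-6, growth = 2)
    g <- build_chamber_grid(config_chamber(cfg), config_array(cfg),
                            config_grid_control(cfg))
    f <- config_fluid(cfg)
    s1 <- solve_stokes_brinkman(g, f, flow_bc("5 uL/min"), kappa = 6e-11)
    s2 <- solve_stokes_brinkman(g, f, flow_bc("10 uL/min"), kappa = 6e-11)
    # flow mass conservation and linearity
    expect_lt(max(abs(divergence(s1))) / s1$Q, 1e-10)
    expect_lt(max(abs(s2$u - 2 * s1$u)) / max(abs(s1$u)), 1e-8)
    # oxygen boundedness and conservation
    ox <- solve_oxygen(g, s1, config_oxygen(cfg), config_loading(cfg))
    expect_gte(min(ox$C), 0)
    expect_lte(max(ox$C), cfg$oxygen$C0 * (1 + 1e-12))
    expect_lt(abs(ox$conservation$residual) /
                max(ox$conservation$consumption, 1e-300), 0.01)
  }
})

test_that("manufactured problems satisfy their own closed forms", {
  ms <- make_manufactured_stokes(Q = "5 uL/min")
  expect_equal(ms$tau_plane, 0.46e-3, tolerance = 1e-3)
  expect_equal(ms$exact_u(0, 0), 0) # no slip
  mms <- make_manufactured_adr(Pe = 10)
  # source is the exact residual of the closed form: at the outlet the
  # gradient vanishes, so the source reduces to the diffusion term
  L <- 6e-3
  expect_equal(mms$source(L), -0.4 * 0.2 * 2e-9 * (pi / L)^2,
               tolerance = 1e-9)
  expect_equal(mms$exact(0), 0.2 * 0.9)
  expect_equal(mms$u * L / 2e-9, 10) # Peclet recovered
})
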