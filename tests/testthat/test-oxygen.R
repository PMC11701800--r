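test_that("Michaelis-Menten kinetics has the defining properties", {
  p <- oxygen_params()
  expect_equal(michaelis_menten_rate(p$Km, p), p$Vmax / 2)
  expect_equal(michaelis_menten_rate(0, p), 0)
  expect_equal(michaelis_menten_rate(0.2, p), 3.989e-17, tolerance = 1e-3)
  cs <- seq(0, 0.3, length.out = 50)
  expect_true(all(diff(michaelis_menten_rate(cs, p)) > 0))
  expect_true(all(michaelis_menten_rate(cs, p) <= p$Vmax))
  expect_error(michaelis_menten_rate(-0.1, p), "negative")
})

test_that("unit conversion reconciles concentration and % atmospheric O2", {
  conv <- unit_conversion()
  expect_equal(conc_to_atm_percent(0.14, conv), 13.02, tolerance = 1e-3)
  expect_equal(conc_to_atm_percent(0, conv), 0)
  # hypoxia threshold back in concentration units
  expect_equal(conv$hypoxia_percent / conv$k, 0.2 / 18.6, tolerance = 1e-9)
  prof <- data.frame(x = c(0, 1), C = c(0.2, 0.14), percent_atm = NA)
  expect_equal(percent_drop(prof, conv), 5.58, tolerance = 1e-3)
  expect_equal(percent_drop(prof, conv, mode = "relative"), 30)
  prof2 <- data.frame(x = c(0, 1), C = c(0.2, 0.1785))
  expect_equal(percent_drop(prof2, conv), 2.0, tolerance = 1e-3)
  flatp <- data.frame(x = c(0, 1), C = c(0.15, 0.15))
  expect_equal(percent_drop(flatp, conv), 0)
  expect_equal(percent_drop(flatp, conv, mode = "relative"), 0)
})

test_that("sink assembly distributes cells with the right totals", {
  g <- coarse_array_grid()
  p <- oxygen_params()
  s <- assemble_sink_field(g, cell_loading(), p)
  # volumetric density integrates back to n_array over the full chamber
  expect_equal(s$rho_vol * s$V_array, 32000)
  expect_equal(s$sigma_area * s$A_strip, 18000)
  expect_equal(s$capacity, 50000 * 4e-17)
  # saturating regime: total sink = n_total * Vmax = 2.0e-12 mol/s
  expect_equal(s$capacity, 2.0e-12, tolerance = 0.003)
  expect_error(assemble_sink_field(
    build_chamber_grid(array = scaffold_array_spec(n_rows = 0L,
                                                   n_cols = 0L)),
    cell_loading(100, 100, 0), p), "zero volume")
})

test_that("tracer solve returns the inlet concentration everywhere", {
  g <- coarse_array_grid()
  fl <- uniform_flow(g, 5e-5)
  ox <- solve_oxygen(g, fl, loading = cell_loading(0, 0, 0))
  expect_equal(max(abs(ox$C - 0.2)), 0, tolerance = 1e-10)
})

test_that("oxygen solution is bounded, conservative and matches the
          zeroth-order outlet balance", {
  g <- coarse_array_grid()
  f <- fluid_properties()
  sol <- solve_stokes_brinkman(g, f, flow_bc("5 uL/min"), kappa = 6e-11)
  ox <- solve_oxygen(g, sol)
  expect_gte(min(ox$C), 0)
  expect_lte(max(ox$C), 0.2 + 1e-12)
  cons <- ox$conservation
  expect_lt(abs(cons$residual) / cons$consumption, 0.01)
  # C >> Km everywhere: consumption ~ half-chamber capacity
  expect_gt(min(ox$C) / oxygen_params()$Km, 100)
  expect_equal(cons$consumption, 1e-12, tolerance = 0.003)
  # mixed-cup outlet against the closed-form zeroth-order balance
  expect_equal(mixed_cup_outlet(ox, sol), 0.2 - 2e-12 / 8.3333e-11,
               tolerance = 0.02)
})

test_that("more cells never raise the oxygen concentration anywhere", {
  g <- coarse_array_grid()
  fl <- uniform_flow(g, 5e-5)
  ox1 <- solve_oxygen(g, fl, loading = cell_loading(30000, 20000, 10000))
  ox2 <- solve_oxygen(g, fl, loading = cell_loading(60000, 40000, 20000))
  expect_true(all(ox2$C <= ox1$C + 1e-12))
})

test_that("plug-flow oracle has the closed-form zeroth-order behaviour", {
  p <- oxygen_params()
  ld <- cell_loading()
  Q <- parse_quantity("5 uL/min")
  po <- plugflow_oracle(Q, p, ld)
  expect_equal(po$C_out, 0.2 - 50000 * 4e-17 / Q, tolerance = 1e-3)
  expect_equal(po$C_out, 0.176, tolerance = 0.005)
  # halving Q doubles the drop in the zeroth-order regime
  po2 <- plugflow_oracle(Q / 2, p, ld)
  expect_equal((0.2 - po2$C_out) / (0.2 - po$C_out), 2, tolerance = 0.01)
  # no cells: flat profile
  po0 <- plugflow_oracle(Q, p, cell_loading(0, 0, 0))
  expect_equal(po0$profile$C, rep(0.2, nrow(po0$profile)))
  expect_error(plugflow_oracle(0, p, ld), "Q > 0")
  expect_error(plugflow_oracle(Q, p, ld, n_segments = 5), "10")
})

test_that("well-mixed 3D solve matches the plug-flow oracle within 1%", {
  ch <- chamber_spec(half_model = FALSE)
  g1 <- build_chamber_grid(ch, scaffold_array_spec(n_rows = 0L, n_cols = 0L),
                           grid_control(dx = 6e-3 / 64, dy = 3e-3,
                                        dz_fine = 5e-4, fine_height = 5e-4,
                                        growth = 1))
  expect_equal(c(g1$ny, g1$nz), c(1L, 1L))
  Q <- parse_quantity("5 uL/min")
  fl <- uniform_flow(g1, Q / (3e-3 * 5e-4))
  ld <- cell_loading(50000, 0, 50000)
  ox <- solve_oxygen(g1, fl, loading = ld)
  po <- plugflow_oracle(Q, oxygen_params(), ld)
  expect_lt(abs(ox$C[g1$nx, 1, 1] - po$C_out) / (0.2 - po$C_out), 0.01)
})

test_that("manufactured advection-diffusion problem converges at first
          order or better", {
  mms <- make_manufactured_adr(Pe = 10)
  errs <- vapply(c(16, 32, 64), function(nx) {
    pr <- mms$make(nx)
    ox <- solve_oxygen(pr$grid, pr$flow, mms$params, cell_loading(0, 0, 0),
                       source = pr$source)
    sqrt(mean((ox$C[, 1, 1] - mms$exact(pr$grid$xc))^2))
  }, numeric(1))
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders > 0.9 & orders < 2.1))
  # pure-diffusion with a linear profile is reproduced to round-off:
  # no flow, fixed inlet, zero-gradient outlet -> constant solution
  pr <- mms$make(16)
  ox0 <- solve_oxygen(pr$grid, uniform_flow(pr$grid, 0), mms$params,
                      cell_loading(0, 0, 0))
  expect_equal(max(abs(ox0$C - mms$params$C0)), 0, tolerance = 1e-9)
})

test_that("line profiles follow the spec'd paths and are monotone for
          sink-only transport", {
  op <- get_op5()
  pa <- op$profile_array; pf <- op$profile_flat
  expect_gte(nrow(pa), 200)
  # the through-array line alternates sink (footprint) and gap zones: the
  # near-floor concentration declines monotonically scaffold-to-scaffold
  # (tiny recoveries inside the gaps come from vertical diffusion)
  g <- op$oxygen$grid
  x_mid <- g$col_starts + g$array$microstructure$footprint_x / 2
  C_mid <- approx(pa$x, pa$C, xout = x_mid)$y
  expect_true(all(diff(C_mid) < 0))
  expect_lt(pa$C[nrow(pa)], pa$C[1])
  # the flat-side sink is continuous in x: monotone over the strip
  x_end <- max(g$col_starts) + g$array$microstructure$footprint_x
  expect_true(all(diff(pf$C[pf$x <= x_end]) < 1e-6))
  expect_true(all(pa$C <= 0.2 & pa$C >= 0))
  # through-array line is depleted more than the flat-side line
  expect_lt(pa$C[nrow(pa)], pf$C[nrow(pf)])
  expect_error(line_profile_at_height(op$oxygen, z = 1), "outside")
})
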