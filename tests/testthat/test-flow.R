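# chamber-scale and pore-scale Stokes solver checks against closed forms

test_that("flat-chamber solve conserves mass and matches the duct solution", {
  g <- flat_grid(nx = 24, ny = 12, nz = 20)
  f <- fluid_properties()
  sol <- solve_stokes_brinkman(g, f, flow_bc("5 uL/min"))
  Qh <- parse_quantity("5 uL/min") / 2
  for (x in c(1e-3, 3e-3, 5e-3)) {
    expect_equal(cross_section_flux(sol, x), Qh, tolerance = 1e-3)
  }
  expect_lt(max(abs(divergence(sol))) / sol$Q, 1e-10)
  # floor shear within 5% of the duct analytic value (mid-width)
  wss <- wall_shear_stress(sol)
  f_ <- fluid_properties()
  ta <- f_$mu * analytic_rect_duct("5 uL/min", 3e-3, 5e-4, f_, y = g$yc[1],
                                   z = 0, derivative = TRUE)$dudz
  expect_equal(wss$tau_floor[12, 1], ta, tolerance = 0.05)
  # mid-height velocity profile against the series solution
  uc <- perfusim:::collocate_velocity(sol)$u
  k <- which.min(abs(g$zc - 2.5e-4))
  ex <- analytic_rect_duct("5 uL/min", 3e-3, 5e-4, f_, y = g$yc,
                           z = rep(g$zc[k], g$ny))
  expect_lt(max(abs(uc[12, , k] - ex)) / max(ex), 0.04)
})

test_that("Stokes solution is exactly linear in Q", {
  g <- flat_grid(nx = 12, ny = 6, nz = 10)
  f <- fluid_properties()
  s1 <- solve_stokes_brinkman(g, f, flow_bc("5 uL/min"))
  s2 <- solve_stokes_brinkman(g, f, flow_bc("10 uL/min"))
  denom <- max(abs(s1$u))
  expect_lt(max(abs(s2$u - 2 * s1$u)) / denom, 1e-8)
  expect_lt(max(abs(s2$w - 2 * s1$w)) / denom, 1e-8)
  wss1 <- wall_shear_stress(s1); wss2 <- wall_shear_stress(s2)
  expect_lt(max(abs(wss2$tau_floor - 2 * wss1$tau_floor)) /
              max(abs(wss1$tau_floor)), 1e-8)
})

test_that("floor-shear error vs the analytic value halves under z-refinement", {
  f <- fluid_properties()
  errs <- vapply(c(8, 16, 32), function(nzv) {
    g <- flat_grid(nx = 12, ny = 20, nz = nzv, half_model = FALSE)
    s <- solve_stokes_brinkman(g, f, flow_bc("5 uL/min"))
    wss <- wall_shear_stress(s)
    jmid <- round(g$ny / 2)
    ta <- f$mu * analytic_rect_duct("5 uL/min", 3e-3, 5e-4, f,
                                    y = g$yc[jmid], z = 0,
                                    derivative = TRUE)$dudz
    abs(wss$tau_floor[6, jmid] - ta) / ta
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 1.5)
  expect_lt(errs[1] / errs[2], 2.8)
  expect_gt(errs[2] / errs[3], 1.4)
  expect_lt(errs[2] / errs[3], 2.8)
})

test_that("manufactured plane-Poiseuille field is reproduced", {
  ms <- make_manufactured_stokes(nx = 12, ny = 8, nz = 16)
  sol <- solve_stokes_brinkman(ms$grid, ms$fluid, ms$bc)
  uc <- perfusim:::collocate_velocity(sol)$u
  ex <- outer(ms$grid$yc, ms$grid$zc, function(y, z) ms$exact_u(y, z))
  expect_lt(max(abs(uc[6, , ] - ex)) / max(ex), 0.05)
  # zero-flow limit: tau = 0 everywhere when Q -> 0 (by linearity)
  s0 <- perfusim:::scale_flow(sol, sol$Q * 1e-12)
  expect_lt(max(abs(wall_shear_stress(s0)$tau_floor)),
            1e-10 * max(abs(wall_shear_stress(sol)$tau_floor)))
})

test_that("permeability correlation behaves physically and matches the
          resolved lattice within a factor of 3", {
  ms <- microstructure_spec()
  m <- compute_lattice_metrics(ms)
  k1 <- estimate_permeability(m)
  expect_gt(k1, 0)
  # monotone decreasing with solid fraction
  phis <- c(0.001, 0.01, 0.05, 0.2, 0.4)
  ks <- vapply(phis, function(p)
    estimate_permeability(list(solid_fraction = p, r_eff = m$r_eff)),
    numeric(1))
  expect_true(all(diff(ks) < 0))
  # vanishing solid: finite cap
  expect_equal(estimate_permeability(list(solid_fraction = 0,
                                          r_eff = m$r_eff)), 1e-6)
  expect_error(estimate_permeability(list(solid_fraction = 0.6,
                                          r_eff = m$r_eff)), "invalid")
  # resolved Darcy measurement within a factor of 3
  k2 <- measure_lattice_permeability(ms, spacing = 2.5e-6)
  expect_gt(k1 / k2, 1 / 3)
  expect_lt(k1 / k2, 3)
})

test_that("Brinkman block recovers the open-chamber flow as kappa grows", {
  g <- build_chamber_grid(resolution = grid_control(dx = 250e-6,
                                                    dy = 250e-6,
                                                    dz_fine = 10e-6,
                                                    growth = 2))
  f <- fluid_properties()
  s_open <- solve_stokes_brinkman(g, f, flow_bc("5 uL/min"), kappa = 1e-6)
  g0 <- g; g0$lab[g0$lab == 2L] <- 1L
  s_flat <- solve_stokes_brinkman(g0, f, flow_bc("5 uL/min"))
  expect_lt(max(abs(s_open$u - s_flat$u)) / max(abs(s_flat$u)), 0.01)
})

test_that("small kappa drives the porous region to the Darcy limit", {
  # 1D porous column: the whole chamber is a porous block
  g <- flat_grid(nx = 24, ny = 2, nz = 10)
  g$lab[] <- 2L # POROUS everywhere
  f <- fluid_properties()
  kappa <- 1e-13
  sol <- solve_stokes_brinkman(g, f, flow_bc("5 uL/min"), kappa = kappa)
  # superficial velocity and pressure gradient in the core
  u_sup <- parse_quantity("5 uL/min") / 2 / (1.5e-3 * 0.5e-3)
  iA <- 8; iB <- 16
  G <- (mean(sol$p[iA, , ]) - mean(sol$p[iB, , ])) /
    (g$xc[iB] - g$xc[iA])
  expect_equal(G, f$mu / kappa * u_sup, tolerance = 0.05)
})

test_that("unit cell flux driving matches the imposed superficial velocity", {
  cell <- suppressWarnings(build_unit_cell_geometry())
  f <- fluid_properties()
  target <- 1e-6
  cs <- solve_unit_cell_stokes(cell, superficial_velocity = target,
                               fluid = f)
  uc <- perfusim:::collocate_velocity(cs)$u
  kin <- which(cell$zc < cell$ms$height)
  Vk <- outer(cell$dx, cell$dy) %o% cell$dz[kin]
  usup <- sum(uc[, , kin] * Vk) / sum(Vk)
  expect_equal(usup, target, tolerance = 0.01)
  # no-slip at beam surfaces: faces adjacent to solid carry zero velocity
  solid <- cell$lab == 3L
  k1 <- cell$meta$beams[[1]]$k[1]
  expect_true(all(cs$u[, which(cell$meta$edge_y), k1] == 0))
  expect_lt(max(abs(divergence(cs))) /
              (target * cell$dy[1] * cell$dz[1]), 1e-8)
})

test_that("beam-free unit cell recovers unobstructed duct flow", {
  cell <- build_unit_cell_geometry(include_beams = FALSE)
  cs <- solve_unit_cell_stokes(cell, superficial_velocity = 1e-6)
  uc <- perfusim:::collocate_velocity(cs)$u
  # planar homogeneity: no x/y structure without beams
  for (k in c(1L, cell$nz %/% 2L, cell$nz)) {
    sl <- uc[, , k]
    expect_lt(diff(range(sl)) / max(abs(sl)), 1e-8)
  }
  # shear-driven mode: velocity approaches the lid value at the top
  cell2 <- build_unit_cell_geometry(include_beams = FALSE)
  cs2 <- solve_unit_cell_stokes(cell2, driving = "shear", lid_velocity = 1e-5)
  expect_gt(uc2 <- perfusim:::collocate_velocity(cs2)$u[1, 1, cell2$nz], 0)
  expect_lt(abs(uc2 - 1e-5) / 1e-5, 0.1)
})

test_that("probe interpolation is exact for uniform and linear fields", {
  g <- flat_grid(nx = 12, ny = 6, nz = 10)
  probes <- list(points = data.frame(microstructure = 1, pore = 1,
                                     height = c(1e-4, 2e-4),
                                     x = c(2e-3, 4e-3), y = c(4e-4, 6e-4),
                                     z = c(1e-4, 2e-4)))
  class(probes) <- "probe_set"
  sol <- uniform_flow(g, 3.3e-6)
  tab <- probe_velocity(sol, probes)
  expect_equal(tab$u_x, rep(3.3e-6, 2))
  # linear-in-z manufactured field
  sol$u <- array(rep(g$zc, each = (g$nx + 1) * g$ny),
                 c(g$nx + 1, g$ny, g$nz)) * 2e-3
  tab2 <- probe_velocity(sol, probes)
  expect_equal(tab2$u_x, 2e-3 * probes$points$z, tolerance = 1e-9)
})

test_that("beam-averaged WSS scales linearly with flow rate", {
  op5 <- get_op5()
  sw <- get_default_sweep()
  op1 <- sw$points[[which(sw$table$Q_uL_min == 1)[1]]]
  expect_equal(op1$wss_table$tau_zx, op5$wss_table$tau_zx / 5,
               tolerance = 1e-8)
  # constant-shear sanity: averaging a constant field returns the constant
  expect_equal(mean(op5$wss_table$tau_zx[op5$wss_table$height_um == 40]) /
                 stats::median(op5$wss_table$tau_zx[op5$wss_table$height_um == 40]),
               1, tolerance = 0.2)
})
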