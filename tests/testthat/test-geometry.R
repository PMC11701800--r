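test_that("chamber grid labels the scaffold array with the right volume", {
  g <- build_chamber_grid()
  # half model: 6 x 1.5 x 0.5 mm, 8 footprints of one row
  expect_equal(max(g$xf), 6e-3)
  expect_equal(max(g$yf), 1.5e-3)
  expect_equal(max(g$zf), 0.5e-3)
  vox <- max(cell_volumes(g))
  expect_equal(region_volume(g, "POROUS_ARRAY"), 8 * 1e-11,
               tolerance = 1e-9) # conforming grid: exact up to round-off
  expect_lt(abs(region_volume(g, "POROUS_ARRAY") - 8e-11), vox + 1e-30)
  # labels partition the domain
  expect_true(all(g$lab %in% c(1L, 2L, 3L)))
  expect_equal(region_volume(g, "FLUID") + region_volume(g, "POROUS_ARRAY"),
               6e-3 * 1.5e-3 * 0.5e-3, tolerance = 0.005)
})

test_that("empty array gives a flat chamber and misplaced arrays error", {
  g0 <- build_chamber_grid(array = scaffold_array_spec(n_rows = 0L,
                                                       n_cols = 0L))
  expect_equal(sum(g0$lab == 2L), 0L)
  expect_true(all(g0$flat_floor))
  # array wider than the chamber
  wide <- scaffold_array_spec(lateral_offset = 1.2e-3)
  expect_error(build_chamber_grid(array = wide), "footprint")
  # pitch pushing the array beyond the chamber length
  long <- scaffold_array_spec(pitch_x = 1e-3)
  expect_error(build_chamber_grid(array = long), "footprint")
})

test_that("too-coarse resolutions are rejected with the violated constraint", {
  expect_error(build_chamber_grid(resolution = grid_control(dz_fine = 15e-6)),
               "4 voxels")
  expect_error(build_chamber_grid(resolution = grid_control(dx = 300e-6)),
               "2 voxels")
})

test_that("full model is mirror-symmetric about y = 0", {
  ch <- chamber_spec(half_model = FALSE)
  g <- build_chamber_grid(ch, scaffold_array_spec(), grid_control())
  expect_equal(g$ny, 24L)
  lab_rev <- g$lab[, rev(seq_len(g$ny)), ]
  expect_identical(g$lab, lab_rev)
})

test_that("2x grid refinement changes region volumes by < 1%", {
  g1 <- build_chamber_grid(resolution = grid_control())
  g2 <- build_chamber_grid(resolution = grid_control(dx = 62.5e-6,
                                                     dy = 62.5e-6,
                                                     dz_fine = 2.5e-6))
  v1 <- region_volume(g1, "POROUS_ARRAY"); v2 <- region_volume(g2,
                                                               "POROUS_ARRAY")
  expect_lt(abs(v1 - v2) / v2, 0.01)
  f1 <- region_volume(g1, "FLUID"); f2 <- region_volume(g2, "FLUID")
  expect_lt(abs(f1 - f2) / f2, 0.01)
})

test_that("lattice metrics agree with a fine voxelisation oracle", {
  ms <- microstructure_spec()
  m <- compute_lattice_metrics(ms)
  expect_gt(m$porosity, 0.95)
  expect_equal(m$porosity, 1 - m$solid_fraction)
  sf_vox <- perfusim:::voxelize_pore_lattice(ms, spacing = 0.25e-6)
  expect_equal(m$solid_fraction, sf_vox, tolerance = 0.05)
  # doubling the lateral beam size ~doubles the solid fraction
  ms2 <- microstructure_spec(beam_lateral = 2e-6)
  m2 <- compute_lattice_metrics(ms2)
  sf2_vox <- perfusim:::voxelize_pore_lattice(ms2, spacing = 0.25e-6)
  expect_equal(m2$solid_fraction, sf2_vox, tolerance = 0.05)
  expect_equal(m2$solid_fraction / m$solid_fraction, 2, tolerance = 0.06)
  # vanishing solid
  ms0 <- microstructure_spec(beam_lateral = 1e-9, beam_axial = 1e-9)
  expect_equal(compute_lattice_metrics(ms0)$porosity, 1, tolerance = 1e-4)
  # beams thicker than pores rejected
  expect_error(compute_lattice_metrics(
    microstructure_spec(beam_lateral = 60e-6)), "thicker")
})

test_that("probe set has 27 unique points at the specified pores", {
  g <- build_chamber_grid()
  p <- build_probe_set(g)
  expect_equal(nrow(p$points), 27L)
  expect_equal(nrow(unique(p$points[, c("x", "y", "z")])), 27L)
  # probe (1,1,10um) sits in the first 50 um band of the first footprint
  r <- p$points[p$points$microstructure == 1 & p$points$pore == 1 &
                  p$points$height == 10e-6, ]
  x0 <- g$col_starts[1]
  expect_gt(r$x, x0); expect_lt(r$x, x0 + 50e-6)
  expect_true(all(p$points$x < max(g$xf) & p$points$x > 0))
  expect_true(all(p$points$z <= 40e-6))
  # out-of-array probes rejected
  expect_error(build_probe_set(g, microstructures = 9L), "outside")
  expect_error(build_probe_set(g, pores = 11L), "outside")
})

test_that("unit cell voxelises beams only along pore edges and levels", {
  cell <- suppressWarnings(build_unit_cell_geometry())
  solid <- which(cell$lab == 3L, arr.ind = TRUE)
  # all solid voxels touch a cell edge (x or y first voxel layer)
  expect_true(all(solid[, 1] == 1L | solid[, 2] == 1L))
  # independent count: 3 framing levels (1, 2, 2 voxel layers) of 39 voxels
  # + vertical post voxels on the remaining scaffold-height layers
  n_beam <- 39 * (1 + 2 + 2)
  n_post <- 16 - 4 # post layers below 40 um not already inside beams
  expect_equal(sum(cell$lab == 3L), n_beam + n_post)
  expect_warning(build_unit_cell_geometry(), "inflated")
  # beam-free control cell is an empty duct
  empty <- build_unit_cell_geometry(include_beams = FALSE)
  expect_equal(sum(empty$lab == 3L), 0L)
})
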