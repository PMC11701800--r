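#' Chamber specification
#'
#' Parametric description of one perfused culture chamber: a shallow
#' rectangular cavity (default 6 x 3 x 0.5 mm) fed through a cylindrical
#' inlet. The inlet/outlet cylinders are not discretised; flow enters through
#' the chamber end face as a fully developed duct profile (see
#' [solve_stokes_brinkman()]). When `half_model` is `TRUE` the longitudinal
#' symmetry of the chamber is exploited and only the half domain
#' `y in [0, width_y/2]` is simulated, with a symmetry plane at `y = 0`.
#'
#' @param length_x,width_y,height_z chamber dimensions (m or unit string).
#' @param inlet_diameter,inlet_height inlet cylinder dimensions (informational;
#'   used to derive the inlet cross-section `A_in`).
#' @param half_model logical; simulate half the chamber width.
#' @return object of class `chamber_spec`.
#' @export
chamber_spec <- function(length_x = 6e-3, width_y = 3e-3, height_z = 0.5e-3,
                         inlet_diameter = 0.76e-3, inlet_height = 3e-3,
                         half_model = TRUE) {
  s <- list(
    length_x = parse_quantity(length_x, "length_x"),
    width_y = parse_quantity(width_y, "width_y"),
    height_z = parse_quantity(height_z, "height_z"),
    inlet_diameter = parse_quantity(inlet_diameter, "inlet_diameter"),
    inlet_height = parse_quantity(inlet_height, "inlet_height"),
    half_model = isTRUE(half_model)
  )
  dims <- unlist(s[1:5])
  if (any(dims <= 0)) stop("all chamber dimensions must be > 0")
  s$A_in <- pi * (s$inlet_diameter / 2)^2
  class(s) <- "chamber_spec"
  s
}

#' Microstructure (single scaffold) specification
#'
#' One 3D-printed microscaffold: a 500 x 500 x 40 um block of 50 x 50 x 20 um
#' pores framed by polymer beams of elliptical cross-section (axial dimension
#' along the optical axis z, lateral dimension in-plane).
#'
#' @param footprint_x,footprint_y,height scaffold envelope (m).
#' @param pore_x,pore_y,pore_z pore dimensions (m); pores must tile the
#'   footprint and height exactly.
#' @param beam_axial,beam_lateral beam cross-section diameters (m).
#' @return object of class `microstructure_spec`.
#' @export
microstructure_spec <- function(footprint_x = 500e-6, footprint_y = 500e-6,
                                height = 40e-6, pore_x = 50e-6, pore_y = 50e-6,
                                pore_z = 20e-6, beam_axial = 4.9e-6,
                                beam_lateral = 1.0e-6) {
  s <- lapply(list(footprint_x = footprint_x, footprint_y = footprint_y,
                   height = height, pore_x = pore_x, pore_y = pore_y,
                   pore_z = pore_z, beam_axial = beam_axial,
                   beam_lateral = beam_lateral),
              parse_quantity)
  if (any(unlist(s) <= 0)) stop("all microstructure dimensions must be > 0")
  tile_ok <- function(a, b) abs(a / b - round(a / b)) < 1e-9
  if (!tile_ok(s$footprint_x, s$pore_x) || !tile_ok(s$footprint_y, s$pore_y))
    stop("pores must tile the footprint exactly (footprint/pore must be an integer)")
  if (!tile_ok(s$height, s$pore_z))
    stop("scaffold height must be an integer number of pore layers")
  s$n_pores_x <- as.integer(round(s$footprint_x / s$pore_x))
  s$n_pores_y <- as.integer(round(s$footprint_y / s$pore_y))
  s$n_layers <- as.integer(round(s$height / s$pore_z))
  class(s) <- "microstructure_spec"
  s
}

#' Scaffold array specification
#'
#' The lattice of microscaffolds inside the chamber: `n_rows` rows straddling
#' the symmetry plane `y = 0` and `n_cols` columns equally spaced along the
#' flow direction. The center-to-center pitch defaults to
#' `length_x / n_cols` with the array centred in `x`; the inner edge of each
#' row sits at `|y| = lateral_offset` (rows adjacent by default).
#'
#' @param n_rows,n_cols array layout (rows across, columns along flow).
#' @param pitch_x center-to-center column spacing (m); `NULL` for
#'   `length_x / n_cols` once combined with a chamber.
#' @param lateral_offset distance from the symmetry plane to the inner edge of
#'   each row (m).
#' @param microstructure a [microstructure_spec()].
#' @return object of class `scaffold_array_spec`.
#' @export
scaffold_array_spec <- function(n_rows = 2L, n_cols = 8L, pitch_x = NULL,
                                lateral_offset = 0,
                                microstructure = microstructure_spec()) {
  stopifnot(inherits(microstructure, "microstructure_spec"))
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 0L || n_cols < 0L) stop("n_rows and n_cols must be >= 0")
  s <- list(n_rows = n_rows, n_cols = n_cols,
            pitch_x = if (is.null(pitch_x)) NULL else parse_quantity(pitch_x),
            lateral_offset = parse_quantity(lateral_offset),
            microstructure = microstructure)
  class(s) <- "scaffold_array_spec"
  s
}

#' Grid resolution control
#'
#' Structured-grid spacing: uniform in x and y, graded in z with fine uniform
#' cells of size `dz_fine` up to `fine_height` (shear probes and scaffolds
#' live in the bottom 40 um) and geometrically coarsening cells above.
#'
#' @param dx,dy horizontal cell sizes (m).
#' @param dz_fine fine vertical cell size used below `fine_height` (m).
#' @param fine_height extent of the fine vertical zone (m).
#' @param growth geometric growth factor of the vertical spacing above the
#'   fine zone.
#' @return object of class `grid_control`.
#' @export
grid_control <- function(dx = 125e-6, dy = 125e-6, dz_fine = 5e-6,
                         fine_height = 50e-6, growth = 1.6) {
  s <- list(dx = parse_quantity(dx), dy = parse_quantity(dy),
            dz_fine = parse_quantity(dz_fine),
            fine_height = parse_quantity(fine_height),
            growth = as.numeric(growth))
  if (any(unlist(s[1:4]) <= 0) || s$growth < 1)
    stop("grid spacings must be > 0 and growth >= 1")
  class(s) <- "grid_control"
  s
}

# graded vertical spacing: uniform dz_fine cells up to fine_height, then
# geometric growth; the coarse block is rescaled so cells fit the height exactly
graded_spacing <- function(height, dz_fine, fine_height, growth) {
  fine_height <- min(fine_height, height)
  n_fine <- max(1L, as.integer(round(fine_height / dz_fine)))
  dz <- rep(fine_height / n_fine, n_fine)
  rem <- height - fine_height
  if (rem > 1e-12) {
    sizes <- numeric(0)
    s <- dz_fine * growth
    while (sum(sizes) < rem) {
      sizes <- c(sizes, s)
      s <- s * growth
      if (length(sizes) > 10000L) stop("vertical grading failed to converge")
    }
    sizes <- sizes * (rem / sum(sizes))
    dz <- c(dz, sizes)
  }
  dz
}

# region label codes for the structured grid
LAB_FLUID <- 1L
LAB_POROUS <- 2L
LAB_SOLID <- 3L

#' Build the labelled chamber grid
#'
#' Discretises the chamber and scaffold array onto a structured voxel grid.
#' Voxels are labelled `FLUID` or `POROUS_ARRAY` (scaffold footprints below
#' the scaffold height); floor faces lateral to the array band are flagged as
#' the flat cell strip. Face boundary conditions record the inlet (x = 0),
#' outlet (x = L), symmetry plane (y = 0 in half-model mode) and no-slip
#' walls.
#'
#' @param chamber a [chamber_spec()].
#' @param array a [scaffold_array_spec()].
#' @param resolution a [grid_control()].
#' @return object of class `labeled_grid` with node coordinates, cell sizes,
#'   a 3D region-label array, boundary-face types and the flat-strip floor
#'   mask.
#' @export
build_chamber_grid <- function(chamber = chamber_spec(),
                               array = scaffold_array_spec(),
                               resolution = grid_control()) {
  stopifnot(inherits(chamber, "chamber_spec"),
            inherits(array, "scaffold_array_spec"),
            inherits(resolution, "grid_control"))
  ms <- array$microstructure
  L <- chamber$length_x; H <- chamber$height_z
  Wsim <- if (chamber$half_model) chamber$width_y / 2 else chamber$width_y
  y0 <- if (chamber$half_model) 0 else -chamber$width_y / 2

  # resolution preconditions: the scaffold must be representable
  if (array$n_cols > 0L) {
    if (resolution$dz_fine > ms$height / 4)
      stop("resolution too coarse: need >= 4 voxels across the scaffold height (",
           "dz_fine <= height/4 = ", ms$height / 4, " m)")
    if (resolution$fine_height < ms$height)
      stop("resolution invalid: fine_height must cover the scaffold height")
    if (resolution$dx > ms$footprint_x / 2 || resolution$dy > ms$footprint_y / 2)
      stop("resolution too coarse: need >= 2 voxels across each scaffold footprint")
  }

  pitch <- array$pitch_x %||% (L / max(array$n_cols, 1L))
  span_x <- if (array$n_cols > 0L) (array$n_cols - 1L) * pitch + ms$footprint_x else 0
  x_first <- (L - span_x) / 2 # array centred along the chamber length
  if (array$n_cols > 0L) {
    if (x_first < -1e-12 || span_x > L + 1e-12)
      stop("configuration error: scaffold array exceeds the chamber footprint in x")
    row_extent <- array$lateral_offset + ms$footprint_y
    if (row_extent > chamber$width_y / 2 + 1e-12)
      stop("configuration error: scaffold rows exceed the chamber footprint in y")
  }

  nx <- max(1L, as.integer(round(L / resolution$dx)))
  ny <- max(1L, as.integer(round(Wsim / resolution$dy)))
  dx <- rep(L / nx, nx); dy <- rep(Wsim / ny, ny)
  dz <- graded_spacing(H, resolution$dz_fine, resolution$fine_height,
                       resolution$growth)
  nz <- length(dz)
  xf <- c(0, cumsum(dx)); yf <- y0 + c(0, cumsum(dy)); zf <- c(0, cumsum(dz))
  xc <- (xf[-1] + xf[-(nx + 1)]) / 2
  yc <- (yf[-1] + yf[-(ny + 1)]) / 2
  zc <- (zf[-1] + zf[-(nz + 1)]) / 2

  lab <- array(LAB_FLUID, dim = c(nx, ny, nz))
  col_starts <- if (array$n_cols > 0L) x_first + (seq_len(array$n_cols) - 1L) * pitch else numeric(0)
  in_col <- rep(FALSE, nx)
  for (x0c in col_starts)
    in_col <- in_col | (xc > x0c & xc < x0c + ms$footprint_x)
  # rows straddle y = 0: band |y| in [offset, offset + footprint_y]
  in_row <- abs(yc) > array$lateral_offset &
    abs(yc) < array$lateral_offset + ms$footprint_y
  if (array$n_rows == 0L) in_row[] <- FALSE
  if (array$n_rows == 1L) in_row <- in_row & yc > 0 # single row on +y side
  in_z <- zc < ms$height
  porous <- outer(in_col, in_row) > 0 # nx x ny logical mask
  for (k in which(in_z)) lab[, , k][porous] <- LAB_POROUS

  # flat cell strip: floor area lateral to the array band
  strip_edge <- array$lateral_offset + ms$footprint_y
  flat_floor <- matrix(rep(abs(yc) > strip_edge, each = nx), nx, ny)
  if (array$n_cols == 0L) flat_floor[] <- TRUE

  bc <- list(xlo = "inlet", xhi = "outlet",
             ylo = if (chamber$half_model) "symmetry" else "wall",
             yhi = "wall", zlo = "wall", zhi = "wall")

  g <- list(nx = nx, ny = ny, nz = nz, dx = dx, dy = dy, dz = dz,
            xf = xf, yf = yf, zf = zf, xc = xc, yc = yc, zc = zc,
            lab = lab, bc = bc, periodic = c(x = FALSE, y = FALSE, z = FALSE),
            flat_floor = flat_floor, chamber = chamber, array = array,
            resolution = resolution, col_starts = col_starts, pitch = pitch,
            meta = list())
  class(g) <- "labeled_grid"

  # volume closure check: labelled volume must match the chamber volume
  vol <- sum(outer(dx, dy) %o% dz)
  vol_target <- L * Wsim * H
  if (abs(vol - vol_target) / vol_target > 0.005)
    stop("grid volume differs from chamber volume by more than 0.5%")
  g
}

#' @export
print.labeled_grid <- function(x, ...) {
  cat("labeled_grid:", x$nx, "x", x$ny, "x", x$nz, "cells\n")
  cat("  extent [m]:", max(x$xf), "x", max(x$yf) - min(x$yf), "x", max(x$zf), "\n")
  tab <- table(factor(x$lab, levels = 1:3,
                      labels = c("FLUID", "POROUS_ARRAY", "SOLID")))
  print(tab)
  invisible(x)
}

#' Cell volumes of a labelled grid
#' @param grid a `labeled_grid`.
#' @return 3D array of voxel volumes (m^3).
#' @export
cell_volumes <- function(grid) {
  outer(grid$dx, grid$dy) %o% grid$dz
}

#' Total volume of a region
#' @param grid a `labeled_grid`.
#' @param label one of `"FLUID"`, `"POROUS_ARRAY"`, `"SOLID"`.
#' @return volume in m^3.
#' @export
region_volume <- function(grid, label = "POROUS_ARRAY") {
  code <- switch(label, FLUID = LAB_FLUID, POROUS_ARRAY = LAB_POROUS,
                 SOLID = LAB_SOLID, stop("unknown region label"))
  sum(cell_volumes(grid)[grid$lab == code])
}

# ---- beam lattice metrics ------------------------------------------------

# beams are elliptical cylinders along the pore edges; horizontal beams have
# in-plane semi-axis beam_lateral/2 and vertical semi-axis beam_axial/2
# (two-photon printing elongates the voxel along the optical z axis);
# vertical posts have a circular cross-section of diameter beam_lateral.

#' Solid fraction, porosity and specific surface of the beam lattice
#'
#' Analytic estimate from the beam layout of one pore cell
#' (`pore_x x pore_y x pore_z`): one x-beam and one y-beam per horizontal
#' level plus one vertical post, with elliptical cross-sections. Junction
#' overlaps are neglected (the solid fraction is below 1%, so the error is
#' second order; see the voxelisation cross-check in the test-suite).
#'
#' @param ms a [microstructure_spec()].
#' @return list with `solid_fraction`, `porosity`, `specific_surface` (1/m)
#'   and the effective (equal-area) beam radius `r_eff` (m).
#' @export
compute_lattice_metrics <- function(ms) {
  stopifnot(inherits(ms, "microstructure_spec"))
  if (ms$beam_lateral >= min(ms$pore_x, ms$pore_y) ||
      ms$beam_axial >= 2 * ms$pore_z)
    stop("beams thicker than pores: lattice metrics undefined")
  a <- ms$beam_axial / 2   # vertical semi-axis of horizontal beams
  b <- ms$beam_lateral / 2 # in-plane semi-axis
  A_h <- pi * a * b                      # horizontal beam cross-section
  A_v <- pi * b^2                        # vertical post cross-section
  V_cell <- ms$pore_x * ms$pore_y * ms$pore_z
  # per pore cell: one beam along x (length pore_x), one along y, one post
  V_solid <- A_h * (ms$pore_x + ms$pore_y) + A_v * ms$pore_z
  sf <- V_solid / V_cell
  # Ramanujan perimeter of the elliptical cross-section
  per_h <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  per_v <- 2 * pi * b
  S_solid <- per_h * (ms$pore_x + ms$pore_y) + per_v * ms$pore_z
  list(solid_fraction = sf, porosity = 1 - sf,
       specific_surface = S_solid / V_cell,
       r_eff = sqrt(a * b))
}

# ---- probes --------------------------------------------------------------

#' Probe locations for velocity and wall shear stress extraction
#'
#' Velocity probes at the centres of pores 1, 5 and 10 (counted along +x from
#' the inlet-facing edge) of microstructures 1, 4 and 8, at 10, 20 and 40 um
#' above the chamber floor; shear probes reference the beam segments of each
#' probed pore's outlet-side face at the same heights.
#'
#' @param grid a `labeled_grid` built with a scaffold array.
#' @param microstructures,pores,heights probe indices; defaults follow the
#'   probing protocol of the device study (3 x 3 x 3 = 27 points).
#' @return object of class `probe_set`: a data frame of velocity probe points
#'   plus the array placement metadata needed for shear sampling.
#' @export
build_probe_set <- function(grid,
                            microstructures = c(1L, 4L, 8L),
                            pores = c(1L, 5L, 10L),
                            heights = c(10e-6, 20e-6, 40e-6)) {
  stopifnot(inherits(grid, "labeled_grid"))
  arr <- grid$array; ms <- arr$microstructure
  if (arr$n_cols < max(microstructures))
    stop("probe microstructure index outside the array (n_cols = ", arr$n_cols, ")")
  if (ms$n_pores_x < max(pores))
    stop("probe pore index outside the microstructure (", ms$n_pores_x, " pores)")
  if (max(heights) > grid$chamber$height_z)
    stop("probe height outside the chamber")
  y_center <- arr$lateral_offset + ms$footprint_y / 2
  rows <- expand.grid(height = heights, pore = pores,
                      microstructure = microstructures)
  rows <- rows[, c("microstructure", "pore", "height")]
  rows$x <- grid$col_starts[rows$microstructure] + (rows$pore - 0.5) * ms$pore_x
  rows$y <- y_center
  rows$z <- rows$height
  # downstream (outlet-side) pore face position, for shear sampling
  rows$x_face <- grid$col_starts[rows$microstructure] + rows$pore * ms$pore_x
  out <- list(points = rows, y_center = y_center, microstructure = ms)
  class(out) <- "probe_set"
  out
}

# ---- resolved unit cell --------------------------------------------------

#' Resolved pore-scale unit cell geometry
#'
#' One pore column (default 50 x 50 um in plan) spanning the scaffold height
#' plus a free-fluid clearance above, with the framing beams voxelised as
#' solid cells. The cell is periodic in both horizontal directions (the pore
#' lattice repeats every 50 um), the floor is a no-slip wall and the top of
#' the clearance is a free-slip boundary standing in for the fluid above.
#' Beams thinner than one voxel are inflated to a single voxel layer (with a
#' warning recorded in the metadata), the standard price of voxelising 1 um
#' beams on a micron-scale grid.
#'
#' @param ms a [microstructure_spec()].
#' @param spacing voxel size (m), default 2.5 um.
#' @param clearance free-fluid height above the scaffold (m), default 40 um.
#' @param include_beams set `FALSE` for the beam-free (empty duct) control
#'   cell used in verification tests.
#' @return a `labeled_grid` (periodic in x and y) with `SOLID` beam voxels
#'   and beam sample masks in `meta`.
#' @export
build_unit_cell_geometry <- function(ms = microstructure_spec(),
                                     spacing = 2.5e-6, clearance = 40e-6,
                                     include_beams = TRUE) {
  stopifnot(inherits(ms, "microstructure_spec"))
  spacing <- parse_quantity(spacing); clearance <- parse_quantity(clearance)
  if (spacing > 2.5e-6 + 1e-12)
    stop("unit-cell spacing must be <= 2.5 um to resolve the pore")
  Lx <- ms$pore_x; Ly <- ms$pore_y; Lz <- ms$height + clearance
  nx <- as.integer(round(Lx / spacing)); ny <- as.integer(round(Ly / spacing))
  nz <- as.integer(round(Lz / spacing))
  dx <- rep(Lx / nx, nx); dy <- rep(Ly / ny, ny); dz <- rep(Lz / nz, nz)
  xf <- c(0, cumsum(dx)); yf <- c(0, cumsum(dy)); zf <- c(0, cumsum(dz))
  xc <- (xf[-1] + xf[-(nx + 1)]) / 2
  yc <- (yf[-1] + yf[-(ny + 1)]) / 2
  zc <- (zf[-1] + zf[-(nz + 1)]) / 2

  inflated <- ms$beam_lateral < spacing
  half_h <- max(ms$beam_axial / 2, spacing / 2) # vertical half-extent
  lab <- array(LAB_FLUID, dim = c(nx, ny, nz))
  levels_z <- seq(0, ms$height, by = ms$pore_z) # framing beam heights

  # beams straddle the periodic cell edges at x = 0 and y = 0; thinner than a
  # voxel, they occupy the single adjacent voxel layer
  edge_mask <- function(c1, L) {
    if (inflated) return(seq_along(c1) == 1L)
    d <- abs(((c1 + L / 2) %% L) - L / 2)
    sel <- d < ms$beam_lateral / 2
    if (!any(sel)) sel[1] <- TRUE
    sel
  }
  edge_x <- edge_mask(xc, Lx)
  edge_y <- edge_mask(yc, Ly)
  beams <- list()
  for (zl in levels_z) {
    in_z <- abs(zc - zl) < half_h
    if (!any(in_z)) in_z <- rank(abs(zc - zl), ties.method = "first") == 1L
    if (include_beams) {
      for (k in which(in_z)) {
        lab[, edge_y, k] <- LAB_SOLID # beam along x at y = 0 edge
        lab[edge_x, , k] <- LAB_SOLID # beam along y at x = 0 edge
      }
    }
    beams[[sprintf("h_%g", zl * 1e6)]] <- list(level = zl, k = which(in_z))
  }
  # vertical posts at the pore corners (x = 0, y = 0 edge intersection)
  if (include_beams) {
    post_z <- zc < ms$height
    for (k in which(post_z)) lab[edge_x, edge_y, k] <- LAB_SOLID
  }

  g <- list(nx = nx, ny = ny, nz = nz, dx = dx, dy = dy, dz = dz,
            xf = xf, yf = yf, zf = zf, xc = xc, yc = yc, zc = zc,
            lab = lab,
            bc = list(xlo = "periodic", xhi = "periodic", ylo = "periodic",
                      yhi = "periodic", zlo = "wall", zhi = "symmetry"),
            periodic = c(x = TRUE, y = TRUE, z = FALSE),
            flat_floor = matrix(FALSE, nx, ny),
            ms = ms, spacing = spacing, clearance = clearance,
            meta = list(beams_inflated = inflated, beam_levels = levels_z,
                        edge_x = edge_x, edge_y = edge_y, beams = beams))
  class(g) <- c("unit_cell_grid", "labeled_grid")
  if (inflated && include_beams)
    warning("beam_lateral (", ms$beam_lateral * 1e6,
            " um) below voxel size; beams inflated to one voxel layer")
  g
}

#' Fully periodic lattice cell for Darcy permeability measurement
#'
#' One pore of the beam lattice (50 x 50 x 20 um) with periodic x/y and
#' symmetry z boundaries: the representative volume element of the scaffold
#' interior, away from floor and free-surface effects. Used by
#' [measure_lattice_permeability()].
#'
#' @param ms a [microstructure_spec()].
#' @param spacing voxel size (m).
#' @return a `unit_cell_grid` spanning one pore layer.
#' @export
build_lattice_cell <- function(ms = microstructure_spec(),
                               spacing = 1.25e-6) {
  stopifnot(inherits(ms, "microstructure_spec"))
  spacing <- parse_quantity(spacing)
  Lx <- ms$pore_x; Ly <- ms$pore_y; Lz <- ms$pore_z
  nx <- as.integer(round(Lx / spacing)); ny <- as.integer(round(Ly / spacing))
  nz <- as.integer(round(Lz / spacing))
  dx <- rep(Lx / nx, nx); dy <- rep(Ly / ny, ny); dz <- rep(Lz / nz, nz)
  xf <- c(0, cumsum(dx)); yf <- c(0, cumsum(dy)); zf <- c(0, cumsum(dz))
  xc <- (xf[-1] + xf[-(nx + 1)]) / 2
  yc <- (yf[-1] + yf[-(ny + 1)]) / 2
  zc <- (zf[-1] + zf[-(nz + 1)]) / 2
  inflated <- ms$beam_lateral < spacing
  half_h <- max(ms$beam_axial / 2, spacing / 2)
  edge_mask <- function(c1, L) {
    if (inflated) return(seq_along(c1) == 1L)
    d <- abs(((c1 + L / 2) %% L) - L / 2)
    sel <- d < ms$beam_lateral / 2
    if (!any(sel)) sel[1] <- TRUE
    sel
  }
  edge_x <- edge_mask(xc, Lx); edge_y <- edge_mask(yc, Ly)
  lab <- array(LAB_FLUID, dim = c(nx, ny, nz))
  # framing beams straddle the symmetry planes at z = 0 and z = pore_z
  in_z <- zc < half_h | zc > Lz - half_h
  for (k in which(in_z)) {
    lab[, edge_y, k] <- LAB_SOLID
    lab[edge_x, , k] <- LAB_SOLID
  }
  for (k in seq_len(nz)) lab[edge_x, edge_y, k] <- LAB_SOLID # posts
  g <- list(nx = nx, ny = ny, nz = nz, dx = dx, dy = dy, dz = dz,
            xf = xf, yf = yf, zf = zf, xc = xc, yc = yc, zc = zc,
            lab = lab,
            bc = list(xlo = "periodic", xhi = "periodic", ylo = "periodic",
                      yhi = "periodic", zlo = "symmetry", zhi = "symmetry"),
            periodic = c(x = TRUE, y = TRUE, z = FALSE),
            flat_floor = matrix(FALSE, nx, ny),
            ms = ms, spacing = spacing, clearance = 0,
            meta = list(beams_inflated = inflated,
                        edge_x = edge_x, edge_y = edge_y))
  class(g) <- c("unit_cell_grid", "labeled_grid")
  g
}

# independent voxelisation of the beam lattice of a single pore cell, used as
# an oracle for compute_lattice_metrics and build_unit_cell_geometry
voxelize_pore_lattice <- function(ms, spacing = 0.25e-6) {
  nx <- as.integer(round(ms$pore_x / spacing))
  ny <- as.integer(round(ms$pore_y / spacing))
  nz <- as.integer(round(ms$pore_z / spacing))
  xc <- (seq_len(nx) - 0.5) * spacing
  yc <- (seq_len(ny) - 0.5) * spacing
  zc <- (seq_len(nz) - 0.5) * spacing
  a <- ms$beam_axial / 2; b <- ms$beam_lateral / 2
  wrap <- function(d, L) ((d + L / 2) %% L) - L / 2
  dxe <- wrap(xc, ms$pore_x); dye <- wrap(yc, ms$pore_y)
  dzl <- wrap(zc, ms$pore_z) # framing levels at z = 0 (mod pore_z)
  # x-beam at (y=0, z=level): ellipse in (y, z)
  in_xbeam <- outer(dye^2 / b^2, dzl^2 / a^2, `+`) < 1   # ny x nz
  in_ybeam <- outer(dxe^2 / b^2, dzl^2 / a^2, `+`) < 1   # nx x nz
  in_post <- outer(dxe^2, dye^2, `+`) < b^2              # nx x ny
  solid <- array(FALSE, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    solid[, , k] <- rep(in_xbeam[, k], each = nx) |
      matrix(in_ybeam[, k], nx, ny) | in_post
  }
  mean(solid)
}
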