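# Synthetic inputs: the reference device configuration, manufactured
# transport problems with known closed-form solutions (solver verification),
# and randomized-but-valid configurations for property tests. Everything is
# generated in memory; no external data are required.

#' Reference device configuration
#'
#' The complete configuration of the millifluidic chamber study: 6 x 3 x
#' 0.5 mm chamber with a 0.76 mm inlet, a 2 x 8 array of 500 x 500 x 40 um
#' microstructures with 50 x 50 x 20 um pores and 4.9 x 1.0 um beams, medium
#' approximated as water at 37 C, oxygen kinetics D = 2e-9 m^2/s, C0 = 0.2
#' mol/m^3, Vmax = 4e-17 mol/s, Km = 5.5e-4 mol/m^3, 50,000 cells split
#' 32,000 (array) / 18,000 (flat strip), candidate flow rates 1, 3, 5 and
#' 10 uL/min, physiological windows 0.1-5 um/s and 0.1-10 mPa, hypoxia and
#' normoxia thresholds 1 % and 13 % atmospheric O2.
#'
#' @return nested configuration list (class `perfusim_config`), all values
#'   SI.
#' @export
default_config <- function() {
  cfg <- list(
    chamber = list(length_x = 6e-3, width_y = 3e-3, height_z = 0.5e-3,
                   inlet_diameter = 0.76e-3, inlet_height = 3e-3,
                   half_model = TRUE),
    microstructure = list(footprint_x = 500e-6, footprint_y = 500e-6,
                          height = 40e-6, pore_x = 50e-6, pore_y = 50e-6,
                          pore_z = 20e-6, beam_axial = 4.9e-6,
                          beam_lateral = 1.0e-6),
    array = list(n_rows = 2L, n_cols = 8L, pitch_x = 750e-6,
                 lateral_offset = 0),
    grid = list(dx = 125e-6, dy = 125e-6, dz_fine = 5e-6,
                fine_height = 50e-6, growth = 1.6),
    fluid = list(mu = 6.9e-4, rho = 993, temperature = 37),
    oxygen = list(D = 2e-9, C0 = 0.2, Vmax = 4e-17, Km = 5.5e-4),
    loading = list(n_total = 50000, n_array = 32000, n_flat = 18000),
    conversion = list(percent_atm_inlet = 18.6, hypoxia_percent = 1,
                      normoxia_percent = 13),
    ranges = list(velocity_min = 0.1e-6, velocity_max = 5e-6,
                  velocity_max_broad = 10e-6,
                  wss_min = 0.1e-3, wss_max = 10e-3),
    sweep = list(rates_uL_min = c(1, 3, 5, 10), rule = "largest"),
    unit_cell = list(spacing = 2.5e-6, clearance = 40e-6)
  )
  class(cfg) <- "perfusim_config"
  cfg
}

#' Instantiate domain objects from a configuration
#'
#' Each helper builds the corresponding spec/parameter object from a
#' configuration list (see [default_config()], [load_config()]).
#'
#' @param cfg a `perfusim_config`.
#' @return the corresponding domain object.
#' @name config-accessors
NULL

#' @rdname config-accessors
#' @export
config_chamber <- function(cfg) do.call(chamber_spec, cfg$chamber)
#' @rdname config-accessors
#' @export
config_microstructure <- function(cfg) do.call(microstructure_spec,
                                               cfg$microstructure)
#' @rdname config-accessors
#' @export
config_array <- function(cfg) {
  scaffold_array_spec(n_rows = cfg$array$n_rows, n_cols = cfg$array$n_cols,
                      pitch_x = cfg$array$pitch_x,
                      lateral_offset = cfg$array$lateral_offset,
                      microstructure = config_microstructure(cfg))
}
#' @rdname config-accessors
#' @export
config_grid_control <- function(cfg) do.call(grid_control, cfg$grid)
#' @rdname config-accessors
#' @export
config_fluid <- function(cfg) do.call(fluid_properties, cfg$fluid)
#' @rdname config-accessors
#' @export
config_oxygen <- function(cfg) do.call(oxygen_params, cfg$oxygen)
#' @rdname config-accessors
#' @export
config_loading <- function(cfg) do.call(cell_loading, cfg$loading)
#' @rdname config-accessors
#' @export
config_conversion <- function(cfg) {
  unit_conversion(C0 = cfg$oxygen$C0,
                  percent_atm_inlet = cfg$conversion$percent_atm_inlet,
                  hypoxia_percent = cfg$conversion$hypoxia_percent,
                  normoxia_percent = cfg$conversion$normoxia_percent)
}
#' @rdname config-accessors
#' @export
config_ranges <- function(cfg) {
  physiological_ranges(
    velocity_window = c(cfg$ranges$velocity_min, cfg$ranges$velocity_max),
    velocity_window_broad = c(cfg$ranges$velocity_min,
                              cfg$ranges$velocity_max_broad),
    wss_window = c(cfg$ranges$wss_min, cfg$ranges$wss_max),
    hypoxia_percent = cfg$conversion$hypoxia_percent,
    normoxia_percent = cfg$conversion$normoxia_percent)
}

# flat (array-free) grid used by the verification problems
mms_grid <- function(nx = 32, ny = 4, nz = 8, length_x = 6e-3,
                     width_y = 3e-3, height_z = 0.5e-3, half_model = FALSE) {
  ch <- chamber_spec(length_x = length_x, width_y = width_y,
                     height_z = height_z, half_model = half_model)
  W <- if (half_model) width_y / 2 else width_y
  res <- grid_control(dx = length_x / nx, dy = W / ny,
                      dz_fine = height_z / nz, fine_height = height_z,
                      growth = 1)
  build_chamber_grid(ch, scaffold_array_spec(n_rows = 0L, n_cols = 0L),
                     res)
}

#' Synthetic uniform (plug) flow on a grid
#'
#' A `flow_solution` with constant streamwise velocity, used by the
#' manufactured-solution problems and the plug-flow equivalence checks.
#'
#' @param grid a `labeled_grid`.
#' @param ux streamwise velocity (m/s).
#' @param fluid a [fluid_properties()].
#' @return a `flow_solution`.
#' @export
uniform_flow <- function(grid, ux, fluid = fluid_properties()) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  sol <- list(grid = grid,
              u = array(ux, c(nx + 1, ny, nz)),
              v = array(0, c(nx, ny + 1, nz)),
              w = array(0, c(nx, ny, nz + 1)),
              p = array(0, c(nx, ny, nz)),
              Q = ux * sum(outer(grid$dy, grid$dz)), Q_sim = NA_real_,
              fluid = fluid, kappa = Inf, Re = NA_real_,
              residuals = list(linear_rel = 0, div_max_rel = 0))
  class(sol) <- "flow_solution"
  sol
}

#' Manufactured Stokes problem (plane Poiseuille)
#'
#' A flat chamber carrying flow `Q`: the exact solution is the plane
#' Poiseuille / rectangular-duct field, with zero body force. Used to verify
#' the staggered solver and the shear extraction against closed forms.
#'
#' @param Q flow rate (m^3/s or unit string).
#' @param nx,ny,nz grid resolution.
#' @param length_x,width_y,height_z chamber dimensions (m).
#' @param fluid a [fluid_properties()].
#' @return list with the `grid`, the boundary condition, exact velocity
#'   and floor-shear functions, and the fluid.
#' @export
make_manufactured_stokes <- function(Q = "5 uL/min", nx = 24, ny = 6,
                                     nz = 10, length_x = 6e-3,
                                     width_y = 3e-3, height_z = 0.5e-3,
                                     fluid = fluid_properties()) {
  Q <- parse_quantity(Q, "Q")
  grid <- mms_grid(nx, ny, nz, length_x, width_y, height_z,
                   half_model = FALSE)
  list(grid = grid, bc = flow_bc(Q), fluid = fluid,
       exact_u = function(y, z) analytic_rect_duct(Q, width_y, height_z,
                                                   fluid, y = y, z = z),
       exact_floor_shear = function(y) {
         d <- analytic_rect_duct(Q, width_y, height_z, fluid, y = y,
                                 z = rep(0, length(y)), derivative = TRUE)
         fluid$mu * d$dudz
       },
       tau_plane = analytic_plane_poiseuille(Q, width_y, height_z,
                                             fluid)$tau_floor)
}

#' Manufactured advection-diffusion problem
#'
#' Uniform plug flow at Peclet number `Pe = u L / D` with the smooth exact
#' field `C(x) = C0 (0.5 + 0.4 cos(pi x / L))`, compatible with the
#' solver's inlet-Dirichlet / outflow boundary pair (`dC/dx = 0` at the
#' outlet). The back-computed source makes the closed form an exact steady
#' solution; under grid refinement the upwind scheme must converge to it at
#' first order (second order when diffusion dominates).
#'
#' @param Pe Peclet number of the plug flow.
#' @param length_x,width_y,height_z domain dimensions (m).
#' @param D diffusivity (m^2/s).
#' @param C0_base amplitude scale (mol/m^3).
#' @return list with `exact(x)`, `source(x)`, `params`, `u`, and
#'   `make(nx, ny, nz)` returning grid + flow + source array ready for
#'   [solve_oxygen()].
#' @export
make_manufactured_adr <- function(Pe = 10, length_x = 6e-3, width_y = 3e-3,
                                  height_z = 0.5e-3, D = 2e-9,
                                  C0_base = 0.2) {
  L <- length_x
  u0 <- Pe * D / L
  exact <- function(x) C0_base * (0.5 + 0.4 * cos(pi * x / L))
  source_fun <- function(x) {
    -0.4 * C0_base * pi / L * u0 * sin(pi * x / L) +
      0.4 * C0_base * D * (pi / L)^2 * cos(pi * x / L)
  }
  params <- oxygen_params(D = D, C0 = exact(0), Vmax = 1e-30, Km = 1)
  make <- function(nx, ny = 1, nz = 1) {
    grid <- mms_grid(nx, ny, nz, length_x, width_y, height_z)
    flow <- uniform_flow(grid, u0)
    src <- array(rep(source_fun(grid$xc), times = ny * nz),
                 c(nx, ny, nz))
    list(grid = grid, flow = flow, source = src)
  }
  list(exact = exact, source = source_fun, params = params, u = u0,
       Pe = Pe, make = make)
}

#' Randomized valid configuration
#'
#' Bounded perturbation of the reference configuration (up to +/-20 % on
#' chamber dimensions and fluid properties, +/-50 % on kinetic parameters
#' and cell counts), validity-preserving and deterministic for a fixed
#' seed. Used by the property-test suites.
#'
#' @param seed integer seed.
#' @return a `perfusim_config`.
#' @export
random_config <- function(seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  cfg <- default_config()
  pert <- function(x, frac) x * stats::runif(1, 1 - frac, 1 + frac)
  cfg$chamber$length_x <- pert(cfg$chamber$length_x, 0.2)
  cfg$chamber$width_y <- pert(cfg$chamber$width_y, 0.2)
  cfg$chamber$height_z <- pert(cfg$chamber$height_z, 0.2)
  cfg$fluid$mu <- pert(cfg$fluid$mu, 0.2)
  cfg$fluid$rho <- pert(cfg$fluid$rho, 0.2)
  cfg$oxygen$D <- pert(cfg$oxygen$D, 0.5)
  cfg$oxygen$C0 <- pert(cfg$oxygen$C0, 0.5)
  cfg$oxygen$Vmax <- pert(cfg$oxygen$Vmax, 0.5)
  cfg$oxygen$Km <- pert(cfg$oxygen$Km, 0.5)
  n_total <- round(pert(cfg$loading$n_total, 0.5))
  frac <- stats::runif(1, 0.4, 0.8)
  cfg$loading <- list(n_total = n_total, n_array = round(frac * n_total),
                      n_flat = n_total - round(frac * n_total))
  # keep the array inside the (possibly shrunk) chamber
  cfg$array$pitch_x <- cfg$chamber$length_x / cfg$array$n_cols
  cfg$grid$dx <- cfg$chamber$length_x / 48
  cfg$grid$dy <- (cfg$chamber$width_y / 2) / 12
  cfg$grid$dz_fine <- min(5e-6, cfg$chamber$height_z / 12)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "perfusim_config"
  cfg
}
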