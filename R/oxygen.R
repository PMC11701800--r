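# Steady oxygen transport with Michaelis-Menten consumption:
#
#   div(u C) = div(D grad C) - sink(C)
#
# finite-volume, first-order upwind convection, Picard iteration on the
# saturating kinetics. Cells seeded in the scaffold array consume oxygen as
# a volumetric sink; cells on the flat floor strip as an outgoing surface
# flux. Both use the same per-cell Michaelis-Menten rate.

#' Oxygen transport parameters
#'
#' Defaults are the values used for endothelial-cell culture medium:
#' diffusivity 2e-9 m^2/s, inlet (air-equilibrated, Henry's law)
#' concentration 0.2 mol/m^3, per-cell maximum consumption 4e-17 mol/s and
#' half-saturation 5.5e-4 mol/m^3.
#'
#' @param D oxygen diffusivity in medium (m^2/s).
#' @param C0 inlet oxygen concentration (mol/m^3).
#' @param Vmax per-cell maximum consumption rate (mol/s).
#' @param Km half-saturation concentration (mol/m^3).
#' @return object of class `oxygen_params`.
#' @export
oxygen_params <- function(D = 2e-9, C0 = 0.2, Vmax = 4e-17, Km = 5.5e-4) {
  s <- list(D = parse_quantity(D, "D"), C0 = parse_quantity(C0, "C0"),
            Vmax = parse_quantity(Vmax, "Vmax"),
            Km = parse_quantity(Km, "Km"))
  if (any(unlist(s) <= 0)) stop("all oxygen parameters must be > 0")
  class(s) <- "oxygen_params"
  s
}

#' Cell loading of the chamber
#'
#' Total seeded cells split between the scaffold array (volumetric
#' distribution over the porous voxels) and the flat floor strip beside it
#' (areal distribution over the strip floor faces).
#'
#' @param n_total,n_array,n_flat cell counts; `n_array + n_flat` must equal
#'   `n_total`.
#' @return object of class `cell_loading`.
#' @export
cell_loading <- function(n_total = 50000, n_array = 32000, n_flat = 18000) {
  if (n_array < 0 || n_flat < 0) stop("cell counts must be >= 0")
  if (abs(n_array + n_flat - n_total) > 1e-9)
    stop("n_array + n_flat must equal n_total")
  structure(list(n_total = n_total, n_array = n_array, n_flat = n_flat),
            class = "cell_loading")
}

#' Michaelis-Menten per-cell consumption rate
#'
#' `rate = Vmax * C / (Km + C)`: saturating, monotone, half of `Vmax` at
#' `C = Km`.
#'
#' @param C oxygen concentration (mol/m^3, vectorised).
#' @param params an [oxygen_params()].
#' @return consumption rate per cell (mol/s).
#' @export
michaelis_menten_rate <- function(C, params = oxygen_params()) {
  if (any(C < 0)) stop("negative concentration passed to the kinetics")
  params$Vmax * C / (params$Km + C)
}

#' Henry's-law conversion between concentration and % atmospheric oxygen
#'
#' Linear through the origin: the inlet concentration `C0` is anchored to
#' `percent_atm_inlet` (18.6 % of atmospheric oxygen partial pressure for
#' air-equilibrated medium at 37 C), giving `percent = k * C` with
#' `k = percent_atm_inlet / C0`. Carries the dermal hypoxia (1 %) and
#' normoxia (13 %) reference levels.
#'
#' @param C0 anchor concentration (mol/m^3).
#' @param percent_atm_inlet percent atmospheric O2 at the anchor.
#' @param hypoxia_percent,normoxia_percent physiological thresholds (%).
#' @return object of class `unit_conversion`.
#' @export
unit_conversion <- function(C0 = 0.2, percent_atm_inlet = 18.6,
                            hypoxia_percent = 1, normoxia_percent = 13) {
  if (C0 <= 0 || percent_atm_inlet <= 0) stop("conversion anchor must be > 0")
  structure(list(C0 = C0, percent_atm_inlet = percent_atm_inlet,
                 k = percent_atm_inlet / C0,
                 hypoxia_percent = hypoxia_percent,
                 normoxia_percent = normoxia_percent),
            class = "unit_conversion")
}

#' Concentration to % atmospheric oxygen
#' @param C concentration (mol/m^3, vectorised).
#' @param conv a [unit_conversion()].
#' @return percent atmospheric O2.
#' @export
conc_to_atm_percent <- function(C, conv = unit_conversion()) conv$k * C

#' Volumetric and surface oxygen sink densities
#'
#' Distributes `n_array` cells uniformly over the porous (scaffold) voxels as
#' a volumetric sink density and `n_flat` cells uniformly over the flat strip
#' floor as an areal flux density. Densities are computed from full-chamber
#' counts and region measures, so they are identical in half- and full-model
#' grids.
#'
#' @param grid a `labeled_grid`.
#' @param loading a [cell_loading()].
#' @param params an [oxygen_params()].
#' @return list with `rho_vol` (cells/m^3), `sigma_area` (cells/m^2), the
#'   corresponding masks, and `capacity` (= `n_total * Vmax`, mol/s), the
#'   zeroth-order total consumption.
#' @export
assemble_sink_field <- function(grid, loading = cell_loading(),
                                params = oxygen_params()) {
  half <- if (isTRUE(grid$chamber$half_model)) 2 else 1
  V_array <- region_volume(grid, "POROUS_ARRAY") * half
  A_strip <- sum((outer(grid$dx, grid$dy))[grid$flat_floor]) * half
  if (loading$n_array > 0 && V_array <= 0)
    stop("array cells specified but the porous region has zero volume")
  if (loading$n_flat > 0 && A_strip <= 0)
    stop("flat-strip cells specified but the strip has zero area")
  list(rho_vol = if (V_array > 0) loading$n_array / V_array else 0,
       sigma_area = if (A_strip > 0) loading$n_flat / A_strip else 0,
       mask_vol = grid$lab == LAB_POROUS,
       mask_floor = grid$flat_floor,
       V_array = V_array, A_strip = A_strip,
       capacity = loading$n_total * params$Vmax)
}

#' Solve steady oxygen advection-diffusion-reaction
#'
#' Finite-volume, first-order upwind convection, implicit diffusion,
#' Michaelis-Menten sinks linearised by Picard iteration
#' (`rate = Vmax C / (Km + C_old)`), which keeps the discrete operator an
#' M-matrix and the solution bounded in `[0, C0]`. Inlet: Dirichlet `C0`;
#' outlet: advective outflow (zero diffusive flux); walls and symmetry: zero
#' flux.
#'
#' @param grid a `labeled_grid`.
#' @param flow a `flow_solution` on the same grid.
#' @param params an [oxygen_params()].
#' @param loading a [cell_loading()]; use `cell_loading(0, 0, 0)` for a
#'   tracer-only solve.
#' @param source optional volumetric source array (mol/m^3/s, cell-centred),
#'   used by the manufactured-solution verification problems.
#' @param tol Picard relative-update tolerance.
#' @param max_iter Picard iteration cap.
#' @return object of class `concentration_field` with the cell-centred `C`
#'   (mol/m^3), iteration metadata and a conservation report.
#' @export
solve_oxygen <- function(grid, flow, params = oxygen_params(),
                         loading = cell_loading(), source = NULL,
                         tol = 1e-8, max_iter = 50L) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  if (any(grid$periodic)) stop("oxygen solver expects a non-periodic grid")
  solid <- grid$lab == LAB_SOLID
  gidc <- array(NA_integer_, c(nx, ny, nz))
  gidc[!solid] <- seq_len(sum(!solid))
  N <- sum(!solid)
  Ax <- outer(grid$dy, grid$dz); Axz <- outer(grid$dx, grid$dz)
  Axy <- outer(grid$dx, grid$dy)
  Vol <- cell_volumes(grid)
  D <- params$D

  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  diag0 <- array(0, c(nx, ny, nz))
  rhs0 <- array(0, c(nx, ny, nz))

  # internal faces along x: between (i,j,k) and (i+1,j,k)
  if (nx > 1) {
    iW <- 1:(nx - 1)
    F <- sol_face_flux(flow$u[2:nx, , , drop = FALSE],
                       array(rep(Ax, each = nx - 1), c(nx - 1, ny, nz)))
    dWE <- (grid$dx[iW] + grid$dx[iW + 1]) / 2
    Dd <- D * array(rep(Ax, each = nx - 1), c(nx - 1, ny, nz)) /
      array(dWE, c(nx - 1, ny, nz))
    P <- gidc[iW, , , drop = FALSE]; Nb <- gidc[iW + 1, , , drop = FALSE]
    bothm <- !is.na(P) & !is.na(Nb)
    # row W: + (max(F,0) + Dd) C_W - (max(-F,0) + Dd) C_E
    aP_W <- pmax(F, 0) + Dd; aoff_W <- pmax(-F, 0) + Dd
    aP_E <- pmax(-F, 0) + Dd; aoff_E <- pmax(F, 0) + Dd
    diag0[iW, , ][bothm] <- diag0[iW, , , drop = FALSE][bothm] + aP_W[bothm]
    diag0[iW + 1, , ][bothm] <- diag0[iW + 1, , , drop = FALSE][bothm] + aP_E[bothm]
    ti <- c(ti, P[bothm], Nb[bothm]); tj <- c(tj, Nb[bothm], P[bothm])
    tx <- c(tx, -aoff_W[bothm], -aoff_E[bothm])
  }
  if (ny > 1) {
    jS <- 1:(ny - 1)
    Aarr <- array(0, c(nx, ny - 1, nz))
    for (k in seq_len(nz)) Aarr[, , k] <- outer(grid$dx, rep(grid$dz[k], ny - 1))
    F <- flow$v[, 2:ny, , drop = FALSE] * Aarr
    dSN <- (grid$dy[jS] + grid$dy[jS + 1]) / 2
    Dd <- D * Aarr / array(rep(dSN, each = nx), c(nx, ny - 1, nz))
    P <- gidc[, jS, , drop = FALSE]; Nb <- gidc[, jS + 1, , drop = FALSE]
    bothm <- !is.na(P) & !is.na(Nb)
    aP_S <- pmax(F, 0) + Dd; aoff_S <- pmax(-F, 0) + Dd
    aP_N <- pmax(-F, 0) + Dd; aoff_N <- pmax(F, 0) + Dd
    diag0[, jS, ][bothm] <- diag0[, jS, , drop = FALSE][bothm] + aP_S[bothm]
    diag0[, jS + 1, ][bothm] <- diag0[, jS + 1, , drop = FALSE][bothm] + aP_N[bothm]
    ti <- c(ti, P[bothm], Nb[bothm]); tj <- c(tj, Nb[bothm], P[bothm])
    tx <- c(tx, -aoff_S[bothm], -aoff_N[bothm])
  }
  if (nz > 1) {
    kB <- 1:(nz - 1)
    Aarr <- array(outer(grid$dx, grid$dy), c(nx, ny, nz - 1))
    F <- flow$w[, , 2:nz, drop = FALSE] * Aarr
    dBT <- (grid$dz[kB] + grid$dz[kB + 1]) / 2
    Dd <- D * Aarr / array(rep(dBT, each = nx * ny), c(nx, ny, nz - 1))
    P <- gidc[, , kB, drop = FALSE]; Nb <- gidc[, , kB + 1, drop = FALSE]
    bothm <- !is.na(P) & !is.na(Nb)
    aP_B <- pmax(F, 0) + Dd; aoff_B <- pmax(-F, 0) + Dd
    aP_T <- pmax(-F, 0) + Dd; aoff_T <- pmax(F, 0) + Dd
    diag0[, , kB][bothm] <- diag0[, , kB, drop = FALSE][bothm] + aP_B[bothm]
    diag0[, , kB + 1][bothm] <- diag0[, , kB + 1, drop = FALSE][bothm] + aP_T[bothm]
    ti <- c(ti, P[bothm], Nb[bothm]); tj <- c(tj, Nb[bothm], P[bothm])
    tx <- c(tx, -aoff_B[bothm], -aoff_T[bothm])
  }

  # boundaries along x: inlet (Dirichlet C0) and outlet (advective outflow)
  Fin <- flow$u[1, , ] * Ax
  Ddb <- D * Ax / (grid$dx[1] / 2)
  diag0[1, , ] <- diag0[1, , ] + Ddb + pmax(-Fin, 0)
  rhs0[1, , ] <- rhs0[1, , ] + (pmax(Fin, 0) + Ddb) * params$C0
  Fout <- flow$u[nx + 1, , ] * Ax
  diag0[nx, , ] <- diag0[nx, , ] + pmax(Fout, 0)
  # (y and z boundaries: zero flux, nothing to add)

  # manufactured source
  if (!is.null(source)) rhs0 <- rhs0 + source * Vol

  sink <- assemble_sink_field(grid, loading, params)
  Afloor <- outer(grid$dx, grid$dy)
  sink_vol_coef0 <- array(0, c(nx, ny, nz))
  sink_vol_coef0[sink$mask_vol] <- sink$rho_vol * params$Vmax *
    Vol[sink$mask_vol]
  sink_surf_coef0 <- array(0, c(nx, ny, nz))
  if (sink$sigma_area > 0) {
    s1 <- sink_surf_coef0[, , 1]
    s1[sink$mask_floor] <- sink$sigma_area * params$Vmax *
      Afloor[sink$mask_floor]
    sink_surf_coef0[, , 1] <- s1
  }
  sink_cap <- sink_vol_coef0 + sink_surf_coef0 # x Vmax-normalised capacity

  C <- array(params$C0, c(nx, ny, nz))
  iters <- 0L; upd <- Inf
  has_sink <- any(sink_cap > 0)
  repeat {
    iters <- iters + 1L
    lin <- sink_cap / (params$Km + pmax(C, 0)) # Picard-linearised sink/C
    dtot <- diag0 + lin
    A <- Matrix::sparseMatrix(i = c(ti, gidc[!solid]), j = c(tj, gidc[!solid]),
                              x = c(tx, dtot[!solid]), dims = c(N, N))
    b <- rhs0[!solid]
    Cnew_v <- as.numeric(Matrix::solve(A, b))
    Cnew <- C
    Cnew[!solid] <- Cnew_v
    upd <- max(abs(Cnew - C)) / params$C0
    C <- Cnew
    if (!has_sink || upd < tol || iters >= max_iter) break
  }
  if (upd >= tol && iters >= max_iter && has_sink)
    stop("Picard iteration did not converge: final update ", signif(upd, 3))
  if (is.null(source) && min(C) < -1e-12 * params$C0)
    stop("scheme boundedness violated: min C = ", min(C))

  # conservation report
  C1 <- C[1, , ]
  inflow <- sum(pmax(Fin, 0) * params$C0 - pmax(-Fin, 0) * C1 +
                  Ddb * (params$C0 - C1))
  outflow <- sum(pmax(Fout, 0) * C[nx, , ])
  consumption <- sum(sink_cap * C / (params$Km + pmax(C, 0)))
  out <- list(grid = grid, C = C, params = params, loading = loading,
              iterations = iters, final_update = upd,
              conservation = list(inflow = inflow, outflow = outflow,
                                  consumption = consumption,
                                  residual = inflow - outflow - consumption),
              flow_Q = flow$Q)
  class(out) <- "concentration_field"
  out
}

# helper kept trivial so the x-face flux line above reads clearly
sol_face_flux <- function(u, A) u * A

#' @export
print.concentration_field <- function(x, ...) {
  cat("concentration_field:", paste(dim(x$C), collapse = " x "),
      "cells; Picard iterations:", x$iterations, "\n")
  cat("  C range [mol/m^3]:", signif(min(x$C), 4), "-", signif(max(x$C), 4), "\n")
  cons <- x$conservation
  cat("  balance: in", signif(cons$inflow, 4), " out", signif(cons$outflow, 4),
      " consumed", signif(cons$consumption, 4), "\n")
  invisible(x)
}

#' Oxygen concentration profile along the chamber
#'
#' Interpolated `C(x)` at fixed height, either through the scaffold array
#' (row centreline) or along the flat strip beside it (strip mid-line).
#'
#' @param field a `concentration_field`.
#' @param z sampling height (m), default 10 um.
#' @param path `"through-array"` or `"flat-side"`.
#' @param n number of sampling stations (>= 200).
#' @param y optional explicit lateral position (m) overriding `path`.
#' @param conv a [unit_conversion()] used for the percent column.
#' @return data frame with `x`, `C` and `percent_atm`.
#' @export
line_profile_at_height <- function(field, z = 10e-6,
                                   path = c("through-array", "flat-side"),
                                   n = 256, y = NULL,
                                   conv = unit_conversion()) {
  path <- match.arg(path)
  g <- field$grid
  if (z < 0 || z > max(g$zf)) stop("profile height outside the domain")
  if (is.null(y)) {
    arr <- g$array; ms <- arr$microstructure
    y <- if (path == "through-array") {
      arr$lateral_offset + ms$footprint_y / 2
    } else {
      strip_edge <- arr$lateral_offset + ms$footprint_y
      (strip_edge + max(g$yf)) / 2 # mid-line of the flat strip
    }
  }
  if (y < min(g$yf) || y > max(g$yf)) stop("profile line outside the domain")
  n <- max(n, 200L)
  xs <- seq(0, max(g$xf), length.out = n)
  C <- interp_trilinear(g$xc, g$yc, g$zc, field$C, xs, rep(y, n), rep(z, n))
  data.frame(x = xs, C = C, percent_atm = conc_to_atm_percent(C, conv))
}

#' Inlet-to-outlet oxygen drop of a profile
#'
#' Percentage-point mode converts the concentration drop to percentage
#' points of atmospheric oxygen through the linear Henry's-law anchor
#' (the default reporting scale); relative mode reports
#' `100 (C_start - C_end)/C_start`.
#'
#' @param profile a [line_profile_at_height()] data frame.
#' @param conv a [unit_conversion()].
#' @param mode `"percentage-points-atm"` or `"relative"`.
#' @return dimensionless drop.
#' @export
percent_drop <- function(profile, conv = unit_conversion(),
                         mode = c("percentage-points-atm", "relative")) {
  mode <- match.arg(mode)
  if (nrow(profile) == 0) stop("empty profile")
  Cs <- profile$C[1]; Ce <- profile$C[nrow(profile)]
  if (mode == "percentage-points-atm") (Cs - Ce) * conv$k
  else 100 * (Cs - Ce) / Cs
}

#' Hypoxia / normoxia check of an oxygen field
#'
#' @param field a `concentration_field`.
#' @param conv a [unit_conversion()].
#' @param flow optional `flow_solution` for the mixed-cup outlet value.
#' @param tol tolerance (percentage points) on the normoxia band.
#' @return list with `min_percent`, `hypoxic`, `normoxic_band` and
#'   `outlet_percent`.
#' @export
hypoxia_check <- function(field, conv = unit_conversion(), flow = NULL,
                          tol = 1) {
  minp <- conc_to_atm_percent(min(field$C), conv)
  outlet_p <- if (!is.null(flow)) {
    conc_to_atm_percent(mixed_cup_outlet(field, flow), conv)
  } else {
    conc_to_atm_percent(mean(field$C[dim(field$C)[1], , ]), conv)
  }
  list(min_percent = minp,
       hypoxic = minp < conv$hypoxia_percent,
       normoxic_band = outlet_p >= conv$normoxia_percent - tol &
         outlet_p <= conv$percent_atm_inlet,
       outlet_percent = outlet_p)
}

#' Mixed-cup (flow-weighted) outlet concentration
#'
#' @param field a `concentration_field`.
#' @param flow the `flow_solution` used for the transport solve.
#' @return mixed-cup outlet concentration (mol/m^3).
#' @export
mixed_cup_outlet <- function(field, flow) {
  g <- field$grid; nx <- g$nx
  A <- outer(g$dy, g$dz)
  F <- flow$u[nx + 1, , ] * A
  sum(F * field$C[nx, , ]) / sum(F)
}

#' One-dimensional plug-flow oxygen oracle
#'
#' Well-mixed plug-flow reduction `dC/dx = -lambda(x) MM(C) / Q`, with
#' `lambda(x)` the line density of cells (cells per metre of chamber
#' length). Exact in the well-mixed limit; used as an independent oracle
#' for the 3D solver and as a fast screening path. Integrated with RK4.
#'
#' @param Q flow rate (m^3/s or unit string).
#' @param params an [oxygen_params()].
#' @param loading a [cell_loading()]; all cells contribute to the line
#'   density.
#' @param length_x chamber length (m).
#' @param n_segments number of integration steps (>= 10).
#' @param density_fun optional function `x -> cells per metre`; defaults to
#'   uniform `n_total / length_x`.
#' @return list with `C_out` and a data frame `profile` (`x`, `C`).
#' @export
plugflow_oracle <- function(Q, params = oxygen_params(),
                            loading = cell_loading(), length_x = 6e-3,
                            n_segments = 500L, density_fun = NULL) {
  Q <- parse_quantity(Q, "Q")
  if (Q <= 0) stop("plug-flow oracle requires Q > 0")
  if (n_segments < 10L) stop("n_segments must be >= 10")
  lam <- density_fun %||% function(x) rep(loading$n_total / length_x,
                                          length(x))
  h <- length_x / n_segments
  xs <- seq(0, length_x, by = h)
  C <- numeric(length(xs)); C[1] <- params$C0
  f <- function(x, C) {
    C <- max(C, 0)
    -lam(x) * michaelis_menten_rate(C, params) / Q
  }
  for (s in seq_len(n_segments)) {
    x0 <- xs[s]; C0s <- C[s]
    k1 <- f(x0, C0s)
    k2 <- f(x0 + h / 2, C0s + h * k1 / 2)
    k3 <- f(x0 + h / 2, C0s + h * k2 / 2)
    k4 <- f(x0 + h, C0s + h * k3)
    C[s + 1] <- max(C0s + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6, 0)
  }
  list(C_out = C[length(C)], profile = data.frame(x = xs, C = C))
}
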