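#' Fluid properties
#'
#' Cell culture medium is approximated as water at 37 C: dynamic viscosity
#' 6.9e-4 Pa s, density 993 kg/m^3.
#'
#' @param mu dynamic viscosity (Pa s or unit string).
#' @param rho density (kg/m^3).
#' @param temperature informational, degrees C.
#' @return object of class `fluid_properties`.
#' @export
fluid_properties <- function(mu = 6.9e-4, rho = 993, temperature = 37) {
  s <- list(mu = parse_quantity(mu, "mu"), rho = parse_quantity(rho, "rho"),
            temperature = temperature)
  if (s$mu <= 0 || s$rho <= 0) stop("mu and rho must be > 0")
  class(s) <- "fluid_properties"
  s
}

#' Plane Poiseuille flow between parallel plates
#'
#' Closed-form velocity profile and floor shear stress for pressure-driven
#' flow in a wide shallow channel (the totally flat chamber limit):
#' `u_x(z) = 6 (Q/(w h)) (z/h)(1 - z/h)` and `tau_floor = 6 mu Q / (w h^2)`.
#'
#' @param Q flow rate (m^3/s or unit string such as `"5 uL/min"`).
#' @param width,height channel cross-section (m).
#' @param fluid a [fluid_properties()].
#' @param z height(s) at which to evaluate the velocity (m).
#' @return list with `u_x` (m/s, same length as `z`) and `tau_floor` (Pa).
#' @examples
#' analytic_plane_poiseuille("5 uL/min", 3e-3, 0.5e-3, z = 10e-6)
#' @export
analytic_plane_poiseuille <- function(Q, width, height,
                                      fluid = fluid_properties(), z = 0) {
  Q <- parse_quantity(Q, "Q"); width <- parse_quantity(width)
  height <- parse_quantity(height)
  if (any(z < 0 | z > height)) stop("z outside the channel [0, height]")
  u_mean <- Q / (width * height)
  list(u_x = 6 * u_mean * (z / height) * (1 - z / height),
       tau_floor = 6 * fluid$mu * Q / (width * height^2))
}

# cosh(x)/cosh(X) without overflow, x >= 0, X >= x not required
cosh_ratio <- function(x, X) {
  exp(abs(x) - abs(X)) * (1 + exp(-2 * abs(x))) / (1 + exp(-2 * abs(X)))
}

# pressure gradient magnitude G for a rectangular duct carrying Q
rect_duct_G <- function(Q, width, height, mu, nterms = 50) {
  a <- height / 2; b <- width / 2
  i <- seq(1, 2 * nterms - 1, by = 2)
  corr <- 1 - (192 * a / (pi^5 * b)) * sum(tanh(i * pi * b / (2 * a)) / i^5)
  Q * 3 * mu / (4 * b * a^3 * corr)
}

#' Rectangular duct flow (exact Fourier-series solution)
#'
#' Fully developed laminar flow in a rectangular duct of width `width`
#' (spanwise, `|y| <= width/2`) and height `height` (`0 <= z <= height`),
#' carrying flow rate `Q`. Used as the chamber inlet profile and as the
#' independent oracle for the flat-chamber solver checks.
#'
#' @inheritParams analytic_plane_poiseuille
#' @param y,z evaluation coordinates (vectors of equal length, or one of
#'   length 1, m).
#' @param nterms number of odd Fourier terms (default 50).
#' @param derivative if `TRUE`, also return `dudz` (useful for floor shear
#'   `tau = mu * dudz` at `z = 0`).
#' @return `u_x` in m/s (list with `u_x` and `dudz` when `derivative`).
#' @export
analytic_rect_duct <- function(Q, width, height, fluid = fluid_properties(),
                               y = 0, z, nterms = 50, derivative = FALSE) {
  Q <- parse_quantity(Q, "Q"); width <- parse_quantity(width)
  height <- parse_quantity(height)
  if (nterms < 1) stop("series truncation order must be >= 1")
  if (any(abs(y) > width / 2 + 1e-15)) stop("y outside the duct")
  if (any(z < -1e-15 | z > height + 1e-15)) stop("z outside the duct")
  n <- max(length(y), length(z))
  y <- rep_len(y, n); z <- rep_len(z, n)
  a <- height / 2; b <- width / 2
  zp <- z - a
  G <- rect_duct_G(Q, width, height, fluid$mu, nterms)
  pref <- 16 * a^2 * G / (fluid$mu * pi^3)
  u <- numeric(n); dudz <- numeric(n)
  for (ii in seq_len(nterms)) {
    i <- 2 * ii - 1
    sgn <- (-1)^((i - 1) / 2)
    ycosh <- cosh_ratio(i * pi * y / (2 * a), i * pi * b / (2 * a))
    u <- u + sgn * (1 - ycosh) * cos(i * pi * zp / (2 * a)) / i^3
    if (derivative)
      dudz <- dudz - sgn * (1 - ycosh) * sin(i * pi * zp / (2 * a)) *
        (pi / (2 * a)) / i^2
  }
  u <- pref * u
  if (derivative) list(u_x = u, dudz = pref * dudz) else u
}

#' Reynolds number of the chamber flow
#'
#' `Re = rho * u_mean * height / mu` with `u_mean = Q / (width * height)`,
#' the standard check that the creeping-flow (Stokes) model is justified.
#'
#' @inheritParams analytic_plane_poiseuille
#' @return Reynolds number (dimensionless).
#' @export
reynolds_number <- function(Q, width, height, fluid = fluid_properties()) {
  Q <- parse_quantity(Q, "Q"); width <- parse_quantity(width)
  height <- parse_quantity(height)
  u_mean <- Q / (width * height)
  fluid$rho * u_mean * height / fluid$mu
}
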