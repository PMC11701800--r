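#' Unit-aware quantity parsing
#'
#' Configuration files mix millimetre-scale chamber dimensions with
#' micrometre-scale scaffold features, so lengths (and a few other physical
#' quantities) may be written either as plain SI numbers or as strings with an
#' explicit unit suffix, e.g. `"500 um"`, `"0.76 mm"`, `"5 uL/min"`.
#' Everything is stored in SI internally.
#'
#' @param x a numeric (interpreted as SI) or a string `"<value> <unit>"`.
#' @param what quantity class, used only for error messages.
#' @return numeric value in SI units.
#' @examples
#' parse_quantity("5 uL/min")   # 8.3333e-11 m^3/s
#' parse_quantity("40 um")      # 4e-05 m
#' @export
parse_quantity <- function(x, what = "quantity") {
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x) || length(x) != 1L)
    stop("cannot parse ", what, ": expected a number or a '<value> <unit>' string")
  s <- trimws(x)
  m <- regmatches(s, regexec("^([-+0-9.eE]+)\\s*(.*)$", s))[[1]]
  if (length(m) != 3L || m[2] == "")
    stop("cannot parse ", what, " from string '", x, "'")
  val <- suppressWarnings(as.numeric(m[2]))
  if (is.na(val)) stop("cannot parse numeric part of ", what, " '", x, "'")
  unit <- m[3]
  if (unit == "") return(val)
  fac <- .unit_factors[[unit]]
  if (is.null(fac))
    stop("unknown unit '", unit, "' in ", what, " '", x, "'; known units: ",
         paste(names(.unit_factors), collapse = ", "))
  val * fac
}

# multiplicative factors to SI
.unit_factors <- list(
  # length
  "m" = 1, "mm" = 1e-3, "um" = 1e-6, "μm" = 1e-6, "nm" = 1e-9,
  # area / volume
  "m2" = 1, "m3" = 1, "uL" = 1e-9, "ul" = 1e-9, "mL" = 1e-6,
  # flow rate
  "m3/s" = 1, "uL/min" = 1e-9 / 60, "ul/min" = 1e-9 / 60,
  "uL/s" = 1e-9, "mL/min" = 1e-6 / 60,
  # velocity
  "m/s" = 1, "um/s" = 1e-6, "mm/s" = 1e-3,
  # stress / pressure
  "Pa" = 1, "mPa" = 1e-3, "kPa" = 1e3,
  # viscosity
  "Pa.s" = 1, "Pa*s" = 1, "mPa.s" = 1e-3,
  # diffusivity
  "m2/s" = 1,
  # concentration
  "mol/m3" = 1, "mM" = 1, # 1 mM = 1 mol/m3
  # per-cell rate
  "mol/s" = 1,
  # density
  "kg/m3" = 1
)

# convenience SI constants used throughout
UL_PER_MIN <- 1e-9 / 60

`%||%` <- function(a, b) if (is.null(a)) b else a

# trilinear interpolation of a cell-centred field at arbitrary points.
# Coordinates outside the cell-centre lattice are clamped (constant
# extrapolation over the boundary half-cells).
interp_trilinear <- function(xc, yc, zc, field, px, py, pz) {
  n <- length(px)
  stopifnot(length(py) == n, length(pz) == n)
  locate <- function(c1, p) {
    nc <- length(c1)
    p <- pmin(pmax(p, c1[1]), c1[nc])
    i0 <- findInterval(p, c1, rightmost.closed = TRUE)
    i0 <- pmin(pmax(i0, 1L), nc - 1L)
    if (nc == 1L) return(list(i = rep(1L, length(p)), w = rep(0, length(p))))
    w <- (p - c1[i0]) / (c1[i0 + 1L] - c1[i0])
    list(i = i0, w = pmin(pmax(w, 0), 1))
  }
  if (length(xc) == 1L) { lx <- list(i = rep(1L, n), w = rep(0, n)) } else lx <- locate(xc, px)
  ly <- if (length(yc) == 1L) list(i = rep(1L, n), w = rep(0, n)) else locate(yc, py)
  lz <- if (length(zc) == 1L) list(i = rep(1L, n), w = rep(0, n)) else locate(zc, pz)
  nx <- dim(field)[1]; ny <- dim(field)[2]; nz <- dim(field)[3]
  ix1 <- lx$i; ix2 <- pmin(ix1 + 1L, nx)
  iy1 <- ly$i; iy2 <- pmin(iy1 + 1L, ny)
  iz1 <- lz$i; iz2 <- pmin(iz1 + 1L, nz)
  wx <- lx$w; wy <- ly$w; wz <- lz$w
  at <- function(i, j, k) field[cbind(i, j, k)]
  (1 - wx) * (1 - wy) * (1 - wz) * at(ix1, iy1, iz1) +
    wx * (1 - wy) * (1 - wz) * at(ix2, iy1, iz1) +
    (1 - wx) * wy * (1 - wz) * at(ix1, iy2, iz1) +
    wx * wy * (1 - wz) * at(ix2, iy2, iz1) +
    (1 - wx) * (1 - wy) * wz * at(ix1, iy1, iz2) +
    wx * (1 - wy) * wz * at(ix2, iy1, iz2) +
    (1 - wx) * wy * wz * at(ix1, iy2, iz2) +
    wx * wy * wz * at(ix2, iy2, iz2)
}
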