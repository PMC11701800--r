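# Staggered (MAC) finite-volume discretisation of creeping flow
#
#   0 = -grad p + mu lap(u)            in FLUID cells
#   0 = -grad p + mu lap(u) - (mu/k) u in POROUS_ARRAY cells (Brinkman)
#   div u = 0
#
# Velocity components live on cell faces, pressure at cell centres. Boundary
# types per domain face: inlet (Dirichlet normal profile, zero tangential),
# outlet (p = p_out, zero-gradient velocity), wall (no slip), symmetry (zero
# normal velocity, zero tangential stress), lid (moving-lid tangential
# Dirichlet), periodic (per axis). The coupled saddle-point system is solved
# by an augmented-Lagrangian Uzawa iteration around one sparse Cholesky
# factorisation of the grad-div-augmented velocity block.

wrap1 <- function(i, n) ((i - 1L) %% n) + 1L

# momentum assembly for one velocity component, in a permuted frame where the
# component is aligned with axis 1. labp/binvp have dims (n1,n2,n3); fixedp
# and gid_own have node dims (m1,n2,n3) with m1 = n1 + !per1. gid_p carries
# pressure unknown ids (NA in solid). Returns triplets and rhs entries.
mom_block <- function(labp, h1, h2, h3, bc1lo, bc1hi, bc2lo, bc2hi,
                      bc3lo, bc3hi, per1, per2, per3, mu, binvp,
                      fixedp, gid_own, gid_p, fbody1 = 0, p_out = 0,
                      fold_vals = c(lo2 = 0, hi2 = 0, lo3 = 0, hi3 = 0)) {
  n1 <- dim(labp)[1]; n2 <- dim(labp)[2]; n3 <- dim(labp)[3]
  m1 <- dim(fixedp)[1]
  dims <- c(m1, n2, n3)
  Q1 <- slice.index(array(0L, dims), 1)
  Q2 <- slice.index(array(0L, dims), 2)
  Q3 <- slice.index(array(0L, dims), 3)

  cell_lin <- function(c1, c2, c3) { # linear index into (n1,n2,n3), NA outside
    bad <- is.na(c1) | c1 < 1L | c1 > n1
    out <- c1 + (c2 - 1L) * n1 + (c3 - 1L) * n1 * n2
    out[bad] <- NA_integer_
    out
  }
  node_lin <- function(q1, q2, q3) q1 + (q2 - 1L) * m1 + (q3 - 1L) * m1 * n2

  cm <- if (per1) wrap1(Q1 - 1L, n1) else Q1 - 1L
  cp <- if (per1) Q1 else { tmp <- Q1; tmp } # cp = Q1; outside when Q1 > n1
  cmL <- cell_lin(cm, Q2, Q3)
  cpL <- cell_lin(cp, Q2, Q3)
  h1cm <- array(NA_real_, dims); h1cp <- array(NA_real_, dims)
  ok <- !is.na(cmL); h1cm[ok] <- h1[cm[ok]]
  ok <- !is.na(cpL); h1cp[ok] <- h1[cp[ok]]
  wd <- ifelse(is.na(h1cm), h1cp / 2, ifelse(is.na(h1cp), h1cm / 2,
                                             (h1cm + h1cp) / 2))
  H2 <- array(h2[Q2], dims); H3 <- array(h3[Q3], dims)
  A1 <- H2 * H3
  V <- wd * A1

  bcm <- array(NA_real_, dims); bcp <- array(NA_real_, dims)
  ok <- !is.na(cmL); bcm[ok] <- binvp[cmL[ok]]
  ok <- !is.na(cpL); bcp[ok] <- binvp[cpL[ok]]
  binv_face <- ifelse(is.na(bcm), bcp, ifelse(is.na(bcp), bcm, (bcm + bcp) / 2))
  binv_face[is.na(binv_face)] <- 0

  act <- is.na(fixedp)
  row <- gid_own
  diag_c <- binv_face * V
  rhs_i <- integer(0); rhs_x <- numeric(0)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)

  add_rhs <- function(idx, val) {
    rhs_i <<- c(rhs_i, idx); rhs_x <<- c(rhs_x, val)
  }
  # link from active nodes (mask) to neighbour nodes at (q1n,q2n,q3n)
  add_link <- function(mask, a, q1n, q2n, q3n) {
    mask <- mask & act & a > 0
    if (!any(mask)) return(invisible())
    diag_c[mask] <<- diag_c[mask] + a[mask]
    nbl <- node_lin(q1n, q2n, q3n)[mask]
    nf <- fixedp[nbl]
    r <- row[mask]; av <- a[mask]
    free <- is.na(nf)
    if (any(free)) {
      ti <<- c(ti, r[free]); tj <<- c(tj, gid_own[nbl[free]])
      tx <<- c(tx, -av[free])
    }
    fx <- !free & nf != 0
    if (any(fx)) add_rhs(r[fx], av[fx] * nf[fx])
    invisible()
  }
  add_fold <- function(mask, a) { # boundary Dirichlet value 0 folded in
    mask <- mask & act & a > 0
    diag_c[mask] <<- diag_c[mask] + a[mask]
    invisible()
  }

  # --- axis 1 (same-component) neighbours -------------------------------
  aW <- ifelse(is.na(h1cm), 0, mu * A1 / ifelse(is.na(h1cm), 1, h1cm))
  aE <- ifelse(is.na(h1cp), 0, mu * A1 / ifelse(is.na(h1cp), 1, h1cp))
  if (per1) {
    add_link(rep(TRUE, length(Q1)), aW, wrap1(Q1 - 1L, m1), Q2, Q3)
    add_link(rep(TRUE, length(Q1)), aE, wrap1(Q1 + 1L, m1), Q2, Q3)
  } else {
    add_link(Q1 > 1L, aW, pmax(Q1 - 1L, 1L), Q2, Q3)
    add_link(Q1 < m1, aE, pmin(Q1 + 1L, m1), Q2, Q3)
    # Q1 == m1 active only for outlet: do-nothing east viscous flux
  }

  # --- transverse neighbours (axis 2 and axis 3) ------------------------
  trans <- function(Qt, ht, nt, pert, bclo, bchi, Aother, dir) {
    # dir: +1 (towards hi) or -1 (towards lo)
    if (dir > 0) {
      interior <- Qt < nt
      dnb <- (ht[Qt] + ht[pmin(Qt + 1L, nt)]) / 2
      nbq <- pmin(Qt + 1L, nt)
      bnd <- Qt == nt; bctype <- bchi
    } else {
      interior <- Qt > 1L
      dnb <- (ht[Qt] + ht[pmax(Qt - 1L, 1L)]) / 2
      nbq <- pmax(Qt - 1L, 1L)
      bnd <- Qt == 1L; bctype <- bclo
    }
    a_int <- mu * Aother / dnb
    if (pert) {
      nbq_all <- wrap1(Qt + dir, nt)
      dwrap <- (ht[Qt] + ht[nbq_all]) / 2
      a_all <- mu * Aother / dwrap
      list(interior = rep(TRUE, length(Qt)), a = a_all, nbq = nbq_all,
           fold = rep(FALSE, length(Qt)), a_fold = a_all * 0)
    } else {
      fold_mask <- bnd & bctype %in% c("wall", "inlet", "lid")
      a_fold <- mu * Aother / (ht[Qt] / 2)
      list(interior = interior, a = a_int, nbq = nbq,
           fold = fold_mask, a_fold = a_fold)
    }
  }
  fold_with_value <- function(t, val) {
    add_fold(t$fold, t$a_fold)
    if (val != 0) { # tangential Dirichlet (moving lid) folded into the rhs
      m <- t$fold & act
      if (any(m)) add_rhs(row[m], t$a_fold[m] * val)
    }
  }
  A2 <- wd * H3 # area of CV faces normal to axis 2
  for (dir in c(-1, 1)) {
    t2 <- trans(Q2, h2, n2, per2, bc2lo, bc2hi, A2, dir)
    add_link(t2$interior, t2$a, Q1, t2$nbq, Q3)
    fold_with_value(t2, if (dir < 0) fold_vals["lo2"] else fold_vals["hi2"])
  }
  A3 <- wd * H2
  for (dir in c(-1, 1)) {
    t3 <- trans(Q3, h3, n3, per3, bc3lo, bc3hi, A3, dir)
    add_link(t3$interior, t3$a, Q1, Q2, t3$nbq)
    fold_with_value(t3, if (dir < 0) fold_vals["lo3"] else fold_vals["hi3"])
  }

  # --- pressure gradient ------------------------------------------------
  pcm <- array(NA_integer_, dims); pcp <- array(NA_integer_, dims)
  ok <- !is.na(cmL); pcm[ok] <- gid_p[cmL[ok]]
  ok <- !is.na(cpL); pcp[ok] <- gid_p[cpL[ok]]
  m <- act & !is.na(pcp)
  ti <- c(ti, row[m]); tj <- c(tj, pcp[m]); tx <- c(tx, A1[m])
  m <- act & !is.na(pcm)
  ti <- c(ti, row[m]); tj <- c(tj, pcm[m]); tx <- c(tx, -A1[m])
  # outside-domain pressure (outlet): fixed at p_out
  m <- act & is.na(cpL)
  if (any(m) && p_out != 0) add_rhs(row[m], -A1[m] * p_out)

  # --- body force and diagonal -----------------------------------------
  if (fbody1 != 0) add_rhs(row[act], fbody1 * V[act])
  ti <- c(ti, row[act]); tj <- c(tj, row[act]); tx <- c(tx, diag_c[act])

  list(i = ti, j = tj, x = tx, rhs_i = rhs_i, rhs_x = rhs_x)
}

# build the Dirichlet/fixed-value array for one component in its permuted
# frame; NA marks an active unknown
fixed_component <- function(labp, per1, bc1lo, bc1hi, uin = NULL) {
  n1 <- dim(labp)[1]; n2 <- dim(labp)[2]; n3 <- dim(labp)[3]
  m1 <- n1 + !per1
  fixedp <- array(NA_real_, c(m1, n2, n3))
  if (!per1) {
    fixedp[1, , ] <- switch(bc1lo,
      inlet = if (is.null(uin)) stop("inlet profile missing") else uin,
      wall = 0, symmetry = 0,
      stop("unsupported low-side normal boundary: ", bc1lo))
    fixedp[m1, , ] <- switch(bc1hi,
      outlet = NA_real_, wall = 0, symmetry = 0, lid = 0,
      stop("unsupported high-side normal boundary: ", bc1hi))
  }
  # faces touching a solid cell are no-slip
  solid <- labp == LAB_SOLID
  if (per1) {
    for (q1 in seq_len(m1)) {
      s <- solid[wrap1(q1 - 1L, n1), , ] | solid[q1, , ]
      f <- fixedp[q1, , ]; f[s] <- 0; fixedp[q1, , ] <- f
    }
  } else {
    for (q1 in seq_len(m1)) {
      s <- array(FALSE, c(n2, n3))
      if (q1 > 1L) s <- s | solid[q1 - 1L, , ]
      if (q1 <= n1) s <- s | solid[q1, , ]
      f <- fixedp[q1, , ]; f[s] <- 0; fixedp[q1, , ] <- f
    }
  }
  fixedp
}

# core driver: assemble and solve the coupled Stokes(-Brinkman) system.
# The saddle-point problem  [A -D^T; D 0] [u; p] = [f; g]  is solved by an
# augmented-Lagrangian Uzawa iteration: the velocity block
# A_aug = A + gamma D^T W D is symmetric positive definite (one CHOLMOD
# Cholesky factorisation), and the multiplier update
# p <- p - gamma W (D u - g) reduces the divergence residual by a factor
# ~ mu/gamma per iteration, so a handful of cheap triangular solves reach
# machine-level incompressibility.
solve_stokes_system <- function(g, mu, binv, uin = NULL, p_out = 0,
                                fbody = c(0, 0, 0), pin_pressure = FALSE,
                                gamma_factor = 1e4, tol = 1e-11,
                                max_uzawa = 60L, lid_ux = 0) {
  nx <- g$nx; ny <- g$ny; nz <- g$nz
  per <- g$periodic
  perms <- list(u = c(1L, 2L, 3L), v = c(2L, 1L, 3L), w = c(3L, 1L, 2L))
  inv_perms <- list(u = c(1L, 2L, 3L), v = c(2L, 1L, 3L), w = c(2L, 3L, 1L))
  hs <- list(g$dx, g$dy, g$dz)
  bcs <- list(c(g$bc$xlo, g$bc$xhi), c(g$bc$ylo, g$bc$yhi),
              c(g$bc$zlo, g$bc$zhi))

  labp <- list(); binvp <- list(); fixedp <- list()
  for (ci in 1:3) {
    nm <- names(perms)[ci]; pm <- perms[[ci]]
    labp[[nm]] <- aperm(g$lab, pm)
    binvp[[nm]] <- aperm(binv, pm)
    fixedp[[nm]] <- fixed_component(labp[[nm]], per[pm[1]],
                                    bcs[[pm[1]]][1], bcs[[pm[1]]][2],
                                    uin = if (ci == 1L) uin else NULL)
  }

  # global velocity numbering: u, v, w nodes; pressure numbered separately
  offset <- 0L; gid <- list()
  for (nm in names(perms)) {
    act <- is.na(fixedp[[nm]])
    ids <- array(NA_integer_, dim(fixedp[[nm]]))
    ids[act] <- offset + seq_len(sum(act))
    offset <- offset + sum(act)
    gid[[nm]] <- ids
  }
  Nu <- offset
  solid <- g$lab == LAB_SOLID
  gid_p <- array(NA_integer_, c(nx, ny, nz))
  gid_p[!solid] <- seq_len(sum(!solid))
  Np <- sum(!solid)

  trip_i <- list(); trip_j <- list(); trip_x <- list()
  f_mom <- numeric(Nu)
  gid_p_none <- array(NA_integer_, c(nx, ny, nz)) # pressure handled via D
  for (ci in 1:3) {
    nm <- names(perms)[ci]; pm <- perms[[ci]]
    blk <- mom_block(labp[[nm]], hs[[pm[1]]], hs[[pm[2]]], hs[[pm[3]]],
                     bcs[[pm[1]]][1], bcs[[pm[1]]][2],
                     bcs[[pm[2]]][1], bcs[[pm[2]]][2],
                     bcs[[pm[3]]][1], bcs[[pm[3]]][2],
                     per[pm[1]], per[pm[2]], per[pm[3]],
                     mu, binvp[[nm]], fixedp[[nm]], gid[[nm]],
                     aperm(gid_p_none, pm), fbody1 = fbody[ci],
                     p_out = p_out,
                     fold_vals = c(lo2 = 0, hi2 = 0, lo3 = 0,
                                   # a moving lid at z-hi drives u only;
                                   # for u the permuted axis 3 is z
                                   hi3 = if (ci == 1L) lid_ux else 0))
    trip_i[[nm]] <- blk$i; trip_j[[nm]] <- blk$j; trip_x[[nm]] <- blk$x
    if (length(blk$rhs_i))
      f_mom[blk$rhs_i] <- f_mom[blk$rhs_i] + blk$rhs_x
  }

  # continuity D u = g_cont, in the original frame
  gid_u <- aperm(gid$u, inv_perms$u); fix_u <- aperm(fixedp$u, inv_perms$u)
  gid_v <- aperm(gid$v, inv_perms$v); fix_v <- aperm(fixedp$v, inv_perms$v)
  gid_w <- aperm(gid$w, inv_perms$w); fix_w <- aperm(fixedp$w, inv_perms$w)
  Ax <- outer(rep(1, nx), outer(g$dy, g$dz)); dim(Ax) <- c(nx, ny, nz)
  Ay <- outer(g$dx, outer(rep(1, ny), g$dz)); dim(Ay) <- c(nx, ny, nz)
  Az <- outer(outer(g$dx, g$dy), rep(1, nz)); dim(Az) <- c(nx, ny, nz)
  prow <- gid_p
  g_cont <- numeric(Np)
  ci_ <- integer(0); cj_ <- integer(0); cx_ <- numeric(0)
  add_flux <- function(gidf, fixf, idx_lo, idx_hi, A) {
    # idx_lo/idx_hi: node index arrays (same dims as cells) for the low/high
    # face of each cell along the component axis
    for (side in c("lo", "hi")) {
      sgn <- if (side == "lo") -1 else 1
      nid <- if (side == "lo") idx_lo else idx_hi
      gv <- gidf[nid]; fv <- fixf[nid]
      m <- !solid & !is.na(gv)
      ci_ <<- c(ci_, prow[m]); cj_ <<- c(cj_, gv[m]); cx_ <<- c(cx_, sgn * A[m])
      mf <- !solid & is.na(gv) & !is.na(fv) & fv != 0
      if (any(mf)) g_cont[prow[mf]] <<- g_cont[prow[mf]] - sgn * A[mf] * fv[mf]
    }
  }
  I <- slice.index(array(0L, c(nx, ny, nz)), 1)
  J <- slice.index(array(0L, c(nx, ny, nz)), 2)
  K <- slice.index(array(0L, c(nx, ny, nz)), 3)
  mu_ <- dim(fix_u)[1] # nx + !per_x
  lin_u <- function(i, j, k) i + (j - 1L) * mu_ + (k - 1L) * mu_ * ny
  mv_ <- dim(fix_v)[2]
  lin_v <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * mv_
  lin_w <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  uE <- if (per["x"]) wrap1(I + 1L, nx) else I + 1L
  add_flux(gid_u, fix_u, lin_u(I, J, K), lin_u(uE, J, K), Ax)
  vN <- if (per["y"]) wrap1(J + 1L, ny) else J + 1L
  add_flux(gid_v, fix_v, lin_v(I, J, K), lin_v(I, vN, K), Ay)
  wT <- if (per["z"]) wrap1(K + 1L, nz) else K + 1L
  add_flux(gid_w, fix_w, lin_w(I, J, K), lin_w(I, J, wT), Az)

  Av <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                             x = unlist(trip_x), dims = c(Nu, Nu))
  D <- Matrix::sparseMatrix(i = ci_, j = cj_, x = cx_, dims = c(Np, Nu))
  Vc <- cell_volumes(g)
  W <- Matrix::Diagonal(x = 1 / Vc[!solid])
  # the grad-div penalty must dominate both the viscous and the Brinkman
  # drag scales for the multiplier update to converge quickly
  h_typ <- max(mean(g$dx), mean(g$dy), mean(g$dz))
  gamma <- gamma_factor * (mu + max(binv) * h_typ^2)
  A_aug <- Matrix::forceSymmetric(Av + gamma * Matrix::crossprod(
    D, W %*% D), uplo = "U")
  Ch <- Matrix::Cholesky(A_aug, LDL = FALSE, super = TRUE)
  DtWg <- gamma * as.numeric(Matrix::crossprod(D, W %*% g_cont))

  p_vec <- numeric(Np)
  flux_ref <- max(abs(g_cont))
  res_div <- Inf; prev <- Inf
  for (it in seq_len(max_uzawa)) {
    u_vec <- as.numeric(Matrix::solve(
      Ch, f_mom + as.numeric(Matrix::crossprod(D, p_vec)) + DtWg))
    r <- as.numeric(D %*% u_vec) - g_cont
    if (flux_ref <= 0) flux_ref <- max(max(abs(r)), 1e-300)
    res_div <- max(abs(r)) / flux_ref
    p_vec <- p_vec - gamma * as.numeric(W %*% r)
    # stop at tolerance or at the rounding floor (stagnation)
    if (res_div < tol || (it > 3L && res_div > 0.5 * prev)) break
    prev <- res_div
  }
  if (pin_pressure) p_vec <- p_vec - mean(p_vec)
  # momentum residual of the original (unaugmented) system
  rm_ <- as.numeric(Av %*% u_vec) - as.numeric(Matrix::crossprod(D, p_vec)) -
    f_mom
  res_mom <- sqrt(sum(rm_^2)) /
    max(sqrt(sum(f_mom^2)), sqrt(sum((Av %*% u_vec)^2)), 1e-300)
  x <- u_vec

  fill <- function(fixedp_c, gid_c, inv) {
    out <- fixedp_c
    act <- is.na(fixedp_c)
    out[act] <- x[gid_c[act]]
    aperm(out, inv)
  }
  u <- fill(fixedp$u, gid$u, inv_perms$u)
  v <- fill(fixedp$v, gid$v, inv_perms$v)
  w <- fill(fixedp$w, gid$w, inv_perms$w)
  p <- array(0, c(nx, ny, nz))
  p[!solid] <- p_vec[gid_p[!solid]]

  list(u = u, v = v, w = w, p = p, residual = res_mom,
       div_residual = res_div, uzawa_iterations = it,
       n_unknowns = Nu + Np)
}

#' Discrete divergence of a flow solution
#'
#' Net volumetric outflux of every cell (m^3/s); zero to solver tolerance in
#' all fluid and porous cells of a converged solution.
#'
#' @param sol a `flow_solution`.
#' @return 3D array of per-cell net fluxes.
#' @export
divergence <- function(sol) {
  g <- sol$grid; nx <- g$nx; ny <- g$ny; nz <- g$nz
  per <- g$periodic
  ue <- if (per["x"]) sol$u[wrap1(seq_len(nx) + 1L, nx), , , drop = FALSE] else
    sol$u[2:(nx + 1), , , drop = FALSE]
  uw <- sol$u[seq_len(nx), , , drop = FALSE]
  vn <- if (per["y"]) sol$v[, wrap1(seq_len(ny) + 1L, ny), , drop = FALSE] else
    sol$v[, 2:(ny + 1), , drop = FALSE]
  vs <- sol$v[, seq_len(ny), , drop = FALSE]
  wt <- if (per["z"]) sol$w[, , wrap1(seq_len(nz) + 1L, nz), drop = FALSE] else
    sol$w[, , 2:(nz + 1), drop = FALSE]
  wb <- sol$w[, , seq_len(nz), drop = FALSE]
  Ax <- array(rep(outer(g$dy, g$dz), each = nx), c(nx, ny, nz))
  Ay <- array(g$dx, c(nx, ny, nz)) *
    array(rep(g$dz, each = nx * ny), c(nx, ny, nz))
  Az <- array(outer(g$dx, g$dy), c(nx, ny, nz))
  (ue - uw) * Ax + (vn - vs) * Ay + (wt - wb) * Az
}

#' Permeability of the beam lattice (sparse fibre-array correlation)
#'
#' Jackson-James drag correlation for 3D random fibre arrays,
#' `kappa = 3 r^2 / (20 phi) * (-ln(phi) - 0.931)`, with `phi` the solid
#' fraction and `r` the effective (equal-area) fibre radius of the
#' elliptical beams. Valid for sparse lattices; an error is raised for
#' `phi >= 0.5`. As `phi -> 0` the permeability is capped at `kappa_max`.
#'
#' @param metrics output of [compute_lattice_metrics()].
#' @param kappa_max finite cap returned for vanishing solid fraction (m^2).
#' @return permeability `kappa` (m^2).
#' @export
estimate_permeability <- function(metrics, kappa_max = 1e-6) {
  phi <- metrics$solid_fraction
  if (phi >= 0.5) stop("fibre-array correlation invalid for solid_fraction >= 0.5")
  if (phi <= 0) return(kappa_max)
  r <- metrics$r_eff
  k <- 3 * r^2 / (20 * phi) * (-log(phi) - 0.931)
  min(max(k, 0), kappa_max)
}

#' Measured (resolved) Darcy permeability of the beam lattice
#'
#' Solves Stokes flow through the fully periodic lattice cell under a unit
#' streamwise body force and returns `kappa = mu <u> / G`, the Darcy
#' pressure-drop-per-superficial-velocity measurement. This is the
#' permeability actually exhibited by the resolved beam geometry and is
#' used to parameterise the chamber-scale Brinkman block; the analytic
#' sparse-fibre correlation [estimate_permeability()] serves as an
#' independent cross-check.
#'
#' @param ms a [microstructure_spec()].
#' @param fluid a [fluid_properties()].
#' @param spacing lattice-cell voxel size (m).
#' @return permeability (m^2).
#' @export
measure_lattice_permeability <- function(ms = microstructure_spec(),
                                         fluid = fluid_properties(),
                                         spacing = 1.25e-6) {
  cell <- build_lattice_cell(ms, spacing)
  binv <- array(0, dim(cell$lab))
  G <- 1 # Pa/m; result is independent of G by linearity
  core <- solve_stokes_system(cell, fluid$mu, binv, fbody = c(G, 0, 0),
                              pin_pressure = TRUE)
  nx <- cell$nx
  uc <- (core$u + core$u[wrap1(seq_len(nx) + 1L, nx), , , drop = FALSE]) / 2
  Vc <- cell_volumes(cell)
  usup <- sum(uc * Vc) / sum(Vc) # superficial: zeros in solid included
  fluid$mu * usup / G
}

#' Flow boundary conditions
#'
#' @param Q flow rate through the full chamber (m^3/s or unit string).
#' @param p_out outlet pressure (Pa), fixed at 0 to avoid backflow.
#' @return object of class `flow_bc`.
#' @export
flow_bc <- function(Q, p_out = 0) {
  Q <- parse_quantity(Q, "Q")
  if (Q <= 0) stop("Q must be > 0")
  if (p_out != 0) stop("outlet pressure is fixed at 0 Pa")
  structure(list(Q = Q, p_out = p_out), class = "flow_bc")
}

#' Solve chamber-scale Stokes-Brinkman flow
#'
#' Creeping flow through the labelled chamber grid. The scaffold array is a
#' Brinkman block of permeability `kappa`; the inlet imposes the fully
#' developed rectangular-duct profile scaled to `Q` (`Q/2` through the half
#' model), the outlet is at 0 Pa and walls are no slip.
#'
#' @param grid a `labeled_grid` from [build_chamber_grid()].
#' @param fluid a [fluid_properties()].
#' @param bc a [flow_bc()].
#' @param kappa Brinkman permeability of the scaffold array (m^2), e.g. from
#'   [estimate_permeability()].
#' @return object of class `flow_solution` with staggered velocities `u, v,
#'   w` (m/s), pressure `p` (Pa), solver residuals and the Reynolds number.
#' @export
solve_stokes_brinkman <- function(grid, fluid = fluid_properties(),
                                  bc = flow_bc("5 uL/min"), kappa = Inf) {
  stopifnot(inherits(grid, "labeled_grid"))
  if (!is.finite(kappa)) kappa <- 1e-6 # effectively unobstructed
  if (kappa <= 0) stop("kappa must be > 0")
  ch <- grid$chamber
  Q_sim <- if (ch$half_model) bc$Q / 2 else bc$Q
  Re <- reynolds_number(bc$Q, ch$width_y, ch$height_z, fluid)
  if (Re > 1)
    warning("Re = ", signif(Re, 3), " > 1: creeping-flow assumption strained")

  uin <- outer(grid$yc, grid$zc,
               function(y, z) analytic_rect_duct(bc$Q, ch$width_y, ch$height_z,
                                                 fluid, y = y, z = z))
  # rescale so the discrete inlet flux is exactly Q_sim
  flux <- sum(uin * outer(grid$dy, grid$dz))
  uin <- uin * Q_sim / flux

  binv <- array(0, dim(grid$lab))
  binv[grid$lab == LAB_POROUS] <- fluid$mu / kappa
  core <- solve_stokes_system(grid, fluid$mu, binv, uin = uin,
                              p_out = bc$p_out)
  sol <- list(grid = grid, u = core$u, v = core$v, w = core$w, p = core$p,
              Q = bc$Q, Q_sim = Q_sim, fluid = fluid, kappa = kappa,
              Re = Re,
              residuals = list(linear_rel = core$residual,
                               uzawa_div = core$div_residual,
                               uzawa_iterations = core$uzawa_iterations),
              n_unknowns = core$n_unknowns)
  class(sol) <- "flow_solution"
  dv <- divergence(sol)
  sol$residuals$div_max_rel <- max(abs(dv)) / bc$Q
  sol
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("flow_solution: Q =", x$Q / UL_PER_MIN, "uL/min, Re =",
      signif(x$Re, 3), "\n")
  cat("  grid:", x$grid$nx, "x", x$grid$ny, "x", x$grid$nz,
      " unknowns:", x$n_unknowns, "\n")
  cat("  residuals: linear", signif(x$residuals$linear_rel, 3),
      " max |div u|/Q", signif(x$residuals$div_max_rel, 3), "\n")
  invisible(x)
}

#' Solve the resolved pore-scale unit cell
#'
#' Stokes flow around the scaffold beams in one periodic pore column. Two
#' driving modes implement the one-way nesting from the chamber solve:
#'
#' * `"flux"`: a uniform streamwise body force (the mean pressure gradient),
#'   rescaled so the superficial velocity over the in-scaffold portion of
#'   the cell matches `superficial_velocity` (flux matching; exact by
#'   Stokes linearity).
#' * `"shear"`: a moving lid at the top of the clearance imposes the
#'   overlying-stream velocity `lid_velocity`; the in-pore flow develops as
#'   the shear-driven boundary layer penetrating the beam lattice, which is
#'   the mechanism that actually sets the near-surface velocities and beam
#'   shear stresses below a free stream.
#'
#' @param cell a `unit_cell_grid` from [build_unit_cell_geometry()].
#' @param superficial_velocity target volume-averaged streamwise velocity
#'   over the scaffold height (m/s), for `driving = "flux"`.
#' @param fluid a [fluid_properties()].
#' @param driving `"flux"` or `"shear"`.
#' @param lid_velocity lid (overlying stream) velocity (m/s), for
#'   `driving = "shear"`.
#' @return a `flow_solution` on the unit cell with `u_sup`, `u_lid` and
#'   `driving` recorded.
#' @export
solve_unit_cell_stokes <- function(cell, superficial_velocity = 1e-6,
                                   fluid = fluid_properties(),
                                   driving = c("flux", "shear"),
                                   lid_velocity = 1) {
  stopifnot(inherits(cell, "unit_cell_grid"))
  driving <- match.arg(driving)
  binv <- array(0, dim(cell$lab))
  if (driving == "flux") {
    core <- solve_stokes_system(cell, fluid$mu, binv,
                                fbody = c(1, 0, 0), pin_pressure = TRUE)
  } else {
    cell$bc$zhi <- "lid"
    core <- solve_stokes_system(cell, fluid$mu, binv, pin_pressure = TRUE,
                                lid_ux = 1)
  }
  # superficial (volume-averaged, zeros in solid) velocity over the scaffold
  nx <- cell$nx
  uc <- (core$u + core$u[wrap1(seq_len(nx) + 1L, nx), , , drop = FALSE]) / 2
  hz <- cell$ms$height
  kin <- which(cell$zc < hz)
  Vk <- outer(cell$dx, cell$dy) %o% cell$dz[kin]
  usup0 <- sum(uc[, , kin, drop = FALSE] * Vk) / sum(Vk)
  if (abs(usup0) < 1e-300) stop("unit cell carries no flow; check geometry")
  s <- if (driving == "flux") superficial_velocity / usup0 else lid_velocity
  sol <- list(grid = cell, u = core$u * s, v = core$v * s, w = core$w * s,
              p = core$p * s, Q = NA_real_, fluid = fluid,
              u_sup = if (driving == "flux") superficial_velocity else
                usup0 * s,
              u_lid = if (driving == "shear") lid_velocity else NA_real_,
              driving = driving,
              residuals = list(linear_rel = core$residual,
                               uzawa_div = core$div_residual,
                               uzawa_iterations = core$uzawa_iterations),
              n_unknowns = core$n_unknowns)
  class(sol) <- "flow_solution"
  dv <- divergence(sol)
  uref <- max(abs(sol$u))
  sol$residuals$div_max_rel <- max(abs(dv)) /
    max(uref * cell$dy[1] * cell$dz[1], 1e-300)
  sol
}

# per-probe multiplier transferring the normalised unit-cell fields to the
# local chamber conditions: the local superficial velocity (flux driving) or
# the local overlying-stream velocity at the cell-top height (shear driving)
nesting_scale <- function(sol, cell_sol, x, y) {
  g <- cell_sol$grid
  if (identical(cell_sol$driving, "shear")) {
    z_top <- max(g$zf)
    uc <- collocate_velocity(sol)$u
    gch <- sol$grid
    u_loc <- interp_trilinear(gch$xc, gch$yc, gch$zc, uc, x, y,
                              rep(z_top, length(x)))
    u_loc / cell_sol$u_lid
  } else {
    superficial_velocity(sol, x, y, depth = g$ms$height) / cell_sol$u_sup
  }
}

# cell-centred (collocated) velocity components
collocate_velocity <- function(sol) {
  g <- sol$grid; nx <- g$nx; ny <- g$ny; nz <- g$nz
  per <- g$periodic
  ue <- if (per["x"]) sol$u[wrap1(seq_len(nx) + 1L, nx), , , drop = FALSE] else
    sol$u[2:(nx + 1), , , drop = FALSE]
  vn <- if (per["y"]) sol$v[, wrap1(seq_len(ny) + 1L, ny), , drop = FALSE] else
    sol$v[, 2:(ny + 1), , drop = FALSE]
  wt <- if (per["z"]) sol$w[, , wrap1(seq_len(nz) + 1L, nz), drop = FALSE] else
    sol$w[, , 2:(nz + 1), drop = FALSE]
  list(u = (sol$u[seq_len(nx), , , drop = FALSE] + ue) / 2,
       v = (sol$v[, seq_len(ny), , drop = FALSE] + vn) / 2,
       w = (sol$w[, , seq_len(nz), drop = FALSE] + wt) / 2)
}

#' Wall shear stress field tau_zx
#'
#' `tau_zx = mu * du_x/dz`, evaluated at cell centres: one-sided into the
#' fluid at the chamber floor and above solid (beam) voxels, central
#' elsewhere. Positive for flow in +x over a floor.
#'
#' @param sol a `flow_solution`.
#' @param fluid a [fluid_properties()]; defaults to the one in `sol`.
#' @return list with the cell-centred `tau` array (Pa) and the floor map
#'   `tau_floor` (nx x ny, Pa) evaluated one-sided at z = 0.
#' @export
wall_shear_stress <- function(sol, fluid = NULL) {
  fluid <- fluid %||% sol$fluid
  g <- sol$grid; nx <- g$nx; ny <- g$ny; nz <- g$nz
  uc <- collocate_velocity(sol)$u
  solid <- g$lab == LAB_SOLID
  tau <- array(NA_real_, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    below_solid <- if (k == 1L) matrix(TRUE, nx, ny) else solid[, , k - 1L]
    if (k == 1L || any(below_solid)) {
      one_sided <- fluid$mu * uc[, , k] / (g$dz[k] / 2)
      if (k == 1L) tau[, , k] <- fluid$mu * uc[, , k] / g$zc[1]
      if (any(below_solid) && k > 1L) {
        tk <- tau[, , k]; tk[below_solid] <- one_sided[below_solid]
        tau[, , k] <- tk
      }
    }
    if (k > 1L && k < nz) {
      central <- fluid$mu * (uc[, , k + 1L] - uc[, , k - 1L]) /
        (g$zc[k + 1L] - g$zc[k - 1L])
      tk <- tau[, , k]
      fillm <- is.na(tk)
      tk[fillm] <- central[fillm]
      tau[, , k] <- tk
    } else if (k == nz && nz > 1L) {
      one <- fluid$mu * (uc[, , k] - uc[, , k - 1L]) / (g$zc[k] - g$zc[k - 1L])
      tk <- tau[, , k]; fillm <- is.na(tk); tk[fillm] <- one[fillm]
      tau[, , k] <- tk
    }
  }
  tau[solid] <- NA_real_
  tau_floor <- fluid$mu * uc[, , 1] / g$zc[1]
  tau_floor[solid[, , 1]] <- NA_real_
  structure(list(tau = tau, tau_floor = tau_floor, fluid = fluid, grid = g),
            class = "shear_stress_field")
}

#' Floor shear stress in the flat region of the chamber
#'
#' Median of the floor `tau_zx` over the flat strip beside the scaffold
#' array, excluding entry/exit margins and a side-wall margin of one chamber
#' height where the duct side walls depress the shear.
#'
#' @param sol a chamber `flow_solution`.
#' @param margin_x streamwise margin excluded at both ends (m).
#' @return median floor shear stress (Pa).
#' @export
flat_region_floor_shear <- function(sol, margin_x = NULL) {
  g <- sol$grid
  margin_x <- margin_x %||% g$chamber$height_z
  wss <- wall_shear_stress(sol)
  sel_x <- g$xc > margin_x & g$xc < max(g$xf) - margin_x
  wall_y <- max(abs(g$yf))
  sel_y_wall <- abs(g$yc) < wall_y - g$chamber$height_z
  mask <- g$flat_floor & (outer(sel_x, sel_y_wall) > 0)
  if (!any(mask)) stop("no flat-region floor cells after margins")
  stats::median(wss$tau_floor[mask], na.rm = TRUE)
}

#' Probe point velocities
#'
#' Trilinear interpolation of the collocated velocity at the probe points
#' (pore centres at 10/20/40 um). With `sampling = "unit_cell"` the pore
#' centre velocity comes from the resolved unit-cell solution, scaled by the
#' local superficial velocity from the chamber solve (near-surface sampling);
#' with `"chamber"` it is interpolated from the Brinkman-smoothed chamber
#' field.
#'
#' @param sol chamber `flow_solution`.
#' @param probes a [build_probe_set()] result.
#' @param sampling `"chamber"` or `"unit_cell"`.
#' @param cell_sol unit-cell `flow_solution` (required for
#'   `sampling = "unit_cell"`).
#' @return data frame keyed by (microstructure, pore, height_um) with `u_x`
#'   and `speed` (m/s).
#' @export
probe_velocity <- function(sol, probes, sampling = c("chamber", "unit_cell"),
                           cell_sol = NULL) {
  sampling <- match.arg(sampling)
  g <- sol$grid
  pts <- probes$points
  if (sampling == "chamber") {
    cc <- collocate_velocity(sol)
    ux <- interp_trilinear(g$xc, g$yc, g$zc, cc$u, pts$x, pts$y, pts$z)
    uy <- interp_trilinear(g$xc, g$yc, g$zc, cc$v, pts$x, pts$y, pts$z)
    uz <- interp_trilinear(g$xc, g$yc, g$zc, cc$w, pts$x, pts$y, pts$z)
    speed <- sqrt(ux^2 + uy^2 + uz^2)
  } else {
    if (is.null(cell_sol)) stop("unit_cell sampling requires cell_sol")
    prof <- unit_cell_velocity_at(cell_sol, pts$z)
    s <- nesting_scale(sol, cell_sol, pts$x, pts$y)
    ux <- prof$u_x * s
    speed <- prof$speed * s
  }
  out <- data.frame(microstructure = pts$microstructure, pore = pts$pore,
                    height_um = pts$height * 1e6, u_x = ux, speed = speed)
  attr(out, "sampling") <- sampling
  out
}

#' Local superficial velocity of the chamber flow
#'
#' Depth-averaged streamwise velocity over the scaffold height at given
#' horizontal positions, used to drive the pore-scale unit cell.
#'
#' @param sol chamber `flow_solution`.
#' @param x,y horizontal coordinates (m, vectorised).
#' @param depth averaging depth (m), the scaffold height.
#' @return superficial velocities (m/s).
#' @export
superficial_velocity <- function(sol, x, y, depth = 40e-6) {
  g <- sol$grid
  uc <- collocate_velocity(sol)$u
  kin <- which(g$zc < depth)
  wts <- g$dz[kin] / sum(g$dz[kin])
  out <- 0
  for (ii in seq_along(kin)) {
    out <- out + wts[ii] * interp_trilinear(g$xc, g$yc, g$zc, uc,
                                            x, y, rep(g$zc[kin[ii]], length(x)))
  }
  out
}

# pore-centre velocity of the unit cell at requested heights
unit_cell_velocity_at <- function(cell_sol, z) {
  g <- cell_sol$grid
  cc <- collocate_velocity(cell_sol)
  x0 <- max(g$xf) / 2; y0 <- max(g$yf) / 2 # pore centre (beams on the edges)
  ux <- interp_trilinear(g$xc, g$yc, g$zc, cc$u, rep(x0, length(z)),
                         rep(y0, length(z)), z)
  uy <- interp_trilinear(g$xc, g$yc, g$zc, cc$v, rep(x0, length(z)),
                         rep(y0, length(z)), z)
  uz <- interp_trilinear(g$xc, g$yc, g$zc, cc$w, rep(x0, length(z)),
                         rep(y0, length(z)), z)
  list(u_x = ux, speed = sqrt(ux^2 + uy^2 + uz^2))
}

# mean tau_zx along the three beam segments of the pore's downstream face at
# one reporting height, from the resolved unit cell (normalised to u_sup)
unit_cell_beam_wss <- function(cell_sol, height) {
  g <- cell_sol$grid
  wss <- wall_shear_stress(cell_sol)
  levels_z <- g$meta$beam_levels
  # horizontal framing beam nearest the reporting height (floor/mid/top);
  # ties resolve to the lower beam
  lev <- levels_z[which.min(abs(levels_z - height) + 1e-9 * levels_z)]
  ks <- g$meta$beams[[sprintf("h_%g", lev * 1e6)]]$k
  k_above <- min(max(ks) + 1L, g$nz)
  edge_x <- which(g$meta$edge_x); edge_y <- which(g$meta$edge_y)
  # segment 1: horizontal beam along y on the downstream (x-edge) face,
  # sampled one voxel above the beam crest
  seg1 <- wss$tau[edge_x, setdiff(seq_len(g$ny), edge_y), k_above]
  # segments 2 and 3: the two vertical corner posts, sampled at the
  # reporting height on either side of the face
  kz <- which.min(abs(g$zc - height))
  jn <- setdiff(c(min(edge_y) - 1L, max(edge_y) + 1L,
                  wrap1(min(edge_y) - 1L, g$ny), wrap1(max(edge_y) + 1L, g$ny)),
                edge_y)
  jn <- unique(pmin(pmax(jn, 1L), g$ny))
  seg23 <- wss$tau[edge_x, jn, kz]
  segs <- c(mean(seg1, na.rm = TRUE), mean(seg23, na.rm = TRUE),
            mean(seg23, na.rm = TRUE))
  mean(segs, na.rm = TRUE)
}

#' Beam-averaged wall shear stress at the probe pores
#'
#' For each probed pore and height, the arithmetic mean of `tau_zx` along
#' three beam segments of the pore's outlet-side face (the horizontal framing
#' beam nearest the height plus the two vertical corner posts), computed on
#' the resolved unit cell and scaled by the local superficial velocity from
#' the chamber solve.
#'
#' @param sol chamber `flow_solution`.
#' @param probes a [build_probe_set()] result.
#' @param cell_sol unit-cell `flow_solution`.
#' @return data frame keyed by (microstructure, pore, height_um) with
#'   `tau_zx` (Pa).
#' @export
beam_averaged_wss <- function(sol, probes, cell_sol) {
  pts <- probes$points
  heights <- sort(unique(pts$height))
  base <- vapply(heights, function(h) unit_cell_beam_wss(cell_sol, h),
                 numeric(1))
  if (all(!is.finite(base))) stop("empty beam sample set")
  names(base) <- as.character(heights)
  s <- nesting_scale(sol, cell_sol, pts$x_face, pts$y)
  data.frame(microstructure = pts$microstructure, pore = pts$pore,
             height_um = pts$height * 1e6,
             tau_zx = base[as.character(pts$height)] * s)
}

#' Cross-sectional volumetric flux at a streamwise station
#'
#' @param sol chamber `flow_solution`.
#' @param x station (m); the nearest u-face is used.
#' @return flux (m^3/s) through the simulated cross-section.
#' @export
cross_section_flux <- function(sol, x) {
  g <- sol$grid
  i <- which.min(abs(g$xf - x))
  sum(sol$u[i, , ] * outer(g$dy, g$dz))
}
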