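# Fluid mechanics of the flow cell: a Stokes-type reduction in which the
# pressure is harmonic, the velocity components solve vector Poisson
# problems forced by the pressure gradient, and the dissolved species obey
# a steady advection-diffusion balance in the fluid coupled to transient
# diffusion-reaction inside the biofilm through concentration- and
# flux-continuity at the interface (harmonic-mean face diffusivities).
#
# Domain sides: i = 1 is the inlet (parabolic u, Dirichlet concentrations),
# i = nx the outlet (P = 0, zero-gradient u, v = 0, free outflow),
# j = 1 / j = ny the bottom / top walls (no-slip, no-flux).  The biofilm
# region (phi < 0) is solid for the flow: no-slip on its interface.

.idx2 <- function(i, j, nx) i + (j - 1L) * nx

# Generic assembler: pentadiagonal operator sum_f c_f (x_nb - x_i) over
# active cells, with per-cell-face ghost closures supplied by `face_fun`.
# Returns a dgCMatrix and rhs.  face_fun(i, j, side, inside_nb) must return
# list(type = "link"|"dirichlet"|"neumann", coef, value) where `coef` is the
# face conductance (1/h^2-scaled by the caller) and `value` the Dirichlet
# face value or Neumann flux contribution to the rhs.
.assemble5 <- function(grid, active, face_fun, rhs0 = 0, diag0 = 0) {
  nx <- grid$nx; ny <- grid$ny
  act <- which(active)
  n <- length(act)
  map <- integer(nx * ny); map[act] <- seq_len(n)
  ii <- jj <- integer(0); vv <- numeric(0)
  dg <- rep(0, n)
  b <- rep(rhs0, length.out = n)
  if (length(diag0) > 1) dg <- dg + diag0[act] else dg <- dg + diag0
  sides <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  names(sides) <- c("W", "E", "S", "N")
  ai <- ((act - 1L) %% nx) + 1L
  aj <- ((act - 1L) %/% nx) + 1L
  for (s in names(sides)) {
    di <- sides[[s]][1]; dj <- sides[[s]][2]
    ni <- ai + di; nj <- aj + dj
    inside <- ni >= 1L & ni <= nx & nj >= 1L & nj <= ny
    nb <- ifelse(inside, .idx2(pmax(ni, 1L), pmax(nj, 1L), nx), NA_integer_)
    nb_active <- inside & active[ifelse(is.na(nb), 1L, nb)]
    spec <- face_fun(ai, aj, s, inside, nb_active)
    coef <- spec$coef
    link <- nb_active & spec$type == "link"
    dir <- spec$type == "dirichlet"
    neu <- spec$type == "neumann"
    # links
    w <- which(link)
    if (length(w)) {
      ii <- c(ii, w); jj <- c(jj, map[nb[w]]); vv <- c(vv, coef[w])
      dg[w] <- dg[w] - coef[w]
    }
    # Dirichlet face: ghost = 2*value - x_i
    w <- which(dir)
    if (length(w)) {
      dg[w] <- dg[w] - 2 * coef[w]
      b[w] <- b[w] - 2 * coef[w] * spec$value[w]
    }
    # Neumann: rhs gets the prescribed flux term; zero-flux contributes nothing
    w <- which(neu & spec$value != 0)
    if (length(w)) b[w] <- b[w] - spec$value[w]
  }
  A <- Matrix::sparseMatrix(i = c(seq_len(n), ii), j = c(seq_len(n), jj),
                            x = c(dg, vv), dims = c(n, n))
  list(A = A, b = b, map = map, act = act)
}

#' Solve the flow-cell pressure and velocity fields
#'
#' Pressure: `lap(P) = 0` with `dP/dn = 0` on walls and on the biofilm
#' interface, `P = 0` at the outlet, and the inlet gradient consistent with
#' the imposed parabolic profile.  Velocities: `mu lap(u) = dP/dx`,
#' `mu lap(v) = dP/dy` with no-slip on walls and biofilm, the parabolic
#' profile (centerline speed `u0`) at the inlet, and far-field outlet
#' conditions.  Velocities are zero inside the biofilm.
#'
#' @param grid `grid2d`.
#' @param phi level-set field (negative inside the biofilm).
#' @param p parameter set (uses `mu`, `u0`).
#' @param u0 inlet centerline speed (mm/hour); defaults to `p$u0`.
#' @return list of class `fluid_field` with matrices `u`, `v`, `P` and the
#'   inlet profile `u_in(y)`.
#' @export
solve_pressure_velocity <- function(grid, phi, p, u0 = p$u0) {
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  fluid <- phi >= 0
  if (u0 > 0) {
    solid_cols <- which(apply(!fluid, 1, all))
    if (length(solid_cols))
      stop("biofilm occludes the full channel width", call. = FALSE)
  }
  a <- grid$Ly / 2
  u_in <- u0 * (1 - ((grid$y - a) / a)^2)
  gp <- -2 * p$mu * u0 / a^2           # dP/dx of the Poiseuille solution
  c2 <- 1 / h^2
  # pressure
  fp <- function(ai, aj, side, inside, nb_active) {
    n <- length(ai)
    type <- rep("neumann", n); coef <- rep(c2, n); val <- rep(0, n)
    type[nb_active] <- "link"
    bnd <- !inside
    # inlet face carries the Poiseuille-consistent gradient: the constant
    # -gp/h it contributes to the discrete Laplacian moves to the rhs
    w <- bnd & side == "W"; val[w] <- -gp / h
    w <- bnd & side == "E"; type[w] <- "dirichlet"; val[w] <- 0
    list(type = type, coef = coef, value = val)
  }
  sysP <- .assemble5(grid, fluid, fp)
  Pv <- as.vector(Matrix::solve(sysP$A, sysP$b))
  P <- matrix(0, nx, ny); P[sysP$act] <- Pv
  # pressure gradients at cell centers (ghosts: dP/dn = 0 at walls/interface,
  # P = 0 at outlet face, inlet gradient gp)
  PW <- rbind(P[1, ] - h * gp, P[-nx, ])
  PE <- rbind(P[-1, ], -P[nx, ])
  PS <- cbind(P[, 1], P[, -ny]); PN <- cbind(P[, -1], P[, ny])
  nbW <- rbind(rep(FALSE, ny), fluid[-nx, ]); nbE <- rbind(fluid[-1, ], rep(FALSE, ny))
  nbS <- cbind(rep(FALSE, nx), fluid[, -ny]); nbN <- cbind(fluid[, -1], rep(FALSE, nx))
  iW <- row(P) == 1; iE <- row(P) == nx
  PW <- ifelse(nbW | iW, PW, P); PE <- ifelse(nbE | iE, PE, P)
  PS <- ifelse(nbS, PS, P); PN <- ifelse(nbN, PN, P)
  dPdx <- (PE - PW) / (2 * h)
  dPdy <- (PN - PS) / (2 * h)
  # u velocity
  fu <- function(ai, aj, side, inside, nb_active) {
    n <- length(ai)
    type <- rep("dirichlet", n); coef <- rep(p$mu * c2, n); val <- rep(0, n)
    type[nb_active] <- "link"
    bnd <- !inside
    w <- bnd & side == "W"; type[w] <- "dirichlet"; val[w] <- u_in[aj[w]]
    w <- bnd & side == "E"; type[w] <- "neumann"; val[w] <- 0
    list(type = type, coef = coef, value = val)
  }
  sysU <- .assemble5(grid, fluid, fu)
  uv <- as.vector(Matrix::solve(sysU$A, sysU$b + dPdx[sysU$act]))
  u <- matrix(0, nx, ny); u[sysU$act] <- uv
  # v velocity (Dirichlet 0 on every boundary)
  fv <- function(ai, aj, side, inside, nb_active) {
    n <- length(ai)
    type <- rep("dirichlet", n); coef <- rep(p$mu * c2, n); val <- rep(0, n)
    type[nb_active] <- "link"
    list(type = type, coef = coef, value = val)
  }
  sysV <- .assemble5(grid, fluid, fv)
  vv <- as.vector(Matrix::solve(sysV$A, sysV$b + dPdy[sysV$act]))
  v <- matrix(0, nx, ny); v[sysV$act] <- vv
  structure(list(u = u, v = v, P = P, u_in = u_in, u0 = u0),
            class = "fluid_field")
}

# Face velocities (x-faces between i and i+1, y-faces between j and j+1).
# Faces touching the solid biofilm region carry no advective flux
# (no-penetration).
.face_velocities <- function(fluid_field, grid, inside = NULL) {
  u <- fluid_field$u; v <- fluid_field$v
  nx <- grid$nx; ny <- grid$ny
  uf <- (u[-nx, ] + u[-1, ]) / 2        # [(nx-1), ny]
  vf <- (v[, -ny] + v[, -1]) / 2        # [nx, (ny-1)]
  if (!is.null(inside)) {
    uf[inside[-nx, ] | inside[-1, ]] <- 0
    vf[inside[, -ny] | inside[, -1]] <- 0
  }
  list(uf = uf, vf = vf)
}

# Assemble the transport operator for one species over the whole domain:
# quasi-steady in the fluid, backward-Euler transient in the biofilm,
# harmonic-mean diffusivity at mixed faces, first-order upwind advection on
# the fluid velocity field, inlet Dirichlet, no-flux walls, advective
# outflow at the outlet.  Options: bc_left = "wall" closes the inlet (used
# by closed/verification configurations), bc_top = "far_field" imposes the
# far-field concentration on the top boundary.
.transport_system <- function(grid, phi, fluid_field, D_b, D_fl, c_far, dt,
                              bc_left = "inlet", bc_top = "wall",
                              quasi_steady_fluid = TRUE) {
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  inside <- phi < 0
  D <- ifelse(inside, D_b, D_fl)
  fv <- .face_velocities(fluid_field, grid, inside)
  active <- matrix(TRUE, nx, ny)
  hm <- function(a, b) 2 * a * b / (a + b)
  # Per-face diffusive conductances (divided by h^2)
  Dx <- hm(D[-nx, ], D[-1, ]) / h^2      # x-faces
  Dy <- hm(D[, -ny], D[, -1]) / h^2      # y-faces
  ff <- function(ai, aj, side, inside_dom, nb_active) {
    n <- length(ai)
    type <- rep("neumann", n); coef <- rep(0, n); val <- rep(0, n)
    lk <- nb_active
    type[lk] <- "link"
    coef[lk] <- switch(substr(side, 1, 1),
      W = Dx[cbind(pmax(ai[lk] - 1L, 1L), aj[lk])],
      E = Dx[cbind(pmin(ai[lk], nx - 1L), aj[lk])],
      S = Dy[cbind(ai[lk], pmax(aj[lk] - 1L, 1L))],
      N = Dy[cbind(ai[lk], pmin(aj[lk], ny - 1L))])
    bnd <- !inside_dom
    if (bc_left == "inlet") {
      w <- bnd & side == "W"
      type[w] <- "dirichlet"; coef[w] <- D_fl / h^2; val[w] <- c_far
    }
    if (bc_top == "far_field") {
      w <- bnd & side == "N"
      type[w] <- "dirichlet"; coef[w] <- D_fl / h^2; val[w] <- c_far
    }
    list(type = type, coef = coef, value = val)
  }
  diag0 <- ifelse(inside | !quasi_steady_fluid, -1 / dt, 0)
  sys <- .assemble5(grid, active, ff, rhs0 = 0, diag0 = c(diag0))
  # advection: advective upwind form -u . grad(c) on cell-centered
  # velocities.  The reduced Stokes system does not enforce a discretely
  # divergence-free velocity, so the flux-divergence form would lose the
  # maximum principle near the biofilm; the advective form keeps fluid
  # concentrations within the hull of boundary and interface values.
  # Velocities vanish inside the biofilm, so only fluid cells advect.
  n <- length(sys$act)
  dg <- rep(0, n); badv <- rep(0, n)
  map <- sys$map
  ii <- jj <- integer(0); vv <- numeric(0)
  um <- fluid_field$u; vm <- fluid_field$v
  ci <- ((sys$act - 1L) %% nx) + 1L
  cj <- ((sys$act - 1L) %/% nx) + 1L
  uv <- um[sys$act]; vvel <- vm[sys$act]
  # x-direction
  w <- which(uv > 0 & ci > 1L)
  if (length(w)) {
    dg[w] <- dg[w] - uv[w] / h
    ii <- c(ii, w); jj <- c(jj, map[.idx2(ci[w] - 1L, cj[w], nx)])
    vv <- c(vv, uv[w] / h)
  }
  w <- which(uv > 0 & ci == 1L)         # inlet ghost carries c_far
  if (length(w) && bc_left == "inlet") {
    dg[w] <- dg[w] - uv[w] / h
    badv[w] <- badv[w] - uv[w] * c_far / h
  }
  w <- which(uv < 0 & ci < nx)
  if (length(w)) {
    dg[w] <- dg[w] + uv[w] / h
    ii <- c(ii, w); jj <- c(jj, map[.idx2(ci[w] + 1L, cj[w], nx)])
    vv <- c(vv, -uv[w] / h)
  }
  # y-direction
  w <- which(vvel > 0 & cj > 1L)
  if (length(w)) {
    dg[w] <- dg[w] - vvel[w] / h
    ii <- c(ii, w); jj <- c(jj, map[.idx2(ci[w], cj[w] - 1L, nx)])
    vv <- c(vv, vvel[w] / h)
  }
  w <- which(vvel < 0 & cj < ny)
  if (length(w)) {
    dg[w] <- dg[w] + vvel[w] / h
    ii <- c(ii, w); jj <- c(jj, map[.idx2(ci[w], cj[w] + 1L, nx)])
    vv <- c(vv, -vvel[w] / h)
  }
  Aadv <- Matrix::sparseMatrix(i = c(seq_len(n), ii), j = c(seq_len(n), jj),
                               x = c(dg, vv), dims = c(n, n))
  A <- sys$A + Aadv
  transient <- inside | !quasi_steady_fluid
  list(A = A, b0 = sys$b + badv, map = sys$map, act = sys$act,
       inside = inside, transient = transient, dt = dt,
       lu = if (is.finite(dt)) Matrix::lu(A) else NULL)
}

# One implicit transport step: fluid cells solve the steady balance,
# transient cells advance c by backward Euler from c_old.  Reactions are
# handled by the splitting (not in this operator).
.transport_step <- function(sys, c_old) {
  b <- sys$b0
  w <- which(sys$transient[sys$act])
  b[w] <- b[w] - c_old[sys$act][w] / sys$dt
  cv <- as.vector(Matrix::solve(sys$lu, b))
  cn <- c_old
  cn[sys$act] <- cv
  cn
}

#' Steady dissolved-species fields in the flow cell
#'
#' Solves the steady advection-diffusion balance for one species over the
#' whole domain (no reactions), coupled across the biofilm interface by
#' harmonic-mean face diffusivities.  This is the transport operator used
#' inside [run_2d()], exposed for verification runs.
#'
#' @param grid,phi,fluid_field geometry and flow.
#' @param p parameter set.
#' @param species `"G"` or `"K"`.
#' @param bc_left,bc_top boundary options (see Details in [run_2d()]).
#' @return concentration matrix.
#' @export
fluid_transport_steady <- function(grid, phi, fluid_field, p,
                                   species = c("G", "K"),
                                   bc_left = "inlet", bc_top = "wall") {
  species <- match.arg(species)
  D_b <- if (species == "G") p$D_G else p$D_K
  D_fl <- if (species == "G") p$D_G_fl else p$D_K_fl
  c_far <- if (species == "G") p$G0 else p$K0
  sys <- .transport_system(grid, phi, fluid_field, D_b, D_fl, c_far,
                           dt = Inf, bc_left = bc_left, bc_top = bc_top,
                           quasi_steady_fluid = TRUE)
  # steady everywhere: dt = Inf removes the transient diagonal
  cv <- as.vector(Matrix::solve(sys$A, sys$b0))
  cn <- matrix(0, grid$nx, grid$ny)
  cn[sys$act] <- cv
  cn
}

#' One interface-coupled diffusion step
#'
#' Advances `G` and `K` by `dt`: transient backward Euler inside the
#' biofilm, quasi-steady balance in the fluid, concentration and flux
#' continuity at the interface via harmonic-mean face diffusivities.
#'
#' @param state list with matrices `G`, `K`.
#' @param fluid_field flow field from [solve_pressure_velocity()].
#' @param grid,phi geometry.
#' @param p parameter set.
#' @param dt step (hours).
#' @param systems optional prebuilt operator pair (reused between steps
#'   while the geometry is unchanged).
#' @param bc_left,bc_top boundary options.
#' @return updated state (and the operator pair as attribute `systems`).
#' @export
interface_coupled_diffusion_step <- function(state, fluid_field, grid, phi,
                                             p, dt, systems = NULL,
                                             bc_left = "inlet",
                                             bc_top = "wall") {
  if (is.null(systems)) {
    systems <- list(
      G = .transport_system(grid, phi, fluid_field, p$D_G, p$D_G_fl, p$G0,
                            dt, bc_left, bc_top),
      K = .transport_system(grid, phi, fluid_field, p$D_K, p$D_K_fl, p$K0,
                            dt, bc_left, bc_top))
  }
  state$G <- .transport_step(systems$G, state$G)
  state$K <- .transport_step(systems$K, state$K)
  attr(state, "systems") <- systems
  state
}
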