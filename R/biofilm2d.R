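# Two-dimensional biofilm dynamics in the flow cell: cellular state fields
# live on the cells with phi < 0, expand with the growth-potential velocity
# field, and the interface moves by the level-set method.

#' Growth potential, biomass velocity and interface normal speed
#'
#' Solves the Poisson problem `lap(Omega) = delta_grow * M_grow * G_in`
#' inside the biofilm with `Omega = 0` on the biofilm-fluid interface and
#' `dOmega/dn = 0` on flow-cell walls, then takes `U = grad(Omega)` as the
#' biomass expansion velocity.  In a 1D slab of thickness L with a uniform
#' source g this reduces to `Omega = g (x^2 - L^2) / 2`, giving interface
#' speed `g L` — exactly the 1D growth law, which ties the two formulations
#' together.  The interface normal speed `|grad(Omega)|` is extended to a
#' narrow band around the interface by copying from the nearest
#' interface-adjacent biofilm cell.
#'
#' @param state list with matrices `G_in`, `V` (and the rest of the
#'   cellular fields).
#' @param grid,phi geometry (`phi < 0` inside).
#' @param p parameter set.
#' @param M_grow optional growth-propensity matrix (variants).
#' @param band half-width (cells) of the speed-extension band.
#' @return list with `Omega`, `Ux`, `Uy` (all matrices, zero outside the
#'   biofilm) and `speed` (extension of `|grad(Omega)|`, defined on the
#'   band, zero elsewhere).
#' @export
growth_potential_velocity <- function(state, grid, phi, p, M_grow = NULL,
                                      band = 4) {
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  inside <- phi < 0
  if (!any(inside)) stop("empty biofilm region", call. = FALSE)
  if (is.null(M_grow)) M_grow <- growth_mode(state$G_in, state$V, p)
  src <- p$delta_grow * M_grow * state$G_in
  c2 <- 1 / h^2
  fo <- function(ai, aj, side, inside_dom, nb_active) {
    n <- length(ai)
    # interface faces: Omega = 0 (Dirichlet); flow-cell walls: no growth
    # through walls (Neumann 0)
    type <- rep("dirichlet", n); coef <- rep(c2, n); val <- rep(0, n)
    type[nb_active] <- "link"
    type[!inside_dom] <- "neumann"; val[!inside_dom] <- 0
    list(type = type, coef = coef, value = val)
  }
  sys <- .assemble5(grid, inside, fo)
  Ov <- as.vector(Matrix::solve(sys$A, sys$b + src[sys$act]))
  Omega <- matrix(0, nx, ny)
  Omega[sys$act] <- Ov
  # gradients with ghosts: interface faces Omega = 0 -> ghost = -Omega_i;
  # domain walls: ghost = Omega_i (no normal growth)
  gW <- rbind(Omega[1, ], Omega[-nx, ]); gE <- rbind(Omega[-1, ], Omega[nx, ])
  gS <- cbind(Omega[, 1], Omega[, -ny]); gN <- cbind(Omega[, -1], Omega[, ny])
  inW <- rbind(rep(FALSE, ny), inside[-nx, ]); inE <- rbind(inside[-1, ], rep(FALSE, ny))
  inS <- cbind(rep(FALSE, nx), inside[, -ny]); inN <- cbind(inside[, -1], rep(FALSE, nx))
  bW <- row(Omega) == 1; bE <- row(Omega) == nx
  bS <- col(Omega) == 1; bN <- col(Omega) == ny
  gW <- ifelse(inW | bW, ifelse(bW & !inW, Omega, gW), -Omega)
  gE <- ifelse(inE | bE, ifelse(bE & !inE, Omega, gE), -Omega)
  gS <- ifelse(inS | bS, ifelse(bS & !inS, Omega, gS), -Omega)
  gN <- ifelse(inN | bN, ifelse(bN & !inN, Omega, gN), -Omega)
  Ux <- ifelse(inside, (gE - gW) / (2 * h), 0)
  Uy <- ifelse(inside, (gN - gS) / (2 * h), 0)
  spd_cell <- sqrt(Ux^2 + Uy^2)
  # extension: copy |U| from the nearest interface-adjacent inside cell
  near_int <- inside & (!inW & !bW | !inE & !bE | !inS & !bS | !inN & !bN)
  src_idx <- which(near_int)
  speed <- matrix(0, nx, ny)
  if (length(src_idx)) {
    bandm <- abs(phi) <= band * h
    tgt <- which(bandm)
    sx <- ((src_idx - 1L) %% nx) + 1L; sy <- ((src_idx - 1L) %/% nx) + 1L
    tx <- ((tgt - 1L) %% nx) + 1L; ty <- ((tgt - 1L) %/% nx) + 1L
    chunk <- max(1L, floor(4e6 / length(src_idx)))
    for (s in seq(1L, length(tgt), by = chunk)) {
      e <- min(length(tgt), s + chunk - 1L)
      dd <- outer(tx[s:e], sx, "-")^2 + outer(ty[s:e], sy, "-")^2
      speed[tgt[s:e]] <- spd_cell[src_idx[max.col(-dd, ties.method = "first")]]
    }
  }
  list(Omega = Omega, Ux = Ux, Uy = Uy, speed = speed)
}

#' Advance the biofilm interface by the level-set equation
#'
#' Moves the zero contour of `phi` outward with normal speed `speed`
#' (Godunov upwind for non-negative speeds) and reinitializes `phi` to a
#' signed distance when requested.
#'
#' @param phi level-set field.
#' @param speed extended normal speed field (mm/hour, non-negative).
#' @param dt step (hours); must satisfy `dt * max(speed) <= h / 2`.
#' @param grid `grid2d`.
#' @param reinit reinitialize to signed distance after the advance.
#' @return updated `phi`.
#' @export
advance_interface <- function(phi, speed, dt, grid, reinit = FALSE) {
  if (dt * max(speed) > grid$h / 2 + 1e-12)
    stop("level-set CFL violated: dt * max speed exceeds h/2", call. = FALSE)
  phi <- .advance_phi(phi, speed, dt, grid)
  if (reinit) phi <- .signed_distance(phi, grid)
  phi
}

# Fill cellular fields of cells newly inside the biofilm from the nearest
# previously-inside cell.
.fill_new_cells <- function(state, new_idx, old_idx, nx) {
  if (!length(new_idx) || !length(old_idx)) return(state)
  nxv <- ((new_idx - 1L) %% nx) + 1L; nyv <- ((new_idx - 1L) %/% nx) + 1L
  ox <- ((old_idx - 1L) %% nx) + 1L; oy <- ((old_idx - 1L) %/% nx) + 1L
  dd <- outer(nxv, ox, "-")^2 + outer(nyv, oy, "-")^2
  donor <- old_idx[max.col(-dd, ties.method = "first")]
  for (nm in .field_names) state[[nm]][new_idx] <- state[[nm]][donor]
  state
}

# Material upwind advection of one cellular field by (Ux, Uy), restricted
# to the biofilm region; gradients one-sided toward the upwind neighbor,
# frozen (zero) where the upwind neighbor is outside.
.advect_material <- function(q, Ux, Uy, inside, h, dt) {
  nx <- nrow(q); ny <- ncol(q)
  qW <- rbind(q[1, ], q[-nx, ]); qE <- rbind(q[-1, ], q[nx, ])
  qS <- cbind(q[, 1], q[, -ny]); qN <- cbind(q[, -1], q[, ny])
  inW <- rbind(rep(FALSE, ny), inside[-nx, ]); inE <- rbind(inside[-1, ], rep(FALSE, ny))
  inS <- cbind(rep(FALSE, nx), inside[, -ny]); inN <- cbind(inside[, -1], rep(FALSE, nx))
  gx <- ifelse(Ux > 0, ifelse(inW, (q - qW) / h, 0),
               ifelse(inE, (qE - q) / h, 0))
  gy <- ifelse(Uy > 0, ifelse(inS, (q - qS) / h, 0),
               ifelse(inN, (qN - q) / h, 0))
  ifelse(inside, q - dt * (Ux * gx + Uy * gy), q)
}

.means_over <- function(state, sel, area) {
  c(mean_V_mV = mean(state$V[sel]), mean_K_mM = mean(state$K[sel]),
    mean_Gin_mM = mean(state$G_in[sel]), mean_Kin_mM = mean(state$K_in[sel]),
    mean_T = mean(state$T[sel]), mean_A = mean(state$A[sel]),
    area_mm2 = area)
}

#' Run a 2D flow-cell simulation
#'
#' Couples, per outer step: the Stokes-type flow solve (refreshed whenever
#' the interface has moved into new cells), the quasi-steady fluid /
#' transient biofilm transport of glutamate and potassium, adaptive
#' explicit integration of the cellular reaction system inside the biofilm,
#' material upwind advection of the cellular fields by the growth velocity,
#' the growth-potential solve, and the level-set interface advance with
#' periodic reinitialization.
#'
#' Initial cellular values follow the homeostatic 2D initial condition
#' (`G = G0`, `K = K0`, `G_in = 20`, `K_in = 300`, `K_acclimated = K0`,
#' `V = -160` mV, `n = 0.1`).
#'
#' @param shapes a mask matrix `[nx, ny]`, a `shape_spec`, or a list of
#'   `shape_spec`s rasterized onto the grid.
#' @param p parameter set.
#' @param t_end_h simulated hours.
#' @param grid `grid2d` (defaults to the 3 mm flow cell at coarse 30 µm).
#' @param u0 inlet centerline speed (mm/hour); defaults to `p$u0`.
#' @param dt outer step (hours).
#' @param out_every trace output interval (hours).
#' @param snapshot_every optional full-field snapshot interval (hours).
#' @param variant [variant_spec()].
#' @param init named list of initial-value overrides.
#' @param bc_left `"inlet"` or `"wall"`; `bc_top` `"wall"` or
#'   `"far_field"` (Dirichlet far-field concentrations on the top side;
#'   verification configurations).
#' @param reinit_every reinitialize the level set every this many steps.
#' @param ctrl reaction-integrator controls (see [step_1d()]).
#' @return list of class `biofilm2d_result`: `trace` (overall means, class
#'   `oscillation_trace`), `per_biofilm` (per-component means, long
#'   format), `snapshots`, `grid`, final `state`, `phi`, `fluid`.
#' @export
run_2d <- function(shapes, p = biofilm_params(), t_end_h = 10,
                   grid = make_grid2d(), u0 = p$u0, dt = 0.005,
                   out_every = 0.05, snapshot_every = NULL,
                   variant = variant_spec(), init = list(),
                   bc_left = "inlet", bc_top = "wall",
                   reinit_every = 10, ctrl = list()) {
  variant <- as_variant(variant)
  ct <- utils::modifyList(list(literal_tv = FALSE, rtol = 1e-3, atol = 1e-4,
                               n_fixed = NULL), ctrl)
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  mask <- if (is.matrix(shapes)) shapes
          else if (inherits(shapes, "shape_spec")) generate_fixture(shapes, grid)
          else Reduce(`|`, lapply(shapes, generate_fixture, grid = grid))
  stopifnot(all(dim(mask) == c(nx, ny)))
  if (u0 > 0 && (any(mask[1, ]) || any(mask[nx, ])))
    stop("biofilm touches the inlet or outlet", call. = FALSE)
  phi <- phi_from_mask(mask, grid)
  inside <- phi < 0
  defaults <- list(G = p$G0, K = p$K0, G_in = 20, K_in = 300,
                   K_acc = p$K0, V = -160, n = 0.1, T = 0, A = 0)
  for (nm in names(init)) defaults[[nm]] <- init[[nm]]
  state <- list()
  for (nm in .field_names)
    state[[nm]] <- matrix(defaults[[nm]], nx, ny)
  comp0 <- .label_components(inside)
  n_comp <- max(comp0)

  fluid <- solve_pressure_velocity(grid, phi, p, u0 = u0)
  systems <- NULL
  n_steps <- ceiling(t_end_h / dt)
  out_stride <- max(1L, round(out_every / dt))
  snap_stride <- if (is.null(snapshot_every)) Inf else max(1L, round(snapshot_every / dt))
  trace <- list(); per <- list(); snaps <- list()
  dt_react <- NULL

  record <- function(t, k) {
    area <- sum(inside) * h^2
    trace[[length(trace) + 1L]] <<- c(time_h = t, .means_over(state, inside, area))
    lab <- comp0
    # newly grown cells adopt the label of the nearest initial component
    cur <- .label_components(inside)
    for (cc in seq_len(max(cur))) {
      cells <- cur == cc
      ov <- tabulate(comp0[cells & comp0 > 0], nbins = n_comp)
      lab[cells] <- if (any(ov > 0)) which.max(ov) else 0L
    }
    for (cc in seq_len(n_comp)) {
      sel <- lab == cc & inside
      if (!any(sel)) next
      per[[length(per) + 1L]] <<- c(biofilm = cc, time_h = t,
                                    .means_over(state, sel, sum(sel) * h^2))
    }
    if (is.finite(snap_stride) && (k %% snap_stride == 0L || k == 0L)) {
      snaps[[paste0("t_", k)]] <<- list(time_h = t, phi = phi, state = state,
                                        fluid = fluid)
    }
  }
  record(0, 0L)

  for (k in seq_len(n_steps)) {
    # transport (geometry-cached operators)
    if (is.null(systems)) {
      systems <- list(
        G = .transport_system(grid, phi, fluid, p$D_G, p$D_G_fl, p$G0, dt,
                              bc_left, bc_top),
        K = .transport_system(grid, phi, fluid, p$D_K, p$D_K_fl, p$K0, dt,
                              bc_left, bc_top))
    }
    state$G <- .transport_step(systems$G, state$G)
    state$K <- .transport_step(systems$K, state$K)

    # reactions inside the biofilm
    idx <- which(inside)
    f <- lapply(.field_names, function(nm) state[[nm]][idx])
    names(f) <- .field_names
    f <- react_substep(f, p, dt, variant, literal_tv = ct$literal_tv,
                       rtol = ct$rtol, atol = ct$atol, dt_init = dt_react,
                       n_fixed = ct$n_fixed)
    dt_react <- attr(f, "dt_last")
    for (nm in .field_names) state[[nm]][idx] <- f[[nm]]
    # clamping as in 1D
    state$G_in <- pmin(pmax(state$G_in, 0), p$G_max)
    state$n <- pmin(pmax(state$n, 0), 1)
    for (nm in c("G", "K", "K_in", "K_acc", "T", "A"))
      state[[nm]] <- pmax(state[[nm]], 0)

    # growth and interface motion
    M <- if (variant$kind == "constant_mgrow")
      matrix(variant$mgrow_value, nx, ny)
    else growth_mode(state$G_in, state$V, p, literal = ct$literal_tv)
    gp <- growth_potential_velocity(state, grid, phi, p, M_grow = M)
    for (nm in c("G_in", "K_in", "K_acc", "V", "n", "T", "A"))
      state[[nm]] <- .advect_material(state[[nm]], gp$Ux, gp$Uy, inside, h, dt)
    n_cfl <- max(1L, ceiling(dt * max(gp$speed) / (0.45 * h)))
    phi_new <- phi
    for (s in seq_len(n_cfl))
      phi_new <- .advance_phi(phi_new, gp$speed, dt / n_cfl, grid)
    if (k %% reinit_every == 0L) phi_new <- .signed_distance(phi_new, grid)
    inside_new <- phi_new < 0
    grew <- inside_new & !inside
    if (any(grew)) {
      state <- .fill_new_cells(state, which(grew), which(inside), nx)
      # geometry changed: refresh flow and transport operators
      fluid <- solve_pressure_velocity(grid, phi_new, p, u0 = u0)
      systems <- NULL
    }
    phi <- phi_new
    inside <- inside_new
    if (!any(inside)) stop("biofilm vanished", call. = FALSE)
    if (u0 > 0 && (any(inside[1, ]) || any(inside[nx, ])))
      stop("biofilm reached the inlet or outlet", call. = FALSE)
    if (k %% out_stride == 0L) record(k * dt, k)
  }

  tr <- as.data.frame(do.call(rbind, trace))
  class(tr) <- c("oscillation_trace", "data.frame")
  pb <- if (length(per)) as.data.frame(do.call(rbind, per)) else NULL
  structure(list(trace = tr, per_biofilm = pb, snapshots = snaps,
                 grid = grid, state = state, phi = phi, fluid = fluid,
                 params = p),
            class = "biofilm2d_result")
}

#' Track the outward potassium wave along a ray
#'
#' Samples the extracellular potassium along a ray from an interior origin
#' (typically the deepest point of a wall-attached biofilm) across the
#' snapshots of a 2D run, locates the crest (position of maximum K inside
#' the biofilm) per snapshot, and fits a line to the advancing crest
#' positions during the wave episode — the episode being the snapshots
#' whose crest value exceeds the ambient level by `k_thresh`.
#'
#' @param result `biofilm2d_result` with snapshots.
#' @param origin_mm `c(x, y)` ray origin (mm).
#' @param dir ray direction (normalized internally).
#' @param k_thresh crest-over-ambient threshold (mM) defining the episode.
#' @return list with `speed_mm_per_h`, `speed_um_per_min`, and the episode
#'   data frame (`time_h`, `r_mm`, `K_crest`).
#' @export
track_wave <- function(result, origin_mm, dir = c(0, 1), k_thresh = 10) {
  grid <- result$grid
  dir <- dir / sqrt(sum(dir^2))
  rmax <- sqrt(grid$Lx^2 + grid$Ly^2)
  rs <- seq(0, rmax, by = grid$h / 2)
  px <- origin_mm[1] + rs * dir[1]
  py <- origin_mm[2] + rs * dir[2]
  keep <- px >= grid$h / 2 & px <= grid$Lx - grid$h / 2 &
          py >= grid$h / 2 & py <= grid$Ly - grid$h / 2
  rs <- rs[keep]; px <- px[keep]; py <- py[keep]
  ii <- pmin(pmax(round(px / grid$h + 0.5), 1), grid$nx)
  jj <- pmin(pmax(round(py / grid$h + 0.5), 1), grid$ny)
  amb <- result$params$K0
  rows <- lapply(result$snapshots, function(s) {
    kv <- s$state$K[cbind(ii, jj)]
    ins <- s$phi[cbind(ii, jj)] < 0
    if (!any(ins)) return(NULL)
    kv[!ins] <- -Inf
    i <- which.max(kv)
    data.frame(time_h = s$time_h, r_mm = rs[i], K_crest = kv[i])
  })
  ep <- do.call(rbind, rows)
  ep <- ep[is.finite(ep$K_crest) & ep$K_crest > amb + k_thresh, , drop = FALSE]
  if (nrow(ep) < 3)
    return(list(speed_mm_per_h = NA_real_, speed_um_per_min = NA_real_,
                episode = ep))
  # advancing portion: from the first episode snapshot to the crest's
  # farthest advance
  ep <- ep[seq_len(which.max(ep$r_mm)), , drop = FALSE]
  fit <- lm(r_mm ~ time_h, data = ep)
  sp <- unname(coef(fit)[2])
  list(speed_mm_per_h = sp, speed_um_per_min = sp * 1000 / 60, episode = ep)
}
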