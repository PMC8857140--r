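# One-dimensional moving-domain model: a cross-section of the biofilm from
# the attachment wall (x = 0) to the biofilm-fluid interface (x = L(t)).
# Extracellular glutamate and potassium diffuse; all cellular state variables
# are advected outward with the growth velocity U(x).

# --- grid ---------------------------------------------------------------

# Nodes: regular spacing dx from the wall, plus one interface node that
# tracks L exactly.  The gap between the last regular node and the interface
# is kept in (0.5*dx, 1.5*dx] so stencils never degenerate; nodes are
# appended (with constant extrapolation of field values from the previous
# interface value) as L grows and dropped as it shrinks.
.n_reg_for <- function(L, dx) max(3L, as.integer(ceiling(L / dx - 1.5)) + 1L)

#' Construct a 1D biofilm state
#'
#' Initializes all fields uniformly over `[0, width_mm]`.  Defaults follow
#' the homeostatic initial condition: `G = G0`, `K = K0`, `G_in = 20`,
#' `K_in = 300`, `K_acclimated = K0`, `V = -156` mV, `n = 0.1`, reporters 0.
#'
#' @param width_mm initial biofilm width (mm).
#' @param p parameter set (internal units).
#' @param init named list overriding initial values (scalars, mM / mV).
#' @param dx nominal node spacing (mm; default 2 microns).
#' @return list of class `state1d`.
#' @export
make_state1d <- function(width_mm, p = biofilm_params(), init = list(), dx = 0.002) {
  stopifnot(width_mm > 0, dx > 0)
  defaults <- list(G = p$G0, K = p$K0, G_in = 20, K_in = 300,
                   K_acc = p$K0, V = -156, n = 0.1, T = 0, A = 0)
  unknown <- setdiff(names(init), names(defaults))
  if (length(unknown))
    stop("unknown initial field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  for (nm in names(init)) defaults[[nm]] <- init[[nm]]
  n_reg <- .n_reg_for(width_mm, dx)
  dx_eff <- if ((n_reg - 1) * dx >= width_mm) width_mm / (n_reg + 0.5) else dx
  n_reg <- .n_reg_for(width_mm, dx_eff)
  x <- c(seq(0, by = dx_eff, length.out = n_reg), width_mm)
  st <- list(x = x, dx = dx_eff, L = width_mm)
  for (nm in names(defaults)) st[[nm]] <- rep(defaults[[nm]], length(x))
  class(st) <- "state1d"
  st
}

# Re-grid after L changed: maintain the regular-node invariant.  New nodes
# inherit the previous interface value (constant extrapolation).
.regrid1d <- function(st) {
  dx <- st$dx
  n_reg_old <- length(st$x) - 1L
  n_reg_new <- .n_reg_for(st$L, dx)
  if (n_reg_new != n_reg_old) {
    for (nm in .field_names) {
      v <- st[[nm]]
      int_val <- v[length(v)]
      reg <- v[seq_len(min(n_reg_old, n_reg_new))]
      if (n_reg_new > n_reg_old)
        reg <- c(reg, rep(int_val, n_reg_new - n_reg_old))
      st[[nm]] <- c(reg, int_val)
    }
  }
  st$x <- c(seq(0, by = dx, length.out = n_reg_new), st$L)
  st
}

# Area-weighted (trapezoid) mean of a nodal field over [0, L].
.trapz_mean <- function(x, v) {
  h <- diff(x)
  sum((v[-1] + v[-length(v)]) / 2 * h) / (x[length(x)] - x[1])
}

.cumtrapz <- function(x, v) {
  h <- diff(x)
  c(0, cumsum((v[-1] + v[-length(v)]) / 2 * h))
}

# --- growth -------------------------------------------------------------

#' Growth velocity field and interface speed
#'
#' `U(x) = delta_grow * integral_0^x G_in * M_grow dx` (trapezoid rule on
#' the grid) and `dL/dt = U(L)`.  `U(0) = 0` and U is non-decreasing since
#' the integrand is non-negative.
#'
#' @param state `state1d`.
#' @param p parameter set.
#' @param M_grow optional growth-propensity vector (ablation variants pass
#'   their own); defaults to the full-model [growth_mode()].
#' @return list with `U` (mm/hour, per node) and `dLdt` (mm/hour).
#' @export
growth_velocity <- function(state, p, M_grow = NULL) {
  if (is.null(M_grow)) M_grow <- growth_mode(state$G_in, state$V, p)
  U <- p$delta_grow * .cumtrapz(state$x, state$G_in * M_grow)
  list(U = U, dLdt = U[length(U)])
}

# --- spatial right-hand side (diagnostic / oracle surface) --------------

#' Full spatial right-hand side of the 1D system
#'
#' Assembles, per node, the time derivative of every field: reaction terms
#' (shared kernel), central-difference diffusion of `G` and `K` with the
#' wall Neumann and interface boundary-layer closures, and conservative
#' first-order upwind advection of the cellular fields.  Used directly for
#' conservation diagnostics and oracle tests; the production stepper
#' integrates the same terms by operator splitting.
#'
#' @param state `state1d`; `p` parameters; `variant` ablation spec.
#' @param p parameter set.
#' @param variant [variant_spec()].
#' @param closed zero-flux at the interface instead of the boundary-layer
#'   closure (verification configurations).
#' @param freeze_growth force `U = 0` (verification configurations).
#' @param conservative_advection use the conservative flux form
#'   `-d(Uq)/dx` instead of the default material form `-U dq/dx` for the
#'   cellular fields (see Details).
#' @details The cellular state variables are intensive per-cell quantities:
#'   daughter cells inherit their parent's voltage and internal stores, so
#'   uniform fields must be invariant under growth.  The material (advective)
#'   transport form has that property; the conservative flux form adds a
#'   dilution term `-q * dU/dx` that, for the voltage, acts as a spurious
#'   depolarizing drift of order `+V_L0 * delta_grow * G_in * M_grow`
#'   (about +10 mV/hour at homeostasis) strong enough to shut down glutamate
#'   uptake during normal growth.  The material form is therefore the
#'   default; the flux form is retained for comparison.
#' @return list of derivative vectors (one per field), plus `dLdt` and the
#'   diagnostic `M_grow`.
#' @export
rhs_1d <- function(state, p, variant = variant_spec(), closed = FALSE,
                   freeze_growth = FALSE, conservative_advection = FALSE) {
  f <- state[.field_names]
  rr <- reaction_rhs(f, p, variant)
  x <- state$x
  N <- length(x)
  h <- diff(x)
  w <- c(h[1] / 2, (h[-1] + h[-(N - 1)]) / 2, h[N - 1] / 2)
  for (sp in c("G", "K")) {
    D <- if (sp == "G") p$D_G else p$D_K
    D_fl <- if (sp == "G") p$D_G_fl else p$D_K_fl
    c_far <- if (sp == "G") p$G0 else p$K0
    v <- state[[sp]]
    flux <- D * diff(v) / h               # flux at interior faces
    ext <- if (closed) 0 else D_fl * (c_far - v[N]) / p$B_L
    div <- (c(flux, ext) - c(0, flux)) / w
    rr[[sp]] <- rr[[sp]] + div
  }
  if (freeze_growth) {
    U <- rep(0, N); dLdt <- 0
  } else {
    gv <- growth_velocity(state, p, M_grow = rr$M_grow)
    U <- gv$U; dLdt <- gv$dLdt
  }
  for (nm in c("G_in", "K_in", "K_acc", "V", "n", "T", "A")) {
    adv <- if (conservative_advection) c(0, diff(U * state[[nm]]) / h)
           else U * c(0, diff(state[[nm]]) / h)  # upwind (U >= 0): left-biased
    rr[[nm]] <- rr[[nm]] - adv
  }
  bad <- .field_names[vapply(.field_names, function(nm) any(!is.finite(rr[[nm]])), logical(1))]
  if (length(bad))
    stop("non-finite derivative in field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  rr$U <- U
  rr$dLdt <- dLdt
  rr
}

# --- operator-split stepper ---------------------------------------------

# Implicit (backward Euler) diffusion step for one species on the moving
# grid; finite-volume tridiagonal system, interface coupled to the far field
# through the boundary-layer conductance D_fl/B_L (Robin), wall no-flux.
.diffuse_implicit <- function(v, x, dt, D, D_fl, c_far, B_L, closed = FALSE) {
  N <- length(x)
  h <- diff(x)
  w <- c(h[1] / 2, (h[-1] + h[-(N - 1)]) / 2, h[N - 1] / 2)
  C <- D / h
  kext <- if (closed) 0 else D_fl / B_L
  d <- w / dt + c(C, 0) + c(0, C)
  d[N] <- d[N] + kext
  b <- w / dt * v
  b[N] <- b[N] + kext * c_far
  solve_tridiag(-C, d, -C, b)
}

#' Advance the 1D state by one outer step
#'
#' Operator splitting: adaptive explicit sub-stepping of the stiff reaction
#' system, explicit conservative upwind advection of the cellular fields
#' (CFL-subcycled), backward-Euler diffusion of `G` and `K`, then the domain
#' update `L += dt * U(L)` with re-gridding and clamping (`G_in` to
#' `[0, G_max]`, `n` to `[0,1]`, concentrations and reporters to `>= 0`).
#'
#' @param state `state1d`.
#' @param p parameter set.
#' @param dt_max outer step (hours).
#' @param variant [variant_spec()].
#' @param ctrl list of stepper controls: `closed`, `freeze_growth`,
#'   `literal_tv`, `rtol`, `n_fixed` (fixed reaction sub-steps per outer
#'   step; `NULL` = adaptive), `dt_min`.
#' @return updated `state1d`.
#' @export
step_1d <- function(state, p, dt_max = 0.01, variant = variant_spec(), ctrl = list()) {
  ct <- utils::modifyList(list(closed = FALSE, freeze_growth = FALSE,
                               literal_tv = FALSE, conservative_advection = FALSE,
                               rtol = 1e-3, atol = 1e-4, n_fixed = NULL,
                               dt_min = 1e-9),
                          ctrl)
  dt <- dt_max
  f <- state[.field_names]
  f <- react_substep(f, p, dt, variant, literal_tv = ct$literal_tv,
                     rtol = ct$rtol, atol = ct$atol,
                     dt_init = attr(state, "dt_react"), n_fixed = ct$n_fixed,
                     dt_min = ct$dt_min)
  dt_react <- attr(f, "dt_last")
  for (nm in .field_names) state[[nm]] <- f[[nm]]

  # growth velocity from the post-reaction state
  vk <- as_variant(variant)
  M <- if (vk$kind == "constant_mgrow") rep(vk$mgrow_value, length(state$x))
       else growth_mode(state$G_in, state$V, p, literal = ct$literal_tv)
  if (ct$freeze_growth) {
    U <- rep(0, length(state$x)); dLdt <- 0
  } else {
    gv <- growth_velocity(state, p, M_grow = M)
    U <- gv$U; dLdt <- gv$dLdt
  }

  # advection of cellular (material) fields, upwind, CFL-subcycled
  if (!all(is.finite(U)))
    stop("non-finite growth velocity; state diverged", call. = FALSE)
  if (any(U > 0)) {
    h <- diff(state$x)
    n_sub <- max(1L, ceiling(dt * max(U) / (0.8 * min(h))))
    ha <- dt / n_sub
    for (s in seq_len(n_sub)) {
      for (nm in c("G_in", "K_in", "K_acc", "V", "n", "T", "A")) {
        adv <- if (ct$conservative_advection) c(0, diff(U * state[[nm]]) / h)
               else U * c(0, diff(state[[nm]]) / h)
        state[[nm]] <- state[[nm]] - ha * adv
      }
    }
  }

  # implicit diffusion of the extracellular species
  state$G <- .diffuse_implicit(state$G, state$x, dt, p$D_G, p$D_G_fl, p$G0,
                               p$B_L, ct$closed)
  state$K <- .diffuse_implicit(state$K, state$x, dt, p$D_K, p$D_K_fl, p$K0,
                               p$B_L, ct$closed)

  # domain growth and re-gridding
  if (!ct$freeze_growth && dLdt != 0) {
    state$L <- state$L + dt * dLdt
    state$x[length(state$x)] <- state$L
    state <- .regrid1d(state)
  }

  # clamping
  state$G_in <- pmin(pmax(state$G_in, 0), p$G_max)
  state$n <- pmin(pmax(state$n, 0), 1)
  for (nm in c("G", "K", "K_in", "K_acc", "T", "A"))
    state[[nm]] <- pmax(state[[nm]], 0)
  attr(state, "dt_react") <- dt_react
  attr(state, "dLdt") <- dLdt
  state
}

# --- driver --------------------------------------------------------------

.trace_row <- function(state, t, p, dLdt = NA_real_) {
  x <- state$x
  c(time_h = t,
    width_mm = state$L,
    dLdt_mm_per_h = dLdt,
    mean_V_mV = .trapz_mean(x, state$V),
    mean_K_mM = .trapz_mean(x, state$K),
    mean_Gin_mM = .trapz_mean(x, state$G_in),
    mean_Kin_mM = .trapz_mean(x, state$K_in),
    mean_T = .trapz_mean(x, state$T),
    mean_A = .trapz_mean(x, state$A))
}

#' Run a 1D biofilm simulation
#'
#' Advances the moving-domain model from a uniform initial condition and
#' records spatial means at regular output intervals.  The run is
#' deterministic given its configuration (the model itself has no noise).
#'
#' @param initial_width_mm starting biofilm width (mm).
#' @param p parameter set (internal units).
#' @param t_end_h simulated hours.
#' @param variant [variant_spec()] or kind string.
#' @param init named list of initial-value overrides (see [make_state1d()]).
#' @param dx nominal grid spacing (mm).
#' @param dt_max outer time step (hours).
#' @param out_every output interval (hours).
#' @param snapshot_every optional interval for full-field snapshots (hours).
#' @param ctrl stepper controls (see [step_1d()]).
#' @param stop_when optional function of the trace-so-far (data.frame);
#'   returning `TRUE` ends the run early (checked at output steps).
#' @param state optional `state1d` to resume from (overrides
#'   `initial_width_mm`/`init`).
#' @param on_blowup `"error"` (default) propagates integration failures;
#'   `"truncate"` returns the trace accumulated before the failure with a
#'   `blowup_time_h` attribute.  The leak-ablated variant is explosively
#'   unstable by construction (potassium release and depolarization reinforce
#'   each other without the moderating leak uptake), so its runs are
#'   typically truncated.
#' @return an `oscillation_trace` data.frame with columns `time_h`,
#'   `width_mm`, `dLdt_mm_per_h`, `mean_V_mV`, `mean_K_mM`, `mean_Gin_mM`,
#'   `mean_Kin_mM`, `mean_T`, `mean_A`; attributes carry snapshots and the
#'   final state.
#' @export
run_1d <- function(initial_width_mm = 0.2, p = biofilm_params(), t_end_h = 20,
                   variant = variant_spec(), init = list(), dx = 0.002,
                   dt_max = 0.01, out_every = 0.05, snapshot_every = NULL,
                   ctrl = list(), stop_when = NULL, state = NULL,
                   on_blowup = c("error", "truncate")) {
  stopifnot(t_end_h >= 0)
  on_blowup <- match.arg(on_blowup)
  variant <- as_variant(variant)
  if (is.null(state)) state <- make_state1d(initial_width_mm, p, init, dx)
  n_out <- floor(t_end_h / out_every + 1e-9)
  rows <- matrix(NA_real_, nrow = n_out + 1, ncol = 9)
  rows[1, ] <- .trace_row(state, 0, p, dLdt = growth_velocity(state, p)$dLdt)
  colnames(rows) <- names(.trace_row(state, 0, p))
  snaps <- list()
  next_snap <- if (is.null(snapshot_every)) Inf else 0
  if (next_snap == 0) { snaps[["t_0"]] <- state; next_snap <- snapshot_every }
  t <- 0
  i_out <- 1L
  stopped <- FALSE
  blowup_t <- NULL
  while (i_out <= n_out && !stopped) {
    t_target <- i_out * out_every
    while (t < t_target - 1e-12) {
      dt <- min(dt_max, t_target - t)
      st2 <- if (on_blowup == "truncate")
        tryCatch(step_1d(state, p, dt, variant, ctrl), error = function(e) e)
      else step_1d(state, p, dt, variant, ctrl)
      if (inherits(st2, "error")) { blowup_t <- t; stopped <- TRUE; break }
      state <- st2
      t <- t + dt
    }
    if (stopped) break
    rows[i_out + 1, ] <- .trace_row(state, t, p, dLdt = attr(state, "dLdt"))
    if (t >= next_snap - 1e-9) {
      snaps[[paste0("t_", i_out)]] <- state
      next_snap <- next_snap + snapshot_every
    }
    if (!is.null(stop_when)) {
      tr <- as.data.frame(rows[seq_len(i_out + 1), , drop = FALSE])
      if (isTRUE(stop_when(tr))) stopped <- TRUE
    }
    i_out <- i_out + 1L
  }
  keep <- rowSums(is.na(rows)) < ncol(rows) & is.finite(rows[, "mean_V_mV"])
  tr <- as.data.frame(rows[keep, , drop = FALSE])
  class(tr) <- c("oscillation_trace", "data.frame")
  if (!is.null(blowup_t)) attr(tr, "blowup_time_h") <- blowup_t
  attr(tr, "params") <- p
  attr(tr, "variant") <- variant
  attr(tr, "dx") <- dx
  attr(tr, "final_state") <- state
  attr(tr, "snapshots") <- snaps
  tr
}
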