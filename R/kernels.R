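# Pointwise model kernels shared by the 1D and 2D solvers.  All functions are
# vectorized over grid nodes / cells and operate in internal units
# {mm, hour, mM, mV}.

#' Ablation variant specification
#'
#' The model supports three ablations of the full system:
#' * `constant_mgrow`: the growth propensity is pinned to a constant
#'   (`mgrow_value`, 0.2 in the reference comparison) instead of responding
#'   to internal glutamate and voltage;
#' * `no_acclimation`: cells respond to the absolute extracellular potassium
#'   level rather than its change — the acclimated level is held at 0 and the
#'   leak reversal sensitivity is reduced to `delta_L_override`
#'   (6 mV/mM, 10% of the fitted value);
#' * `no_leak_uptake`: potassium does not move through the leak gates in the
#'   two potassium balance equations (the leak term is retained in the
#'   voltage equation).
#'
#' @param kind one of `"full"`, `"constant_mgrow"`, `"no_acclimation"`,
#'   `"no_leak_uptake"`.
#' @param mgrow_value constant growth propensity for `constant_mgrow`.
#' @param delta_L_override leak reversal sensitivity (mV/mM) for
#'   `no_acclimation`.
#' @return list of class `variant_spec`.
#' @export
variant_spec <- function(kind = c("full", "constant_mgrow", "no_acclimation", "no_leak_uptake"),
                         mgrow_value = 0.2, delta_L_override = 6) {
  kind <- match.arg(kind)
  structure(list(kind = kind, mgrow_value = mgrow_value,
                 delta_L_override = delta_L_override),
            class = "variant_spec")
}

as_variant <- function(variant) {
  if (is.null(variant)) return(variant_spec())
  if (inherits(variant, "variant_spec")) return(variant)
  if (is.character(variant) && length(variant) == 1) return(variant_spec(variant))
  if (is.list(variant)) return(do.call(variant_spec, variant))
  stop("cannot interpret 'variant'", call. = FALSE)
}

#' Growth propensity ("Grow Mode")
#'
#' Dimensionless propensity in \[0,1\]: the cells grow only when internal
#' glutamate is high (Hill activation against the bound `G_u`) and the cell
#' is not hyperpolarized (hyperbolic-tangent activation against `V_low`).
#' `M = T_G / (T_G + T_V)` with `T_G = G_in/(G_in + G_u)` and, by default,
#' `T_V = eta_V * (tanh(gamma_V*(V/V_low - 1)) + 1)`.
#'
#' The default groups the shape factor `eta_V` outside the `tanh(.)+1`
#' bracket, which keeps `T_V >= 0` and hence the propensity in \[0,1\]
#' everywhere.  The alternative grouping `eta_V*tanh(.) + 1` (available via
#' `literal = TRUE`) goes negative at the homeostatic initial voltage and
#' pushes the propensity outside \[0,1\]; it is retained for comparison only.
#'
#' @param G_in internal glutamate (mM), vectorized.
#' @param V membrane voltage differential (mV), vectorized.
#' @param p parameter set (internal units).
#' @param literal use the non-bracketed `T_V` grouping.
#' @return numeric vector in \[0,1\] (for the default grouping).
#' @export
growth_mode <- function(G_in, V, p, literal = FALSE) {
  T_G <- G_in / (G_in + p$G_u)
  th <- tanh(p$gamma_V * (V / p$V_low - 1))
  T_V <- if (literal) p$eta_V * th + 1 else p$eta_V * (th + 1)
  T_G / (T_G + T_V)
}

#' Reversal potentials of the potassium and leak gates
#'
#' `V_K = V_K0 + delta_K * K`; `V_L = V_L0 + delta_L * (K - K_acclimated)`:
#' the leak pathway responds to the change in extracellular potassium
#' relative to the level the cells have acclimated to, not to the absolute
#' level.
#'
#' @param K extracellular potassium (mM).
#' @param K_acclimated acclimated potassium level (mM).
#' @param p parameter set.
#' @param delta_L leak reversal sensitivity; defaults to `p$delta_L`
#'   (ablation variants override it).
#' @return list with components `V_K` and `V_L` (mV).
#' @export
reversal_potentials <- function(K, K_acclimated, p, delta_L = p$delta_L) {
  list(V_K = p$V_K0 + p$delta_K * K,
       V_L = p$V_L0 + delta_L * (K - K_acclimated))
}

#' Trans-membrane potassium exchange terms
#'
#' Hodgkin-Huxley-style gate and leak fluxes plus the active pump, all in
#' mM/hour of extracellular potassium.  Sign convention: positive means
#' potassium added to the extracellular pool.  The extracellular balance
#' receives `+J_gate + J_leak - J_pump`; the intracellular balance receives
#' the negation of each; the voltage equation receives
#' `-(J_gate + J_leak + J_pump)/F`.
#'
#' @param V voltage (mV); `n` gate openness; `V_K`,`V_L` reversal potentials
#'   (mV); `K`,`K_in` extra-/intracellular potassium (mM); `p` parameters.
#' @return list with `J_gate`, `J_leak`, `J_pump` (mM/hour).
#' @export
membrane_exchange <- function(V, n, V_K, V_L, K, K_in, p) {
  list(J_gate = p$F * p$g_K * n^4 * (V - V_K),
       J_leak = p$F * p$g_L * (V - V_L),
       J_pump = pmax(p$gamma_K * K * (p$K_max - K_in), 0))
}

#' Gate-opening kinetics (reaction part of dn/dt)
#'
#' Starvation response: the opening rate follows a Hill-like function of the
#' internal glutamate deficit `G_max - G_in` (half-saturation at
#' `G_in = G_l`, exponent `m`), so gates open when internal glutamate is low;
#' closure decays at rate `beta`.  The deficit is clamped at zero so the
#' expression stays defined for `G_in > G_max`.
#'
#' @param G_in internal glutamate (mM); `n` gate openness; `p` parameters.
#' @param n gate openness in \[0,1\].
#' @param p parameter set.
#' @return dn/dt reaction part (1/hour).
#' @export
gate_opening_rate <- function(G_in, n, p) {
  defic <- pmax(p$G_max - G_in, 0)
  h <- defic^p$m / ((p$G_max - p$G_l)^p$m + defic^p$m)
  p$alpha * h * (1 - n) - p$beta * n
}

#' Voltage-gated glutamate uptake
#'
#' `delta_G / (1 + exp(V - V_th)) * G * (G_max - G_in)`: uptake requires
#' available substrate, spare internal capacity, and sufficient polarization
#' (the exponential shuts uptake off sharply as `V` rises above `V_th`).
#' The capacity term is clamped at zero.
#'
#' @param G extracellular glutamate (mM); `G_in` internal glutamate (mM);
#'   `V` voltage (mV); `p` parameters.
#' @param G_in internal glutamate (mM).
#' @param V voltage (mV).
#' @param p parameter set.
#' @return uptake rate (mM/hour), added to `G_in` and removed from `G`.
#' @export
uptake_glutamate <- function(G, G_in, V, p) {
  p$delta_G / (1 + exp(V - p$V_th)) * G * pmax(p$G_max - G_in, 0)
}

#' Interface boundary gradient (1D Neumann closure)
#'
#' Concentration and flux continuity across the biofilm-fluid interface,
#' closed with an effective boundary layer of thickness `B_L`:
#' `D_biofilm * dc/dx = D_fluid * (c_far - c_int) / B_L` at `x = L`.
#' Returns the gradient imposed at the interface node.
#'
#' @param c_int interface concentration (mM); `c_far` far-field value (mM).
#' @param c_far far-field (inlet) concentration (mM).
#' @param D_biofilm,D_fluid diffusivities (mm^2/hour).
#' @param B_L boundary-layer thickness (mm).
#' @return gradient dc/dx at the interface (mM/mm).
#' @export
boundary_flux <- function(c_int, c_far, D_biofilm, D_fluid, B_L) {
  D_fluid * (c_far - c_int) / (B_L * D_biofilm)
}

# Full reaction right-hand side (all local, non-transport terms) for the
# field set f = list(G, K, G_in, K_in, K_acc, V, n, T, A) of equal-length
# vectors.  Returns derivative vectors in the same order plus the derived
# M_grow.  This single kernel backs the 1D stepper, the 2D stepper and the
# well-mixed ODE oracle, so the model physics has one authoritative home.
reaction_rhs <- function(f, p, variant = variant_spec(), literal_tv = FALSE) {
  vk <- as_variant(variant)
  K_acc <- if (vk$kind == "no_acclimation") 0 * f$K_acc else f$K_acc
  dL <- if (vk$kind == "no_acclimation") vk$delta_L_override else p$delta_L
  rp <- reversal_potentials(f$K, K_acc, p, delta_L = dL)
  J <- membrane_exchange(f$V, f$n, rp$V_K, rp$V_L, f$K, f$K_in, p)
  leak_K <- if (vk$kind == "no_leak_uptake") 0 else J$J_leak
  upt <- uptake_glutamate(f$G, f$G_in, f$V, p)
  M <- if (vk$kind == "constant_mgrow") rep(vk$mgrow_value, length(f$G_in))
       else growth_mode(f$G_in, f$V, p, literal = literal_tv)
  list(
    G     = -upt,
    K     = J$J_gate + leak_K - J$J_pump,
    G_in  = upt - p$gamma_G * f$G_in * (M + p$r_b),
    K_in  = -J$J_gate - leak_K + J$J_pump,
    K_acc = if (vk$kind == "no_acclimation") 0 * f$K_acc else p$eta_K * (f$K - f$K_acc),
    V     = -p$g_K * f$n^4 * (f$V - rp$V_K) - p$g_L * (f$V - rp$V_L) - J$J_pump / p$F,
    n     = gate_opening_rate(f$G_in, f$n, p),
    T     = p$alpha_T / (1 + exp(p$g_T * (f$V - p$V_0T))) - p$gamma_T * f$T,
    A     = p$alpha_A * f$K - p$gamma_A * f$A,
    M_grow = M
  )
}

# Names of the prognostic fields, in kernel order.
.field_names <- c("G", "K", "G_in", "K_in", "K_acc", "V", "n", "T", "A")

# Adaptive explicit (embedded Euler/Heun) integration of the reaction system
# over an interval dt.  Error control spans every field (the leak-gate
# coupling makes extracellular K itself stiff: d(dK/dt)/dK ~ -F*g_L*delta_L);
# fixed-step mode (n_fixed substeps) gives a smooth discrete
# parameter-to-solution map for finite-difference sensitivity work.
react_substep <- function(f, p, dt, variant, literal_tv = FALSE,
                          rtol = 1e-3, atol = 1e-4, dt_init = NULL,
                          n_fixed = NULL, dt_min = 1e-9) {
  if (!is.null(n_fixed)) {
    h <- dt / n_fixed
    for (i in seq_len(n_fixed)) {
      k1 <- reaction_rhs(f, p, variant, literal_tv)
      f1 <- f
      for (nm in .field_names) f1[[nm]] <- f[[nm]] + h * k1[[nm]]
      k2 <- reaction_rhs(f1, p, variant, literal_tv)
      for (nm in .field_names) f[[nm]] <- f[[nm]] + (h / 2) * (k1[[nm]] + k2[[nm]])
    }
    attr(f, "dt_last") <- h
    return(f)
  }
  t <- 0
  h <- if (is.null(dt_init)) dt / 4 else min(dt_init, dt)
  while (t < dt) {
    h <- min(h, dt - t)
    k1 <- reaction_rhs(f, p, variant, literal_tv)
    f1 <- f
    for (nm in .field_names) f1[[nm]] <- f[[nm]] + h * k1[[nm]]
    k2 <- reaction_rhs(f1, p, variant, literal_tv)
    # Heun solution and embedded error estimate (Heun - Euler)/2, all fields
    err <- 0
    for (nm in .field_names) {
      e <- max(abs(k2[[nm]] - k1[[nm]])) * h / 2
      scl <- atol + rtol * max(abs(f[[nm]]), 1)
      err <- max(err, e / scl)
    }
    if (!is.finite(err)) {
      bad <- .field_names[vapply(.field_names, function(nm) any(!is.finite(k1[[nm]])) || any(!is.finite(k2[[nm]])), logical(1))]
      stop("non-finite derivative in field(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    if (err <= 1) {
      for (nm in .field_names) f[[nm]] <- f[[nm]] + (h / 2) * (k1[[nm]] + k2[[nm]])
      t <- t + h
      h <- h * min(4, max(0.5, 0.9 / sqrt(max(err, 1e-8))))
    } else {
      h <- h * max(0.2, 0.9 / sqrt(err))
      if (h < dt_min)
        stop("reaction sub-step underflow (dt < ", dt_min, "); state too stiff", call. = FALSE)
    }
  }
  attr(f, "dt_last") <- h
  f
}
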