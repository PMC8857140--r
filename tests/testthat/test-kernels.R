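test_that("growth propensity matches closed-form evaluations and bounds", {
  p <- p_default
  # symmetry point: G_in = G_u and V = V_low make both activations half/neutral
  expect_equal(growth_mode(p$G_u, p$V_low, p), 0.5 / (0.5 + p$eta_V))
  expect_equal(growth_mode(0, -156, p), 0)
  # independent closed-form evaluation at the homeostatic point
  T_G <- 20 / (20 + 18)
  T_V <- 20 * (tanh(20 * (-156 / -175 - 1)) + 1)
  expect_equal(growth_mode(20, -156, p), T_G / (T_G + T_V), tolerance = 1e-12)
  expect_equal(growth_mode(20, -156, p), 0.5063, tolerance = 1e-3)
  # monotone in G_in; rising with V away from the hyperpolarized cutoff
  # (growth shuts off for V below V_low and recovers as cells repolarize)
  g <- seq(0, 20, length.out = 30)
  expect_true(all(diff(growth_mode(g, -156, p)) > 0))
  v <- seq(-250, -100, length.out = 40)
  expect_true(all(diff(growth_mode(15, v, p)) > 0))
  expect_lt(growth_mode(15, -250, p), 0.02)   # hyperpolarized: no growth
  expect_true(all(growth_mode(runif(50, 0, 20), runif(50, -400, 0), p) >= 0))
  expect_true(all(growth_mode(runif(50, 0, 20), runif(50, -400, 0), p) <= 1))
  # the non-bracketed grouping goes negative at homeostasis (why it is not
  # the default)
  expect_lt(growth_mode(20, -156, p, literal = TRUE), 0)
})

test_that("reversal potentials follow their affine laws", {
  p <- p_default
  rp <- reversal_potentials(8, 8, p)
  expect_equal(rp$V_K, -380 + 8)
  expect_equal(rp$V_L, -156)          # zero acclimation gap
  rp2 <- reversal_potentials(10, 8, p)
  expect_equal(rp2$V_L, -156 + 60 * 2)
  # variant override of the leak sensitivity
  rp3 <- reversal_potentials(10, 8, p, delta_L = 6)
  expect_equal(rp3$V_L, -156 + 12)
})

test_that("membrane exchange terms have the published forms and signs", {
  p <- p_default
  J <- membrane_exchange(V = -156, n = 0.1, V_K = -372, V_L = -156,
                         K = 8, K_in = 300, p)
  expect_equal(J$J_gate, 5.6 * 180 * 1e-4 * 216)   # 21.7728 mM/hour
  expect_equal(J$J_leak, 0)
  expect_equal(J$J_pump, 0)                        # store at the threshold
  # zero crossings
  expect_equal(membrane_exchange(-372, 0.5, -372, -150, 8, 100, p)$J_gate, 0)
  # pump never releases
  for (K_in in c(100, 250, 301, 500)) {
    J <- membrane_exchange(-156, 0.1, -372, -156, 8, K_in, p)
    expect_gte(J$J_pump, 0)
  }
  expect_equal(membrane_exchange(-156, 0.1, -372, -156, 8, 400, p)$J_pump, 0)
})

test_that("gate opening kinetics: closed-gate decay, half-saturation, root", {
  p <- p_default
  expect_equal(gate_opening_rate(20, 0.5, p), -2.5 * 0.5)
  # half-saturation of the deficit Hill function at G_in = G_l
  h_at_Gl <- (20 - 10)^2 / ((20 - 10)^2 + (20 - 10)^2)
  expect_equal(h_at_Gl, 0.5)
  expect_equal(gate_opening_rate(10, 0, p), 5 * 0.5)
  # steady openness at full starvation, found by an independent root search
  root <- uniroot(function(n) gate_opening_rate(0, n, p), c(0, 1),
                  tol = 1e-12)$root
  expect_equal(root, 4 / 6.5, tolerance = 1e-8)
  # rate keeps n in [0, 1]
  expect_gte(gate_opening_rate(0, 0, p), 0)
  expect_lte(gate_opening_rate(0, 1, p), 0)
  # deficit clamp: G_in above G_max behaves like a closed gate
  expect_equal(gate_opening_rate(25, 0.3, p), -2.5 * 0.3)
})

test_that("glutamate uptake needs substrate, spare capacity and polarization", {
  p <- p_default
  expect_equal(uptake_glutamate(0, 10, -156, p), 0)
  expect_equal(uptake_glutamate(30, 20, -156, p), 0)   # saturated cell
  expect_gt(uptake_glutamate(30, 10, -156, p), 0)
  # sharp shut-off above V_th
  expect_lt(uptake_glutamate(30, 10, -130, p),
            1e-6 * uptake_glutamate(30, 10, -156, p))
  # extreme depolarization must not overflow to NaN
  expect_equal(uptake_glutamate(30, 10, 1e4, p), 0)
})

test_that("interface boundary gradient satisfies flux continuity", {
  p <- p_default
  expect_equal(boundary_flux(30, 30, p$D_G, p$D_G_fl, p$B_L), 0)
  gr <- boundary_flux(20, 30, p$D_G, p$D_G_fl, p$B_L)
  # continuity: biofilm-side flux equals boundary-layer flux
  expect_equal(p$D_G * gr, p$D_G_fl * (30 - 20) / p$B_L)
  expect_equal(p$D_G * gr, 18 / 24)     # 18 mM mm/day in table units
  expect_lt(boundary_flux(35, 30, p$D_G, p$D_G_fl, p$B_L), 0)
})

test_that("ablation variants modify exactly the terms they claim", {
  p <- p_default
  f <- list(G = 25, K = 12, G_in = 15, K_in = 280, K_acc = 9, V = -150,
            n = 0.3, T = 1, A = 2)
  full <- biofilmosc:::reaction_rhs(f, p, variant_spec("full"))
  nl <- biofilmosc:::reaction_rhs(f, p, variant_spec("no_leak_uptake"))
  rp <- reversal_potentials(f$K, f$K_acc, p)
  J <- membrane_exchange(f$V, f$n, rp$V_K, rp$V_L, f$K, f$K_in, p)
  # leak removed from both potassium balances only
  expect_equal(nl$K, full$K - J$J_leak)
  expect_equal(nl$K_in, full$K_in + J$J_leak)
  expect_equal(nl$V, full$V)            # retained in the voltage equation
  expect_equal(nl$G_in, full$G_in)
  cm <- biofilmosc:::reaction_rhs(f, p, variant_spec("constant_mgrow",
                                                     mgrow_value = 0.2))
  expect_equal(cm$M_grow, 0.2)
  expect_equal(cm$G_in, with(f, uptake_glutamate(G, G_in, V, p)) -
                 p$gamma_G * f$G_in * (0.2 + p$r_b))
  na <- biofilmosc:::reaction_rhs(f, p, variant_spec("no_acclimation"))
  expect_equal(na$K_acc, 0)
  rp6 <- reversal_potentials(f$K, 0, p, delta_L = 6)
  expect_equal(na$V, -p$g_K * f$n^4 * (f$V - rp6$V_K) -
                 p$g_L * (f$V - rp6$V_L) -
                 max(p$gamma_K * f$K * (p$K_max - f$K_in), 0) / p$F)
})
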