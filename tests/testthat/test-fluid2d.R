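test_that("empty-channel flow reproduces the Poiseuille closed form", {
  p <- p_default
  g <- make_grid2d(3, 3, 0.05)
  phi <- matrix(1, g$nx, g$ny)
  fl <- solve_pressure_velocity(g, phi, p, u0 = 90)
  u_exact <- outer(rep(1, g$nx), 90 * (1 - ((g$y - 1.5) / 1.5)^2))
  expect_lt(max(abs(fl$u - u_exact)) / 90, 0.02)
  expect_lt(max(abs(fl$v)) / 90, 1e-8)
  # pressure linear in x: second differences vanish
  Pmid <- fl$P[, round(g$ny / 2)]
  expect_lt(max(abs(diff(diff(Pmid)))), 1e-6 * abs(Pmid[1]))
  expect_equal(Pmid[1] - Pmid[g$nx],
               2 * p$mu * 90 / 1.5^2 * (g$Lx - g$h), tolerance = 0.01)
  # zero forcing
  fl0 <- solve_pressure_velocity(g, phi, p, u0 = 0)
  expect_equal(max(abs(fl0$u)) + max(abs(fl0$v)) + max(abs(fl0$P)), 0)
})

test_that("no-slip holds on the interface of an immersed biofilm", {
  p <- p_default
  g <- make_grid2d(3, 3, 0.05)
  mask <- generate_fixture(shape_spec("wall_half_disc", r = 0.5), g)
  phi <- phi_from_mask(mask, g)
  fl <- solve_pressure_velocity(g, phi, p, u0 = 90)
  expect_equal(max(abs(fl$u[mask])), 0)
  expect_equal(max(abs(fl$v[mask])), 0)
  # fluid speed in the first ring of cells around the biofilm stays small
  ring <- !mask & (abs(phi) < 1.5 * g$h)
  expect_lt(max(sqrt(fl$u[ring]^2 + fl$v[ring]^2)) / 90, 0.15)
  # occlusion is a geometry error
  occl <- matrix(FALSE, g$nx, g$ny); occl[30, ] <- TRUE
  expect_error(solve_pressure_velocity(g, phi_from_mask(occl, g), p, u0 = 90),
               "occlude")
})

test_that("steady transport with no sources carries the inlet value", {
  p <- p_default
  g <- make_grid2d(3, 3, 0.05)
  phi <- matrix(1, g$nx, g$ny)
  fl <- solve_pressure_velocity(g, phi, p, u0 = 90)
  G <- fluid_transport_steady(g, phi, fl, p, "G")
  expect_equal(range(G), c(30, 30), tolerance = 1e-6)
  # with a (non-consuming) biofilm the maximum principle still holds
  mask <- generate_fixture(shape_spec("wall_half_disc", r = 0.4), g)
  phi2 <- phi_from_mask(mask, g)
  fl2 <- solve_pressure_velocity(g, phi2, p, u0 = 90)
  K <- fluid_transport_steady(g, phi2, fl2, p, "K")
  expect_true(all(K >= 8 - 1e-8 & K <= 8 + 1e-8))
})

test_that("uniform diffusivities reduce the interface scheme to the standard one", {
  p <- biofilm_params(list(D_K = 4.97))     # biofilm D equals fluid D
  g <- make_grid2d(0.4, 0.4, 0.02)
  phi <- phi_from_mask(outer(rep(TRUE, g$nx), g$y < 0.2), g)
  fl <- solve_pressure_velocity(g, phi, p, u0 = 0)
  sys_mixed <- biofilmosc:::.transport_system(g, phi, fl, p$D_K, p$D_K_fl,
                                              8, 0.01, "wall", "far_field",
                                              quasi_steady_fluid = FALSE)
  sys_unif <- biofilmosc:::.transport_system(g, matrix(1, g$nx, g$ny), fl,
                                             p$D_K_fl, p$D_K_fl, 8, 0.01,
                                             "wall", "far_field",
                                             quasi_steady_fluid = FALSE)
  expect_lt(max(abs(sys_mixed$A - sys_unif$A)), 1e-10)
})

test_that("closed transient transport conserves mass to solver precision", {
  p <- p_default
  g <- make_grid2d(0.4, 0.4, 0.02)
  mask <- generate_fixture(shape_spec("disc", r = 0.1, center = c(0.2, 0.2)), g)
  phi <- phi_from_mask(mask, g)
  fl <- solve_pressure_velocity(g, phi, p, u0 = 0)
  sys <- biofilmosc:::.transport_system(g, phi, fl, p$D_K, p$D_K_fl, 8,
                                        0.01, bc_left = "wall",
                                        bc_top = "wall",
                                        quasi_steady_fluid = FALSE)
  set.seed(1)
  K <- matrix(8 + runif(g$nx * g$ny, 0, 20), g$nx, g$ny)
  tot0 <- sum(K)
  for (i in 1:20) K <- biofilmosc:::.transport_step(sys, K)
  expect_equal(sum(K), tot0, tolerance = 1e-10)
})

test_that("two-layer slab with a uniform biofilm sink reaches the closed form", {
  p <- p_default
  h <- 0.01
  g <- make_grid2d(0.2, 0.6, h)
  d <- 0.2; H <- 0.6
  inside <- matrix(rep(g$y < d, each = g$nx), g$nx)
  phi <- phi_from_mask(inside, g)
  fl <- solve_pressure_velocity(g, phi, p, u0 = 0)
  dt <- 0.05
  sys <- biofilmosc:::.transport_system(g, phi, fl, p$D_G, p$D_G_fl, 30,
                                        dt, bc_left = "wall",
                                        bc_top = "far_field",
                                        quasi_steady_fluid = FALSE)
  s <- 2                                     # sink, mM/hour, biofilm only
  G <- matrix(30, g$nx, g$ny)
  for (i in 1:600) {
    G[inside] <- G[inside] - dt * s
    G <- biofilmosc:::.transport_step(sys, G)
  }
  # analytic steady state: parabola in the biofilm, linear in the fluid,
  # flux continuity at the interface, far-field value at the top
  mid <- round(g$nx / 2)
  y <- g$y
  G_d <- 30 - s * d * (H - d) / p$D_G_fl
  exact <- ifelse(y < d, G_d - s * (d^2 - y^2) / (2 * p$D_G),
                  30 - s * d * (H - y) / p$D_G_fl)
  expect_lt(max(abs(G[mid, ] - exact)), 0.35)
  # flux continuity at the interface face: the biofilm-side flux sampled a
  # cell below the face is corrected for the parabolic profile (the sink
  # accumulates s per unit depth); the fluid-side profile is linear
  i_in <- max(which(y < d)) - 1
  grad_in <- (G[mid, i_in + 1] - G[mid, i_in]) / h
  y_mid <- (y[i_in] + y[i_in + 1]) / 2
  flux_bio <- p$D_G * grad_in + s * (d - y_mid)
  i_fl <- min(which(y >= d)) + 1
  flux_fl <- p$D_G_fl * (G[mid, i_fl + 1] - G[mid, i_fl]) / h
  expect_lt(abs(flux_bio - flux_fl), 0.03 * s * d)
})
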