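test_that("source flux follows the free-cortisol gradient law", {
  p <- default_p
  # hand arithmetic: k_DE * (alpha*C_blood - C_ISF) * V_p
  expect_equal(source_flux(3.55e-4, 0, p),
               1.01e-3 * (0.05 * 3.55e-4) * 3.02e-13, tolerance = 1e-12)
  expect_equal(source_flux(3.55e-4, 0, p), 5.414e-21, tolerance = 1e-3)
  # equilibrium and no-free-cortisol limits
  expect_equal(source_flux(3.55e-4, 0.05 * 3.55e-4, p), 0)
  expect_equal(source_flux(3.55e-4, 0, update_parameters(p, alpha = 0)), 0)
  # back-flux when ISF exceeds the free blood concentration
  expect_lt(source_flux(1e-5, 1e-3, p), 0)
  expect_error(source_flux(-1, 0, p), "non-negative")
  expect_error(source_flux(1, -1, p), "non-negative")
})

test_that("Starling filtration matches hand arithmetic and is linear in L_pc", {
  p <- default_p
  expect_equal(water_flow(p), 3.2175e-16, tolerance = 1e-12)
  expect_equal(water_flow(update_parameters(p, P_c = -3)), 0)
  expect_equal(water_flow(update_parameters(p, L_pc = 2 * p$L_pc)),
               2 * water_flow(p))
})

test_that("compartment velocities follow from the water flow", {
  p <- default_p
  Q <- water_flow(p)
  expect_equal(isf_velocity(Q, p), 1.4625e-8, tolerance = 1e-4)
  expect_equal(isf_velocity(0, p), 0)
  expect_equal(isf_velocity(Q, update_parameters(p, A_ISF = p$A_ISF / 2)),
               2 * isf_velocity(Q, p))
  expect_error(isf_velocity(NaN, p), "finite")

  gv <- gland_velocity(Q, 1, p)
  expect_equal(gv$u_sg, 1.6416e-5, tolerance = 1e-4)
  expect_equal(gv$u_sg_n, 1, tolerance = 1e-12)  # reference velocity anchors u_sg_n = 1
  expect_equal(gland_velocity(Q, 0, p)$u_sg, 0)
  expect_equal(gland_velocity(Q, 3, p)$u_sg, 3 * gv$u_sg)
  expect_error(gland_velocity(Q, -1, p), "non-negative")
})

test_that("gland-wall flux is Fickian and antisymmetric", {
  p <- default_p
  expect_equal(gland_wall_flux(1e-6, 0, p), 2.84e-10 * 1e-6 / 5e-5,
               tolerance = 1e-12)
  expect_equal(gland_wall_flux(1e-6, 0, p), 5.68e-12, tolerance = 1e-12)
  expect_equal(gland_wall_flux(3e-6, 3e-6, p), 0)
  expect_equal(gland_wall_flux(1e-6, 2e-6, p), -gland_wall_flux(2e-6, 1e-6, p))
  expect_error(gland_wall_flux(-1e-6, 0, p), "non-negative")
})

test_that("entry dilution divides by the water-to-cortisol flow ratio", {
  p <- default_p
  expect_equal(dilute_at_entry(21e-6, 1, p), 1e-6, tolerance = 1e-15)
  expect_equal(dilute_at_entry(21e-6, 0, p), 21e-6)
  u <- seq(0, 4, by = 0.5)
  expect_true(all(diff(dilute_at_entry(21e-6, u, p)) < 0))
  expect_error(dilute_at_entry(1e-6, -1, p), "non-negative")
})

test_that("steady-state solution vanishes without blood or free cortisol", {
  expect_equal(simulate_steady_state(0, 1, default_p, default_d)$C_sweat_surface, 0)
  p0 <- update_parameters(default_p, alpha = 0)
  expect_equal(simulate_steady_state(355, 1, p0, default_d)$C_sweat_surface, 0)
  expect_error(simulate_steady_state(-1, 1, default_p, default_d), "non-negative")
  expect_error(simulate_steady_state(355, -1, default_p, default_d), "non-negative")
})

test_that("surface sweat cortisol is linear in blood cortisol and alpha", {
  probes <- c(50, 150, 355, 600, 1000)
  out <- vapply(probes, surface_nmoll, numeric(1))
  fit <- lm(out ~ probes)
  expect_gt(summary(fit)$r.squared, 1 - 1e-6)
  expect_lt(abs(coef(fit)[1]) / max(out), 1e-9)  # through the origin
  # exact doubling
  expect_equal(surface_nmoll(710), 2 * surface_nmoll(355), tolerance = 1e-10)
  # proportionality in alpha
  alphas <- c(0.02, 0.048, 0.05, 0.113, 0.2)
  outa <- vapply(alphas, function(a) {
    surface_nmoll(355, p = update_parameters(default_p, alpha = a))
  }, numeric(1))
  expect_equal(outa, outa[3] * alphas / 0.05, tolerance = 1e-9)
})

test_that("enzymatic conversion and entry dilution attenuate the output", {
  s_vals <- c(0, 1e-3, 5e-3, 1e-2)
  out_s <- vapply(s_vals, function(S) {
    surface_nmoll(355, p = update_parameters(default_p, S_enzyme = S))
  }, numeric(1))
  expect_true(all(diff(out_s) < 0))
  k_vals <- c(0, 5, 20, 60)
  out_k <- vapply(k_vals, function(K) {
    surface_nmoll(355, p = update_parameters(default_p, K_wc = K))
  }, numeric(1))
  expect_true(all(diff(out_k) < 0))
})

test_that("transient integration and direct steady solve agree", {
  for (u in c(0, 1, 2.5)) {
    tr <- simulate_steady_state(355, u, default_p, default_d)
    di <- simulate_steady_state(355, u, default_p, default_d, method = "direct")
    expect_true(tr$converged)
    expect_equal(tr$C_sweat_surface, di$C_sweat_surface, tolerance = 1e-6)
  }
})

test_that("the discretization is grid-converged at defaults", {
  coarse <- surface_nmoll(355)
  fine <- surface_nmoll(355, d = discretization(n_ISF = 2 * default_d$n_ISF,
                                                n_sg = 2 * default_d$n_sg))
  expect_lt(abs(fine - coarse) / fine, 0.01)
})

test_that("solver matches an independent dense-grid oracle", {
  # pure diffusion balance in the gland: no sweating, no enzymatic sink
  pkg0 <- surface_nmoll(355, u_sweat_n = 0)
  orc0 <- oracle_steady_surface(355, 0, default_p)
  expect_lt(abs(pkg0 - orc0) / orc0, 0.01)
  # operating point with advection, dilution and sink active
  pS <- update_parameters(default_p, S_enzyme = 5e-3)
  pkg1 <- surface_nmoll(355, p = pS)
  orc1 <- oracle_steady_surface(355, 1, pS)
  expect_lt(abs(pkg1 - orc1) / orc1, 0.01)
})

test_that("cortisol mass is conserved through the transport chain", {
  # with the enzymatic sink off, molar inflow from the capillary source
  # equals the advective molar outflow at the duct outlet
  res <- simulate_steady_state(355, 1, default_p, default_d, method = "direct")
  p <- default_p
  dy_I <- p$L_ISF / (default_d$n_ISF - 1)
  src_density <- p$k_DE * (p$alpha * nmol_l_to_mol_m3(355) -
                             res$C_ISF_profile) * p$V_p / p$V_ISF
  inflow <- sum(src_density) * p$A_ISF * dy_I
  outflow <- res$u_sg * p$A_sg *
    res$C_sg_profile[length(res$C_sg_profile)]
  expect_lt(abs(inflow - outflow) / inflow, 0.02)
})

test_that("steady profiles are non-negative across parameter perturbations", {
  set.seed(42)
  base <- unlist(default_p)
  perturbable <- setdiff(names(base), c("alpha"))
  for (i in 1:12) {
    fac <- runif(length(base), 0.8, 1.2)
    vals <- as.list(base * fac)
    vals$alpha <- min(vals$alpha, 1)
    pp <- do.call(transport_parameters, vals)
    res <- simulate_steady_state(runif(1, 10, 800), runif(1, 0, 3), pp,
                                 default_d, method = "direct")
    expect_true(all(res$C_ISF_profile >= 0))
    expect_true(all(res$C_sg_profile >= 0))
    expect_gte(res$C_sweat_surface, 0)
  }
})

test_that("model properties hold across a 10x range of the free geometry", {
  for (L_I in c(3e-5, 3e-4)) {
    for (L_g in c(6e-4, 6e-3)) {
      pp <- update_parameters(default_p, L_ISF = L_I, L_sg = L_g)
      expect_equal(surface_nmoll(710, p = pp), 2 * surface_nmoll(355, p = pp),
                   tolerance = 1e-9)
      expect_gt(surface_nmoll(355, p = pp), 0)
      orc <- oracle_steady_surface(355, 1, pp)
      expect_lt(abs(surface_nmoll(355, p = pp) - orc) / orc, 0.01)
    }
  }
})

test_that("non-convergence is reported, never silent", {
  d_hopeless <- discretization(steady_tol = 1e-15, max_time = 5)
  res <- simulate_steady_state(355, 1, default_p, d_hopeless)
  expect_false(res$converged)
})

test_that("the surface readout equals the outlet node of the duct profile", {
  res <- simulate_steady_state(355, 1, default_p, default_d, method = "direct")
  expect_identical(res$C_sweat_surface,
                   res$C_sg_profile[length(res$C_sg_profile)])
  expect_equal(sweat_surface_nmol_l(res), res$C_sweat_surface * 1e6)
})
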