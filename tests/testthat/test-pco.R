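test_that("projected objective gradient direction behaves on chain, cycle and dead ends", {
  net <- chain_net()
  expect_equal(objective_gradient_direction(net, nullspace_basis(net)),
               c(0.5, 0.5), tolerance = 1e-12)

  cyc <- generate_network("cycle", n_free = 3, n_fixed = 0, n_reactions = 3,
                          seed = 2)
  cyc$reactions$growth <- rep(TRUE, 3)
  yg <- objective_gradient_direction(cyc, nullspace_basis(cyc))
  expect_equal(yg / yg[1], rep(1, 3), tolerance = 1e-10)

  de <- dead_end_net()
  expect_error(objective_gradient_direction(de, nullspace_basis(de)),
               "unreachable")
})

test_that("initialization aligns driving forces with the growth direction", {
  net <- chain_net(log_K = c(2, 3), eta_A = 4, eta_C = -4)
  ns <- nullspace_basis(net)
  init <- pco_initialize(net, ns)
  expect_lt(init$lsq_residual, 1e-8)
  expect_true(all(init$slack >= 0))
  expect_true(all(init$eta0[!net$metabolites$fixed] <= net$eta_max + 1e-9))
  # favorable chain: initial fluxes point toward growth
  expect_true(all(init$y0 > 0))
  # linearity in zeta
  init2 <- pco_initialize(net, ns, pco_settings(zeta = 20))
  expect_equal(init2$y0, 2 * init$y0, tolerance = 1e-9)
})

test_that("relaxed program enumerates the expected constraints and is feasible at a zero-residual start", {
  net <- chain_net(log_K = c(2, 3), eta_A = 4, eta_C = -4)
  ns <- nullspace_basis(net)
  settings <- pco_settings()
  init <- pco_initialize(net, ns, settings)
  prog <- build_pco_program(net, ns, settings, init)
  expect_identical(prog$counts$eta_bounds, 1L)
  expect_identical(prog$counts$eta_fixed, 2L)
  expect_identical(prog$counts$bigM_pair, 4L)
  expect_identical(prog$counts$direction, 2L)
  expect_identical(prog$counts$definitions_h, 2L)
  expect_identical(prog$counts$definitions_u, 2L)

  z <- prog$pieces(prog$x0)
  # with residual ~ 0 the big-M and direction constraints hold at the start
  expect_true(all(z$c1 > -1e-8))
  expect_true(all(z$c2 > -1e-8))
  expect_true(all(z$c3 > -1e-8))
  # switching variable sits on the branch of the initial flux sign; with u
  # near 1 the backward inequality is relaxed by M while the forward one is
  # the bare force bound
  expect_equal(z$U$u, (sign(init$y0) + 1) / 2, tolerance = 1e-9)
  expect_equal(z$c2, z$H$h - z$dgk + (1 - z$U$u) * settings$big_M,
               tolerance = 1e-12)
})

test_that("equilibrium boundary conditions admit only zero growth flux", {
  fit <- pco(equilibrium_chain())
  expect_lt(abs(fit$objective), 1e-6)
  expect_true(fit$certificate$feasible)
})

test_that("solver matches the brute-force oracle on a downhill chain", {
  net <- chain_net(log_K = c(1, 0.5), eta_A = 5, eta_C = -5,
                   eta_max = concentration_to_log_count(1))
  fit <- pco(net)
  orc <- brute_force_pco(net)
  expect_equal(fit$objective, orc$objective, tolerance = 1e-4)
  expect_true(fit$solver_status %in% c("optimal", "acceptable"))
})

test_that("competing-branch networks shut down the non-growth branch", {
  net <- generate_network("branch", n_free = 1, n_fixed = 3, n_reactions = 3,
                          potential_scale = 2, drive = 4, seed = 2)
  fit <- pco(net)
  orc <- brute_force_pco(net)
  expect_equal(fit$objective, orc$objective, tolerance = 1e-4)
  # the branch into the non-growth sink is regulated toward zero
  non_growth_branch <- which(!net$reactions$growth)[2]
  expect_lt(abs(fit$y[3]), 1e-5 * max(abs(fit$y)))
})

test_that("accepted solutions never regress below the feasible scaling of the start", {
  for (seed in c(5L, 19L)) {
    net <- generate_network("chain", n_free = 1, n_fixed = 2,
                            potential_scale = 2, drive = 3, seed = seed)
    ns <- nullspace_basis(net)
    init <- pco_initialize(net, ns)
    fit <- pco(net)
    if (init$lsq_residual < 1e-8 &&
        fit$solver_status %in% c("optimal", "acceptable")) {
      t_ <- pcoflux:::feasible_scaling(net, init$eta0, init$y0)
      start_obj <- sum((t_ * init$y0)[net$reactions$growth])
      expect_gte(fit$objective, start_obj - 1e-7)
    }
  }
})

test_that("relaxing the concentration cap never shrinks the optimum", {
  net_lo <- chain_net(log_K = c(3, 2), eta_A = 4, eta_C = -4, eta_max = 6)
  net_hi <- chain_net(log_K = c(3, 2), eta_A = 4, eta_C = -4, eta_max = 9)
  expect_gte(pco(net_hi)$objective, pco(net_lo)$objective - 1e-6)
})

test_that("solution validation flags controlled corruption", {
  net <- chain_net(log_K = c(1, 1), eta_A = 3, eta_C = -3)
  exact <- chain_exact_state(net)
  v <- validate_solution(exact, net, tol = 1e-10)
  expect_true(attr(v, "ok"))

  bad <- exact
  bad$alpha[1] <- bad$alpha[1] * (1 - 1e-2)
  vb <- validate_solution(bad, net, tol = 1e-8)
  expect_false(vb$pass[vb$check == "stationarity"])
  expect_true(vb$pass[vb$check == "steady_state"])
  expect_true(vb$pass[vb$check == "direction"])
  expect_true(vb$pass[vb$check == "eta_bound"])
  expect_true(vb$pass[vb$check == "alpha_bounds"])
})

test_that("fitted-model interface exposes activities, fluxes and residuals", {
  net <- chain_net(log_K = c(1, 0.5), eta_A = 4, eta_C = -4)
  fit <- pco(net)
  expect_s3_class(fit, "pco_fit")
  expect_named(coef(fit), net$reactions$id)
  expect_true(all(coef(fit) >= -1e-9 & coef(fit) <= 1 + 1e-9))
  expect_equal(as.numeric(fitted(fit)), as.numeric(fit$y))
  expect_lt(max(abs(residuals(fit))), 1e-6 * max(1, max(abs(fit$y))))
  s <- summary(fit)
  expect_identical(s$reactions$reaction, net$reactions$id)
  expect_output(print(fit), "Pathway-controlled")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
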