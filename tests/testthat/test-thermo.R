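test_that("forces and fluxes follow the Marcelin law", {
  # equilibrium at unit counts
  net <- chain_net(log_K = c(0, 0), eta_A = 0, eta_C = 0)
  eta <- assemble_eta(net, 0)
  expect_equal(reaction_force(eta, net), c(1, 1))
  expect_equal(net_flux(reaction_force(eta, net)), c(0, 0))

  # A <-> B with K = 2, n_A = 4, n_B = 1: f = K n_A / n_B = 8
  net2 <- chain_net(log_K = c(log(2), 0), eta_A = log(4), eta_C = 0)
  f <- reaction_force(assemble_eta(net2, 0), net2, j = 1)
  expect_equal(f, 8, tolerance = 1e-12)
  expect_equal(net_flux(8, 1), 7.875)
  expect_equal(net_flux(8, 0), 0)
  expect_equal(net_flux(1, 0.37), 0)
  expect_error(net_flux(-1, 1), "positive")
  expect_error(net_flux(2, 1.5), "\\[0, 1\\]")
})

test_that("log-space flux agrees with the force composition and is linear in alpha", {
  net <- generate_network("random_sparse", n_free = 2, n_fixed = 3,
                          n_reactions = 5, seed = 8)
  set.seed(1)
  for (rep in 1:20) {
    eta <- assemble_eta(net, runif(2, -3, 3))
    alpha <- runif(n_a <- nrow(net$reactions))
    expect_equal(log_space_flux(eta, net, alpha),
                 net_flux(reaction_force(eta, net), alpha),
                 tolerance = 1e-12)
    expect_equal(log_space_flux(eta, net, 2 * (alpha / 2)),
                 2 * log_space_flux(eta, net, alpha / 2), tolerance = 1e-14)
  }
})

test_that("flux inversion matches its frozen closed form and both algebraic forms agree", {
  expect_equal(y_hat(0, 1, 0.7), 0.7)
  expect_equal(y_hat(3, 1, 0), -1.1947632172871097, tolerance = 1e-10)
  expect_equal(y_hat(3, 1, 0, form = "direct"), -1.1947632172871097,
               tolerance = 1e-10)
  set.seed(2)
  y <- runif(2000, -5, 5); a <- 10^runif(2000, -3, 0); k <- runif(2000, -4, 4)
  expect_equal(y_hat(y, a, k), y_hat(y, a, k, form = "direct"),
               tolerance = 1e-10)
  # antisymmetry in the flux
  expect_equal(y_hat(-y, a, 0), -y_hat(y, a, 0), tolerance = 1e-12)
  expect_error(y_hat(1, 0), "no solution")
  degen <- y_hat(0, 0, 1.3)
  expect_equal(as.numeric(degen), 1.3)
  expect_equal(attr(degen, "degenerate"), 1L)
})

test_that("flux-inversion sensitivity matches a central-difference oracle", {
  expect_equal(y_hat_sensitivity(0, 1), 0.5)
  expect_equal(y_hat_sensitivity(3, 1), 1 / sqrt(13), tolerance = 1e-14)
  expect_error(y_hat_sensitivity(0, 0), "unbounded")
  set.seed(3)
  for (rep in 1:25) {
    y <- runif(1, -3, 3); a <- runif(1, 0.05, 1)
    hstep <- 1e-6
    fd <- (y_hat(y + hstep, a, 0) - y_hat(y - hstep, a, 0)) / (2 * hstep)
    expect_equal(y_hat_sensitivity(y, a), abs(fd), tolerance = 1e-6)
    expect_lt(fd, 0)  # signed derivative: more flux needs more displacement
  }
})

test_that("smooth signum is odd, bounded, and close to sgn away from zero", {
  expect_identical(smooth_sign(0), 0)
  x <- c(-10, -0.1, 0.1, 3)
  expect_equal(smooth_sign(-x), -smooth_sign(x))
  expect_true(all(abs(smooth_sign(x, eps = 1e-3)) < 1))
  expect_equal(smooth_sign(1, lam = 1, eps = 1e-50), 1, tolerance = 1e-40)
  lam <- 2; eps <- 1e-4
  err <- abs(smooth_sign(x, lam, eps) - sign(x))
  expect_true(all(err <= eps / (lam * abs(x)) + 1e-15))
})

test_that("mass-balance right-hand side is S_v times the flux and vanishes at equilibrium", {
  net <- chain_net(log_K = c(0, 0), eta_A = 1, eta_C = 1)
  expect_equal(unname(dynamics_rhs(assemble_eta(net, 1), net)), 0)

  rnet <- generate_network("random_sparse", n_free = 2, n_fixed = 3,
                           n_reactions = 5, seed = 12)
  Sv <- stoichiometric_matrix(rnet, variable_only = TRUE, sparse = FALSE)
  set.seed(4)
  for (rep in 1:10) {
    eta <- assemble_eta(rnet, runif(2, -3, 3))
    alpha <- runif(5)
    expect_equal(unname(dynamics_rhs(eta, rnet, alpha)),
                 as.numeric(Sv %*% log_space_flux(eta, rnet, alpha)),
                 tolerance = 1e-12)
  }
})

test_that("flux direction follows the thermodynamic force and inversion closes the loop", {
  net <- generate_network("random_sparse", n_free = 2, n_fixed = 3,
                          n_reactions = 5, seed = 21)
  log_K <- net$reactions$log_K
  Sfull <- stoichiometric_matrix(net, sparse = FALSE)
  set.seed(5)
  for (rep in 1:20) {
    eta <- assemble_eta(net, runif(2, -4, 4))
    alpha <- runif(5, 0.01, 1)
    g <- as.numeric(crossprod(Sfull, eta))
    J <- log_space_flux(eta, net, alpha)
    expect_equal(sign(J), sign(log_K - g))
    # recovering g from (J, alpha) closes the loop
    expect_equal(y_hat(J, alpha, log_K), g, tolerance = 1e-8)
  }
})
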