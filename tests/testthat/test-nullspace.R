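test_that("nullspace basis is orthonormal, deterministic and annihilated by S_v", {
  net <- chain_net()
  ns <- nullspace_basis(net)
  expect_equal(ns$m, 1L)
  expect_equal(abs(as.numeric(ns$basis)), rep(1 / sqrt(2), 2), tolerance = 1e-12)
  expect_equal(unname(ns$basis[1, 1]), unname(ns$basis[2, 1]))  # through-flux

  cyc <- generate_network("cycle", n_free = 2, n_fixed = 2, n_reactions = 4,
                          seed = 3)
  nsc <- nullspace_basis(cyc)
  Svc <- stoichiometric_matrix(cyc, variable_only = TRUE, sparse = FALSE)
  # the cycle vector is a steady state: it must be reproduced by projection
  cvec <- rep(1, 4)
  expect_equal(as.numeric(Svc %*% cvec), rep(0, nrow(Svc)))
  expect_equal(nsc$basis %*% crossprod(nsc$basis, cvec), cbind(cvec),
               ignore_attr = TRUE, tolerance = 1e-10)

  rnet <- generate_network("random_sparse", n_free = 3, n_fixed = 3,
                           n_reactions = 8, seed = 17)
  nsr <- nullspace_basis(rnet)
  Svr <- stoichiometric_matrix(rnet, variable_only = TRUE, sparse = FALSE)
  expect_lt(max(abs(Svr %*% nsr$basis)), 1e-10)
  expect_equal(crossprod(nsr$basis), diag(nsr$m), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_identical(nsr$basis, nullspace_basis(rnet)$basis)

  # a dead-end free metabolite pins its only reaction: full-rank S_v
  mets <- data.frame(id = c("A", "B"), fixed = c(TRUE, FALSE),
                     fixed_log_count = c(0, NA))
  rxn <- list(list(id = "R1", stoich = c(A = -1, B = 1), log_K = 0,
                   growth = TRUE))
  expect_error(nullspace_basis(metabolic_network(mets, rxn)),
               "no nonzero steady state")
})

test_that("nullspace projection is an orthogonal projector", {
  net <- generate_network("random_sparse", n_free = 2, n_fixed = 3,
                          n_reactions = 6, seed = 23)
  ns <- nullspace_basis(net)
  Sv <- stoichiometric_matrix(net, variable_only = TRUE, sparse = FALSE)
  P <- ns$basis %*% t(ns$basis)
  expect_equal(P %*% P, P, tolerance = 1e-12)
  expect_equal(P, t(P), tolerance = 1e-14)
  set.seed(6)
  for (rep in 1:10) {
    v <- rnorm(6)
    pv <- project_to_nullspace(v, ns)
    expect_lt(max(abs(Sv %*% pv)), 1e-8 * max(1, sqrt(sum(v^2))))
    expect_equal(project_to_nullspace(pv, ns), pv, tolerance = 1e-12)
  }
  # in-space vectors unchanged, orthogonal-complement vectors annihilated
  inspace <- as.numeric(ns$basis %*% rnorm(ns$m))
  expect_equal(project_to_nullspace(inspace, ns), inspace, tolerance = 1e-12)
  ortho <- as.numeric(t(Sv) %*% rnorm(nrow(Sv)))
  expect_equal(project_to_nullspace(ortho, ns), rep(0, 6), tolerance = 1e-10)

  # chain: projecting the growth indicator spreads it along the through-flux
  expect_equal(project_to_nullspace(c(0, 1), nullspace_basis(chain_net())),
               c(0.5, 0.5), tolerance = 1e-12)
})

test_that("reducibility certificate accepts zero flux, boundary flux, and flags sign errors", {
  net <- chain_net(log_K = c(1, 0.5), eta_A = 2, eta_C = -2)
  eta <- assemble_eta(net, 0.3)
  expect_true(reducibility_certificate(eta, c(0, 0), net)$feasible)
  J1 <- log_space_flux(eta, net, alpha = 1)
  expect_true(reducibility_certificate(eta, J1, net)$feasible)
  # reversing the flux against its force violates the direction condition
  cert <- reducibility_certificate(eta, -J1, net)
  expect_false(cert$feasible)
  expect_true("direction" %in% cert$violations$condition)
  # exceeding the unregulated magnitude violates the force bound
  cert2 <- reducibility_certificate(eta, 2 * J1, net)
  expect_false(cert2$feasible)
  expect_true(all(c("force_bound", "flux_cap") %in% cert2$violations$condition))

  tsv <- file.path(tempdir(), "cert.tsv")
  write_certificate(cert2, net, tsv)
  rep_ <- read.delim(tsv)
  expect_identical(rep_$reaction, net$reactions$id)
  expect_false(any(rep_$force_bound_ok))
})

test_that("certificate feasibility coincides with brute-force search over activities", {
  # single reaction between fixed species: alpha is the only freedom
  alphas <- seq(0, 1, length.out = 2001)
  for (log_K in c(-1, 0.5, 2)) for (eta_A in c(-1, 0, 1.5)) {
    net <- one_reaction_net(log_K = log_K, eta_A = eta_A, eta_B = 0)
    eta <- assemble_eta(net, numeric(0))
    J1 <- log_space_flux(eta, net, alpha = 1)
    for (y in seq(-1.5, 1.5, length.out = 21) * max(abs(J1), 0.5)) {
      feas <- reducibility_certificate(eta, y, net, tol = 1e-9)$feasible
      reachable <- min(abs(alphas * J1 - y)) < max(abs(J1), 1) * 1e-3
      expect_identical(feas, reachable)
    }
  }
})

test_that("activity recovery inverts the regulated flux law", {
  net <- chain_net(log_K = c(1, -0.5), eta_A = 2.5, eta_C = -2)
  eta <- assemble_eta(net, 0.2)
  J1 <- log_space_flux(eta, net, alpha = 1)
  expect_equal(unname(recover_activities(eta, J1, net)), c(1, 1))
  expect_equal(unname(recover_activities(eta, rep(0, 2), net)), c(0, 0))
  expect_equal(unname(recover_activities(eta, J1 / 2, net)), c(0.5, 0.5))
  expect_error(recover_activities(eta, -J1, net), "not reducible")

  # round trip on random feasible states
  rnet <- generate_network("random_sparse", n_free = 2, n_fixed = 3,
                           n_reactions = 5, seed = 31)
  set.seed(7)
  for (rep in 1:20) {
    eta <- assemble_eta(rnet, runif(2, -3, 3))
    alpha <- runif(5, 1e-4, 1)
    y <- log_space_flux(eta, rnet, alpha)
    expect_equal(unname(recover_activities(eta, y, rnet)), alpha,
                 tolerance = 1e-8)
  }
})
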