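# Hand-built fixtures used across the suite. All are tiny enough that their
# steady states and optima can be reasoned about (or brute-forced) directly.

# canonical chain A(fixed) <-> B <-> C(fixed)
chain_net <- function(log_K = c(0, 0), eta_A = 3, eta_C = -3, eta_max = NULL,
                      growth = c(FALSE, TRUE)) {
  mets <- data.frame(id = c("A", "B", "C"), fixed = c(TRUE, FALSE, TRUE),
                     fixed_log_count = c(eta_A, NA, eta_C))
  rxns <- list(
    list(id = "R1", stoich = c(A = -1, B = 1), log_K = log_K[1],
         growth = growth[1]),
    list(id = "R2", stoich = c(B = -1, C = 1), log_K = log_K[2],
         growth = growth[2]))
  metabolic_network(mets, rxns, eta_max = eta_max)
}

# equilibrium boundary: no thermodynamic driving force, optimum flux is zero
equilibrium_chain <- function() {
  em <- concentration_to_log_count(1.0)
  chain_net(log_K = c(0, 0), eta_A = em, eta_C = em, eta_max = em)
}

# strongly favorable first step drives the free metabolite far above the
# 1 mM cap (unregulated steady state near eta_B ~ (logK1 - logK2)/2)
overshoot_chain <- function(log_K1 = 30) {
  chain_net(log_K = c(log_K1, -2), eta_A = 0, eta_C = 0)
}

# two independent overshooting chains with different violation sizes
two_violation_net <- function() {
  mets <- data.frame(
    id = c("A1", "B1", "C1", "A2", "B2", "C2"),
    fixed = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
    fixed_log_count = c(0, NA, 0, 0, NA, 0))
  rxns <- list(
    list(id = "P1", stoich = c(A1 = -1, B1 = 1), log_K = 30, growth = FALSE),
    list(id = "P2", stoich = c(B1 = -1, C1 = 1), log_K = -2, growth = TRUE),
    list(id = "Q1", stoich = c(A2 = -1, B2 = 1), log_K = 34, growth = FALSE),
    list(id = "Q2", stoich = c(B2 = -1, C2 = 1), log_K = -2, growth = FALSE))
  metabolic_network(mets, rxns)
}

# growth reaction feeding a free dead-end metabolite: unreachable at steady
# state (its projected objective gradient is zero)
dead_end_net <- function() {
  mets <- data.frame(id = c("A", "B", "C", "D"),
                     fixed = c(TRUE, FALSE, TRUE, FALSE),
                     fixed_log_count = c(2, NA, -2, NA))
  rxns <- list(
    list(id = "R1", stoich = c(A = -1, B = 1), log_K = 0, growth = FALSE),
    list(id = "R2", stoich = c(B = -1, D = 1), log_K = 0, growth = TRUE),
    list(id = "R3", stoich = c(B = -1, C = 1), log_K = 0, growth = FALSE))
  metabolic_network(mets, rxns)
}

# single reaction between two fixed metabolites: S_v has zero rows, every
# flux with the right sign and magnitude is reducible
one_reaction_net <- function(log_K = 1, eta_A = 1, eta_B = 0) {
  mets <- data.frame(id = c("A", "B"), fixed = c(TRUE, TRUE),
                     fixed_log_count = c(eta_A, eta_B))
  rxns <- list(list(id = "R1", stoich = c(A = -1, B = 1), log_K = log_K,
                    growth = TRUE))
  metabolic_network(mets, rxns)
}

# seeded toy-network panel shared by the oracle-equivalence and certificate
# acceptance checks (<= 2 free metabolites throughout)
toy_panel <- function() {
  specs <- list(
    list(top = "chain", nf = 1, nx = 2, nr = 2, ps = 2, dr = 3),
    list(top = "branch", nf = 1, nx = 3, nr = 3, ps = 2, dr = 4),
    list(top = "random_sparse", nf = 1, nx = 3, nr = 3, ps = 2, dr = 4),
    list(top = "chain", nf = 2, nx = 2, nr = 3, ps = 1.5, dr = 5),
    list(top = "random_sparse", nf = 2, nx = 3, nr = 4, ps = 1.5, dr = 3.5))
  out <- list()
  for (s in specs) for (seed in c(11L, 42L)) {
    out[[length(out) + 1L]] <- generate_network(
      s$top, n_free = s$nf, n_fixed = s$nx, n_reactions = s$nr,
      potential_scale = s$ps, drive = s$dr, seed = seed)
  }
  out
}

# steady-state chain triple (eta, y, alpha) built by hand: pick a through-flux
# below both unregulated caps and recover the activities analytically
chain_exact_state <- function(net, frac = 0.5) {
  eta_B <- (net$metabolites$fixed_log_count[1] +
            net$metabolites$fixed_log_count[3]) / 2
  eta <- assemble_eta(net, eta_B)
  J1 <- log_space_flux(eta, net, alpha = 1)
  t_ <- frac * min(abs(J1)) * sign(J1[1])
  list(eta = eta, y = rep(t_, 2), alpha = rep(t_, 2) / J1)
}
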