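test_that("construction validates ids, partition and stoichiometry", {
  mets <- data.frame(id = c("A", "B"), fixed = c(TRUE, FALSE),
                     fixed_log_count = c(1, NA))
  rxn <- list(list(id = "R1", stoich = c(A = -1, B = 1), log_K = 0,
                   growth = TRUE))

  expect_s3_class(metabolic_network(mets, rxn), "metabolic_network")
  expect_error(metabolic_network(rbind(mets, mets[1, ]), rxn), "duplicate")
  expect_error(metabolic_network(
    data.frame(id = c("A", "B"), fixed = c(TRUE, FALSE),
               fixed_log_count = c(NA, NA)), rxn), "finite fixed_log_count")
  expect_error(metabolic_network(mets, list(
    list(id = "R1", stoich = c(A = -1, Z = 1), log_K = 0, growth = FALSE))),
    "unknown metabolites")
  expect_error(metabolic_network(mets, list(
    list(id = "R1", stoich = c(A = -1), log_K = 0, growth = FALSE))),
    "reactant .* and one product")
  expect_error(metabolic_network(mets, list(
    list(id = "R1", stoich = c(A = -1, B = 1), log_K = NA, growth = FALSE))),
    "finite log_K")
})

test_that("stoichiometric matrix has declared order, signs and submatrix", {
  net <- chain_net()
  S <- stoichiometric_matrix(net, sparse = FALSE)
  expect_equal(dim(S), c(3L, 2L))
  expect_equal(unname(S[, 1]), c(-1, 1, 0))
  expect_equal(unname(S[, 2]), c(0, -1, 1))
  Sv <- stoichiometric_matrix(net, variable_only = TRUE, sparse = FALSE)
  expect_equal(dim(Sv), c(1L, 2L))
  expect_equal(unname(Sv[1, ]), c(1, -1))
  # S_v is exactly the row-submatrix of S on the variable set
  expect_equal(Sv, S[!net$metabolites$fixed, , drop = FALSE])
  # column sums equal the reaction's net molecularity
  expect_equal(unname(colSums(S)),
               vapply(net$reactions$stoich, sum, numeric(1)))

  all_fixed <- one_reaction_net()
  expect_equal(nrow(stoichiometric_matrix(all_fixed, variable_only = TRUE)), 0L)
})

test_that("unit conversions reproduce the physiological bound and invert", {
  ctx <- unit_context(cell_volume = 1e-15)
  expect_equal(concentration_to_log_count(1.0, ctx), 13.308, tolerance = 1e-3)
  # a single molecule has log count zero
  conc_one <- 1 / (1e-3 * ctx$avogadro * ctx$cell_volume)
  expect_equal(concentration_to_log_count(conc_one, ctx), 0, tolerance = 1e-12)
  # bijection
  conc <- 10^runif(50, -6, 3)
  back <- log_count_to_concentration(concentration_to_log_count(conc, ctx), ctx)
  expect_equal(back, conc, tolerance = 1e-12)
  expect_error(concentration_to_log_count(0, ctx), "positive")
  expect_error(concentration_to_log_count(-1, ctx), "positive")
})

test_that("equilibrium-constant unit change leaves the force invariant", {
  ctx <- unit_context(cell_volume = 1e-15)
  expect_equal(convert_log_K_units(2.5, 0, ctx), 2.5)
  expect_equal(convert_log_K_units(0, 1, ctx), log(6.02214076e5),
               tolerance = 1e-12)
  # A <-> B + C: force in mM units equals force in count units
  log_K_mM <- 1.7
  n_mM <- c(A = 4, B = 0.3, C = 11)
  gamma <- c(A = -1, B = 1, C = 1)
  f_mM <- exp(log_K_mM - sum(gamma * log(n_mM)))
  eta <- concentration_to_log_count(n_mM, ctx)
  f_count <- exp(convert_log_K_units(log_K_mM, sum(gamma), ctx) -
                 sum(gamma * eta))
  expect_equal(f_count, f_mM, tolerance = 1e-10)
})

test_that("JSON and TSV serialization round-trip generated networks", {
  net <- generate_network("random_sparse", n_free = 3, n_fixed = 4,
                          n_reactions = 10, seed = 99)
  for (fmt in c("json", "tsv")) {
    base <- file.path(tempdir(), paste0("net_rt_", fmt))
    path <- if (fmt == "json") paste0(base, ".json") else base
    write_network(net, path, format = fmt)
    back <- load_network(path, format = fmt)
    expect_identical(back$metabolites$id, net$metabolites$id)
    expect_identical(back$metabolites$fixed, net$metabolites$fixed)
    expect_equal(back$metabolites$fixed_log_count,
                 net$metabolites$fixed_log_count, tolerance = 1e-12)
    expect_identical(back$reactions$id, net$reactions$id)
    expect_identical(back$reactions$growth, net$reactions$growth)
    expect_equal(back$reactions$log_K, net$reactions$log_K, tolerance = 1e-12)
    expect_equal(lapply(back$reactions$stoich, sort),
                 lapply(net$reactions$stoich, sort))
    expect_equal(back$eta_max, net$eta_max, tolerance = 1e-12)
    expect_equal(as.matrix(back$S), as.matrix(net$S))
  }
})

test_that("loader reports malformed input precisely", {
  expect_error(load_network(file.path(tempdir(), "nope.json")), "no such file")
  bad <- file.path(tempdir(), "bad.json")
  writeLines("{not json", bad)
  expect_error(load_network(bad), "malformed JSON")
  nofx <- file.path(tempdir(), "nofix.json")
  jsonlite::write_json(list(
    metabolites = list(list(id = "A", fixed = TRUE),
                       list(id = "B", fixed = FALSE)),
    reactions = list(list(id = "R1", stoich = list(A = -1, B = 1),
                          log_K = 0, growth = TRUE))),
    nofx, auto_unbox = TRUE)
  expect_error(load_network(nofx), "fixed_conc_mM")
})

test_that("equilibrium constants can be loaded in concentration units", {
  net <- chain_net(log_K = c(1, -1))
  path <- file.path(tempdir(), "units.json")
  write_network(net, path)
  as_count <- load_network(path, log_K_units = "count")
  as_mM <- load_network(path, log_K_units = "mM")
  # uni-uni reactions have zero net molecularity: no shift either way
  expect_equal(as_mM$reactions$log_K, as_count$reactions$log_K)
})
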