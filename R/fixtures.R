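# run expr with a locally seeded RNG, restoring the caller's stream
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a thermodynamically consistent toy metabolic network
#'
#' Every metabolite is first assigned a standard chemical potential
#' \eqn{\mu_i} drawn from a seeded normal distribution; equilibrium
#' constants are then derived as \eqn{\log K_j = -\sum_i \gamma_{ij}\mu_i},
#' which makes the free-energy landscape exact by construction: around any
#' reaction cycle the log equilibrium constants telescope to zero
#' (Wegscheider consistency). Boundary (fixed) metabolites are displaced
#' from their natural abundance \eqn{e^{-\mu_i}} to create a non-equilibrium
#' driving force: sources upward by `drive` log units, sinks downward.
#'
#' @param topology `"chain"` (fixed source - free interior - fixed sink),
#'   `"branch"` (one fixed source, a free hub chain, competing fixed
#'   sinks), `"cycle"` (closed loop of free metabolites), or
#'   `"random_sparse"`.
#' @param n_free,n_fixed,n_reactions Metabolite/reaction counts; each
#'   topology validates the combination it supports.
#' @param potential_scale Standard deviation of the chemical potentials.
#' @param drive Magnitude of the boundary displacement in log-count units.
#' @param seed Integer seed; generation is fully determined by it.
#' @param eta_max Log-count cap passed to the network (default: 1 mM at the
#'   default cell volume).
#' @return A [metabolic_network()]; growth defaults to the terminal sink
#'   reaction(s).
#' @export
generate_network <- function(topology = c("chain", "branch", "cycle",
                                          "random_sparse"),
                             n_free = 1L, n_fixed = 2L,
                             n_reactions = n_free + n_fixed - 1L,
                             potential_scale = 1, drive = 3, seed = 1L,
                             eta_max = NULL) {
  topology <- match.arg(topology)
  n_free <- as.integer(n_free); n_fixed <- as.integer(n_fixed)
  n_reactions <- as.integer(n_reactions)
  if (n_free < 0L || n_fixed < 0L || n_reactions < 1L)
    stop("counts must be positive", call. = FALSE)
  with_seed(seed, {
    switch(topology,
      chain = gen_chain(n_free, n_fixed, n_reactions, potential_scale,
                        drive, eta_max),
      branch = gen_branch(n_free, n_fixed, n_reactions, potential_scale,
                          drive, eta_max),
      cycle = gen_cycle(n_free, n_fixed, n_reactions, potential_scale,
                        eta_max),
      random_sparse = gen_random(n_free, n_fixed, n_reactions,
                                 potential_scale, drive, eta_max))
  })
}

make_fixture_network <- function(ids, fixed, eta_bar, stoich_list, growth,
                                 mu, eta_max) {
  mets <- data.frame(id = ids, name = ids, fixed = fixed,
                     fixed_log_count = eta_bar, stringsAsFactors = FALSE)
  rxns <- lapply(seq_along(stoich_list), function(j) {
    s <- stoich_list[[j]]
    list(id = sprintf("R%d", j), stoich = s,
         log_K = -sum(s * mu[names(s)]), growth = growth[j])
  })
  metabolic_network(mets, rxns, eta_max = eta_max)
}

gen_chain <- function(n_free, n_fixed, n_reactions, potential_scale, drive,
                      eta_max) {
  if (n_fixed != 2L)
    stop("chain topology needs exactly 2 fixed metabolites (the ends)",
         call. = FALSE)
  n <- n_free + 2L
  if (n_reactions != n - 1L)
    stop("chain with ", n, " metabolites needs ", n - 1L, " reactions",
         call. = FALSE)
  ids <- sprintf("M%d", seq_len(n))
  mu <- stats::setNames(stats::rnorm(n, 0, potential_scale), ids)
  fixed <- c(TRUE, rep(FALSE, n_free), TRUE)
  eta_bar <- rep(NA_real_, n)
  eta_bar[1] <- -mu[1] + drive      # source held above natural abundance
  eta_bar[n] <- -mu[n] - drive      # sink held below
  stoich <- lapply(seq_len(n - 1L), function(j)
    stats::setNames(c(-1, 1), ids[c(j, j + 1L)]))
  growth <- c(rep(FALSE, n - 2L), TRUE)
  make_fixture_network(ids, fixed, eta_bar, stoich, growth, mu, eta_max)
}

gen_branch <- function(n_free, n_fixed, n_reactions, potential_scale, drive,
                       eta_max) {
  if (n_fixed < 3L)
    stop("branch topology needs a source and at least two sinks", call. = FALSE)
  if (n_free < 1L) stop("branch topology needs a free hub", call. = FALSE)
  n_sinks <- n_fixed - 1L
  expected <- n_free + n_sinks
  if (n_reactions != expected)
    stop("branch with ", n_free, " free and ", n_fixed, " fixed metabolites ",
         "needs ", expected, " reactions", call. = FALSE)
  ids <- c("SRC", sprintf("H%d", seq_len(n_free)), sprintf("SNK%d",
                                                           seq_len(n_sinks)))
  n <- length(ids)
  mu <- stats::setNames(stats::rnorm(n, 0, potential_scale), ids)
  fixed <- c(TRUE, rep(FALSE, n_free), rep(TRUE, n_sinks))
  eta_bar <- rep(NA_real_, n)
  eta_bar[1] <- -mu[1] + drive
  eta_bar[(n_free + 2L):n] <- -mu[(n_free + 2L):n] - drive
  hub <- sprintf("H%d", n_free)
  stoich <- c(
    list(stats::setNames(c(-1, 1), c("SRC", "H1"))),
    if (n_free > 1L) lapply(seq_len(n_free - 1L), function(k)
      stats::setNames(c(-1, 1), sprintf("H%d", c(k, k + 1L)))),
    lapply(seq_len(n_sinks), function(k)
      stats::setNames(c(-1, 1), c(hub, sprintf("SNK%d", k)))))
  growth <- rep(FALSE, length(stoich))
  growth[length(stoich) - n_sinks + 1L] <- TRUE  # branch into sink 1
  make_fixture_network(ids, fixed, eta_bar, stoich, growth, mu, eta_max)
}

gen_cycle <- function(n_free, n_fixed, n_reactions, potential_scale,
                      eta_max) {
  n <- n_free + n_fixed
  if (n < 3L) stop("a cycle needs at least 3 species", call. = FALSE)
  if (n_reactions != n)
    stop("cycle with ", n, " metabolites needs ", n, " reactions",
         call. = FALSE)
  ids <- sprintf("M%d", seq_len(n))
  mu <- stats::setNames(stats::rnorm(n, 0, potential_scale), ids)
  fixed <- c(rep(FALSE, n_free), rep(TRUE, n_fixed))
  eta_bar <- ifelse(fixed, -mu, NA_real_)
  stoich <- lapply(seq_len(n), function(j)
    stats::setNames(c(-1, 1), ids[c(j, if (j == n) 1L else j + 1L)]))
  growth <- c(rep(FALSE, n - 1L), TRUE)
  make_fixture_network(ids, fixed, eta_bar, stoich, growth, mu, eta_max)
}

gen_random <- function(n_free, n_fixed, n_reactions, potential_scale, drive,
                       eta_max) {
  if (n_fixed < 2L)
    stop("random_sparse needs at least a fixed source and sink", call. = FALSE)
  n <- n_free + n_fixed
  ids <- c(sprintf("F%d", seq_len(n_free)),
           "SRC", if (n_fixed > 2L) sprintf("X%d", seq_len(n_fixed - 2L)),
           "SNK")
  mu <- stats::setNames(stats::rnorm(n, 0, potential_scale), ids)
  fixed <- c(rep(FALSE, n_free), rep(TRUE, n_fixed))
  eta_bar <- rep(NA_real_, n)
  offs <- stats::rnorm(n_fixed, 0, drive / 2)
  offs[1] <- drive; offs[n_fixed] <- -drive
  eta_bar[(n_free + 1L):n] <- -mu[(n_free + 1L):n] + offs
  # spanning path SRC -> free metabolites -> SNK guarantees connectivity
  path <- c("SRC", sprintf("F%d", seq_len(n_free)), "SNK")
  stoich <- lapply(seq_len(length(path) - 1L), function(k)
    stats::setNames(c(-1, 1), path[c(k, k + 1L)]))
  extra <- n_reactions - length(stoich)
  if (extra < 0L)
    stop("random_sparse with ", n_free, " free metabolites needs at least ",
         length(stoich), " reactions", call. = FALSE)
  guard <- 0L
  while (extra > 0L && guard < 1000L) {
    guard <- guard + 1L
    pair <- sample(ids, 2L)
    coeff <- sample(c(1, 1, 2), 2L, replace = TRUE)
    s <- stats::setNames(c(-coeff[1], coeff[2]), pair)
    if (any(vapply(stoich, function(x) identical(sort(names(x)),
                                                 sort(names(s))), logical(1))))
      next
    stoich <- c(stoich, list(s))
    extra <- extra - 1L
  }
  growth <- rep(FALSE, length(stoich))
  growth[n_free + 1L] <- TRUE   # the path reaction into SNK
  make_fixture_network(ids, fixed, eta_bar, stoich, growth, mu, eta_max)
}

## ---------------------------------------------------------------------------
## Brute-force oracle
## ---------------------------------------------------------------------------

# exact maximizer of sum(y[G]) over y = B beta subject to the per-reaction
# box lower <= y <= upper, for nullspace dimension m <= 2 (vertex enumeration)
max_growth_lp <- function(B, gI, lower, upper) {
  m <- ncol(B)
  cc <- colSums(B[gI, , drop = FALSE])
  if (m == 1L) {
    b <- B[, 1]
    lo <- -Inf; hi <- Inf
    for (j in seq_along(b)) {
      if (abs(b[j]) < 1e-14) next
      iv <- sort(c(lower[j], upper[j]) / b[j])
      lo <- max(lo, iv[1]); hi <- min(hi, iv[2])
    }
    if (lo > hi) return(list(objective = 0, beta = 0))
    beta <- if (cc >= 0) hi else lo
    return(list(objective = cc * beta, beta = beta))
  }
  # m == 2: constraints A beta <= b
  A <- rbind(B, -B)
  bvec <- c(upper, -lower)
  keep <- is.finite(bvec)
  A <- A[keep, , drop = FALSE]; bvec <- bvec[keep]
  best <- list(objective = 0, beta = c(0, 0))   # beta = 0 always feasible
  nr <- nrow(A)
  if (nr >= 2L) {
    for (k in seq_len(nr - 1L)) for (l in (k + 1L):nr) {
      Akl <- A[c(k, l), , drop = FALSE]
      det_ <- Akl[1, 1] * Akl[2, 2] - Akl[1, 2] * Akl[2, 1]
      if (abs(det_) < 1e-12) next
      v <- solve(Akl, bvec[c(k, l)])
      if (all(A %*% v <= bvec + 1e-9 * (1 + abs(bvec)))) {
        obj <- sum(cc * v)
        if (obj > best$objective) best <- list(objective = obj, beta = v)
      }
    }
  }
  best
}

#' Brute-force oracle for the PCO optimum on small networks
#'
#' Exhaustive reference for networks with at most two free metabolites and
#' nullspace dimension at most two. For each grid point of the free log
#' counts, the reducibility certificate reduces the feasible fluxes to a
#' per-reaction interval \eqn{y_j \in [0, 2\sinh(\log K_j - g_j)]} (or its
#' mirror), so the inner problem is a tiny linear program over the nullspace
#' coordinates, solved exactly by vertex enumeration. The outer grid is
#' refined around the incumbent until the step size is below `eta_tol`.
#'
#' @param net A [metabolic_network()].
#' @param n_grid Grid points per free dimension and refinement level.
#' @param n_refine Number of zoom-in refinement levels.
#' @param span Half-width of the first-level search interval below
#'   `eta_max` (log-count units).
#' @param eta_tol Target resolution of the final grid.
#' @return List with `objective`, `eta` (arg max state), and `y`.
#' @export
brute_force_pco <- function(net, n_grid = 33L, n_refine = 5L, span = NULL,
                            eta_tol = 1e-6) {
  iv <- variable_index(net)
  if (length(iv) > 2L)
    stop("oracle is exponential in the free metabolites; at most 2 supported",
         call. = FALSE)
  ns <- nullspace_basis(net)
  if (ns$m > 2L)
    stop("oracle supports nullspace dimension at most 2", call. = FALSE)
  B <- ns$basis
  gI <- growth_index(net)
  log_K <- net$reactions$log_K

  eval_eta <- function(ev) {
    eta <- assemble_eta(net, ev)
    d <- log_K - reaction_log_action(eta, net)
    z <- pmax(pmin(d, 300), -300)
    cap <- exp(z) - exp(-z)          # 2 sinh(d), signed
    lower <- pmin(0, cap); upper <- pmax(0, cap)
    sol <- max_growth_lp(B, gI, lower, upper)
    list(objective = sol$objective, y = as.numeric(B %*% sol$beta))
  }

  if (length(iv) == 0L) {
    sol <- eval_eta(numeric(0))
    return(list(objective = sol$objective, eta = assemble_eta(net, numeric(0)),
                y = sol$y))
  }
  if (is.null(span)) {
    lo_ref <- min(c(net$metabolites$fixed_log_count[fixed_index(net)],
                    net$eta_max))
    span <- max(10, net$eta_max - lo_ref + 10)
  }
  dim_v <- length(iv)
  make_grid <- function(centers, half, n) {
    axes <- lapply(centers, function(cc)
      pmin(seq(cc - half, cc + half, length.out = n), net$eta_max))
    if (dim_v == 1L) matrix(axes[[1]], ncol = 1) else
      as.matrix(expand.grid(axes[[1]], axes[[2]]))
  }
  scan <- function(grid) {
    obj <- vapply(seq_len(nrow(grid)),
                  function(r) eval_eta(grid[r, ])$objective, numeric(1))
    list(grid = grid, obj = obj)
  }

  # level 1: full-range scan; the landscape can be multimodal with narrow
  # peaks, so refine around several well-separated leading candidates
  n1 <- max(2L * n_grid - 1L, n_grid)
  half1 <- span / 2
  centers0 <- rep(net$eta_max - half1, dim_v)
  lvl1 <- scan(make_grid(centers0, half1, n1))
  step1 <- 2 * half1 / (n1 - 1)
  ord <- order(lvl1$obj, decreasing = TRUE)
  seeds_ev <- list()
  for (r in ord) {
    cand <- lvl1$grid[r, ]
    if (length(seeds_ev) >= 8L) break
    sep <- !length(seeds_ev) ||
      all(vapply(seeds_ev, function(s) max(abs(s - cand)) > 2 * step1,
                 logical(1)))
    if (sep) seeds_ev <- c(seeds_ev, list(cand))
  }

  best <- list(objective = -Inf, ev = seeds_ev[[1]], y = NULL)
  for (sv in seeds_ev) {
    centers <- sv
    half <- 2 * step1
    local_best <- list(objective = -Inf, ev = centers)
    for (level in seq_len(n_refine)) {
      sc <- scan(make_grid(centers, half, n_grid))
      top <- which.max(sc$obj)
      if (sc$obj[top] > local_best$objective)
        local_best <- list(objective = sc$obj[top], ev = sc$grid[top, ])
      centers <- local_best$ev
      half <- half * 2.5 / (n_grid - 1)
      if (2 * half / (n_grid - 1) < eta_tol) break
    }
    if (local_best$objective > best$objective) best <- local_best
  }

  # The maximum often sits where two flux-cap constraints balance: a narrow
  # tent-shaped peak over a plateau, invisible to axis-aligned grids. The
  # displacements d_j(eta_v) are affine, so the balance loci d_i = +/- d_j
  # are lines (2D) or points (1D); scan and refine along each of them.
  Sv_d <- as.matrix(stoichiometric_matrix(net, variable_only = TRUE))
  eta_f <- net$metabolites$fixed_log_count; eta_f[iv] <- 0
  d0 <- log_K - as.numeric(Matrix::crossprod(net$S, eta_f)) # d at eta_v = 0
  Dmat <- -t(Sv_d)                                          # d = d0 + D eta_v
  lo_box <- rep(net$eta_max - span, dim_v); hi_box <- rep(net$eta_max, dim_v)
  refine_1d <- function(fn, t_best, half0) {
    half <- half0
    for (lv in 1:6) {
      ts <- seq(t_best - half, t_best + half, length.out = 25)
      vals <- vapply(ts, fn, numeric(1))
      t_best <- ts[which.max(vals)]
      half <- half / 6
    }
    list(t = t_best, value = fn(t_best))
  }
  nJ <- length(log_K)
  for (i in seq_len(nJ - 1L)) for (j in (i + 1L):nJ) for (sgn2 in c(1, -1)) {
    a <- Dmat[i, ] - sgn2 * Dmat[j, ]
    b <- sgn2 * d0[j] - d0[i]
    if (dim_v == 1L) {
      if (abs(a[1]) < 1e-12) next
      t0 <- b / a[1]
      if (t0 < lo_box[1] - 1 || t0 > hi_box[1]) next
      fn <- function(t) eval_eta(min(t, net$eta_max))$objective
      r <- refine_1d(fn, min(t0, net$eta_max), half0 = 2 * step1)
      if (r$value > best$objective)
        best <- list(objective = r$value, ev = min(r$t, net$eta_max))
    } else {
      if (max(abs(a)) < 1e-12) next
      # parameterize the line eta_v = p + t * u inside the search box
      k <- which.max(abs(a))
      u <- if (k == 1L) c(-a[2] / a[1], 1) else c(1, -a[1] / a[2])
      u <- u / sqrt(sum(u^2))
      p <- if (k == 1L) c(b / a[1], 0) else c(0, b / a[2])
      t_span <- 2 * span
      ts <- seq(-t_span, t_span, length.out = 241)
      fn <- function(t) {
        ev <- pmin(p + t * u, net$eta_max)
        if (any(ev < lo_box - span)) return(-Inf)
        eval_eta(ev)$objective
      }
      vals <- vapply(ts, fn, numeric(1))
      tb <- ts[which.max(vals)]
      if (!is.finite(max(vals))) next
      r <- refine_1d(fn, tb, half0 = ts[2] - ts[1])
      if (r$value > best$objective)
        best <- list(objective = r$value, ev = pmin(p + r$t * u, net$eta_max))
    }
  }

  # deterministic derivative-free polish of the incumbent
  neg_obj <- function(ev) -eval_eta(pmin(ev, net$eta_max))$objective
  pol <- if (dim_v == 1L)
    stats::optim(best$ev, neg_obj, method = "Brent",
                 lower = best$ev - 4 * step1, upper = min(best$ev + 4 * step1,
                                                          net$eta_max))
  else
    stats::optim(best$ev, neg_obj, method = "Nelder-Mead",
                 control = list(maxit = 2000L, reltol = 1e-14))
  if (-pol$value > best$objective)
    best <- list(objective = -pol$value, ev = pmin(pol$par, net$eta_max))
  sol <- eval_eta(best$ev)
  list(objective = sol$objective, eta = assemble_eta(net, best$ev),
       y = sol$y)
}
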