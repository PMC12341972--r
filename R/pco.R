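#' Solver and relaxation settings for pathway-controlled optimization
#'
#' Defaults mirror the numerical configuration the method was developed
#' with: big-M constant 100, initialization scale zeta = 10, a near-exact
#' smooth signum (lambda = 1e50, eps = 1e-50) inside the force-bound
#' constraint, a unit-scale smooth signum (lambda = 1, eps = 1e-50) pinning
#' the switching variable, solver tolerance 1e-7 and an iteration cap of
#' 10000.
#'
#' @param big_M Big-M relaxation constant (> 0).
#' @param zeta Scale applied to the initial flux direction (> 0).
#' @param sign_lam_hcon,sign_eps_hcon Smooth-signum parameters used in the
#'   force-bound constraint definition of h.
#' @param sign_lam_switch,sign_eps_switch Smooth-signum parameters pinning
#'   the switching variable u.
#' @param tol Solver convergence tolerance.
#' @param max_iter Total inner-iteration cap across barrier stages.
#' @param mu_init,mu_final Initial and final barrier parameters of the
#'   interior-point continuation.
#' @param seed Seed controlling any randomized fallback; the primary
#'   initialization is deterministic.
#' @return An object of class `pco_settings`.
#' @export
pco_settings <- function(big_M = 100, zeta = 10,
                         sign_lam_hcon = 1e50, sign_eps_hcon = 1e-50,
                         sign_lam_switch = 1, sign_eps_switch = 1e-50,
                         tol = 1e-7, max_iter = 10000L,
                         mu_init = 1e-2, mu_final = 1e-9, seed = 0L) {
  stopifnot(big_M > 0, zeta > 0, tol > 0, max_iter > 0,
            mu_init > mu_final, mu_final > 0)
  structure(list(big_M = big_M, zeta = zeta,
                 sign_lam_hcon = sign_lam_hcon, sign_eps_hcon = sign_eps_hcon,
                 sign_lam_switch = sign_lam_switch,
                 sign_eps_switch = sign_eps_switch,
                 tol = tol, max_iter = as.integer(max_iter),
                 mu_init = mu_init, mu_final = mu_final,
                 seed = as.integer(seed)),
            class = "pco_settings")
}

#' Projected objective gradient direction
#'
#' The gradient of the growth objective with respect to the fluxes is the
#' 0/1 indicator of the growth set; its orthogonal projection onto the
#' steady-state flux space is the direction the initialization aims the
#' fluxes at.
#'
#' @param net A [metabolic_network()].
#' @param ns A [nullspace_basis()] for `net`.
#' @return Numeric vector over reactions.
#' @export
objective_gradient_direction <- function(net, ns) {
  gI <- growth_index(net)
  if (length(gI) == 0L)
    stop("network has no growth reactions", call. = FALSE)
  grad <- numeric(n_reactions(net))
  grad[gI] <- 1
  y_g <- project_to_nullspace(grad, ns)
  if (max(abs(y_g)) < 1e-12)
    stop("growth reactions unreachable at steady state: the objective ",
         "gradient is orthogonal to the nullspace of S_v", call. = FALSE)
  y_g
}

#' Initial point for the PCO solve
#'
#' Solves the bound-constrained least-squares problem
#' \deqn{\min_\eta \| sgn(-y_g) \circ (S^T\eta - \log K) - s \|^2,\quad
#'   s \ge 0,\ \eta_i \le \eta_{max}\ (i \in I_v),\ \eta_i = \bar\eta_i\
#'   (i \in I_f),}
#' aligning the signs of the thermodynamic driving forces with the projected
#' objective gradient. The slack is eliminated analytically
#' (\eqn{s_j^\star = \max(r_j, 0)}), leaving a smooth convex problem solved
#' by bounded quasi-Newton iterations. Initial fluxes are then
#' \eqn{y_0 = -\zeta P_{N(S_v)} (S^T\eta_0 - \log K)}.
#'
#' A zero residual certifies that \eqn{(\eta_0, \gamma y_g)} is feasible for
#' small \eqn{\gamma > 0}; a non-zero residual is reported so callers can
#' judge how far the start is from that guarantee.
#'
#' @param net A [metabolic_network()].
#' @param ns A [nullspace_basis()] for `net`.
#' @param settings A [pco_settings()].
#' @return An object of class `pco_init`: list with `eta0` (full state),
#'   `y0`, `slack`, `lsq_residual`, and `y_g`.
#' @export
pco_initialize <- function(net, ns, settings = pco_settings()) {
  y_g <- objective_gradient_direction(net, ns)
  sgn_target <- sign(-y_g)
  log_K <- net$reactions$log_K
  iv <- variable_index(net)
  Sv <- as.matrix(stoichiometric_matrix(net, variable_only = TRUE))
  eta_fixed_part <- net$metabolites$fixed_log_count
  eta_fixed_part[iv] <- 0
  g_fixed <- as.numeric(Matrix::crossprod(net$S, eta_fixed_part))

  obj <- function(ev) {
    g <- g_fixed + as.numeric(crossprod(Sv, ev))
    r <- sgn_target * (g - log_K)
    sum(pmin(r, 0)^2)
  }
  grad <- function(ev) {
    g <- g_fixed + as.numeric(crossprod(Sv, ev))
    r <- sgn_target * (g - log_K)
    as.numeric(Sv %*% (2 * pmin(r, 0) * sgn_target))
  }
  if (length(iv) > 0L) {
    # start from the least-squares equilibrium point S_v^T eta = log K - g_f,
    # clipped to the bound (flagged least-norm choice for rank-deficient S^T)
    ev0 <- tryCatch(qr.solve(qr(t(Sv), LAPACK = TRUE), log_K - g_fixed),
                    error = function(e) rep(0, length(iv)))
    ev0 <- pmin(ev0, net$eta_max)
    fit <- stats::optim(ev0, obj, grad, method = "L-BFGS-B",
                        lower = rep(-Inf, length(iv)),
                        upper = rep(net$eta_max, length(iv)),
                        control = list(maxit = 500L, factr = 1e1))
    ev <- fit$par
    if (fit$value < 1e-12) {
      # the zero-residual set is typically a region, and its boundary can
      # leave a growth-carrying reaction at equilibrium (zero flux cap);
      # tie-break toward interior points with sign margins of a few log
      # units, weighted by the projected objective gradient
      c_marg <- 3
      w <- abs(y_g) / max(abs(y_g)) + 1e-3
      obj_m <- function(ev) {
        g <- g_fixed + as.numeric(crossprod(Sv, ev))
        r <- sgn_target * (g - log_K)
        sum(w * (pmin(r, c_marg) - c_marg)^2) + 1e6 * sum(pmin(r, 0)^2)
      }
      grad_m <- function(ev) {
        g <- g_fixed + as.numeric(crossprod(Sv, ev))
        r <- sgn_target * (g - log_K)
        dr <- 2 * w * (pmin(r, c_marg) - c_marg) * (r < c_marg) +
          2e6 * pmin(r, 0)
        as.numeric(Sv %*% (dr * sgn_target))
      }
      fit_m <- stats::optim(ev, obj_m, grad_m, method = "L-BFGS-B",
                            lower = rep(-Inf, length(iv)),
                            upper = rep(net$eta_max, length(iv)),
                            control = list(maxit = 500L, factr = 1e1))
      if (obj(fit_m$par) < 1e-10) ev <- fit_m$par
    }
  } else ev <- numeric(0)

  eta0 <- assemble_eta(net, ev)
  g0 <- reaction_log_action(eta0, net)
  r0 <- sgn_target * (g0 - log_K)
  slack <- pmax(r0, 0)
  y0 <- -settings$zeta * project_to_nullspace(g0 - log_K, ns)
  structure(list(eta0 = eta0, y0 = y0, slack = slack,
                 lsq_residual = sqrt(sum(pmin(r0, 0)^2)), y_g = y_g),
            class = "pco_init")
}

## ---------------------------------------------------------------------------
## The relaxed big-M program
## ---------------------------------------------------------------------------

# h_j(y) = smooth_sign(y) * [log 2 - log(|y| + sqrt(y^2+4))] and derivative
h_of_y <- function(y, lam, eps) {
  r <- sqrt(y^2 + 4)
  b <- log(2) - log(abs(y) + r)
  s <- smooth_sign(y, lam, eps)
  h <- s * b
  db <- -(sign(y) + y / r) / (abs(y) + r)
  list(h = h, dh = smooth_sign_deriv(y, lam, eps) * b + s * db)
}

u_of_y <- function(y, lam, eps) {
  list(u = (smooth_sign(y, lam, eps) + 1) / 2,
       du = smooth_sign_deriv(y, lam, eps) / 2)
}

# relaxed log barrier: -log(c) for c > delta, quadratic extension below,
# keeping value and first derivative continuous at delta
relaxed_barrier <- function(c_, delta) {
  out <- numeric(length(c_))
  inside <- c_ > delta
  out[inside] <- -log(c_[inside])
  z <- (c_[!inside] - 2 * delta) / delta
  out[!inside] <- -log(delta) + 0.5 * (z^2 - 1)
  out
}

relaxed_barrier_deriv <- function(c_, delta) {
  out <- numeric(length(c_))
  inside <- c_ > delta
  out[inside] <- -1 / c_[inside]
  out[!inside] <- (c_[!inside] - 2 * delta) / delta^2
  out
}

#' Build the relaxed maximum-growth program
#'
#' Encodes the big-M relaxed PCO problem over the decision variables
#' \eqn{(\eta_v, \beta)}: maximize \eqn{\sum_{j\in G} y_j} with
#' \eqn{y = B\beta}, \eqn{g = S^T\eta}, the force-bound pair
#' \eqn{g_j - \log K_j \ge h_j - u_j M} and
#' \eqn{g_j - \log K_j \le h_j + (1-u_j) M}, the direction condition
#' \eqn{(\log K_j - g_j) y_j \ge 0}, bounds \eqn{\eta_i \le \eta_{max}} on
#' variable metabolites and equality on fixed ones. The definitional
#' equalities for \eqn{h_j} (near-exact smooth signum) and the switching
#' variable \eqn{u_j = (\tilde{sgn}(y_j)+1)/2} are substituted directly, so
#' u is continuous and held at the branch chosen by the initialization.
#'
#' @param net A [metabolic_network()].
#' @param ns A [nullspace_basis()].
#' @param settings A [pco_settings()].
#' @param init A `pco_init` point from [pco_initialize()] (the default).
#' @return An opaque program handle (class `pco_program`) with evaluation
#'   closures used by [solve_pco()] and a `counts` breakdown of the
#'   generated constraints.
#' @export
build_pco_program <- function(net, ns, settings = pco_settings(),
                              init = pco_initialize(net, ns, settings)) {
  nJ <- n_reactions(net)
  iv <- variable_index(net)
  nv <- length(iv)
  m <- ns$m
  B <- ns$basis
  Sv <- as.matrix(stoichiometric_matrix(net, variable_only = TRUE))
  log_K <- net$reactions$log_K
  gI <- growth_index(net)
  ind_G <- numeric(nJ); ind_G[gI] <- 1
  M <- settings$big_M
  eta_template <- net$metabolites$fixed_log_count
  g_fixed <- {
    ef <- eta_template; ef[iv] <- 0
    as.numeric(Matrix::crossprod(net$S, ef))
  }

  split_x <- function(x) list(ev = x[seq_len(nv)], beta = x[nv + seq_len(m)])

  pieces <- function(x) {
    p <- split_x(x)
    g <- g_fixed + if (nv) as.numeric(crossprod(Sv, p$ev)) else 0
    y <- as.numeric(B %*% p$beta)
    dgk <- g - log_K
    H <- h_of_y(y, settings$sign_lam_hcon, settings$sign_eps_hcon)
    U <- u_of_y(y, settings$sign_lam_switch, settings$sign_eps_switch)
    list(ev = p$ev, beta = p$beta, g = g, y = y, dgk = dgk, H = H, U = U,
         c1 = dgk - H$h + U$u * M,
         c2 = H$h + (1 - U$u) * M - dgk,
         c3 = -dgk * y)
  }

  barrier <- function(x, mu, delta) {
    z <- pieces(x)
    -sum(z$y[gI]) + mu * sum(relaxed_barrier(z$c1, delta) +
                             relaxed_barrier(z$c2, delta) +
                             relaxed_barrier(z$c3, delta))
  }
  barrier_grad <- function(x, mu, delta) {
    z <- pieces(x)
    p1 <- relaxed_barrier_deriv(z$c1, delta)
    p2 <- relaxed_barrier_deriv(z$c2, delta)
    p3 <- relaxed_barrier_deriv(z$c3, delta)
    dMu <- M * z$U$du
    dphi_dy <- -ind_G + mu * (p1 * (-z$H$dh + dMu) + p2 * (z$H$dh - dMu) +
                              p3 * (-z$dgk))
    dphi_dg <- mu * (p1 - p2 - p3 * z$y)
    c(if (nv) as.numeric(Sv %*% dphi_dg) else numeric(0),
      as.numeric(crossprod(B, dphi_dy)))
  }

  x0 <- c(init$eta0[iv], as.numeric(crossprod(B, init$y0)))
  structure(list(
    net = net, ns = ns, settings = settings, init = init,
    nv = nv, m = m, x0 = x0,
    lower = c(rep(-Inf, nv), rep(-Inf, m)),
    upper = c(rep(net$eta_max, nv), rep(Inf, m)),
    pieces = pieces, barrier = barrier, barrier_grad = barrier_grad,
    u0 = (sign(init$y0) + 1) / 2,
    counts = list(eta_bounds = nv, eta_fixed = length(fixed_index(net)),
                  bigM_pair = 2L * nJ, direction = nJ,
                  definitions_h = nJ, definitions_u = nJ)),
    class = "pco_program")
}

#' @export
print.pco_program <- function(x, ...) {
  cts <- x$counts
  cat(sprintf(paste0("<pco_program> %d variables (%d log counts + %d nullspace ",
                     "coords)\n  constraints: %d bigM + %d direction ",
                     "inequalities, %d + %d definitional equalities, ",
                     "%d bounds, %d fixed\n"),
              x$nv + x$m, x$nv, x$m, cts$bigM_pair, cts$direction,
              cts$definitions_h, cts$definitions_u, cts$eta_bounds,
              cts$eta_fixed))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Interior-point solve
## ---------------------------------------------------------------------------

# largest t such that (eta, t*ydir) passes the flux-cap/direction bounds;
# used for guaranteed-feasible fallback candidates
feasible_scaling <- function(net, eta, ydir, safety = 1 - 1e-9) {
  g <- reaction_log_action(eta, net)
  d <- net$reactions$log_K - g
  active <- abs(ydir) > 1e-14
  if (!any(active)) return(0)
  t_max <- Inf
  for (j in which(active)) {
    if (sign(ydir[j]) != sign(d[j])) return(0)
    z <- min(abs(d[j]), 300)
    t_max <- min(t_max, (exp(z) - exp(-z)) / abs(ydir[j]))
  }
  safety * t_max
}

# damped projected-Newton refinement of a barrier subproblem: the barrier
# terms are stiff near the central path and quasi-Newton line searches stall
# there, while an explicit (finite-difference) Hessian with eigenvalue
# modification tracks it reliably at these problem sizes
newton_refine <- function(value, gradient, x, mu, delta, upper,
                          maxit = 60L) {
  n <- length(x)
  f <- value(x, mu, delta)
  used <- 0L
  for (it in seq_len(maxit)) {
    gr <- gradient(x, mu, delta)
    H <- matrix(0, n, n)
    hstep <- 1e-6 * pmax(abs(x), 1)
    for (k in seq_len(n)) {
      xk <- x; xk[k] <- xk[k] + hstep[k]
      H[, k] <- (gradient(xk, mu, delta) - gr) / hstep[k]
    }
    H <- (H + t(H)) / 2
    ee <- eigen(H, symmetric = TRUE)
    ev <- pmax(abs(ee$values), 1e-8 * max(abs(ee$values), 1e-8))
    step <- -as.numeric(ee$vectors %*% ((crossprod(ee$vectors, gr)) / ev))
    t_ <- 1; ok <- FALSE
    for (ls in 1:40) {
      xn <- pmin(x + t_ * step, upper)
      fn <- value(xn, mu, delta)
      if (is.finite(fn) && fn < f - 1e-12 * abs(f)) { ok <- TRUE; break }
      t_ <- t_ / 2
    }
    used <- it
    if (!ok) break
    x <- xn; f <- fn
  }
  list(x = x, f = f, iterations = used)
}

# One barrier continuation stage. The relaxation threshold delta is kept
# small and fixed (not tied to mu): the growth objective is exponential in
# the log-space constraint displacements, so a loose quadratic extension can
# be out-run by the objective and the iterates diverge into deep violation.
# As a second safeguard, any mu-step whose iterate grossly violates the true
# constraints (min_c below -0.5) is reverted.
solve_barrier_stage <- function(program, x0, value, gradient, mu_seq,
                                iter_budget, min_constraint = NULL) {
  x <- x0
  iters <- 0L
  conv <- 0L
  n <- length(x0)
  for (mu in mu_seq) {
    delta <- min(mu, 1e-4)
    fit <- stats::optim(x, value, gradient, mu = mu, delta = delta,
                        method = "L-BFGS-B",
                        lower = program$lower, upper = program$upper,
                        control = list(maxit = min(500L,
                                                   max(50L, iter_budget - iters)),
                                       factr = 1e2, pgtol = 0))
    x_new <- fit$par
    iters <- iters + fit$counts[["function"]]
    conv_new <- fit$convergence
    if (n <= 200L && iters < iter_budget) {
      nr <- newton_refine(value, gradient, x_new, mu, delta, program$upper)
      if (is.finite(nr$f) && nr$f <= fit$value) {
        x_new <- nr$x
        conv_new <- 0L
      }
      iters <- iters + nr$iterations
    }
    if (!is.null(min_constraint) && min_constraint(x_new) < -0.5) break
    x <- x_new
    conv <- conv_new
    if (iters >= iter_budget) break
  }
  list(x = x, iterations = iters, convergence = conv)
}

# smooth fixed-sign polish stage: maximize growth with per-reaction
# constraints sigma*y >= 0 and sigma*y <= 2 sinh(sigma*(logK - g))
polish_program <- function(program, sigma) {
  net <- program$net
  gI <- growth_index(net)
  ind_G <- numeric(n_reactions(net)); ind_G[gI] <- 1
  value <- function(x, mu, delta) {
    z <- program$pieces(x)
    a <- sigma * z$y
    zarg <- pmax(pmin(-sigma * z$dgk, 30), -30)
    cap <- exp(zarg) - exp(-zarg)
    -sum(z$y[gI]) + mu * sum(relaxed_barrier(a, delta) +
                             relaxed_barrier(cap - a, delta))
  }
  gradient <- function(x, mu, delta) {
    z <- program$pieces(x)
    a <- sigma * z$y
    zarg <- -sigma * z$dgk
    clamped <- abs(zarg) > 30
    zarg <- pmax(pmin(zarg, 30), -30)
    cap <- exp(zarg) - exp(-zarg)
    dcap_dg <- ifelse(clamped, 0, -(exp(zarg) + exp(-zarg)) * sigma)
    pa <- relaxed_barrier_deriv(a, delta)
    pb <- relaxed_barrier_deriv(cap - a, delta)
    dphi_dy <- -ind_G + mu * (pa * sigma - pb * sigma)
    dphi_dg <- mu * (pb * dcap_dg)
    nv <- program$nv
    Sv <- as.matrix(stoichiometric_matrix(net, variable_only = TRUE))
    c(if (nv) as.numeric(Sv %*% dphi_dg) else numeric(0),
      as.numeric(crossprod(program$ns$basis, dphi_dy)))
  }
  min_constraint <- function(x) {
    z <- program$pieces(x)
    a <- sigma * z$y
    zarg <- pmax(pmin(-sigma * z$dgk, 30), -30)
    min(a, exp(zarg) - exp(-zarg) - a)
  }
  list(value = value, gradient = gradient, min_constraint = min_constraint)
}

#' Solve the pathway-controlled optimization problem
#'
#' Runs the full pipeline: nullspace construction, feasibility-oriented
#' initialization, the big-M relaxed program, and a two-stage interior-point
#' (relaxed log-barrier) solve with decreasing barrier parameter — a first
#' pass on the big-M program to settle the flux directions, then a
#' sign-fixed smooth polish pass driving the barrier parameter to its final
#' value. The solution is post-processed with [recover_activities()],
#' [reducibility_certificate()] and [validate_solution()]. Guaranteed-
#' feasible scaled versions of the initial flux direction serve as fallback
#' candidates so an accepted solution never regresses below the feasible
#' initial point.
#'
#' @param net A [metabolic_network()] with at least one growth reaction.
#' @param settings A [pco_settings()].
#' @return An object of class `pco_fit`. See [pco()] for the fitted-model
#'   interface.
#' @export
solve_pco <- function(net, settings = pco_settings()) {
  stopifnot(inherits(net, "metabolic_network"))
  if (length(growth_index(net)) == 0L)
    stop("PCO needs a non-empty growth reaction set", call. = FALSE)
  ns <- nullspace_basis(net)
  init <- pco_initialize(net, ns, settings)
  program <- build_pco_program(net, ns, settings, init)
  gI <- growth_index(net)
  budget <- settings$max_iter

  mu_seq1 <- 10^seq(log10(settings$mu_init), -6, by = -1)
  min_con1 <- function(x) {
    z <- program$pieces(x)
    min(z$c1, z$c2, z$c3)
  }
  st1 <- solve_barrier_stage(program, program$x0, program$barrier,
                             program$barrier_grad, mu_seq1,
                             iter_budget = round(budget / 2),
                             min_constraint = min_con1)

  z1 <- program$pieces(st1$x)
  sigma <- sign(z1$y)
  sigma[sigma == 0] <- sign(-z1$dgk)[sigma == 0]
  sigma[sigma == 0] <- 1
  pol <- polish_program(program, sigma)
  mu_seq2 <- 10^seq(-3, log10(settings$mu_final), by = -1)
  st2 <- solve_barrier_stage(program, st1$x, pol$value, pol$gradient, mu_seq2,
                             iter_budget = budget - st1$iterations,
                             min_constraint = pol$min_constraint)

  # candidate solutions: polish result, big-M stage result, and
  # guaranteed-feasible scalings of the initial direction
  cert_tol <- settings$tol * 10
  mk_candidate <- function(eta, y) {
    # snap sub-tolerance fluxes to exact zero when that keeps the vector in
    # the nullspace (barrier iterates hold them strictly interior)
    y_s <- y
    y_s[abs(y_s) < cert_tol] <- 0
    if (!identical(y_s, y)) {
      y_p <- project_to_nullspace(y_s, ns)
      if (max(abs(y_p - y_s)) < 1e-12) y <- y_s
    }
    cert <- reducibility_certificate(eta, y, net, tol = cert_tol)
    alpha <- if (cert$feasible)
      tryCatch(recover_activities(eta, y, net, tol = cert_tol),
               error = function(e) NULL) else NULL
    list(eta = eta, y = y, beta = as.numeric(crossprod(ns$basis, y)),
         cert = cert, alpha = alpha, objective = sum(y[gI]),
         valid = cert$feasible && !is.null(alpha))
  }
  from_x <- function(x) {
    z <- program$pieces(x)
    mk_candidate(assemble_eta(net, z$ev), z$y)
  }
  cands <- list(polish = from_x(st2$x), bigM = from_x(st1$x))
  for (nm in c("y0", "y_g")) {
    ydir <- if (nm == "y0") init$y0 else init$y_g
    t_ <- feasible_scaling(net, init$eta0, ydir)
    cands[[nm]] <- mk_candidate(init$eta0, t_ * ydir)
  }
  valid <- vapply(cands, function(cc) cc$valid, logical(1))
  iterations <- st1$iterations + st2$iterations

  if (!any(valid)) {
    best <- cands$polish
    status <- "infeasible"
    alpha <- rep(NA_real_, n_reactions(net))
  } else {
    objs <- vapply(cands, function(cc) cc$objective, numeric(1))
    objs[!valid] <- -Inf
    pick <- names(which.max(objs))
    best <- cands[[pick]]
    converged <- st2$convergence == 0L && iterations < budget
    status <- if (converged) "optimal"
              else if (iterations >= budget) "max_iter" else "acceptable"
    alpha <- best$alpha
  }
  u <- (sign(best$y) + 1) / 2

  fit <- structure(list(
    network = net, settings = settings, nullspace = ns, init = init,
    eta = best$eta, y = stats::setNames(best$y, net$reactions$id),
    beta = best$beta, alpha = alpha, u = u,
    objective = best$objective, certificate = best$cert,
    solver_status = status, iterations = iterations),
    class = "pco_fit")
  fit$validation <- validate_solution(fit, net)
  fit
}

#' Fit the pathway-controlled optimization model
#'
#' `pco()` is the fitting-function interface to [solve_pco()]: it returns a
#' classed object with `print`, `summary`, `coef` (activity coefficients),
#' `fitted` (steady-state fluxes), `residuals` (regulated mass-balance
#' residual) and `plot` (cumulative flux distribution) methods.
#'
#' @inheritParams solve_pco
#' @param ... Passed to [pco_settings()] if `settings` is not supplied.
#' @param settings A [pco_settings()].
#' @export
pco <- function(net, ..., settings = pco_settings(...)) {
  solve_pco(net, settings = settings)
}

#' Validate a regulated steady-state solution
#'
#' Recomputes, from scratch, every property an accepted PCO solution must
#' satisfy: the nullspace residual of the fluxes, activity bounds, the
#' flux-inversion residual \eqn{\|S^T\eta - \hat y(y,\alpha)\|_\infty}
#' (on reactions with non-negligible activity), thermodynamic sign
#' consistency, the log-count bounds, and stationarity of the regulated
#' dynamics.
#'
#' @param sol A `pco_fit`, or any list with elements `eta`, `y`, `alpha`.
#' @param net The network; defaults to `sol$network`.
#' @param tol Pass tolerance for every check.
#' @return A data.frame (class `pco_validation`) with one row per check and
#'   columns `check`, `value`, `tol`, `pass`; attribute `ok` is the
#'   conjunction.
#' @export
validate_solution <- function(sol, net = sol$network, tol = 1e-6) {
  eta <- sol$eta; y <- as.numeric(sol$y); alpha <- as.numeric(sol$alpha)
  iv <- variable_index(net); fi <- fixed_index(net)
  Sv <- stoichiometric_matrix(net, variable_only = TRUE)
  g <- reaction_log_action(eta, net)
  log_K <- net$reactions$log_K

  checks <- list()
  add <- function(name, value) checks[[name]] <<- value
  add("steady_state", max(abs(as.numeric(Sv %*% y)), 0))
  if (all(is.finite(alpha))) {
    add("alpha_bounds", max(0, max(alpha - 1), max(-alpha)))
    act <- alpha > 1e-12
    add("flux_inversion", if (any(act))
      max(abs(g[act] - y_hat(y[act], alpha[act], log_K[act]))) else 0)
    J <- log_space_flux(eta, net, alpha)
    add("stationarity",
        max(abs(as.numeric(Sv %*% J))) / max(1, max(abs(J))))
  } else {
    add("alpha_bounds", Inf); add("flux_inversion", Inf)
    add("stationarity", Inf)
  }
  add("direction", max(0, -min((log_K - g) * y)))
  add("eta_bound", if (length(iv)) max(0, max(eta[iv] - net$eta_max)) else 0)
  add("eta_fixed", if (length(fi))
    max(abs(eta[fi] - net$metabolites$fixed_log_count[fi])) else 0)

  out <- data.frame(check = names(checks),
                    value = unlist(checks, use.names = FALSE),
                    tol = tol, stringsAsFactors = FALSE)
  out$pass <- out$value <= tol
  attr(out, "ok") <- all(out$pass)
  class(out) <- c("pco_validation", class(out))
  out
}
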