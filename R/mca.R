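#' Steady state of the regulated dynamics at fixed activities
#'
#' Solves \eqn{\sum_j \gamma_{ij} J_j(n, \alpha_j) = 0} for all variable
#' metabolites with fixed metabolites pinned at their boundary values.
#' Primary method: damped Newton on the residual in log-count space (the
#' Jacobian \eqn{S_v \,\mathrm{diag}(\partial J/\partial g)\, S_v^T} is
#' analytic and negative semidefinite), with a backtracking line search and
#' a Levenberg-style ridge on near-singular steps. If Newton stalls, the
#' stiff mass-balance ODE is integrated from the current iterate until the
#' residual contracts, then Newton resumes.
#'
#' @param net A [metabolic_network()].
#' @param alpha Activity coefficients over reactions (recycled).
#' @param eta_guess Optional full starting state; defaults to a least-squares
#'   equilibrium point.
#' @param tol Convergence: `max|rhs| <= tol * max(1, flux scale)`.
#' @param max_iter Newton iteration cap per attempt.
#' @return Named numeric log-count vector over all metabolites.
#' @export
solve_steady_state <- function(net, alpha = 1, eta_guess = NULL,
                               tol = 1e-10, max_iter = 200L) {
  iv <- variable_index(net)
  alpha <- rep_len(alpha, n_reactions(net))
  if (length(iv) == 0L) return(assemble_eta(net, numeric(0)))
  Sv <- as.matrix(stoichiometric_matrix(net, variable_only = TRUE))
  log_K <- net$reactions$log_K

  if (is.null(eta_guess)) {
    ef <- net$metabolites$fixed_log_count; ef[iv] <- 0
    g_fixed <- as.numeric(Matrix::crossprod(net$S, ef))
    ev <- tryCatch(qr.solve(qr(t(Sv), LAPACK = TRUE), log_K - g_fixed),
                   error = function(e) rep(0, length(iv)))
  } else ev <- eta_guess[iv]

  resid <- function(ev) {
    eta <- assemble_eta(net, ev)
    J <- log_space_flux(eta, net, alpha)
    list(r = as.numeric(Sv %*% J), J = J, eta = eta)
  }
  scale_of <- function(J) max(1, max(abs(J)))

  newton <- function(ev) {
    for (it in seq_len(max_iter)) {
      rz <- resid(ev)
      if (max(abs(rz$r)) <= tol * scale_of(rz$J)) return(list(ev = ev, ok = TRUE))
      d <- log_K - reaction_log_action(rz$eta, net)
      w <- -alpha * (exp(d) + exp(-d))        # dJ_j / dg_j
      Jac <- Sv %*% (w * t(Sv))
      step <- tryCatch(solve(Jac, -rz$r), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step)))
        step <- tryCatch(solve(Jac - diag(1e-8 * max(abs(w)), length(ev)),
                               -rz$r), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step)))
        return(list(ev = ev, ok = FALSE))
      t_ <- 1
      r0 <- max(abs(rz$r))
      repeat {
        rn <- resid(ev + t_ * step)
        if (all(is.finite(rn$r)) && max(abs(rn$r)) < (1 - 1e-4 * t_) * r0) break
        t_ <- t_ / 2
        if (t_ < 1e-12) return(list(ev = ev, ok = FALSE))
      }
      ev <- ev + t_ * step
    }
    rz <- resid(ev)
    list(ev = ev, ok = max(abs(rz$r)) <= tol * scale_of(rz$J))
  }

  ans <- newton(ev)
  if (!ans$ok) {
    # stiff integration fallback: dn/dt = S_v J, integrated in count space
    derivs <- function(t, state, parms) {
      eta <- assemble_eta(net, log(pmax(state, 1e-300)))
      list(as.numeric(Sv %*% log_space_flux(eta, net, alpha)))
    }
    n0 <- exp(pmin(ans$ev, 500))
    for (t_end in 10^seq(-3, 6, by = 1)) {
      traj <- tryCatch(
        deSolve::lsoda(n0, c(0, t_end), derivs, NULL,
                       rtol = 1e-10, atol = 1e-12),
        error = function(e) NULL)
      if (is.null(traj) || nrow(traj) < 2L) next
      n0 <- pmax(as.numeric(traj[nrow(traj), -1]), 1e-300)
      ans <- newton(log(n0))
      if (ans$ok) break
    }
  }
  if (!ans$ok) {
    rz <- resid(ans$ev)
    stop(sprintf(paste0("steady-state solve did not converge: final residual ",
                        "%.3g (tolerance %.3g)"),
                 max(abs(rz$r)), tol * scale_of(rz$J)), call. = FALSE)
  }
  assemble_eta(net, ans$ev)
}

#' Concentration control coefficients
#'
#' \eqn{C_{ij} = \partial \ln n_i / \partial \ln \alpha_j} at a steady
#' state, estimated by central finite differences in \eqn{\ln \alpha_j}:
#' the steady state is re-solved at \eqn{\alpha_j e^{\pm rel\_step}}.
#' Reactions with \eqn{\alpha_j = 0} cannot be perturbed downward in log and
#' get a zero column; a failed re-solve flags the column with `NA` rather
#' than zeroing it silently.
#'
#' @param net A [metabolic_network()].
#' @param alpha Activity coefficients at which the steady state holds.
#' @param eta_ss The steady state for `alpha` (used as warm start).
#' @param rel_step Relative log step, in (0, 1).
#' @return Matrix |I_v| x |J| of sensitivities (rows named by metabolite,
#'   columns by reaction); attribute `failed` lists unperturbable columns.
#' @export
control_coefficients <- function(net, alpha, eta_ss, rel_step = 0.05) {
  stopifnot(rel_step > 0, rel_step < 1)
  iv <- variable_index(net)
  alpha <- rep_len(alpha, n_reactions(net))
  C <- matrix(0, length(iv), n_reactions(net),
              dimnames = list(net$metabolites$id[iv], net$reactions$id))
  failed <- character(0)
  for (j in seq_len(n_reactions(net))) {
    if (alpha[j] <= 0) next
    a_plus <- a_minus <- alpha
    a_plus[j] <- min(alpha[j] * exp(rel_step), 1)
    a_minus[j] <- alpha[j] * exp(-rel_step)
    span <- log(a_plus[j]) - log(a_minus[j])
    eta_p <- tryCatch(solve_steady_state(net, a_plus, eta_guess = eta_ss),
                      error = function(e) NULL)
    eta_m <- tryCatch(solve_steady_state(net, a_minus, eta_guess = eta_ss),
                      error = function(e) NULL)
    if (is.null(eta_p) || is.null(eta_m)) {
      C[, j] <- NA_real_
      failed <- c(failed, net$reactions$id[j])
      next
    }
    C[, j] <- (eta_p[iv] - eta_m[iv]) / span
  }
  if (length(failed))
    warning("control-coefficient columns failed to re-solve: ",
            paste(failed, collapse = ", "), call. = FALSE)
  attr(C, "failed") <- failed
  C
}

#' MCA concentration-capping regulation loop
#'
#' The comparison baseline: starting from the unregulated steady state,
#' iteratively reduce enzyme activities until every variable metabolite sits
#' at or below the physiological cap. Each iteration (1) solves the steady
#' state, (2) finds cap violations, (3) targets the metabolite with the
#' largest log-ratio violation, (4) picks the reaction whose activity has
#' the largest violation-weighted aggregate control coefficient over all
#' violating metabolites (restricted, when possible, to reactions whose
#' coefficient on the target is positive so that reducing the activity
#' reduces the target), and (5) multiplies that activity by a reduction
#' factor.
#'
#' @param net A [metabolic_network()].
#' @param n_cap Concentration cap in mM applied to all variable metabolites.
#' @param reduction_factor Multiplicative activity reduction per step.
#' @param rel_step Finite-difference step for [control_coefficients()].
#' @param max_iter Iteration cap; reaching it with violations remaining
#'   returns a partial result with a warning.
#' @param tol Cap slack in log-count units.
#' @return An object of class `mca_fit`: activities `alpha`, terminal state
#'   `eta`, fluxes `y`, a step-by-step `trace` data.frame, and `converged`.
#' @export
mca_regulate <- function(net, n_cap = 1.0, reduction_factor = 0.5,
                         rel_step = 0.05, max_iter = 100L, tol = 1e-6) {
  eta_cap <- concentration_to_log_count(n_cap, net$units)
  iv <- variable_index(net)
  alpha <- rep(1, n_reactions(net))
  trace <- list()
  eta <- solve_steady_state(net, alpha)
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    viol <- eta[iv] - eta_cap
    bad <- which(viol > tol)
    if (length(bad) == 0L) { converged <- TRUE; break }
    target <- bad[which.max(viol[bad])]
    C <- control_coefficients(net, alpha, eta, rel_step = rel_step)
    C[!is.finite(C)] <- 0
    score <- as.numeric(viol[bad] %*% C[bad, , drop = FALSE])
    eligible <- alpha > 1e-12 & C[target, ] > 0
    j <- if (any(eligible)) {
      which(eligible)[which.max(score[eligible])]
    } else {
      cand <- which(alpha > 1e-12)
      if (!length(cand)) break
      cand[which.max(C[target, cand])]
    }
    alpha[j] <- alpha[j] * reduction_factor
    eta <- solve_steady_state(net, alpha, eta_guess = eta)
    trace[[it]] <- data.frame(
      iteration = it, metabolite = net$metabolites$id[iv][target],
      reaction = net$reactions$id[j], new_alpha = alpha[j],
      max_violation = max(viol), stringsAsFactors = FALSE)
  }
  viol <- eta[iv] - eta_cap
  if (!converged && all(viol <= tol)) converged <- TRUE
  if (!converged)
    warning(sprintf("cap not reached after %d iterations (max violation %.3g)",
                    max_iter, max(viol)), call. = FALSE)
  structure(list(
    network = net, n_cap = n_cap, eta_cap = eta_cap,
    alpha = stats::setNames(alpha, net$reactions$id),
    eta = eta,
    y = stats::setNames(log_space_flux(eta, net, alpha), net$reactions$id),
    trace = if (length(trace)) do.call(rbind, trace) else
      data.frame(iteration = integer(), metabolite = character(),
                 reaction = character(), new_alpha = numeric(),
                 max_violation = numeric(), stringsAsFactors = FALSE),
    converged = converged),
    class = "mca_fit")
}

#' @rdname mca_regulate
#' @param ... Passed to [mca_regulate()].
#' @export
mca <- function(net, ...) mca_regulate(net, ...)

#' Compare PCO and MCA regulation on the same network
#'
#' Builds the side-by-side comparison table: per reaction, the MCA and PCO
#' steady-state fluxes, both activity coefficients, and the |flux| ratio.
#'
#' @param pco_fit A `pco_fit`.
#' @param mca_fit An `mca_fit` on the same network.
#' @param regulated_only Keep only reactions regulated (activity below
#'   `alpha_threshold`) in at least one method.
#' @param alpha_threshold Activity below which a reaction counts as
#'   regulated.
#' @return A data.frame with columns `reaction`, `J_MCA`, `J_PCO`,
#'   `alpha_MCA`, `alpha_PCO`, `flux_ratio`, `is_growth`.
#' @export
compare_regulation <- function(pco_fit, mca_fit, regulated_only = FALSE,
                               alpha_threshold = 1 - 1e-6) {
  stopifnot(inherits(pco_fit, "pco_fit"), inherits(mca_fit, "mca_fit"))
  out <- data.frame(
    reaction = pco_fit$network$reactions$id,
    J_MCA = as.numeric(mca_fit$y), J_PCO = as.numeric(pco_fit$y),
    alpha_MCA = as.numeric(mca_fit$alpha),
    alpha_PCO = as.numeric(pco_fit$alpha),
    flux_ratio = abs(as.numeric(pco_fit$y)) /
      pmax(abs(as.numeric(mca_fit$y)), .Machine$double.xmin),
    is_growth = pco_fit$network$reactions$growth,
    stringsAsFactors = FALSE)
  if (regulated_only)
    out <- out[out$alpha_MCA < alpha_threshold |
               out$alpha_PCO < alpha_threshold, , drop = FALSE]
  out
}
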