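#' Thermodynamic reaction forces
#'
#' The force on reaction j is \eqn{f_j = K_j \prod_i n_i^{-\gamma_{ij}}},
#' computed in log space as \eqn{\exp(\log K_j - \langle S_j, \eta\rangle)}
#' for numerical stability. A force above 1 drives the reaction forward,
#' below 1 backward; 1 is equilibrium.
#'
#' @param eta Log-count state vector over all metabolites (network order).
#' @param net A [metabolic_network()].
#' @param j Optional reaction index/indices; default all reactions.
#' @return Numeric vector of forces. Overflow yields `Inf` with a warning.
#' @export
reaction_force <- function(eta, net, j = NULL) {
  g <- reaction_log_action(eta, net)
  lf <- net$reactions$log_K - g
  if (!is.null(j)) lf <- lf[j]
  f <- exp(lf)
  if (any(!is.finite(f)))
    warning("reaction force overflow: returning infinite force", call. = FALSE)
  f
}

# g = S^T eta, the per-reaction log mass-action quotient
reaction_log_action <- function(eta, net) {
  stopifnot(length(eta) == n_metabolites(net))
  as.numeric(Matrix::crossprod(net$S, eta))
}

#' Regulated Marcelin net flux from a force
#'
#' \eqn{J = \alpha (f - 1/f)}: the maximum-path-entropy flux law with an
#' activity coefficient \eqn{\alpha \in [0,1]} linearly scaling the rate.
#' \eqn{\alpha = 1} is the unregulated reaction; \eqn{\alpha = 0} shuts it off.
#'
#' @param force Thermodynamic force(s), strictly positive.
#' @param alpha Activity coefficient(s) in \[0, 1\], recycled.
#' @export
net_flux <- function(force, alpha = 1) {
  if (any(force <= 0) || any(is.na(force)))
    stop("forces must be strictly positive", call. = FALSE)
  if (any(alpha < -1e-12) || any(alpha > 1 + 1e-12))
    stop("activity coefficients must lie in [0, 1]", call. = FALSE)
  alpha * (force - 1 / force)
}

#' Regulated fluxes as a function of log counts
#'
#' Evaluates \eqn{J_j = \alpha_j K_j e^{-\langle S_j,\eta\rangle} -
#' (\alpha_j/K_j) e^{\langle S_j,\eta\rangle}} for every reaction, all
#' arithmetic in log space before exponentiation.
#'
#' @inheritParams reaction_force
#' @param alpha Activity coefficients over reactions (recycled).
#' @return Numeric flux vector over reactions.
#' @export
log_space_flux <- function(eta, net, alpha = 1) {
  g <- reaction_log_action(eta, net)
  d <- net$reactions$log_K - g
  alpha <- rep_len(alpha, length(d))
  alpha * (exp(d) - exp(-d))
}

#' Log mass-action quotient required to carry a given flux
#'
#' Inverts the regulated Marcelin flux law: given a flux value y and an
#' activity alpha, returns the value of \eqn{g_j = \langle S_j, \eta\rangle}
#' at which reaction j carries exactly that flux,
#' \deqn{\hat y_j = \log K_j + sgn(y)[\log(2\alpha) - \log(|y| +
#'   \sqrt{y^2 + 4\alpha^2})].}
#' The `direct` form \eqn{\log K_j + \log[(-y + \sqrt{y^2+4\alpha^2}) /
#' (2\alpha)]} is algebraically identical but suffers catastrophic
#' cancellation for large positive y; the sign-split `stable` form is the
#' default.
#'
#' @param y Flux value(s).
#' @param alpha Activity coefficient(s), must be positive (recycled).
#' @param log_K Log equilibrium constant(s) (recycled).
#' @param form `"stable"` (default) or `"direct"`.
#' @return The required log mass-action quotient \eqn{\hat y}.
#' @export
y_hat <- function(y, alpha, log_K = 0, form = c("stable", "direct")) {
  form <- match.arg(form)
  n <- max(length(y), length(alpha), length(log_K))
  y <- rep_len(y, n); alpha <- rep_len(alpha, n); log_K <- rep_len(log_K, n)
  if (any(alpha < 0)) stop("alpha must be non-negative", call. = FALSE)
  if (any(alpha == 0 & y != 0))
    stop("alpha = 0 with nonzero flux admits no solution", call. = FALSE)
  out <- if (form == "stable") {
    log_K + sign(y) * (log(2 * alpha) - log(abs(y) + sqrt(y^2 + 4 * alpha^2)))
  } else {
    log_K + log((-y + sqrt(y^2 + 4 * alpha^2)) / (2 * alpha))
  }
  # alpha = 0, y = 0: any g works; return log K (equilibrium) by convention
  degenerate <- alpha == 0 & y == 0
  if (any(degenerate)) {
    out[degenerate] <- log_K[degenerate]
    attr(out, "degenerate") <- which(degenerate)
  }
  out
}

#' Sensitivity of the flux inversion to the flux
#'
#' Magnitude of the derivative of [y_hat()] with respect to the flux,
#' \eqn{|\partial \hat y / \partial y| = 1/\sqrt{y^2 + 4\alpha^2}}, which
#' grows without bound as both the flux and the activity go to zero — the
#' numerical motivation for the implicit-regulation steady-state conditions.
#' (The signed derivative is \eqn{-1/\sqrt{y^2+4\alpha^2}}: raising the flux
#' through a reaction lowers the log mass-action quotient able to carry it.)
#'
#' @inheritParams y_hat
#' @export
y_hat_sensitivity <- function(y, alpha) {
  n <- max(length(y), length(alpha))
  y <- rep_len(y, n); alpha <- rep_len(alpha, n)
  if (any(y == 0 & alpha == 0))
    stop("sensitivity is unbounded at y = alpha = 0", call. = FALSE)
  1 / sqrt(y^2 + 4 * alpha^2)
}

#' Smooth signum approximation
#'
#' \eqn{\tilde{sgn}(x) = \lambda x / (\lambda |x| + \epsilon)}: an odd
#' function with range (-1, 1) approaching the signum as
#' \eqn{\epsilon/\lambda \to 0}. Used where the optimization formulation
#' needs a differentiable stand-in for sgn.
#'
#' @param x Numeric vector.
#' @param lam Scale \eqn{\lambda > 0}.
#' @param eps Softening \eqn{\epsilon > 0}.
#' @export
smooth_sign <- function(x, lam = 1, eps = 1e-50) {
  stopifnot(lam > 0, eps > 0)
  lam * x / (lam * abs(x) + eps)
}

# derivative of smooth_sign w.r.t. x
smooth_sign_deriv <- function(x, lam = 1, eps = 1e-50) {
  lam * eps / (lam * abs(x) + eps)^2
}

#' Time derivative of variable metabolite counts
#'
#' Mass-balance right-hand side \eqn{dn_i/dt = \sum_j \gamma_{ij}
#' J_j(n, \alpha_j)} restricted to variable metabolites; fixed metabolites
#' are boundary species with zero rate by definition.
#'
#' @inheritParams log_space_flux
#' @return Named numeric vector over variable metabolites.
#' @export
dynamics_rhs <- function(eta, net, alpha = 1) {
  J <- log_space_flux(eta, net, alpha)
  Sv <- stoichiometric_matrix(net, variable_only = TRUE)
  stats::setNames(as.numeric(Sv %*% J), rownames(Sv))
}
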