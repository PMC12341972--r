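#' Orthonormal nullspace basis of the variable-rows stoichiometric matrix
#'
#' Every steady-state flux vector lies in \eqn{N(S_v)}. The basis is computed
#' by singular-value decomposition with rank tolerance
#' `tol * max(singular value)`; columns are orthonormal, so the projector
#' onto the steady-state flux space is simply \eqn{B B^T}. Column signs are
#' normalized (first entry of largest magnitude made positive) so the basis
#' is deterministic for a given network.
#'
#' @param net A [metabolic_network()].
#' @param tol Relative rank tolerance for the SVD.
#' @return An object of class `nullspace_basis`: list with `basis`
#'   (|J| x m matrix), `m` (nullspace dimension) and `rank` (rank of S_v).
#' @export
nullspace_basis <- function(net, tol = 1e-10) {
  Sv <- as.matrix(stoichiometric_matrix(net, variable_only = TRUE))
  nJ <- ncol(Sv)
  if (nrow(Sv) == 0L) {
    B <- diag(nJ)
    return(structure(list(basis = B, m = nJ, rank = 0L),
                     class = "nullspace_basis"))
  }
  sv <- svd(Sv, nu = 0, nv = nJ)
  rk <- sum(sv$d > tol * max(sv$d, 0))
  m <- nJ - rk
  if (m == 0L)
    stop("S_v has full column rank: no nonzero steady state exists",
         call. = FALSE)
  B <- sv$v[, (rk + 1L):nJ, drop = FALSE]
  # deterministic sign convention
  for (k in seq_len(ncol(B))) {
    piv <- which.max(abs(B[, k]))
    if (B[piv, k] < 0) B[, k] <- -B[, k]
  }
  rownames(B) <- colnames(Sv)
  structure(list(basis = B, m = m, rank = rk), class = "nullspace_basis")
}

#' @export
print.nullspace_basis <- function(x, ...) {
  cat(sprintf("<nullspace_basis> dimension %d (rank of S_v = %d, |J| = %d)\n",
              x$m, x$rank, nrow(x$basis)))
  invisible(x)
}

#' Orthogonal projection onto the steady-state flux space
#'
#' \eqn{P_{N(S_v)} v = B B^T v} for an orthonormal basis B; idempotent and
#' symmetric.
#'
#' @param v Numeric vector over reactions.
#' @param ns A [nullspace_basis()].
#' @export
project_to_nullspace <- function(v, ns) {
  stopifnot(inherits(ns, "nullspace_basis"), length(v) == nrow(ns$basis))
  as.numeric(ns$basis %*% crossprod(ns$basis, v))
}

#' Reducibility certificate for a candidate steady state
#'
#' Tests, without constructing activity coefficients, whether a flux vector
#' y can be realized at log counts eta by some admissible regulation
#' \eqn{\alpha \in [0,1]^{|J|}}. Per reaction the conditions are
#' `force_bound` \eqn{|g_j - \log K_j| \ge |h_j|} with
#' \eqn{h_j = sgn(y_j)[\log 2 - \log(|y_j| + \sqrt{y_j^2+4})]},
#' `direction` \eqn{(\log K_j - g_j)\, y_j \ge 0}, and the equivalent
#' magnitude form `flux_cap` \eqn{|y_j| \le |J_j(\eta, 1)|} with sign
#' agreement.
#'
#' @param eta Log-count state over all metabolites.
#' @param y Candidate steady-state flux vector over reactions.
#' @param net A [metabolic_network()].
#' @param tol Absolute slack on the inequalities; default `1e-6` so that
#'   interior-point output at tolerance `1e-7` is never rejected at the
#'   solver's own precision.
#' @return An object of class `steady_state_certificate`: list with `g`,
#'   `h`, `feasible`, and a `violations` data.frame
#'   (reaction, condition, magnitude).
#' @export
reducibility_certificate <- function(eta, y, net, tol = 1e-6) {
  stopifnot(length(y) == n_reactions(net))
  g <- reaction_log_action(eta, net)
  log_K <- net$reactions$log_K
  h <- sign(y) * (log(2) - log(abs(y) + sqrt(y^2 + 4)))
  d <- log_K - g

  viol <- list()
  add_viol <- function(idx, cond, mag) {
    if (length(idx))
      viol[[length(viol) + 1L]] <<- data.frame(
        reaction = net$reactions$id[idx], condition = cond,
        magnitude = mag[idx], stringsAsFactors = FALSE)
  }
  slack_force <- abs(g - log_K) - abs(h)        # >= -tol required
  add_viol(which(slack_force < -tol), "force_bound", -slack_force)
  slack_dir <- d * y                            # >= -tol required
  add_viol(which(slack_dir < -tol), "direction", -slack_dir)
  J1 <- log_space_flux(eta, net, alpha = 1)
  slack_cap <- abs(J1) - abs(y)                 # >= -tol required
  cap_bad <- abs(y) > tol & (slack_cap < -tol | y * J1 < -tol)
  add_viol(which(cap_bad), "flux_cap", pmax(-slack_cap, -y * J1))

  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(reaction = character(), condition = character(),
               magnitude = numeric(), stringsAsFactors = FALSE)
  structure(list(g = g, h = h, log_K = log_K, y = y, tol = tol,
                 feasible = nrow(violations) == 0L, violations = violations),
            class = "steady_state_certificate")
}

#' @export
print.steady_state_certificate <- function(x, ...) {
  cat(sprintf("<steady_state_certificate> %s (%d violation%s, tol %.1g)\n",
              if (x$feasible) "feasible" else "infeasible",
              nrow(x$violations), if (nrow(x$violations) == 1L) "" else "s",
              x$tol))
  if (nrow(x$violations)) print(utils::head(x$violations, 10L))
  invisible(x)
}

#' Write a certificate as a TSV debugging report
#'
#' One row per reaction with g, log K, h, and per-condition pass flags.
#' @param cert A [reducibility_certificate()].
#' @param net The network the certificate was computed on.
#' @param path Output path.
#' @export
write_certificate <- function(cert, net, path) {
  fail_of <- function(cond) net$reactions$id %in%
    cert$violations$reaction[cert$violations$condition == cond]
  utils::write.table(
    data.frame(reaction = net$reactions$id, y = cert$y, g = cert$g,
               log_K = cert$log_K, h = cert$h,
               force_bound_ok = !fail_of("force_bound"),
               direction_ok = !fail_of("direction"),
               flux_cap_ok = !fail_of("flux_cap")),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Recover activity coefficients realizing a reducible flux vector
#'
#' For a certificate-feasible pair (eta, y) the regulated flux law is linear
#' in alpha, so \eqn{\alpha_j = y_j / J_j(\eta, 1)}. Reactions with both a
#' negligible unregulated flux and a negligible target flux get
#' \eqn{\alpha_j = 0} by convention; a negligible unregulated flux with a
#' non-negligible target is an infeasibility.
#'
#' @inheritParams reducibility_certificate
#' @param tol Tolerance forwarded to the certificate and used to clamp
#'   round-off excursions of alpha outside \[0, 1\].
#' @return Named numeric vector of activity coefficients.
#' @export
recover_activities <- function(eta, y, net, tol = 1e-6) {
  cert <- reducibility_certificate(eta, y, net, tol = tol)
  if (!cert$feasible)
    stop("flux vector is not reducible at this state; inspect the ",
         "reducibility_certificate() for per-reaction violations",
         call. = FALSE)
  J1 <- log_space_flux(eta, net, alpha = 1)
  alpha <- numeric(length(y))
  tiny_J <- abs(J1) < 1e-30
  if (any(tiny_J & abs(y) > 1e-12))
    stop("reaction(s) ", paste(net$reactions$id[tiny_J & abs(y) > 1e-12],
                               collapse = ", "),
         " require flux through an equilibrium-pinned reaction", call. = FALSE)
  alpha[!tiny_J] <- y[!tiny_J] / J1[!tiny_J]
  alpha[tiny_J] <- 0
  if (any(alpha < -tol) || any(alpha > 1 + tol))
    stop("recovered activities escape [0,1] beyond tolerance", call. = FALSE)
  stats::setNames(pmin(pmax(alpha, 0), 1), net$reactions$id)
}
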