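#' @export
print.pco_fit <- function(x, ...) {
  n_reg <- sum(is.finite(x$alpha) & x$alpha < 1 - 1e-6)
  cat(sprintf("Pathway-controlled optimization fit (%s)\n", x$solver_status))
  cat(sprintf("  growth objective: %.6g  (%d growth reaction%s)\n",
              x$objective, sum(x$network$reactions$growth),
              if (sum(x$network$reactions$growth) == 1L) "" else "s"))
  cat(sprintf("  regulated reactions (alpha < 1): %d of %d\n",
              n_reg, n_reactions(x$network)))
  cat(sprintf("  certificate: %s;  validation: %s;  iterations: %d\n",
              if (x$certificate$feasible) "feasible" else "INFEASIBLE",
              if (isTRUE(attr(x$validation, "ok"))) "all checks pass"
              else "CHECK FAILURES", x$iterations))
  invisible(x)
}

#' @export
summary.pco_fit <- function(object, ...) {
  net <- object$network
  iv <- variable_index(net)
  out <- list(
    status = object$solver_status,
    objective = object$objective,
    reactions = data.frame(
      reaction = net$reactions$id, y = as.numeric(object$y),
      alpha = as.numeric(object$alpha),
      g = object$certificate$g, log_K = net$reactions$log_K,
      is_growth = net$reactions$growth, stringsAsFactors = FALSE),
    metabolites = data.frame(
      metabolite = net$metabolites$id, eta = as.numeric(object$eta),
      conc_mM = log_count_to_concentration(as.numeric(object$eta), net$units),
      fixed = net$metabolites$fixed, stringsAsFactors = FALSE),
    validation = object$validation)
  class(out) <- "summary.pco_fit"
  out
}

#' @export
print.summary.pco_fit <- function(x, ...) {
  cat(sprintf("PCO solution (%s), growth objective %.6g\n\nReactions:\n",
              x$status, x$objective))
  print(x$reactions, digits = 4)
  cat("\nMetabolites:\n")
  print(x$metabolites, digits = 4)
  cat("\nValidation:\n")
  print(as.data.frame(x$validation), digits = 4)
  invisible(x)
}

#' @export
coef.pco_fit <- function(object, ...) object$alpha

#' @export
fitted.pco_fit <- function(object, ...) object$y

#' Residuals of a PCO fit
#'
#' The regulated mass-balance residual \eqn{S_v J(\eta^\star, \alpha^\star)}
#' — zero at an exact steady state.
#' @param object A `pco_fit`.
#' @param ... Unused.
#' @export
residuals.pco_fit <- function(object, ...) {
  dynamics_rhs(object$eta, object$network, object$alpha)
}

#' Cumulative flux-magnitude distribution of a fit
#'
#' Plots the sorted absolute reaction fluxes cumulatively, the standard view
#' for comparing how regulation redistributes flux between two fits.
#' @param x A `pco_fit` or `mca_fit`.
#' @param compare Optional second fit drawn on the same axes.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pco_fit <- function(x, compare = NULL, ...) {
  plot_cumulative_flux(x, compare, ...)
}

#' @rdname plot.pco_fit
#' @export
plot.mca_fit <- function(x, compare = NULL, ...) {
  plot_cumulative_flux(x, compare, ...)
}

plot_cumulative_flux <- function(fit, compare = NULL, ...) {
  cum1 <- cumsum(sort(abs(as.numeric(fit$y))))
  graphics::plot(seq_along(cum1), cum1, type = "s", xlab = "reactions (sorted)",
                 ylab = "cumulative |flux|",
                 main = "Cumulative flux distribution", ...)
  if (!is.null(compare)) {
    cum2 <- cumsum(sort(abs(as.numeric(compare$y))))
    graphics::lines(seq_along(cum2), cum2, type = "s", lty = 2)
    graphics::legend("topleft", legend = c(class(fit)[1], class(compare)[1]),
                     lty = c(1, 2), bty = "n")
  }
  invisible(fit)
}

#' @export
print.mca_fit <- function(x, ...) {
  n_reg <- sum(x$alpha < 1 - 1e-9)
  cat("MCA concentration-capping fit\n")
  cat(sprintf("  cap: %.3g mM (eta_cap %.4f);  converged: %s\n",
              x$n_cap, x$eta_cap, x$converged))
  cat(sprintf("  regulated reactions: %d of %d;  steps taken: %d\n",
              n_reg, length(x$alpha), nrow(x$trace)))
  invisible(x)
}

#' @export
summary.mca_fit <- function(object, ...) {
  net <- object$network
  iv <- variable_index(net)
  out <- list(
    converged = object$converged, n_cap = object$n_cap,
    reactions = data.frame(reaction = net$reactions$id,
                           y = as.numeric(object$y),
                           alpha = as.numeric(object$alpha),
                           stringsAsFactors = FALSE),
    metabolites = data.frame(
      metabolite = net$metabolites$id[iv],
      eta = as.numeric(object$eta[iv]),
      conc_mM = log_count_to_concentration(as.numeric(object$eta[iv]),
                                           net$units),
      at_cap = object$eta[iv] > object$eta_cap - 1e-6,
      stringsAsFactors = FALSE),
    trace = object$trace)
  class(out) <- "summary.mca_fit"
  out
}

#' @export
print.summary.mca_fit <- function(x, ...) {
  cat(sprintf("MCA capping at %.3g mM (converged: %s)\n\nReactions:\n",
              x$n_cap, x$converged))
  print(x$reactions, digits = 4)
  cat("\nVariable metabolites:\n")
  print(x$metabolites, digits = 4)
  invisible(x)
}

#' @export
coef.mca_fit <- function(object, ...) object$alpha

#' @export
fitted.mca_fit <- function(object, ...) object$y

#' @export
residuals.mca_fit <- function(object, ...) {
  dynamics_rhs(object$eta, object$network, object$alpha)
}

#' @export
print.pco_init <- function(x, ...) {
  cat(sprintf("<pco_init> least-squares residual %.3g, |y0| range [%.3g, %.3g]\n",
              x$lsq_residual, min(abs(x$y0)), max(abs(x$y0))))
  invisible(x)
}

#' @export
print.pco_validation <- function(x, ...) {
  print.data.frame(x, digits = 4)
  cat(if (isTRUE(attr(x, "ok"))) "all checks pass\n" else "CHECK FAILURES\n")
  invisible(x)
}
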