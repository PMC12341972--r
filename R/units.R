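#' Unit context for concentration/count conversion
#'
#' All internal state in pcoflux is kept as natural-log molecule counts
#' \eqn{\eta_i = \ln n_i}. Experimental concentrations are reported in mM, so
#' converting between the two requires a cell volume. The default volume of
#' 1 fL (a typical bacterial cytoplasmic volume) maps a 1.0 mM concentration
#' to \eqn{\ln n = 13.308}, the physiological log-count cap used throughout.
#'
#' @param cell_volume Cell volume in litres. Must be positive.
#' @param avogadro Avogadro constant in 1/mol.
#' @return An object of class `unit_context`.
#' @examples
#' ctx <- unit_context()
#' concentration_to_log_count(1.0, ctx) # 13.308...
#' @export
unit_context <- function(cell_volume = 1e-15, avogadro = 6.02214076e23) {
  stopifnot(is.numeric(cell_volume), length(cell_volume) == 1L,
            is.finite(cell_volume), cell_volume > 0,
            is.numeric(avogadro), length(avogadro) == 1L, avogadro > 0)
  structure(list(cell_volume = cell_volume, avogadro = avogadro),
            class = "unit_context")
}

#' @export
print.unit_context <- function(x, ...) {
  cat(sprintf("<unit_context> cell volume %.3g L, 1 mM = exp(%.4f) molecules\n",
              x$cell_volume, log(mM_to_count_factor(x))))
  invisible(x)
}

# molecules per 1 mM at the context's cell volume
mM_to_count_factor <- function(ctx) 1e-3 * ctx$avogadro * ctx$cell_volume

#' Convert a concentration in mM to a natural-log molecule count
#'
#' @param conc Concentration in millimolar; must be strictly positive.
#' @param ctx A [unit_context()].
#' @return \eqn{\ln(conc \times 10^{-3} N_A V)}.
#' @export
concentration_to_log_count <- function(conc, ctx = unit_context()) {
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("concentrations must be finite and strictly positive", call. = FALSE)
  log(conc) + log(mM_to_count_factor(ctx))
}

#' Convert a natural-log molecule count back to a concentration in mM
#'
#' Inverse of [concentration_to_log_count()].
#' @param eta Natural-log molecule count.
#' @param ctx A [unit_context()].
#' @export
log_count_to_concentration <- function(eta, ctx = unit_context()) {
  exp(eta - log(mM_to_count_factor(ctx)))
}

#' Re-express a log equilibrium constant in molecule-count units
#'
#' Equilibrium constants estimated from standard free energies are usually in
#' concentration units (here mM). The thermodynamic force
#' \eqn{f_j = K_j \prod_i n_i^{-\gamma_{ij}}} is only invariant under the unit
#' change if \eqn{\log K} is shifted by the net molecularity
#' \eqn{\Delta\gamma_j = \sum_i \gamma_{ij}} times the log of the
#' mM-to-count factor.
#'
#' @param log_K_conc Natural-log equilibrium constant in mM units.
#' @param delta_gamma Net stoichiometric coefficient sum of the reaction.
#' @param ctx A [unit_context()].
#' @return Natural-log equilibrium constant in count units.
#' @export
convert_log_K_units <- function(log_K_conc, delta_gamma, ctx = unit_context()) {
  log_K_conc + delta_gamma * log(mM_to_count_factor(ctx))
}
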