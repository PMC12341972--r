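#' Construct a metabolic network
#'
#' A network is a set of metabolites partitioned into variable species and
#' fixed (boundary) species held at constant concentration, together with a
#' set of reversible mass-action reactions, each with a natural-log
#' equilibrium constant in molecule-count units. A subset of reactions is
#' flagged as growth (biomass-producing) reactions; their summed steady-state
#' flux is the PCO objective.
#'
#' Metabolite and reaction order is authoritative: the stoichiometric matrix
#' rows/columns follow the order given here, and serialization preserves it.
#'
#' @param metabolites A data.frame with columns `id` (unique character),
#'   `name` (character, optional), `fixed` (logical), and `fixed_log_count`
#'   (numeric log molecule count, required where `fixed` is `TRUE`).
#' @param reactions A list of reactions, each a list with elements `id`
#'   (unique character), `stoich` (named numeric vector of signed
#'   stoichiometric coefficients, negative for reactants, positive for
#'   products), `log_K` (finite numeric), and `growth` (logical flag).
#' @param eta_max Common upper bound on log counts of variable metabolites.
#'   Defaults to the log count of a 1.0 mM concentration in `units`.
#' @param units A [unit_context()].
#' @return An object of class `metabolic_network` with elements
#'   `metabolites`, `reactions` (data.frame with a `stoich` list-column),
#'   `S` (sparse stoichiometric matrix, metabolites x reactions),
#'   `eta_max`, and `units`.
#' @export
metabolic_network <- function(metabolites, reactions, eta_max = NULL,
                              units = unit_context()) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (!all(c("id", "fixed") %in% names(metabolites)))
    stop("metabolites need at least columns 'id' and 'fixed'", call. = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$fixed_log_count))
    metabolites$fixed_log_count <- NA_real_
  metabolites <- metabolites[, c("id", "name", "fixed", "fixed_log_count")]
  metabolites$id <- as.character(metabolites$id)
  metabolites$fixed <- as.logical(metabolites$fixed)
  metabolites$fixed_log_count <- as.numeric(metabolites$fixed_log_count)

  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]),
               collapse = ", "), call. = FALSE)
  bad <- metabolites$fixed & !is.finite(metabolites$fixed_log_count)
  if (any(bad))
    stop("fixed metabolites must have a finite fixed_log_count: ",
         paste(metabolites$id[bad], collapse = ", "), call. = FALSE)

  if (length(reactions) == 0L) stop("at least one reaction is required", call. = FALSE)
  rids <- vapply(reactions, function(r) as.character(r$id), character(1))
  if (anyDuplicated(rids))
    stop("duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "), call. = FALSE)
  stoich <- lapply(reactions, function(r) {
    s <- r$stoich
    if (is.null(s) || length(s) == 0L || is.null(names(s)))
      stop("reaction '", r$id, "': stoichiometry must be a non-empty named vector",
           call. = FALSE)
    s <- unlist(s)
    storage.mode(s) <- "double"
    unknown <- setdiff(names(s), metabolites$id)
    if (length(unknown))
      stop("reaction '", r$id, "' references unknown metabolites: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (!any(s < 0) || !any(s > 0))
      stop("reaction '", r$id, "' must have at least one reactant (negative ",
           "coefficient) and one product (positive coefficient); model ",
           "exchange through fixed metabolites instead", call. = FALSE)
    s
  })
  log_K <- vapply(reactions, function(r) as.numeric(r$log_K), numeric(1))
  if (any(!is.finite(log_K)))
    stop("all reactions need a finite log_K", call. = FALSE)
  growth <- vapply(reactions, function(r) isTRUE(r$growth), logical(1))

  reactions_df <- data.frame(id = rids, log_K = log_K, growth = growth,
                             stringsAsFactors = FALSE)
  reactions_df$stoich <- stoich

  # sparse |I| x |J| stoichiometric matrix in declared order
  i_idx <- unlist(lapply(stoich, function(s) match(names(s), metabolites$id)))
  j_idx <- rep(seq_along(stoich), lengths(stoich))
  S <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = unlist(stoich),
                            dims = c(nrow(metabolites), length(stoich)),
                            dimnames = list(metabolites$id, rids))

  if (is.null(eta_max)) eta_max <- concentration_to_log_count(1.0, units)
  stopifnot(is.numeric(eta_max), length(eta_max) == 1L, is.finite(eta_max))

  structure(list(metabolites = metabolites, reactions = reactions_df,
                 S = S, eta_max = eta_max, units = units),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %d metabolites (%d fixed), %d reactions (%d growth)\n",
              nrow(x$metabolites), sum(x$metabolites$fixed),
              nrow(x$reactions), sum(x$reactions$growth)))
  cat(sprintf("  eta_max = %.4f (%.3g mM at %.3g L)\n", x$eta_max,
              log_count_to_concentration(x$eta_max, x$units),
              x$units$cell_volume))
  invisible(x)
}

n_metabolites <- function(net) nrow(net$metabolites)
n_reactions <- function(net) nrow(net$reactions)
variable_index <- function(net) which(!net$metabolites$fixed)
fixed_index <- function(net) which(net$metabolites$fixed)
growth_index <- function(net) which(net$reactions$growth)

#' Stoichiometric matrix of a network
#'
#' @param net A [metabolic_network()].
#' @param variable_only If `TRUE`, return the row-submatrix on variable
#'   metabolites only (the matrix whose nullspace contains all steady-state
#'   flux vectors).
#' @param sparse Return a sparse `Matrix` (default) or a base matrix.
#' @return The signed stoichiometric matrix, metabolites x reactions.
#' @export
stoichiometric_matrix <- function(net, variable_only = FALSE, sparse = TRUE) {
  stopifnot(inherits(net, "metabolic_network"))
  S <- net$S
  if (variable_only) S <- S[!net$metabolites$fixed, , drop = FALSE]
  if (sparse) S else as.matrix(S)
}

#' Full log-count state vector from variable-part values
#'
#' Fixed metabolites take their boundary values; variable metabolites take
#' the supplied values (in network order).
#' @param net A [metabolic_network()].
#' @param eta_v Numeric vector over variable metabolites, in network order.
#' @return Named numeric vector over all metabolites.
#' @export
assemble_eta <- function(net, eta_v) {
  iv <- variable_index(net)
  stopifnot(length(eta_v) == length(iv))
  eta <- net$metabolites$fixed_log_count
  eta[iv] <- eta_v
  names(eta) <- net$metabolites$id
  eta
}

## ---------------------------------------------------------------------------
## Serialization: JSON and TSV schemas
## ---------------------------------------------------------------------------

#' Read a metabolic network from file
#'
#' Two plain-text schemas are supported. JSON: a single object with fields
#' `metabolites` (list of `{id, name, fixed, fixed_conc_mM}`), `reactions`
#' (list of `{id, stoich: {met: coeff}, log_K, growth}`), optional `eta_max`
#' and `unit_context: {cell_volume_L}`. TSV: a pair of tab-separated tables
#' `<base>_metabolites.tsv` and `<base>_reactions.tsv` (pass the common
#' `<base>` as `path`), with stoichiometry encoded as `"met:coeff;met:coeff"`
#' and network-level scalars in `#!` comment lines of the metabolites table.
#'
#' @param path File path (JSON) or common base path (TSV).
#' @param format `"json"` or `"tsv"`.
#' @param log_K_units Units of the stored equilibrium constants: `"count"`
#'   (already natural-log in molecule-count units, the default) or `"mM"`
#'   (converted on load via [convert_log_K_units()]).
#' @return A validated [metabolic_network()].
#' @export
load_network <- function(path, format = c("json", "tsv"),
                         log_K_units = c("count", "mM")) {
  format <- match.arg(format)
  log_K_units <- match.arg(log_K_units)
  net <- if (format == "json") load_network_json(path) else load_network_tsv(path)
  if (log_K_units == "mM") {
    dg <- vapply(net$reactions$stoich, sum, numeric(1))
    net$reactions$log_K <- convert_log_K_units(net$reactions$log_K, dg, net$units)
  }
  net
}

load_network_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed JSON in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  for (fld in c("metabolites", "reactions"))
    if (is.null(doc[[fld]]))
      stop("model file '", path, "' lacks required field '", fld, "'",
           call. = FALSE)
  units <- if (!is.null(doc$unit_context$cell_volume_L))
    unit_context(cell_volume = doc$unit_context$cell_volume_L) else unit_context()

  mets <- do.call(rbind, lapply(seq_along(doc$metabolites), function(k) {
    m <- doc$metabolites[[k]]
    if (is.null(m$id)) stop("metabolite #", k, " has no 'id'", call. = FALSE)
    fixed <- isTRUE(m$fixed)
    eta_bar <- NA_real_
    if (fixed) {
      if (is.null(m$fixed_conc_mM))
        stop("fixed metabolite '", m$id, "' lacks 'fixed_conc_mM'", call. = FALSE)
      eta_bar <- concentration_to_log_count(m$fixed_conc_mM, units)
    }
    data.frame(id = as.character(m$id),
               name = if (is.null(m$name)) as.character(m$id) else m$name,
               fixed = fixed, fixed_log_count = eta_bar,
               stringsAsFactors = FALSE)
  }))
  rxns <- lapply(seq_along(doc$reactions), function(k) {
    r <- doc$reactions[[k]]
    if (is.null(r$id)) stop("reaction #", k, " has no 'id'", call. = FALSE)
    if (is.null(r$log_K)) stop("reaction '", r$id, "' has no 'log_K'", call. = FALSE)
    list(id = r$id, stoich = unlist(r$stoich), log_K = r$log_K,
         growth = isTRUE(r$growth))
  })
  metabolic_network(mets, rxns, eta_max = doc$eta_max, units = units)
}

#' Write a metabolic network to file
#'
#' Inverse of [load_network()]; a save/load round trip reproduces the network
#' (concentrations are re-derived from log counts, exact to floating
#' precision).
#'
#' @param net A [metabolic_network()].
#' @param path Output path (JSON) or common base path (TSV).
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") write_network_json(net, path) else write_network_tsv(net, path)
  invisible(path)
}

write_network_json <- function(net, path) {
  mets <- lapply(seq_len(nrow(net$metabolites)), function(i) {
    m <- net$metabolites[i, ]
    out <- list(id = m$id, name = m$name, fixed = m$fixed)
    if (m$fixed)
      out$fixed_conc_mM <- log_count_to_concentration(m$fixed_log_count, net$units)
    out
  })
  rxns <- lapply(seq_len(nrow(net$reactions)), function(j) {
    list(id = net$reactions$id[[j]],
         stoich = as.list(net$reactions$stoich[[j]]),
         log_K = net$reactions$log_K[[j]],
         growth = net$reactions$growth[[j]])
  })
  doc <- list(metabolites = mets, reactions = rxns, eta_max = net$eta_max,
              unit_context = list(cell_volume_L = net$units$cell_volume))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

tsv_paths <- function(base) {
  list(metabolites = paste0(base, "_metabolites.tsv"),
       reactions = paste0(base, "_reactions.tsv"))
}

write_network_tsv <- function(net, base) {
  p <- tsv_paths(base)
  con <- file(p$metabolites, "w")
  on.exit(close(con))
  writeLines(sprintf("#! eta_max=%.17g", net$eta_max), con)
  writeLines(sprintf("#! cell_volume_L=%.17g", net$units$cell_volume), con)
  m <- net$metabolites
  m$fixed_conc_mM <- ifelse(m$fixed,
    log_count_to_concentration(m$fixed_log_count, net$units), NA_real_)
  utils::write.table(
    data.frame(id = m$id, name = m$name, fixed = m$fixed,
               fixed_conc_mM = sprintf("%.17g", m$fixed_conc_mM)),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  r <- net$reactions
  stoich_str <- vapply(r$stoich, function(s)
    paste(sprintf("%s:%.17g", names(s), s), collapse = ";"), character(1))
  utils::write.table(
    data.frame(id = r$id, stoich = stoich_str,
               log_K = sprintf("%.17g", r$log_K), growth = r$growth),
    p$reactions, sep = "\t", quote = FALSE, row.names = FALSE)
}

load_network_tsv <- function(base) {
  p <- tsv_paths(base)
  for (f in unlist(p))
    if (!file.exists(f)) stop("no such file: ", f, call. = FALSE)
  hdr <- readLines(p$metabolites, n = 10L)
  hdr <- hdr[startsWith(hdr, "#!")]
  kv <- do.call(rbind, strsplit(sub("^#!\\s*", "", hdr), "=", fixed = TRUE))
  scalars <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  units <- if (!is.na(scalars["cell_volume_L"]))
    unit_context(cell_volume = scalars[["cell_volume_L"]]) else unit_context()

  m <- utils::read.table(p$metabolites, sep = "\t", header = TRUE,
                         comment.char = "#", stringsAsFactors = FALSE)
  m$fixed_log_count <- NA_real_
  if (any(m$fixed))
    m$fixed_log_count[m$fixed] <-
      concentration_to_log_count(m$fixed_conc_mM[m$fixed], units)
  r <- utils::read.table(p$reactions, sep = "\t", header = TRUE,
                         comment.char = "#", stringsAsFactors = FALSE)
  rxns <- lapply(seq_len(nrow(r)), function(j) {
    parts <- strsplit(strsplit(r$stoich[[j]], ";", fixed = TRUE)[[1]],
                      ":", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad))
      stop("reactions table line ", j + 1L, ": malformed stoich field '",
           r$stoich[[j]], "'", call. = FALSE)
    s <- stats::setNames(as.numeric(vapply(parts, `[`, "", 2L)),
                         vapply(parts, `[`, "", 1L))
    list(id = r$id[[j]], stoich = s, log_K = r$log_K[[j]],
         growth = as.logical(r$growth[[j]]))
  })
  eta_max <- if (!is.na(scalars["eta_max"])) scalars[["eta_max"]] else NULL
  metabolic_network(m[, c("id", "name", "fixed", "fixed_log_count")],
                    rxns, eta_max = eta_max, units = units)
}
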