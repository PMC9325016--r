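# Metabolic network data model: reaction-table parsing, stoichiometric
# matrix construction, and LP-based flux balance analysis.

ARROW_IRREV <- "-->"
ARROW_REV <- "<=>"

#' Parse a plain-text reaction table into a metabolic network
#'
#' Each non-empty line has the form `id : formula`, where the formula uses
#' `-->` for an irreversible reaction or `<=>` for a reversible one, with
#' species separated by `+` and optional positive stoichiometric
#' coefficients (default 1). Either side of the arrow may be empty, giving
#' an exchange reaction (e.g. `v1 : --> acetate` for an uptake or
#' `v18 : CO2 -->` for a secretion). Lines starting with `#` are ignored.
#'
#' Metabolites are registered in order of first appearance (left side
#' before right side, line by line); this order fixes the rows of the
#' stoichiometric matrix. Consumed species get negative coefficients,
#' produced species positive ones.
#'
#' @param text Character scalar (possibly multi-line) or character vector
#'   of lines.
#' @param default_lb,default_ub Default flux bounds applied to every
#'   reaction. Reversibility is recorded from the arrow but does not alter
#'   the default lower bound; pass explicit bounds (or use
#'   [read_reaction_tsv()]) for networks that carry net-negative fluxes.
#' @return A `metabolic_network` object: a list with elements
#'   `metabolites` (character), `reaction_ids` (character), `reactions`
#'   (list of per-reaction stoichiometry maps), `reversible` (logical),
#'   `lb`, `ub` (named numeric) and `S` (dense m x n matrix).
#' @examples
#' net <- parse_reaction_table(c(
#'   "u : --> A",
#'   "r : A <=> B",
#'   "d : B -->"
#' ))
#' net$S
#' @export
parse_reaction_table <- function(text, default_lb = 0, default_ub = 100) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]

  ids <- character(0)
  stoich <- list()
  reversible <- logical(0)
  for (line in lines) {
    pos <- regexpr(":", line, fixed = TRUE)
    if (pos < 0) stop("malformed line (missing ':'): ", line)
    id <- trimws(substr(line, 1L, pos - 1L))
    if (!nzchar(id)) stop("malformed line (empty reaction id): ", line)
    if (id %in% ids) stop("duplicate reaction id: ", id)
    formula <- trimws(substr(line, pos + 1L, nchar(line)))
    parsed <- parse_formula(formula, id)
    ids <- c(ids, id)
    stoich[[id]] <- parsed$stoich
    reversible <- c(reversible, parsed$reversible)
  }

  metabolites <- character(0)
  for (s in stoich) metabolites <- union(metabolites, names(s))

  net <- structure(
    list(
      metabolites = metabolites,
      reaction_ids = ids,
      reactions = stoich,
      reversible = stats::setNames(reversible, ids),
      lb = stats::setNames(rep_len(default_lb, length(ids)), ids),
      ub = stats::setNames(rep_len(default_ub, length(ids)), ids),
      S = NULL
    ),
    class = "metabolic_network"
  )
  net$S <- stoich_matrix(net)
  net
}

# Split `formula` on its arrow and accumulate signed coefficients.
parse_formula <- function(formula, id) {
  if (grepl(ARROW_REV, formula, fixed = TRUE)) {
    reversible <- TRUE
    sides <- strsplit(formula, ARROW_REV, fixed = TRUE)[[1]]
  } else if (grepl(ARROW_IRREV, formula, fixed = TRUE)) {
    reversible <- FALSE
    sides <- strsplit(formula, ARROW_IRREV, fixed = TRUE)[[1]]
  } else {
    stop("reaction ", id, ": no valid arrow ('-->' or '<=>') in formula: ",
         formula)
  }
  if (length(sides) > 2L)
    stop("reaction ", id, ": more than one arrow in formula: ", formula)
  lhs <- if (length(sides) >= 1L) sides[1] else ""
  rhs <- if (length(sides) == 2L) sides[2] else ""

  coef <- numeric(0)
  add_side <- function(coef, side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(coef)
    for (term in trimws(strsplit(side, "+", fixed = TRUE)[[1]])) {
      if (!nzchar(term))
        stop("reaction ", id, ": empty species term in formula")
      toks <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(toks) == 1L) {
        k <- 1
        species <- toks[1]
      } else if (length(toks) == 2L) {
        k <- suppressWarnings(as.numeric(toks[1]))
        species <- toks[2]
        if (is.na(k) || !is.finite(k) || k <= 0)
          stop("reaction ", id, ": coefficient must be a positive real: ",
               toks[1])
      } else {
        stop("reaction ", id, ": cannot parse species term: ", term)
      }
      prev <- if (species %in% names(coef)) coef[[species]] else 0
      coef[[species]] <- prev + sign * k
      coef
    }
    coef
  }
  coef <- add_side(coef, lhs, -1)
  coef <- add_side(coef, rhs, +1)
  list(stoich = coef, reversible = reversible)
}

#' Build the stoichiometric matrix of a network
#'
#' Rows follow metabolite registration order, columns follow reaction
#' order; entry `S[i, j]` is reaction `j`'s signed coefficient for
#' metabolite `i` (0 if absent).
#'
#' @param net A `metabolic_network`.
#' @return A dense m x n numeric matrix with dimnames.
#' @export
stoich_matrix <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  m <- length(net$metabolites)
  n <- length(net$reaction_ids)
  S <- matrix(0, m, n, dimnames = list(net$metabolites, net$reaction_ids))
  for (j in seq_len(n)) {
    s <- net$reactions[[j]]
    if (length(s)) S[names(s), j] <- s
  }
  S
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", length(x$metabolites), " metabolites, ",
      length(x$reaction_ids), " reactions\n", sep = "")
  invisible(x)
}

#' Read a reaction-table TSV
#'
#' Canonical on-disk format: tab-separated columns `id`, `formula` and
#' optionally `lb`, `ub`. Missing bound columns fall back to the defaults
#' of [parse_reaction_table()].
#'
#' @param path File path.
#' @inheritParams parse_reaction_table
#' @return A `metabolic_network`.
#' @export
read_reaction_tsv <- function(path, default_lb = 0, default_ub = 100) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!all(c("id", "formula") %in% names(tab)))
    stop("reaction TSV needs columns 'id' and 'formula'")
  net <- parse_reaction_table(paste(tab$id, ":", tab$formula),
                              default_lb = default_lb,
                              default_ub = default_ub)
  if ("lb" %in% names(tab)) net$lb[] <- as.numeric(tab$lb)
  if ("ub" %in% names(tab)) net$ub[] <- as.numeric(tab$ub)
  if (any(net$lb > net$ub)) stop("lb > ub in reaction TSV")
  net
}

#' Write a flux vector as TSV
#'
#' Two columns, `reaction_id` and `flux` (6 decimal places), one row per
#' reaction.
#'
#' @param fluxes Named numeric vector, or an `fba_result`.
#' @param path Output file path.
#' @export
write_flux_tsv <- function(fluxes, path) {
  if (inherits(fluxes, "fba_result")) {
    if (fluxes$status != "optimal") stop("no fluxes: LP status ", fluxes$status)
    fluxes <- fluxes$fluxes
  }
  df <- data.frame(reaction_id = names(fluxes),
                   flux = sprintf("%.6f", fluxes))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Normalise bound overrides (named list of c(lb, ub), or a matrix with
# rownames and columns lb/ub) into full lb/ub vectors for `net`.
apply_bound_overrides <- function(net, bound_overrides) {
  lb <- net$lb
  ub <- net$ub
  if (is.null(bound_overrides)) return(list(lb = lb, ub = ub))
  if (is.matrix(bound_overrides)) {
    ids <- rownames(bound_overrides)
    if (is.null(ids)) stop("bound override matrix needs rownames")
    ov <- lapply(seq_along(ids), function(i) bound_overrides[i, 1:2])
    names(ov) <- ids
    bound_overrides <- ov
  }
  for (id in names(bound_overrides)) {
    if (!id %in% net$reaction_ids) stop("unknown reaction in overrides: ", id)
    pair <- as.numeric(bound_overrides[[id]])
    if (length(pair) != 2L || anyNA(pair))
      stop("override for ", id, " must be c(lb, ub)")
    if (pair[1] > pair[2]) stop("override for ", id, " has lb > ub")
    lb[id] <- pair[1]
    ub[id] <- pair[2]
  }
  list(lb = lb, ub = ub)
}

#' Solve a flux balance analysis linear program
#'
#' Maximises (or minimises) the flux of one reaction subject to the
#' steady-state mass balance `S v = 0` and the flux bounds
#' `lb <= v <= ub`, using the bundled dense two-phase simplex. The optimal
#' objective value is unique; when alternate optima exist the returned
#' flux vector is the solver's (deterministic) vertex and its
#' non-objective components are informational only.
#'
#' @param net A `metabolic_network`.
#' @param objective Reaction id to optimise.
#' @param sense `"max"` (default) or `"min"`.
#' @param bound_overrides Optional bounds replacing the network's for
#'   selected reactions: a named list of `c(lb, ub)` pairs, or a matrix
#'   with reaction-id rownames and columns `(lb, ub)` such as returned by
#'   [decode_genotype()].
#' @return An `fba_result`: list with `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`), `objective_reaction`, `sense`,
#'   `objective_value` (NA unless optimal) and `fluxes` (named numeric,
#'   NULL unless optimal).
#' @examples
#' net <- build_creinhardtii_network()
#' solve_fba(net, "v14")$objective_value  # 10.6
#' @export
solve_fba <- function(net, objective, sense = c("max", "min"),
                      bound_overrides = NULL) {
  stopifnot(inherits(net, "metabolic_network"))
  sense <- match.arg(sense)
  if (!objective %in% net$reaction_ids)
    stop("unknown objective reaction: ", objective)
  bb <- apply_bound_overrides(net, bound_overrides)
  n <- length(net$reaction_ids)
  cost <- numeric(n)
  cost[match(objective, net$reaction_ids)] <- 1
  ans <- .simplex_box_lp(net$S, numeric(nrow(net$S)), cost,
                         unname(bb$lb), unname(bb$ub), sense == "max")
  status <- c("optimal", "infeasible", "unbounded")[ans$status + 1L]
  fluxes <- NULL
  objval <- NA_real_
  if (status == "optimal") {
    fluxes <- stats::setNames(ans$v, net$reaction_ids)
    objval <- ans$objective
  }
  structure(
    list(status = status, objective_reaction = objective, sense = sense,
         objective_value = objval, fluxes = fluxes),
    class = "fba_result"
  )
}

#' @export
print.fba_result <- function(x, ...) {
  cat("<fba_result> ", x$sense, " ", x$objective_reaction, ": ",
      x$status,
      if (x$status == "optimal") paste0(", objective = ",
                                        format(x$objective_value)),
      "\n", sep = "")
  invisible(x)
}

#' Steady-state residual of a flux vector
#'
#' Returns the infinity norm of `S v`; a vector at steady state has
#' residual 0 up to solver tolerance. The caller compares the returned
#' residual against `tol`.
#'
#' @param net A `metabolic_network`.
#' @param v Named numeric flux vector covering every reaction.
#' @param tol Steady-state tolerance the caller intends to use
#'   (informational; attached as an attribute).
#' @return The residual, a non-negative scalar.
#' @export
check_steady_state <- function(net, v, tol = 1e-6) {
  stopifnot(inherits(net, "metabolic_network"))
  missing <- setdiff(net$reaction_ids, names(v))
  if (length(missing))
    stop("flux vector missing reactions: ", paste(missing, collapse = ", "))
  residual <- max(0, abs(net$S %*% v[net$reaction_ids]))
  structure(residual, tol = tol)
}

# Non-dominated subset of a points matrix (rows = points, maximisation).
pareto_filter <- function(points) {
  n <- nrow(points)
  if (n == 0L) return(points)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    pi <- points[i, ]
    ge <- points >= matrix(pi, n, ncol(points), byrow = TRUE)
    gt <- points > matrix(pi, n, ncol(points), byrow = TRUE)
    dominated_by <- rowSums(ge) == ncol(points) & rowSums(gt) > 0
    if (any(dominated_by & keep)) keep[i] <- FALSE
  }
  points[keep, , drop = FALSE]
}

#' Deterministic epsilon-constraint Pareto front (test oracle)
#'
#' Approximates the Pareto frontier of 2-3 maximised reaction fluxes by
#' sweeping lower-bound constraints: each objective in turn is maximised
#' while the others are constrained to a grid of lower bounds between
#' their base lower bound and their single-objective optimum. Infeasible
#' grid points are skipped. The non-dominated subset of all resulting
#' objective vectors is returned.
#'
#' @param net A `metabolic_network`.
#' @param objectives Character vector of 2 or 3 reaction ids.
#' @param grid_steps Number of grid levels per constrained objective
#'   (>= 2).
#' @return Matrix of non-dominated objective vectors, one row per point,
#'   columns named after `objectives`.
#' @export
oracle_front <- function(net, objectives, grid_steps) {
  stopifnot(inherits(net, "metabolic_network"))
  k <- length(objectives)
  if (k < 2L || k > 3L) stop("oracle_front needs 2 or 3 objectives")
  if (grid_steps < 2L) stop("grid_steps must be >= 2")
  if (!all(objectives %in% net$reaction_ids))
    stop("unknown objective reaction(s)")

  maxima <- vapply(objectives, function(id) {
    res <- solve_fba(net, id, "max")
    if (res$status != "optimal")
      stop("base network LP not optimal for ", id, " (", res$status, ")")
    res$objective_value
  }, numeric(1))

  pts <- list()
  for (lead in seq_len(k)) {
    others <- setdiff(seq_len(k), lead)
    grids <- lapply(others, function(j) {
      seq(net$lb[[objectives[j]]], maxima[j], length.out = grid_steps)
    })
    combos <- as.matrix(expand.grid(grids))
    for (r in seq_len(nrow(combos))) {
      ov <- lapply(seq_along(others), function(t) {
        c(combos[r, t], net$ub[[objectives[others[t]]]])
      })
      names(ov) <- objectives[others]
      res <- solve_fba(net, objectives[lead], "max", bound_overrides = ov)
      if (res$status == "optimal")
        pts[[length(pts) + 1L]] <- res$fluxes[objectives]
    }
  }
  if (!length(pts)) stop("no feasible grid point")
  points <- unique(do.call(rbind, pts))
  colnames(points) <- objectives
  pareto_filter(points)
}
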