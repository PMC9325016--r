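# Bridge between the evolutionary engine and FBA: the fitness evaluation
# function decodes a genotype into bound overrides, solves the
# leading-bioproduct FBA LP and reads the multi-objective vector off the
# optimal flux vector.

# Worst-case sentinel objective for infeasible genotypes. It never enters
# a feasible front because constrained domination screens infeasible
# individuals first.
WORST_OBJECTIVE <- -1e300

#' Define a multi-objective FBA configuration
#'
#' Names the bioproduct reactions to be maximised simultaneously (the
#' first is the leading bioproduct handed to the inner FBA LP) and the
#' control reaction set VM whose bounds the genotype may also re-define.
#' The two sets must be disjoint.
#'
#' @param vb_ids Character vector of 2 or 3 bioproduct reaction ids,
#'   leading bioproduct first.
#' @param vm_ids Character vector of control reaction ids.
#' @param id Optional configuration label (e.g. `"C0"`).
#' @return An `objective_config`.
#' @examples
#' objective_config(c("v10", "v14", "v18"), c("v1", "v16", "v17"), id = "C0")
#' @export
objective_config <- function(vb_ids, vm_ids, id = NULL) {
  vb_ids <- as.character(vb_ids)
  vm_ids <- as.character(vm_ids)
  if (length(vb_ids) < 2L || length(vb_ids) > 3L)
    stop("need 2 or 3 bioproduct reactions")
  if (anyDuplicated(c(vb_ids, vm_ids)))
    stop("vb_ids and vm_ids must be disjoint and free of duplicates")
  structure(list(vb_ids = vb_ids, vm_ids = vm_ids, sense = "max", id = id),
            class = "objective_config")
}

#' @export
print.objective_config <- function(x, ...) {
  cat("<objective_config", if (!is.null(x$id)) paste0(" ", x$id), "> Vb = {",
      paste(x$vb_ids, collapse = ", "), "}, VM = {",
      paste(x$vm_ids, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Assemble the evolutionary problem for a network and configuration
#'
#' Builds the encoding over `VM` then `Vb` from the network's base bounds
#' and returns the vectorised fitness callback used by [nsga2_run()]. The
#' callback decodes each genotype, solves the FBA LP maximising the
#' leading bioproduct under the decoded bounds, and returns the fluxes of
#' all bioproduct reactions as the objective vector. Feasible LPs have
#' violation 0; infeasible (or unbounded) ones yield a large negative
#' sentinel objective vector and a positive violation equal to the LP's
#' Phase-1 infeasibility — the minimum total mass-balance slack needed to
#' satisfy the decoded bounds — so constrained domination can order
#' infeasible genotypes by how far they are from feasibility. The
#' callback is pure: identical genotypes always give identical results.
#'
#' @param net A `metabolic_network`.
#' @param cfg An [objective_config()].
#' @return List with `evaluate` (callback), `spec` ([encoding_spec()]),
#'   `lower`, `upper` (genotype box), `cfg` and `net`.
#' @export
assemble_problem <- function(net, cfg) {
  stopifnot(inherits(net, "metabolic_network"),
            inherits(cfg, "objective_config"))
  spec <- encoding_spec(net, cfg$vm_ids, cfg$vb_ids)
  box <- genotype_bounds(spec)
  n <- length(net$reaction_ids)
  enc_idx <- match(spec$ids, net$reaction_ids)
  vb_idx <- match(cfg$vb_ids, net$reaction_ids)
  lead_col <- vb_idx[1L]
  base_lb <- unname(net$lb)
  base_ub <- unname(net$ub)
  base_enc_ub <- unname(spec$base_ub)
  S <- net$S
  n_obj <- length(cfg$vb_ids)

  evaluate <- function(X) {
    X <- matrix(X, ncol = spec$length)
    K <- nrow(X)
    I <- X[, seq(1L, spec$length, by = 2L), drop = FALSE]
    D <- X[, seq(2L, spec$length, by = 2L), drop = FALSE]
    ub_enc <- sweep(-I, 2L, base_enc_ub, "+") * D + I
    LB <- matrix(base_lb, K, n, byrow = TRUE)
    UB <- matrix(base_ub, K, n, byrow = TRUE)
    LB[, enc_idx] <- I
    UB[, enc_idx] <- ub_enc
    ans <- .fba_solve_batch(S, LB, UB, lead_col, TRUE)
    feas <- ans$status == 0L
    objectives <- matrix(WORST_OBJECTIVE, K, n_obj)
    if (any(feas))
      objectives[feas, ] <- ans$fluxes[feas, vb_idx, drop = FALSE]
    # smallest positive floor keeps degenerate non-optimal statuses
    # (which carry no Phase-1 measure) marked as violating
    violation <- ifelse(feas, 0, pmax(ans$infeasibility, 1e-300))
    list(objectives = objectives, violation = violation,
         fluxes = ans$fluxes)
  }

  list(evaluate = evaluate, spec = spec, lower = box$lower,
       upper = box$upper, cfg = cfg, net = net)
}

#' Evaluate a single genotype
#'
#' Convenience wrapper around the fitness callback of
#' [assemble_problem()] for one genotype.
#'
#' @param w Numeric genotype of length `2 * (|VM| + |Vb|)`.
#' @param net A `metabolic_network`.
#' @param cfg An [objective_config()].
#' @param problem Optional pre-assembled problem (avoids rebuilding).
#' @return List with `objectives` (named numeric, one entry per
#'   bioproduct), `violation` (0 if feasible, otherwise the positive
#'   Phase-1 infeasibility of the decoded LP) and `fluxes` (full flux
#'   vector, NA if infeasible).
#' @export
evaluate_genotype <- function(w, net, cfg, problem = NULL) {
  if (is.null(problem)) problem <- assemble_problem(net, cfg)
  ev <- problem$evaluate(matrix(w, nrow = 1L))
  list(
    objectives = stats::setNames(ev$objectives[1L, ], cfg$vb_ids),
    violation = ev$violation[1L],
    fluxes = stats::setNames(ev$fluxes[1L, ], net$reaction_ids)
  )
}
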