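# Independent oracles used across the suite.

# O(n^2) brute-force non-dominated sorting: build the domination matrix
# with the scalar `dominates()` definition pair by pair, then peel fronts.
brute_force_sort <- function(objectives, violations = 0) {
  n <- nrow(objectives)
  violations <- rep_len(violations, n)
  if (n == 0L) return(list(fronts = list(), rank = integer(0)))
  dom <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j)
        dom[i, j] <- dominates(objectives[i, ], objectives[j, ],
                               violations[i], violations[j])
    }
  }
  rank <- rep(NA_integer_, n)
  fronts <- list()
  level <- 0L
  remaining <- seq_len(n)
  while (length(remaining)) {
    level <- level + 1L
    nd <- remaining[vapply(remaining, function(j)
      !any(dom[remaining, j]), logical(1))]
    fronts[[level]] <- nd
    rank[nd] <- level
    remaining <- setdiff(remaining, nd)
  }
  list(fronts = fronts, rank = rank)
}

# Reference LP solve through boot::simplex (recommended package, pure R).
# Shifts x = v - lb so x >= 0, bounds become x <= ub - lb, mass balance
# S x = -S lb. Returns list(status, value).
boot_fba <- function(net, objective, sense = "max", bound_overrides = NULL) {
  lb <- net$lb
  ub <- net$ub
  for (id in names(bound_overrides)) {
    lb[id] <- bound_overrides[[id]][1]
    ub[id] <- bound_overrides[[id]][2]
  }
  S <- net$S
  n <- ncol(S)
  a <- as.numeric(net$reaction_ids == objective)
  res <- boot::simplex(a = a,
                       A1 = diag(n), b1 = unname(ub - lb),
                       A3 = S, b3 = as.numeric(-S %*% lb),
                       maxi = (sense == "max"), n.iter = 10000)
  if (res$solved == 1) {
    list(status = "optimal", value = unname(res$value) + sum(a * lb),
         v = unname(res$soln) + unname(lb))
  } else if (res$solved == -1) {
    list(status = "infeasible", value = NA_real_, v = NULL)
  } else {
    list(status = "unsolved", value = NA_real_, v = NULL)
  }
}

# Cross-validated reference: boot::simplex first, its solution verified
# against the constraints; pracma::linprog as the second reference when
# boot's vertex fails verification (boot's textbook simplex can report
# bound-violating vertices on shifted problems). Returns status "unknown"
# when neither reference produces a verifiable answer.
ref_fba <- function(net, objective, bound_overrides = NULL) {
  lb <- net$lb
  ub <- net$ub
  for (id in names(bound_overrides)) {
    lb[id] <- bound_overrides[[id]][1]
    ub[id] <- bound_overrides[[id]][2]
  }
  S <- net$S
  a <- as.numeric(net$reaction_ids == objective)
  verify <- function(v) {
    max(abs(S %*% v)) <= 1e-6 * max(1, max(abs(v))) &&
      all(v >= unname(lb) - 1e-6) && all(v <= unname(ub) + 1e-6)
  }
  bs <- boot_fba(net, objective, bound_overrides = bound_overrides)
  if (bs$status == "optimal" && verify(bs$v))
    return(list(status = "optimal", value = sum(a * bs$v)))
  lp <- tryCatch(
    pracma::linprog(cc = a, Aeq = S, beq = rep(0, nrow(S)),
                    lb = unname(lb), ub = unname(ub),
                    maximize = TRUE, maxiter = 1000),
    error = function(e) NULL)
  if (!is.null(lp) && length(lp$fval) == 1 && is.finite(lp$fval) &&
      !is.null(lp$x) && verify(lp$x))
    return(list(status = "optimal", value = unname(lp$fval)))
  if (bs$status == "infeasible" &&
      (is.null(lp) || !isTRUE(is.finite(lp$fval))))
    return(list(status = "infeasible", value = NA_real_))
  list(status = "unknown", value = NA_real_)
}

# shared across acceptance tests so the heavy C0 protocol runs once
.acceptance_cache <- new.env(parent = emptyenv())

# Random genotypes biased toward the feasible region: uniform draws on
# the full [LB, UB] box are almost never feasible on the case study (the
# encoded lower bounds exceed the attainable fluxes), so half the draws
# shrink the I coordinates toward LB while keeping Delta uniform. Uses
# the global RNG stream.
random_genotype_mixed <- function(spec) {
  w <- random_genotype(spec)
  if (runif(1) < 0.5) {
    odd <- seq(1L, spec$length, by = 2L)
    w[odd] <- spec$base_lb + (w[odd] - spec$base_lb) * runif(1, 0, 0.1)
  }
  w
}

c0_config <- function() {
  objective_config(c("v10", "v14", "v18"), c("v1", "v16", "v17"), id = "C0")
}
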