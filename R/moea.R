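# Self-contained NSGA-II engine for real-coded genotypes: constrained
# non-dominated sorting, crowding distance, SBX crossover, polynomial
# mutation, random mating selection and the (mu + lambda) generational
# loop. All objectives are maximised.

#' Constrained domination between two individuals
#'
#' Feasibility-first comparison: a feasible individual always dominates an
#' infeasible one; between two infeasible individuals the smaller
#' violation wins; between two feasible individuals standard Pareto
#' domination under maximisation applies (>= in every coordinate, > in at
#' least one). Domination is strict, so identical individuals do not
#' dominate each other.
#'
#' @param obj_a,obj_b Numeric objective vectors of equal length.
#' @param violation_a,violation_b Non-negative constraint violations
#'   (0 = feasible).
#' @return Logical: does `a` dominate `b`?
#' @export
dominates <- function(obj_a, obj_b, violation_a = 0, violation_b = 0) {
  if (length(obj_a) != length(obj_b))
    stop("objective vectors have different lengths")
  feas_a <- violation_a == 0
  feas_b <- violation_b == 0
  if (feas_a && !feas_b) return(TRUE)
  if (!feas_a && !feas_b) return(violation_a < violation_b)
  if (!feas_a) return(FALSE)
  all(obj_a >= obj_b) && any(obj_a > obj_b)
}

#' Fast non-dominated sorting with constrained domination
#'
#' Partitions a population into fronts: front 1 is the non-dominated set,
#' front k the set non-dominated once fronts `< k` are removed. Every
#' individual lands in exactly one front.
#'
#' @param objectives Numeric matrix, one row per individual, one column
#'   per (maximised) objective.
#' @param violations Numeric vector of constraint violations (recycled
#'   scalar 0 by default).
#' @return List with `fronts` (list of integer index vectors, best first)
#'   and `rank` (integer vector, 1 = best front).
#' @export
fast_nondominated_sort <- function(objectives, violations = 0) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n == 0L) return(list(fronts = list(), rank = integer(0)))
  violations <- rep_len(violations, n)
  feas <- violations == 0

  all_ge <- matrix(TRUE, n, n)
  any_gt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(objectives))) {
    d <- outer(objectives[, k], objectives[, k], "-")
    all_ge <- all_ge & (d >= 0)
    any_gt <- any_gt | (d > 0)
  }
  dom <- (outer(feas, !feas, "&")) |
    (outer(!feas, !feas, "&") & outer(violations, violations, "<")) |
    (outer(feas, feas, "&") & all_ge & any_gt)
  diag(dom) <- FALSE

  n_dom <- .colSums(dom, n, n)
  rank <- integer(n)
  fronts <- list()
  assigned <- 0L
  level <- 0L
  current <- which(n_dom == 0L)
  while (length(current)) {
    level <- level + 1L
    fronts[[level]] <- current
    rank[current] <- level
    assigned <- assigned + length(current)
    n_dom[current] <- NA_integer_  # never reselected
    if (assigned == n) break
    n_dom <- n_dom - .colSums(dom[current, , drop = FALSE],
                              length(current), n)
    current <- which(!is.na(n_dom) & n_dom == 0L)
  }
  list(fronts = fronts, rank = rank)
}

#' Crowding distance within one front
#'
#' For every objective the boundary individuals (extreme values) receive
#' infinite distance; interior individuals accumulate the normalised gap
#' between their neighbours, summed over objectives. An objective with
#' zero range contributes nothing.
#'
#' @param objectives Numeric matrix of the front's objective vectors (one
#'   row per individual).
#' @return Numeric vector of crowding distances (may contain `Inf`).
#' @export
crowding_distance <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n == 0L) return(numeric(0))
  if (n <= 2L) return(rep(Inf, n))
  dist <- numeric(n)
  for (k in seq_len(ncol(objectives))) {
    o <- objectives[, k]
    ord <- order(o)
    rng <- o[ord[n]] - o[ord[1]]
    dist[ord[c(1L, n)]] <- Inf
    if (rng > 0) {
      gaps <- (o[ord[3:n]] - o[ord[1:(n - 2L)]]) / rng
      dist[ord[2:(n - 1L)]] <- dist[ord[2:(n - 1L)]] + gaps
    }
  }
  dist
}

#' Simulated binary crossover (SBX)
#'
#' Real-coded crossover of Deb & Agrawal: with probability `pc` the pair
#' recombines; each variable then recombines with probability 1/2 using a
#' spread factor drawn from the polynomial distribution with index
#' `eta_c`, and children are clipped to the per-variable box. Each
#' variable's pair of child values (recombined or copied) is swapped
#' between the two children with probability 1/2, which makes the two
#' children exchangeable: each child's expected value per variable is the
#' parent midpoint.
#'
#' @param p1,p2 Parent genotypes (equal length).
#' @param pc Crossover probability in `[0, 1]`.
#' @param eta_c Distribution index (larger = children closer to parents).
#' @param lower,upper Per-variable box (may be infinite).
#' @return List with children `c1` and `c2`.
#' @export
sbx_crossover <- function(p1, p2, pc, eta_c, lower, upper) {
  L <- length(p1)
  if (length(p2) != L) stop("parents have different lengths")
  c1 <- p1
  c2 <- p2
  if (stats::runif(1) > pc) return(list(c1 = c1, c2 = c2))

  do_var <- stats::runif(L) <= 0.5
  u <- stats::runif(L)
  do_swap <- stats::runif(L) <= 0.5

  lower <- rep_len(lower, L)
  upper <- rep_len(upper, L)
  y1 <- pmin(p1, p2)
  y2 <- pmax(p1, p2)
  act <- do_var & (y2 - y1) > 1e-14
  if (any(act)) {
    spread <- function(beta, u) {
      alpha <- 2 - beta^(-(eta_c + 1))
      ifelse(u <= 1 / alpha,
             (u * alpha)^(1 / (eta_c + 1)),
             (1 / (2 - u * alpha))^(1 / (eta_c + 1)))
    }
    dy <- y2[act] - y1[act]
    beta_l <- 1 + 2 * (y1[act] - lower[act]) / dy
    beta_u <- 1 + 2 * (upper[act] - y2[act]) / dy
    bq1 <- spread(beta_l, u[act])
    bq2 <- spread(beta_u, u[act])
    v1 <- 0.5 * ((y1[act] + y2[act]) - bq1 * dy)
    v2 <- 0.5 * ((y1[act] + y2[act]) + bq2 * dy)
    c1[act] <- pmin(pmax(v1, lower[act]), upper[act])
    c2[act] <- pmin(pmax(v2, lower[act]), upper[act])
  }
  if (any(do_swap)) {
    tmp <- c1[do_swap]
    c1[do_swap] <- c2[do_swap]
    c2[do_swap] <- tmp
  }
  list(c1 = c1, c2 = c2)
}

#' Polynomial mutation
#'
#' Each variable is independently perturbed with probability `pm` by the
#' bounded polynomial mutation of Deb & Goyal with distribution index
#' `eta_m`; the perturbation is symmetric at the box centre and shrinks
#' near the box edges, so the result always stays inside the box.
#' Requires finite per-variable bounds.
#'
#' @param g Genotype.
#' @param pm Per-variable mutation probability in `[0, 1]`.
#' @param eta_m Distribution index.
#' @param lower,upper Finite per-variable box.
#' @return Mutated genotype.
#' @export
polynomial_mutation <- function(g, pm, eta_m, lower, upper) {
  L <- length(g)
  do_var <- stats::runif(L) <= pm
  if (!any(do_var)) return(g)
  if (!all(is.finite(lower[do_var])) || !all(is.finite(upper[do_var])))
    stop("polynomial mutation requires finite bounds")
  u <- stats::runif(L)
  i <- which(do_var & upper > lower)
  if (length(i)) {
    y <- g[i]
    yl <- lower[i]
    yu <- upper[i]
    d1 <- (y - yl) / (yu - yl)
    d2 <- (yu - y) / (yu - yl)
    mp <- 1 / (eta_m + 1)
    lo <- u[i] <= 0.5
    xy <- ifelse(lo, 1 - d1, 1 - d2)
    val <- ifelse(lo,
                  2 * u[i] + (1 - 2 * u[i]) * xy^(eta_m + 1),
                  2 * (1 - u[i]) + 2 * (u[i] - 0.5) * xy^(eta_m + 1))
    deltaq <- ifelse(lo, val^mp - 1, 1 - val^mp)
    g[i] <- pmin(pmax(y + deltaq * (yu - yl), yl), yu)
  }
  g[do_var & upper <= lower] <- lower[do_var & upper <= lower]
  g
}

# (rank, crowding) environmental selection: fill by fronts, truncate the
# last partially fitting front by descending crowding distance (stable
# order on ties for reproducibility).
environmental_selection <- function(objectives, violations, n_keep) {
  sorted <- fast_nondominated_sort(objectives, violations)
  chosen <- integer(0)
  for (front in sorted$fronts) {
    if (length(chosen) + length(front) <= n_keep) {
      chosen <- c(chosen, front)
    } else {
      cd <- crowding_distance(objectives[front, , drop = FALSE])
      ord <- order(cd, decreasing = TRUE)  # stable: ties keep input order
      chosen <- c(chosen, front[ord][seq_len(n_keep - length(chosen))])
      break
    }
  }
  chosen
}

#' Run NSGA-II
#'
#' Generational NSGA-II with random initialisation inside the box,
#' uniform random mating pairs (no tournament), SBX crossover, polynomial
#' mutation and elitist (mu + lambda) environmental selection by
#' constrained non-domination rank and crowding distance. All objectives
#' are maximised. The run stops once the evaluation budget cannot
#' accommodate another full offspring population.
#'
#' @param evaluate Vectorised fitness callback: takes a `K x L` genotype
#'   matrix, returns a list with `objectives` (`K x M` matrix) and
#'   `violation` (length-`K` numeric, 0 = feasible). See
#'   [assemble_problem()].
#' @param lower,upper Per-variable box of length `L`.
#' @param pop_size Population size `N` (even).
#' @param max_evals Total evaluation budget (>= `pop_size`); the initial
#'   population counts towards it.
#' @param pc,eta_c SBX crossover probability and distribution index.
#' @param pm,eta_m Polynomial mutation probability (default `1 / L`) and
#'   distribution index.
#' @param seed Optional integer; if given, `set.seed(seed)` is called so
#'   the run is bit-reproducible.
#' @param log_file Optional path; one JSON line per generation with the
#'   generation index, evaluations used, feasible count and size of the
#'   best front.
#' @return An `nsga_population`: list with `genotypes` (`N x L`),
#'   `objectives` (`N x M`), `violation`, `rank`, `crowding`,
#'   `evaluations` and `generations`.
#' @export
nsga2_run <- function(evaluate, lower, upper, pop_size, max_evals,
                      pc = 1.0, eta_c = 20, pm = NULL, eta_m = 20,
                      seed = NULL, log_file = NULL) {
  L <- length(lower)
  stopifnot(length(upper) == L, L >= 1L)
  if (pop_size %% 2L != 0L) stop("pop_size must be even")
  if (max_evals < pop_size) stop("max_evals must be >= pop_size")
  if (is.null(pm)) pm <- 1 / L
  if (!is.null(seed)) set.seed(seed)

  logcon <- NULL
  if (!is.null(log_file)) {
    logcon <- file(log_file, open = "wt")
    on.exit(close(logcon), add = TRUE)
  }
  log_gen <- function(gen, evals, V, rank) {
    if (is.null(logcon)) return(invisible())
    writeLines(jsonlite::toJSON(
      list(generation = gen, evaluations = evals,
           feasible = sum(V == 0), front0_size = sum(rank == 1L)),
      auto_unbox = TRUE), logcon)
  }

  X <- matrix(0, pop_size, L)
  for (j in seq_len(L)) X[, j] <- stats::runif(pop_size, lower[j], upper[j])
  ev <- evaluate(X)
  O <- as.matrix(ev$objectives)
  V <- rep_len(ev$violation, pop_size)
  evals <- pop_size
  gen <- 0L
  sorted <- fast_nondominated_sort(O, V)
  log_gen(gen, evals, V, sorted$rank)

  while (evals + pop_size <= max_evals) {
    gen <- gen + 1L
    mates <- sample.int(pop_size)  # random pairs without replacement
    Y <- matrix(0, pop_size, L)
    for (p in seq_len(pop_size %/% 2L)) {
      i1 <- mates[2L * p - 1L]
      i2 <- mates[2L * p]
      kids <- sbx_crossover(X[i1, ], X[i2, ], pc, eta_c, lower, upper)
      Y[2L * p - 1L, ] <- polynomial_mutation(kids$c1, pm, eta_m,
                                              lower, upper)
      Y[2L * p, ] <- polynomial_mutation(kids$c2, pm, eta_m, lower, upper)
    }
    evY <- evaluate(Y)
    evals <- evals + pop_size

    Oc <- rbind(O, as.matrix(evY$objectives))
    Vc <- c(V, rep_len(evY$violation, pop_size))
    Xc <- rbind(X, Y)
    keep <- environmental_selection(Oc, Vc, pop_size)
    X <- Xc[keep, , drop = FALSE]
    O <- Oc[keep, , drop = FALSE]
    V <- Vc[keep]
    sorted <- fast_nondominated_sort(O, V)
    log_gen(gen, evals, V, sorted$rank)
  }

  crowding <- numeric(pop_size)
  for (front in sorted$fronts)
    crowding[front] <- crowding_distance(O[front, , drop = FALSE])
  structure(
    list(genotypes = X, objectives = O, violation = V,
         rank = sorted$rank, crowding = crowding,
         evaluations = evals, generations = gen),
    class = "nsga_population"
  )
}

#' @export
print.nsga_population <- function(x, ...) {
  cat("<nsga_population> N=", nrow(x$genotypes), ", ",
      x$evaluations, " evaluations, ", x$generations, " generations, ",
      sum(x$rank == 1L & x$violation == 0), " feasible rank-1 solutions\n",
      sep = "")
  invisible(x)
}
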