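# Case-study harness: the C. reinhardtii glycolysis fixture, the C0-C36
# configurations, ideal points, quality/diversity indicators, the
# replicated experiment runner and the FBA comparison table.

#' The 18-reaction glycolysis module of Chlamydomonas reinhardtii
#'
#' Builds the heterotrophic (acetate-fed) glycolysis module: 18 reactions
#' over 14 metabolites, with acetate, E4P and X5P as substrates and
#' protein (`v10`), carbohydrate (`v14`) and CO2 (`v18`) drains as the
#' bioproducts of interest.
#'
#' Two bound sets are available. The default `"reference"` bounds cap the
#' acetate uptake at `ub(v1) = 10` and the pentose substrates at
#' `ub(v16) = ub(v17) = 0.3` with `[0, 100]` elsewhere; these are the
#' bounds under which the module's published single-objective optima
#' (max `v10` = 10, max `v14` = 10.6) are attained, and they are the
#' package default. The `"uniform"` variant sets every reaction to
#' `[0, 100]`.
#'
#' @param bounds `"reference"` (default) or `"uniform"`.
#' @return A `metabolic_network`.
#' @examples
#' net <- build_creinhardtii_network()
#' dim(net$S)  # 14 x 18
#' @export
build_creinhardtii_network <- function(bounds = c("reference", "uniform")) {
  bounds <- match.arg(bounds)
  path <- system.file("extdata", "creinhardtii_glycolysis.tsv",
                      package = "mofba", mustWork = TRUE)
  net <- read_reaction_tsv(path)
  if (bounds == "uniform") {
    net$lb[] <- 0
    net$ub[] <- 100
  }
  net
}

#' The C0-C36 experiment configurations
#'
#' `C0 = {v10, v14, v18}` plus 36 three-bioproduct configurations:
#' `C1-C12 = {v10, v14, x}`, `C13-C24 = {v10, v18, x}` and
#' `C25-C36 = {v14, v18, x}`, with `x` iterating over
#' `v2, v3, v4, v5, v6, v7, v8, v9, v11, v12, v13, v15`. The control set
#' is `VM = {v1, v16, v17}` (the three substrate exchanges) throughout.
#' The third block's third elements are reconstructed from the symmetric
#' pattern of the first two blocks (see the attached
#' `"reconstructed_configs"` attribute).
#'
#' @return Named list of 37 [objective_config()] objects, with attribute
#'   `reconstructed_configs` naming the configurations whose bioproduct
#'   triple is pattern-reconstructed rather than taken verbatim.
#' @export
generate_configurations <- function() {
  vm <- c("v1", "v16", "v17")
  third <- c("v2", "v3", "v4", "v5", "v6", "v7", "v8", "v9",
             "v11", "v12", "v13", "v15")
  cfgs <- list(C0 = objective_config(c("v10", "v14", "v18"), vm, id = "C0"))
  pairs <- list(c("v10", "v14"), c("v10", "v18"), c("v14", "v18"))
  k <- 0L
  for (p in pairs) {
    for (x in third) {
      k <- k + 1L
      id <- paste0("C", k)
      cfgs[[id]] <- objective_config(c(p, x), vm, id = id)
    }
  }
  attr(cfgs, "reconstructed_configs") <- paste0("C", 25:36)
  cfgs
}

#' Ideal point of a configuration
#'
#' One entry per bioproduct: the single-objective FBA maximum of that
#' reaction under the network's base bounds. The ideal point is usually
#' not jointly attainable.
#'
#' @param net A `metabolic_network`.
#' @param cfg An [objective_config()].
#' @return Named numeric vector (names = `cfg$vb_ids`).
#' @export
ideal_point <- function(net, cfg) {
  stopifnot(inherits(cfg, "objective_config"))
  vapply(cfg$vb_ids, function(id) {
    res <- solve_fba(net, id, "max")
    if (res$status != "optimal")
      stop("base network LP for ", id, " is ", res$status)
    res$objective_value
  }, numeric(1))
}

#' Quality indicator Q: distance to the ideal point
#'
#' The quality of a solution set is the minimum Euclidean distance from
#' any of its objective vectors to the ideal point (smaller is better;
#' 0 means the ideal point itself was reached).
#'
#' @param points Numeric matrix of objective vectors (one row each) or a
#'   single vector.
#' @param ideal Numeric ideal point of matching arity.
#' @return Non-negative scalar.
#' @export
quality_Q <- function(points, ideal) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  if (nrow(points) == 0L) stop("empty point set")
  if (ncol(points) != length(ideal)) stop("arity mismatch with ideal point")
  diffs <- sweep(points, 2L, as.numeric(ideal), "-")
  min(sqrt(rowSums(diffs^2)))
}

#' Diversity indicator D: number of distinct solutions
#'
#' Counts equivalence classes of objective vectors, where two vectors are
#' directly equivalent when every component differs by at most `tol`
#' (classes are the connected components of that relation).
#'
#' @param points Numeric matrix of objective vectors (one row each).
#' @param tol Positive distinctness tolerance (objective space).
#' @return Integer count (0 for an empty set).
#' @export
diversity_D <- function(points, tol = 1e-6) {
  if (tol <= 0) stop("tol must be positive")
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  n <- nrow(points)
  if (n == 0L) return(0L)
  # adjacency under component-wise closeness; count connected components
  adj <- matrix(TRUE, n, n)
  for (k in seq_len(ncol(points))) {
    d <- abs(outer(points[, k], points[, k], "-"))
    adj <- adj & (d <= tol)
  }
  comp <- integer(n)
  n_comp <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    n_comp <- n_comp + 1L
    queue <- i
    comp[i] <- n_comp
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- n_comp
      queue <- c(queue, nb)
    }
  }
  n_comp
}

#' Run the replicated NSGA-II experiment for one configuration
#'
#' Solves the configuration `runs` times with [nsga2_run()] (one seed per
#' run), pools the feasible best-front points of all runs, and reports
#' the best quality Q over the pooled front together with the number of
#' distinct pooled non-dominated solutions.
#'
#' @param net A `metabolic_network`.
#' @param cfg An [objective_config()].
#' @param runs Number of independent replicates.
#' @param seeds Integer vector of length `runs` (one RNG seed per run).
#' @param pop_size,max_evals,pc,eta_c,pm,eta_m NSGA-II parameters passed
#'   to [nsga2_run()]; `pm = NULL` defaults to 1 / genotype length.
#' @param distinct_tol Objective-space tolerance for [diversity_D()].
#' @return A `front_report`: list with `config_id`, `runs_requested`,
#'   `runs_effective`, `seeds`, `best_Q`, `F0_count` (distinct pooled
#'   non-dominated solutions), `per_run_F0`, `front_points` (pooled
#'   non-dominated objective vectors), `ideal`, `params` and
#'   `lp_backend`.
#' @export
run_experiment <- function(net, cfg, runs = 31L, seeds = seq_len(runs),
                           pop_size = 100L, max_evals = 10000L,
                           pc = 1.0, eta_c = 20, pm = NULL, eta_m = 20,
                           distinct_tol = 1e-6) {
  stopifnot(length(seeds) == runs)
  problem <- assemble_problem(net, cfg)
  ideal <- ideal_point(net, cfg)

  fronts <- vector("list", runs)
  per_run_F0 <- rep(NA_integer_, runs)
  ok <- logical(runs)
  for (r in seq_len(runs)) {
    pop <- tryCatch(
      nsga2_run(problem$evaluate, problem$lower, problem$upper,
                pop_size = pop_size, max_evals = max_evals,
                pc = pc, eta_c = eta_c, pm = pm, eta_m = eta_m,
                seed = seeds[r]),
      error = function(e) {
        warning("run ", r, " (seed ", seeds[r], ") failed: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(pop)) next
    sel <- pop$rank == 1L & pop$violation == 0
    pts <- pop$objectives[sel, , drop = FALSE]
    fronts[[r]] <- pts
    per_run_F0[r] <- if (nrow(pts)) diversity_D(pareto_filter(pts),
                                                distinct_tol) else 0L
    ok[r] <- TRUE
  }
  if (!any(ok)) stop("all runs failed")

  pooled <- do.call(rbind, fronts[ok])
  if (is.null(pooled) || nrow(pooled) == 0L)
    stop("no feasible front point in any run")
  colnames(pooled) <- cfg$vb_ids
  pooled_nd <- pareto_filter(pooled)

  structure(
    list(config_id = cfg$id, cfg = cfg,
         runs_requested = runs, runs_effective = sum(ok),
         seeds = seeds[ok],
         best_Q = quality_Q(pooled, ideal),
         F0_count = diversity_D(pooled_nd, distinct_tol),
         per_run_F0 = per_run_F0,
         front_points = pooled_nd, ideal = ideal,
         params = list(pop_size = pop_size, max_evals = max_evals,
                       pc = pc, eta_c = eta_c,
                       pm = if (is.null(pm)) 1 / (2 * length(c(cfg$vm_ids,
                                                               cfg$vb_ids)))
                            else pm,
                       eta_m = eta_m, distinct_tol = distinct_tol),
         lp_backend = "mofba dense two-phase simplex (Bland's rule)"),
    class = "front_report"
  )
}

#' @export
print.front_report <- function(x, ...) {
  cat("<front_report", if (!is.null(x$config_id)) paste0(" ", x$config_id),
      "> ", x$runs_effective, "/", x$runs_requested, " runs, best_Q = ",
      format(x$best_Q), ", |F0| = ", x$F0_count, "\n", sep = "")
  invisible(x)
}

#' Export a front report
#'
#' Writes the pooled non-dominated front as a TSV (one objective vector
#' per row) and the report metadata (best_Q, |F0|, seeds, parameters, LP
#' backend) as JSON.
#'
#' @param report A `front_report`.
#' @param front_tsv,report_json Output paths (either may be `NULL` to
#'   skip).
#' @export
write_front_report <- function(report, front_tsv = NULL,
                               report_json = NULL) {
  stopifnot(inherits(report, "front_report"))
  if (!is.null(front_tsv)) {
    utils::write.table(as.data.frame(report$front_points), front_tsv,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report_json)) {
    meta <- report[c("config_id", "runs_requested", "runs_effective",
                     "seeds", "best_Q", "F0_count", "per_run_F0",
                     "ideal", "params", "lp_backend")]
    jsonlite::write_json(meta, report_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  invisible(report)
}

#' Compare NSGA-II fronts against per-objective FBA
#'
#' For each report, the single-objective FBA solution of every bioproduct
#' is evaluated at the configuration's objective vector and its distance
#' to the ideal point computed, giving one FBA quality column per
#' objective next to the NSGA-II quality. Across configurations, a paired
#' Wilcoxon signed-rank test compares the NSGA-II column with each FBA
#' column. When all paired differences are zero the test is degenerate
#' and the p-value is reported as 1 with a warning. Note that non-leading
#' flux components of a single-objective FBA solution can be degenerate,
#' so the FBA columns are solver-dependent where alternate optima exist.
#'
#' @param reports A `front_report` or list of them.
#' @param net The `metabolic_network` the reports were computed on.
#' @return List with `table` (data frame: config, Q_NSGAII, one
#'   `Q_FBA_Objk` per objective, F0) and `p_values` (paired Wilcoxon
#'   p-value per FBA column; NA when fewer than 2 configurations).
#' @export
compare_with_fba <- function(reports, net) {
  if (inherits(reports, "front_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1L)
  n_obj <- length(reports[[1L]]$cfg$vb_ids)

  rows <- lapply(reports, function(rep) {
    cfg <- rep$cfg
    q_fba <- vapply(cfg$vb_ids, function(id) {
      res <- solve_fba(net, id, "max")
      if (res$status != "optimal")
        stop("FBA for ", id, " is ", res$status)
      quality_Q(res$fluxes[cfg$vb_ids], rep$ideal)
    }, numeric(1))
    c(Q_NSGAII = rep$best_Q, stats::setNames(q_fba,
        paste0("Q_FBA_Obj", seq_along(q_fba))), F0 = rep$F0_count)
  })
  tab <- data.frame(
    config = vapply(reports, function(r)
      if (is.null(r$config_id)) NA_character_ else r$config_id,
      character(1)),
    do.call(rbind, rows),
    check.names = FALSE
  )

  p_values <- stats::setNames(rep(NA_real_, n_obj),
                              paste0("Q_FBA_Obj", seq_len(n_obj)))
  if (nrow(tab) >= 2L) {
    for (k in seq_len(n_obj)) {
      col <- paste0("Q_FBA_Obj", k)
      diffs <- tab$Q_NSGAII - tab[[col]]
      if (all(diffs == 0)) {
        warning("all paired differences are zero for ", col,
                "; degenerate test, p = 1")
        p_values[k] <- 1
      } else {
        p_values[k] <- suppressWarnings(
          stats::wilcox.test(tab$Q_NSGAII, tab[[col]],
                             paired = TRUE)$p.value)
      }
    }
  }
  list(table = tab, p_values = p_values)
}

#' Random mass-balanced network fixture
#'
#' Generates a connected chain-and-branch network for property tests:
#' one uptake exchange into the first metabolite, a conversion chain
#' through all metabolites, drains on the first and last metabolites, and
#' additional random unit-stoichiometry conversions or drains. All lower
#' bounds are 0, so the zero flux vector is always feasible. Uses R's
#' global RNG stream (seed with [set.seed()]).
#'
#' @param n_metabolites Number of metabolites (>= 2).
#' @param n_reactions Total number of reactions (>=
#'   `n_metabolites + 2`: uptake + chain + two drains).
#' @param uptake_ub Upper bound of the uptake exchange.
#' @param default_ub Upper bound of all other reactions.
#' @return A `metabolic_network`.
#' @export
random_network_fixture <- function(n_metabolites, n_reactions,
                                   uptake_ub = 10, default_ub = 100) {
  if (n_metabolites < 2L) stop("need at least 2 metabolites")
  if (n_reactions < n_metabolites + 2L)
    stop("need at least n_metabolites + 2 reactions")
  mets <- paste0("M", seq_len(n_metabolites))
  lines <- c(
    paste0("up : --> ", mets[1L]),
    paste0("chain", seq_len(n_metabolites - 1L), " : ",
           mets[-n_metabolites], " --> ", mets[-1L]),
    paste0("drain_last : ", mets[n_metabolites], " -->"),
    paste0("drain_first : ", mets[1L], " -->")
  )
  n_extra <- n_reactions - length(lines)
  for (k in seq_len(n_extra) + 0L) {
    if (stats::runif(1) < 0.5) {
      m <- sample(mets, 1L)
      lines <- c(lines, paste0("xdrain", k, " : ", m, " -->"))
    } else {
      ab <- sample(mets, 2L)
      lines <- c(lines, paste0("xconv", k, " : ", ab[1L], " --> ", ab[2L]))
    }
  }
  net <- parse_reaction_table(lines, default_lb = 0, default_ub = default_ub)
  net$ub["up"] <- uptake_ub
  net
}
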