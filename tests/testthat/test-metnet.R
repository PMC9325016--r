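# Reaction-table parsing, stoichiometric matrix, FBA LP and steady state.

test_that("reaction formulas parse with signed stoichiometry and reversibility", {
  net <- parse_reaction_table(c(
    "v2 : acetate --> ACCOA",
    "v6 : OAA <=> PEP + CO2",
    "v1 : --> acetate",
    "vx : CO2 -->",
    "vc : 2 A + B --> 3 C"
  ))
  expect_equal(net$reactions$v2, c(acetate = -1, ACCOA = 1))
  expect_false(net$reversible[["v2"]])
  expect_equal(net$reactions$v6, c(OAA = -1, PEP = 1, CO2 = 1))
  expect_true(net$reversible[["v6"]])
  expect_equal(net$reactions$v1, c(acetate = 1))   # uptake exchange
  expect_equal(net$reactions$vx, c(CO2 = -1))      # secretion exchange
  expect_equal(net$reactions$vc, c(A = -2, B = -1, C = 3))
})

test_that("malformed input is rejected", {
  expect_error(parse_reaction_table("vx : A ?? B"), "arrow")
  expect_error(parse_reaction_table(c("v1 : A --> B", "v1 : B --> C")),
               "duplicate")
  expect_error(parse_reaction_table("v1 : -2 A --> B"), "positive")
  expect_error(parse_reaction_table("v1 : 0 A --> B"), "positive")
  expect_error(parse_reaction_table("v1 : A --> B --> C"), "arrow")
  expect_error(parse_reaction_table("no colon here"), ":")
})

test_that("stoichiometric matrix follows registration order", {
  net <- build_creinhardtii_network()
  expect_equal(dim(net$S), c(14L, 18L))
  expect_equal(net$metabolites[1:3], c("acetate", "ACCOA", "CIT"))
  col <- net$S[, "v15"]
  expect_equal(col[col != 0], c(T3P = 1, F6P = 1, E4P = -1, X5P = -1)[
    names(col[col != 0])])
  expect_equal(dim(stoich_matrix(parse_reaction_table(character(0)))),
               c(0L, 0L))
})

test_that("FBA reproduces the module's reference optima", {
  net <- build_creinhardtii_network()
  r10 <- solve_fba(net, "v10")
  expect_equal(r10$status, "optimal")
  expect_equal(r10$objective_value, 10, tolerance = 1e-9)
  r14 <- solve_fba(net, "v14")
  expect_equal(r14$objective_value, 10.6, tolerance = 1e-9)
  # forcing more protein than the acetate cap allows is infeasible
  inf <- solve_fba(net, "v10", bound_overrides = list(v10 = c(50, 100)))
  expect_equal(inf$status, "infeasible")
  expect_true(is.na(inf$objective_value))
  expect_null(inf$fluxes)
  # all-zero box admits only v = 0
  zero <- solve_fba(net, "v10",
                    bound_overrides = stats::setNames(
                      rep(list(c(0, 0)), 18), net$reaction_ids))
  expect_equal(zero$status, "optimal")
  expect_equal(zero$objective_value, 0)
  expect_equal(unname(zero$fluxes), rep(0, 18))
})

test_that("optimal solutions satisfy bounds and steady state", {
  net <- build_creinhardtii_network()
  for (obj in c("v10", "v14", "v18", "v2")) {
    res <- solve_fba(net, obj)
    expect_lte(as.numeric(check_steady_state(net, res$fluxes)), 1e-6)
    expect_true(all(res$fluxes >= net$lb - 1e-9))
    expect_true(all(res$fluxes <= net$ub + 1e-9))
  }
})

test_that("steady-state residual is the infinity norm of S v", {
  net <- build_creinhardtii_network()
  v0 <- stats::setNames(rep(0, 18), net$reaction_ids)
  expect_equal(as.numeric(check_steady_state(net, v0)), 0)
  v <- v0
  v["v2"] <- 10  # consumes acetate, produces ACCOA, nothing balances them
  expect_equal(as.numeric(check_steady_state(net, v)), 10)
  expect_error(check_steady_state(net, v0[-1]), "missing")
})

test_that("objective value is invariant to row/column permutation", {
  set.seed(42)
  path <- system.file("extdata", "creinhardtii_glycolysis.tsv",
                      package = "mofba")
  tab <- read.delim(path)
  for (rep in 1:5) {
    perm <- sample(nrow(tab))
    shuffled <- parse_reaction_table(
      paste(tab$id[perm], ":", tab$formula[perm]))
    shuffled$lb[] <- tab$lb[perm]
    shuffled$ub[] <- tab$ub[perm]
    for (obj in c("v10", "v14", "v18")) {
      expect_equal(solve_fba(shuffled, obj)$objective_value,
                   c(v10 = 10, v14 = 10.6, v18 = 10)[[obj]],
                   tolerance = 1e-9)
    }
  }
})

test_that("solver agrees with the boot::simplex reference on the fixture", {
  net <- build_creinhardtii_network()
  for (obj in net$reaction_ids) {
    mine <- solve_fba(net, obj)
    ref <- boot_fba(net, obj)
    expect_equal(mine$status, ref$status, info = obj)
    if (mine$status == "optimal")
      expect_equal(mine$objective_value, ref$value, tolerance = 1e-7,
                   info = obj)
  }
})

test_that("solver agrees with reference LP solvers on random networks", {
  set.seed(7)
  n_compared <- 0L
  for (trial in 1:20) {
    net <- random_network_fixture(sample(3:6, 1), sample(8:14, 1))
    obj <- sample(net$reaction_ids, 1)
    ov <- NULL
    if (trial %% 2 == 0) {
      rid <- sample(net$reaction_ids, 2)
      ov <- lapply(rid, function(id) {
        lo <- runif(1, 0, 5)
        c(lo, lo + runif(1, 0, 20))
      })
      names(ov) <- rid
    }
    mine <- solve_fba(net, obj, bound_overrides = ov)
    ref <- ref_fba(net, obj, bound_overrides = ov)
    if (ref$status == "unknown") next  # no verifiable reference answer
    n_compared <- n_compared + 1L
    expect_equal(mine$status, ref$status)
    if (mine$status == "optimal") {
      expect_equal(mine$objective_value, ref$value, tolerance = 1e-7)
      expect_lte(as.numeric(check_steady_state(net, mine$fluxes)), 1e-6)
    }
  }
  expect_gte(n_compared, 15L)
})

test_that("tightening bounds never improves a maximisation objective", {
  set.seed(11)
  net <- build_creinhardtii_network()
  for (trial in 1:20) {
    obj <- sample(net$reaction_ids, 1)
    base <- solve_fba(net, obj)$objective_value
    rid <- sample(net$reaction_ids, 3)
    ov <- lapply(rid, function(id) {
      lo <- net$lb[[id]]
      hi <- runif(1, lo, net$ub[[id]])  # shrink the upper bound
      c(lo, hi)
    })
    names(ov) <- rid
    tightened <- solve_fba(net, obj, bound_overrides = ov)
    if (tightened$status == "optimal")
      expect_lte(tightened$objective_value, base + 1e-9)
  }
})

test_that("epsilon-constraint oracle recovers the protein/carbohydrate trade-off", {
  net <- build_creinhardtii_network()
  # sweeping v10 >= 0, 5, 10 while maximising v14 walks the front line
  for (case in list(c(0, 10.6), c(5, 5.6), c(10, 0.6))) {
    res <- solve_fba(net, "v14",
                     bound_overrides = list(v10 = c(case[1], 100)))
    expect_equal(res$objective_value, case[2], tolerance = 1e-9)
  }
  front <- oracle_front(net, c("v10", "v14", "v18"), grid_steps = 5)
  interior <- front[front[, "v10"] > 1e-6 & front[, "v14"] > 0.6 + 1e-6, ,
                    drop = FALSE]
  expect_gt(nrow(interior), 0)
  expect_true(all(abs(interior[, "v10"] + interior[, "v14"] - 10.6) <= 1e-6))
  expect_true(all(abs(front[, "v18"] - 10) <= 1e-6))
})

test_that("oracle front edge cases", {
  net <- build_creinhardtii_network()
  # two extremes survive a 2-step grid on (v10, v14)
  f2 <- oracle_front(net, c("v10", "v14"), grid_steps = 2)
  f2 <- f2[order(f2[, 1]), , drop = FALSE]
  expect_equal(unname(f2), rbind(c(0, 10.6), c(10, 0.6)), tolerance = 1e-9)
  # the front is mutually non-dominated (brute-force pairwise check)
  f5 <- oracle_front(net, c("v10", "v14"), grid_steps = 5)
  for (i in seq_len(nrow(f5))) {
    for (j in seq_len(nrow(f5))) {
      if (i != j) expect_false(dominates(f5[i, ], f5[j, ]))
    }
  }
})

test_that("reaction TSV round trip and flux export", {
  net <- build_creinhardtii_network()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  res <- solve_fba(net, "v14")
  write_flux_tsv(res, tmp)
  back <- read.delim(tmp)
  expect_equal(back$reaction_id, net$reaction_ids)
  expect_equal(back$flux[back$reaction_id == "v11"], 10.3, tolerance = 1e-6)
})
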