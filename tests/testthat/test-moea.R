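# NSGA-II engine: domination, sorting, crowding, variation operators,
# and the generational loop.

test_that("constrained domination follows feasibility-first rules", {
  expect_true(dominates(c(1, 1), c(0, 0)))
  expect_false(dominates(c(0, 0), c(1, 1)))
  # a feasible solution beats any infeasible one, whatever its objectives
  expect_true(dominates(c(0, 0), c(100, 100), 0, 1))
  expect_false(dominates(c(100, 100), c(0, 0), 1, 0))
  # among infeasible, smaller violation wins
  expect_true(dominates(c(0, 0), c(5, 5), 0.2, 0.5))
  expect_false(dominates(c(0, 0), c(5, 5), 0.5, 0.5))
  # incomparable and identical pairs
  expect_false(dominates(c(1, 0), c(0, 1)))
  expect_false(dominates(c(0, 1), c(1, 0)))
  expect_false(dominates(c(2, 2), c(2, 2)))
  expect_error(dominates(c(1, 2, 3), c(1, 2)), "length")
})

test_that("non-dominated sorting handles simple ordered cases", {
  s <- fast_nondominated_sort(rbind(c(2, 2), c(1, 1), c(0, 0)))
  expect_equal(s$fronts, list(1L, 2L, 3L))
  expect_equal(s$rank, 1:3)
  s2 <- fast_nondominated_sort(rbind(c(1, 0), c(0, 1), c(0, 0)))
  expect_equal(s2$fronts, list(c(1L, 2L), 3L))
  empty <- fast_nondominated_sort(matrix(numeric(0), 0, 2))
  expect_equal(empty$fronts, list())
  expect_equal(empty$rank, integer(0))
})

test_that("sorting matches the brute-force oracle on random populations", {
  set.seed(2024)
  for (trial in 1:60) {
    n <- sample(2:40, 1)
    m <- sample(2:3, 1)
    O <- matrix(sample(0:6, n * m, replace = TRUE), n, m)  # many ties
    V <- ifelse(runif(n) < 0.3, round(runif(n), 2), 0)
    fast <- fast_nondominated_sort(O, V)
    brute <- brute_force_sort(O, V)
    expect_equal(fast$rank, brute$rank)
    expect_equal(fast$fronts, brute$fronts)
  }
})

test_that("with all individuals infeasible, ranking is by violation", {
  O <- rbind(c(0, 0), c(9, 9), c(5, 5))
  V <- c(0.3, 0.1, 0.2)
  s <- fast_nondominated_sort(O, V)
  expect_equal(s$rank, c(3L, 1L, 2L))
})

test_that("crowding distance matches the standard formula", {
  expect_equal(crowding_distance(rbind(c(0, 1), c(1, 0))), c(Inf, Inf))
  d <- crowding_distance(rbind(c(0, 2), c(1, 1), c(2, 0)))
  expect_equal(d, c(Inf, 2, Inf))  # middle: (2-0)/2 + (2-0)/2
  same <- crowding_distance(rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 1)))
  expect_true(all(is.infinite(same[c(1, 4)]) | same[c(1, 4)] == Inf))
  expect_equal(same[2:3], c(0, 0))  # zero range contributes nothing
})

test_that("SBX copies parents when pc = 0 or parents coincide", {
  set.seed(1)
  p1 <- c(2, 5, 8)
  p2 <- c(3, 4, 7)
  lo <- rep(0, 3)
  hi <- rep(10, 3)
  kids <- sbx_crossover(p1, p2, pc = 0, eta_c = 20, lo, hi)
  expect_identical(kids$c1, p1)
  expect_identical(kids$c2, p2)
  for (k in 1:20) {
    same <- sbx_crossover(p1, p1, pc = 1, eta_c = 20, lo, hi)
    expect_equal(same$c1, p1)
    expect_equal(same$c2, p1)
  }
})

test_that("SBX children stay in the box and are symmetric on average", {
  set.seed(42)
  lo <- 0
  hi <- 10
  kids1 <- kids2 <- numeric(1e4)
  for (k in 1:1e4) {
    kk <- sbx_crossover(2, 8, pc = 1, eta_c = 20, -Inf, Inf)
    kids1[k] <- kk$c1
    kids2[k] <- kk$c2
  }
  # SBX is mean-preserving around the parent midpoint
  se <- sd(c(kids1, kids2)) / sqrt(1e4)
  expect_lt(abs(mean(kids1) - 5), 3 * se)
  expect_lt(abs(mean(kids2) - 5), 3 * se)
  set.seed(43)
  for (k in 1:200) {
    kk <- sbx_crossover(c(2, 9.9), c(8, 0.1), 1, 2, c(0, 0), c(10, 10))
    expect_true(all(kk$c1 >= 0 & kk$c1 <= 10))
    expect_true(all(kk$c2 >= 0 & kk$c2 <= 10))
  }
})

test_that("polynomial mutation respects pm, the box, and symmetry", {
  g <- c(1, 5, 9)
  expect_identical(polynomial_mutation(g, 0, 20, rep(0, 3), rep(10, 3)), g)
  set.seed(9)
  # a variable at its lower bound can only move up
  for (k in 1:200) {
    out <- polynomial_mutation(0, 1, 20, 0, 10)
    expect_gte(out, 0)
    expect_lte(out, 10)
  }
  # perturbation at the box centre has mean displacement ~ 0
  set.seed(10)
  disp <- replicate(1e4, polynomial_mutation(5, 1, 20, 0, 10) - 5)
  expect_lt(abs(mean(disp)), 3 * sd(disp) / sqrt(1e4))
})

test_that("NSGA-II approximates a known convex front", {
  # maximise (x, 1 - x^2) over x in [0, 1]; the front is the curve itself
  evaluate <- function(X) {
    x <- X[, 1]
    list(objectives = cbind(x, 1 - x^2), violation = rep(0, nrow(X)))
  }
  pop <- nsga2_run(evaluate, lower = 0, upper = 1, pop_size = 40,
                   max_evals = 2000, pm = 0.5, seed = 3)
  front <- pop$objectives[pop$rank == 1L, , drop = FALSE]
  expect_gt(nrow(front), 10)
  expect_true(all(abs(front[, 2] - (1 - front[, 1]^2)) <= 1e-2))
})

test_that("fixed seed gives a bit-identical population; budget N skips evolution", {
  evaluate <- function(X)
    list(objectives = cbind(X[, 1], -X[, 1] + X[, 2]),
         violation = rep(0, nrow(X)))
  a <- nsga2_run(evaluate, c(0, 0), c(1, 1), 20, 400, seed = 7)
  b <- nsga2_run(evaluate, c(0, 0), c(1, 1), 20, 400, seed = 7)
  expect_identical(a, b)
  init_only <- nsga2_run(evaluate, c(0, 0), c(1, 1), 20, 20, seed = 7)
  expect_equal(init_only$generations, 0L)
  expect_equal(init_only$evaluations, 20L)
  expect_error(nsga2_run(evaluate, c(0, 0), c(1, 1), 21, 400), "even")
  expect_error(nsga2_run(evaluate, c(0, 0), c(1, 1), 20, 10), "max_evals")
})

test_that("environmental selection is elitist and stays in the box", {
  evaluate <- function(X) {
    x <- X[, 1]
    y <- X[, 2]
    list(objectives = cbind(x, 1 - x^2 - 0.5 * y),
         violation = as.numeric(y > 0.9))  # top strip infeasible
  }
  # same seed, budgets one generation apart: the longer run extends the
  # shorter one, so consecutive-generation fronts can be compared
  for (evals in c(200, 400, 800)) {
    a <- nsga2_run(evaluate, c(0, 0), c(1, 1), 20, evals, seed = 12)
    b <- nsga2_run(evaluate, c(0, 0), c(1, 1), 20, evals + 20, seed = 12)
    expect_true(all(a$genotypes >= 0 & a$genotypes <= 1))
    front_a <- a$objectives[a$rank == 1L & a$violation == 0, , drop = FALSE]
    front_b <- b$objectives[b$rank == 1L & b$violation == 0, , drop = FALSE]
    # no feasible non-dominated point of generation t dominates one kept
    # at generation t + 1
    for (i in seq_len(nrow(front_a))) {
      for (j in seq_len(nrow(front_b))) {
        expect_false(dominates(front_a[i, ], front_b[j, ]))
      }
    }
  }
})

test_that("the generation log records budget consumption", {
  evaluate <- function(X)
    list(objectives = cbind(X[, 1], 1 - X[, 1]), violation = rep(0, nrow(X)))
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  nsga2_run(evaluate, 0, 1, 10, 50, seed = 2, log_file = tmp)
  lines <- readLines(tmp)
  expect_length(lines, 5)  # init + 4 generations
  last <- jsonlite::fromJSON(lines[length(lines)])
  expect_equal(last$evaluations, 50)
  expect_equal(last$feasible, 10)
})
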