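# Exact analytics: Condorcet kernels, the accuracy landscape, the optimal
# behavior, benchmarks and regret maps. Expected values come from the
# independent choose()-sum / enumeration oracles in helper-oracles.R.

test_that("majority_prob matches binomial enumeration", {
  expect_equal(majority_prob(0.7, 3), 0.784)
  expect_equal(majority_prob(0.7, 2), 0.7) # tie term contributes 1/2
  expect_equal(majority_prob(1, 9), 1)
  expect_equal(majority_prob(0.5, 8), 0.5)
  for (q in c(0.55, 0.7, 0.9)) {
    for (n in 1:6) {
      expect_equal(majority_prob(q, n), oracle_majority(q, n),
                   tolerance = 1e-12)
    }
  }
  expect_error(majority_prob(1.2, 3), "q")
})

test_that("majority_prob is monotone in competence and odd group size", {
  q <- seq(0, 1, by = 0.01)
  for (n in c(3, 8, 31)) {
    expect_true(all(diff(majority_prob(q, n)) >= -1e-12))
  }
  for (q in c(0.55, 0.7, 0.9)) {
    ns <- seq(1, 31, by = 2)
    vals <- vapply(ns, function(n) majority_prob(q, n), 0)
    expect_true(all(diff(vals) >= -1e-12))
  }
})

test_that("majority_prob_hetero matches exhaustive enumeration", {
  expect_equal(majority_prob_hetero(c(0.9, 0.6, 0.5)), 0.75)
  expect_equal(majority_prob_hetero(c(1, 0, 0)), 0)
  expect_equal(majority_prob_hetero(rep(0.7, 5)), majority_prob(0.7, 5),
               tolerance = 1e-12)
  expect_equal(majority_prob_hetero(rep(0.6, 4)), majority_prob(0.6, 4),
               tolerance = 1e-12)
  set.seed(8)
  for (rep in 1:10) {
    q <- runif(sample(1:6, 1))
    expect_equal(majority_prob_hetero(q), oracle_majority_hetero(q),
                 tolerance = 1e-12)
  }
  expect_error(majority_prob_hetero(numeric(0)), "non-empty")
})

test_that("collective_accuracy matches hand enumeration and n = 1 closed form", {
  env <- env_config(0.7, 0.8)
  expect_equal(collective_accuracy(0.5, 3, env), 0.80775)
  expect_equal(collective_accuracy(0.5, 1, env_config(0.6, 0.8)), 0.70)
  # exclusive high-cue use is flat in n at r_high
  for (n in c(1, 2, 7, 31, 100)) {
    expect_equal(collective_accuracy(0, n, env), 0.8)
    expect_equal(collective_accuracy(1, n, env), majority_prob(0.7, n))
  }
})

test_that("collective_accuracy agrees with brute-force simulation", {
  set.seed(9)
  for (cell in list(c(0.3, 3, 0.7, 0.8), c(0.8, 9, 0.6, 0.9),
                    c(0.5, 4, 0.9, 0.6))) {
    a <- collective_accuracy(cell[1], cell[2],
                             env_config(cell[3], cell[4]))
    mc <- oracle_mc_accuracy(cell[1], cell[2], cell[3], cell[4],
                             trials = 40000)
    expect_lt(abs(a - mc), 3 * sqrt(a * (1 - a) / 40000))
  }
})

test_that("heterogeneous accuracy reduces to the homogeneous case", {
  env <- env_config(0.7, 0.8)
  expect_equal(collective_accuracy_hetero(rep(0.37, 5), env),
               collective_accuracy(0.37, 5, env), tolerance = 1e-12)
  expect_equal(collective_accuracy_hetero(rep(0, 7), env), 0.8)
  # mixed profile against enumeration via the oracle kernels
  p <- c(1, 1, 0)
  q1 <- 1 - (1 - 0.7) * p
  q0 <- 0.7 * p
  expect_equal(collective_accuracy_hetero(p, env),
               0.8 * oracle_majority_hetero(q1) +
                 0.2 * oracle_majority_hetero(q0), tolerance = 1e-12)
  expect_error(collective_accuracy_hetero(numeric(0), env), "non-empty")
})

test_that("accuracy_landscape has the exact endpoint identities", {
  env <- env_config(0.7, 0.8)
  ls <- accuracy_landscape(5, env, resolution = 101)
  expect_equal(ls$accuracy[1], 0.8)
  expect_equal(ls$accuracy[101], majority_prob(0.7, 5))
  expect_true(all(ls$accuracy >= 0 & ls$accuracy <= 1))
  expect_true(all(diff(ls$p) > 0))
  # n = 1: the landscape is affine in p
  ls1 <- accuracy_landscape(1, env_config(0.6, 0.8), resolution = 101)
  expect_lt(max(abs(diff(diff(ls1$accuracy)))), 1e-10)
  # n = 5 mixed case: interior maximum beats both endpoints
  ls5 <- accuracy_landscape(5, env, resolution = 1001)
  expect_gt(max(ls5$accuracy), max(ls5$accuracy[1], ls5$accuracy[1001]))
})

test_that("optimal_policy finds boundary and interior optima", {
  # an isolated individual should follow the more reliable cue exclusively
  pol1 <- optimal_policy(1, env_config(0.6, 0.8))
  expect_equal(pol1$p_star, 0)
  expect_equal(pol1$a_star, 0.8)
  expect_identical(pol1$regime, "high_exclusive")
  # equally reliable cues: groups should use the low-correlation cue only
  pol3 <- optimal_policy(3, env_config(0.7, 0.7))
  expect_equal(pol3$p_star, 1)
  expect_identical(pol3$regime, "low_exclusive")
  # mixed regime, checked against the independent 1e-4 grid-search oracle
  pol5 <- optimal_policy(5, env_config(0.7, 0.8))
  oracle <- oracle_optimum(5, 0.7, 0.8)
  expect_identical(pol5$regime, "mixed")
  expect_lt(abs(pol5$p_star - oracle$p), 2e-4)
  expect_gte(pol5$a_star, oracle$value - 1e-9)
  expect_gt(pol5$a_star, max(collective_accuracy(c(0, 1), 5,
                                                 env_config(0.7, 0.8))))
})

test_that("interior optima satisfy the odd-n stationarity condition", {
  env <- env_config(0.7, 0.8)
  pol <- optimal_policy(5, env)
  q1 <- 1 - (1 - env$r_low) * pol$p_star
  q0 <- env$r_low * pol$p_star
  lhs <- env$r_high * (1 - env$r_low) * (q1 * (1 - q1))^2
  rhs <- (1 - env$r_high) * env$r_low * (q0 * (1 - q0))^2
  expect_lt(abs(lhs - rhs) / lhs, 1e-3)
})

test_that("optimizer is sound against a fine grid", {
  for (cell in list(c(5, 0.7, 0.8), c(11, 0.6, 0.9), c(7, 0.9, 0.6))) {
    env <- env_config(cell[2], cell[3])
    pol <- optimal_policy(cell[1], env)
    grid_max <- max(collective_accuracy(seq(0, 1, by = 1e-4), cell[1], env))
    expect_gte(pol$a_star, grid_max - 1e-9)
  }
})

test_that("bayes_upper_bound matches weighted-aggregation enumeration", {
  expect_equal(bayes_upper_bound(1, env_config(0.6, 0.8)), 0.8)
  expect_equal(bayes_upper_bound(2, env_config(0.6, 0.9)), 0.9)
  expect_equal(bayes_upper_bound(5, env_config(0.7, 0.8)), 0.88102,
               tolerance = 1e-5)
  expect_equal(bayes_upper_bound(4, env_config(1, 0.7)), 1)
  expect_equal(bayes_upper_bound(4, env_config(0.7, 1)), 1)
})

test_that("benchmark accuracies are ordered restricted <= global <= bayes", {
  # single voter: one signal pair, all three coincide
  b1 <- global_optimal_accuracy(1, env_config(0.6, 0.8))
  expect_equal(b1$restricted_accuracy, 0.8)
  expect_equal(b1$global_accuracy, 0.8, tolerance = 1e-9)
  expect_equal(b1$bayes_bound, 0.8)
  for (cell in list(c(5, 0.7, 0.8), c(9, 0.6, 0.9), c(7, 0.85, 0.6),
                    c(4, 0.7, 0.7))) {
    b <- global_optimal_accuracy(cell[1], env_config(cell[2], cell[3]))
    expect_lte(b$restricted_accuracy, b$global_accuracy + 1e-12)
    expect_lte(b$global_accuracy, b$bayes_bound + 1e-12)
  }
  b5 <- global_optimal_accuracy(5, env_config(0.7, 0.8))
  expect_gte(b5$global_accuracy, 0.8477)
  expect_lte(b5$global_accuracy, 0.88102 + 1e-5)
})

test_that("regret maps are zero on the diagonal and never positive", {
  env <- env_config(0.7, 0.8)
  ns <- c(1, 11, 21, 31)
  m <- regret_group_size_map(env, ns, ns)
  expect_equal(unname(diag(m)), rep(0, 4), tolerance = 1e-9)
  expect_true(all(m <= 1e-9))
  # a large change in group size costs more than a small one
  expect_gt(abs(m["1", "31"]), abs(m["21", "31"]))

  rl <- c(0.55, 0.7, 0.75, 0.95)
  mr <- regret_reliability_map(11, 0.8, rl, rl)
  expect_equal(unname(diag(mr)), rep(0, 4), tolerance = 1e-9)
  expect_true(all(mr <= 1e-9))
  expect_gt(abs(mr["0.95", "0.55"]), abs(mr["0.75", "0.7"]))
})
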