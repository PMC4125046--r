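# Core generative model: trial sampling, voting, consensus and learning.

test_that("configuration constructors validate their inputs", {
  expect_error(env_config(0.4, 0.8), "r_low")
  expect_error(env_config(0.7, 1.2), "r_high")
  expect_error(learning_config(alpha = 1.5), "alpha")
  expect_error(learning_config(v_init = 0.5), "v_init")
  expect_error(learning_config(n_trials = 100, window = 200), "window")
  expect_error(voting_rule("logistic", steepness = -1), "steepness")
  expect_error(consensus_rule("threshold"), "threshold_votes")
  expect_error(agent_state(-0.1, 0.2), "non-negative")
})

test_that("sample_trial draws signals at the configured reliabilities", {
  set.seed(1)
  # deterministic cues
  tr <- sample_trial(env_config(1, 1), n = 4)
  expect_identical(tr$high_signal, tr$superior)
  expect_identical(tr$low_signals, rep(tr$superior, 4))
  expect_length(tr$low_signals, 4)
  expect_true(all(c(tr$superior, tr$high_signal, tr$low_signals) %in%
                    c("A", "B")))
  # empirical frequencies against binomial standard errors
  env <- env_config(0.5, 0.8)
  n_draws <- 20000
  hits_high <- hits_low <- 0
  for (i in seq_len(n_draws / 4)) {
    tr <- sample_trial(env, n = 4)
    hits_high <- hits_high + (tr$high_signal == tr$superior)
    hits_low <- hits_low + sum(tr$low_signals == tr$superior)
  }
  se <- sqrt(0.5 * 0.5 / n_draws)
  expect_lt(abs(hits_low / n_draws - 0.5), 3 * se)
  se_h <- sqrt(0.8 * 0.2 / (n_draws / 4))
  expect_lt(abs(hits_high / (n_draws / 4) - 0.8), 3 * se_h)
})

test_that("p_from_strengths is the probability-matching ratio with a floor", {
  expect_equal(p_from_strengths(0.01, 0.01), 0.5)
  expect_equal(p_from_strengths(0.3, 0.1), 0.75)
  expect_equal(p_from_strengths(0, 0), 0.5) # degenerate post-decay state
  expect_equal(p_from_strengths(agent_state(0.2, 0.6)), 0.25)
  expect_equal(p_from_strengths(c(0.3, 0), c(0.1, 0)), c(0.75, 0.5))
  expect_error(p_from_strengths(-0.1, 0.2), "non-negative")
})

test_that("vote always follows agreeing cues and matches p under conflict", {
  set.seed(2)
  a <- agent_state(0.2, 0.7)
  expect_identical(vote(a, "A", "A"), "A")
  expect_identical(vote(a, "B", "B"), "B")
  # p = 1 limit: all strength on the low cue
  sure <- agent_state(1, 0)
  votes <- replicate(200, vote(sure, "B", "A"))
  expect_true(all(votes == "A"))
  # conflict frequency at p = 0.3
  a3 <- agent_state(0.3, 0.7)
  n_draws <- 10000
  f <- mean(replicate(n_draws, vote(a3, "B", "A")) == "A")
  expect_lt(abs(f - 0.3), 3 * sqrt(0.3 * 0.7 / n_draws))
})

test_that("majority_decide picks strict majorities and randomizes ties", {
  set.seed(3)
  expect_identical(majority_decide(5, 2), "A")
  expect_identical(majority_decide(0, 1), "B")
  n_draws <- 10000
  f <- mean(replicate(n_draws, majority_decide(3, 3)) == "A")
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / n_draws))
  expect_error(majority_decide(-1, 2), "non-negative")
})

test_that("threshold_decide implements super- and submajority semantics", {
  set.seed(4)
  expect_identical(threshold_decide(4, 1, m = 4), "A")
  expect_identical(threshold_decide(1, 4, m = 4), "B")
  # deadlock randomization when neither side reaches m
  f <- mean(replicate(5000, threshold_decide(3, 2, m = 4)) == "A")
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 5000))
  # m = 3 on n = 5 reproduces simple majority on every deterministic split
  for (va in 0:5) {
    if (va != 5 - va) {
      expect_identical(threshold_decide(va, 5 - va, m = 3),
                       majority_decide(va, 5 - va))
    }
  }
  # submajority: both sides qualify -> majority fallback
  expect_identical(threshold_decide(4, 2, m = 2), "A")
  expect_identical(threshold_decide(2, 4, m = 2), "B")
  # submajority: only one side qualifies
  expect_identical(threshold_decide(1, 5, m = 2), "B")
  expect_error(threshold_decide(3, 2, m = 6), "exceed")
})

test_that("logistic consensus evaluates the logistic vote-share rule", {
  set.seed(5)
  # closed-form check at moderate steepness, unanimous vote
  p_true <- stats::plogis(2 * 0.5)
  f <- mean(replicate(10000, logistic_consensus_decide(5, 5, s = 2)) == "A")
  expect_lt(abs(f - p_true), 3 * sqrt(p_true * (1 - p_true) / 10000))
  # split vote is exactly symmetric
  f5 <- mean(replicate(10000, logistic_consensus_decide(3, 6, s = 7)) == "A")
  expect_lt(abs(f5 - 0.5), 3 * sqrt(0.25 / 10000))
  # steep limit recovers majority rule
  f_steep <- mean(replicate(2000, logistic_consensus_decide(4, 5, s = 1e6)) ==
                    "A")
  expect_gte(f_steep, 0.999)
})

test_that("update_strengths applies the gated compound prediction error", {
  # single indicated cue with the other strength at zero: textbook form
  a <- update_strengths(agent_state(0.5, 0), "B", "A", chosen = "A",
                        outcome = 1, alpha = 0.1)
  expect_equal(a$v_low, 0.55)
  expect_equal(a$v_high, 0)
  # cue that did not indicate the chosen option is unchanged
  a2 <- update_strengths(agent_state(0.5, 0.4), "B", "A", chosen = "A",
                         outcome = 1, alpha = 0.1)
  expect_equal(a2$v_high, 0.4)
  expect_equal(a2$v_low, 0.5 + 0.1 * (1 - 0.9))
  # fixed point: strength equal to the outcome, no competing strength
  a3 <- update_strengths(agent_state(0, 1), "A", "B", chosen = "A",
                         outcome = 1, alpha = 0.1)
  expect_equal(a3$v_high, 1)
  # both cues update with the shared error when they agreed and were chosen
  a4 <- update_strengths(agent_state(0.3, 0.5), "A", "A", chosen = "A",
                         outcome = 1, alpha = 0.1)
  expect_equal(a4$v_low, 0.3 + 0.1 * (1 - 0.8))
  expect_equal(a4$v_high, 0.5 + 0.1 * (1 - 0.8))
  expect_error(update_strengths(agent_state(0.3, 0.5), "A", "A", "A",
                                outcome = 2, alpha = 0.1), "outcome")
})

test_that("repeated reinforcement follows the geometric recursion", {
  # t consecutive rewarded updates of a lone cue approach 1 geometrically
  alpha <- 0.1
  v0 <- 0.01
  a <- agent_state(v0, 0)
  for (t in 1:25) {
    a <- update_strengths(a, "B", "A", chosen = "A", outcome = 1,
                          alpha = alpha)
    expect_equal(a$v_low, 1 - (1 - alpha)^t * (1 - v0))
    expect_equal(a$v_low, oracle_iterate_update(v0, 0, 1, alpha, t))
  }
})

test_that("associative strengths stay in [0, 1] for any update sequence", {
  set.seed(6)
  for (rep in 1:20) {
    a <- agent_state(runif(1), runif(1))
    for (t in 1:50) {
      sig_h <- sample(c("A", "B"), 1)
      sig_l <- sample(c("A", "B"), 1)
      chosen <- sample(c("A", "B"), 1)
      a <- update_strengths(a, sig_h, sig_l, chosen,
                            outcome = sample(0:1, 1), alpha = runif(1, 0.01, 1))
      expect_true(a$v_low >= 0 && a$v_low <= 1)
      expect_true(a$v_high >= 0 && a$v_high <= 1)
    }
  }
})

test_that("relabeling the options leaves decision probabilities unchanged", {
  set.seed(7)
  # consensus rules: swap the vote counts, expect the mirrored frequency
  f_a <- mean(replicate(5000, threshold_decide(3, 2, m = 4)) == "A")
  f_b <- mean(replicate(5000, threshold_decide(2, 3, m = 4)) == "B")
  expect_lt(abs(f_a - f_b), 3 * sqrt(2 * 0.25 / 5000))
  # voting: swapping both signals mirrors the vote under conflict
  a <- agent_state(0.3, 0.7)
  f_low_a <- mean(replicate(5000, vote(a, "B", "A")) == "A")
  f_low_b <- mean(replicate(5000, vote(a, "A", "B")) == "B")
  expect_lt(abs(f_low_a - f_low_b), 3 * sqrt(2 * 0.3 * 0.7 / 5000))
})

test_that("steep logistic voting converges to the strength argmax", {
  steep <- voting_rule("logistic", steepness = 1e6)
  stronger_low <- agent_state(0.6, 0.4)
  votes <- replicate(300, vote(stronger_low, "B", "A", steep))
  expect_true(all(votes == "A"))
  stronger_high <- agent_state(0.4, 0.6)
  votes2 <- replicate(300, vote(stronger_high, "B", "A", steep))
  expect_true(all(votes2 == "B"))
})
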