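# Exact (simulation-free) analytics: Condorcet majority probabilities, the
# collective-accuracy landscape, the optimal conflict behavior p*, threshold
# benchmarks and the full-information Bayes bound.

#' Probability that a majority vote is correct
#'
#' The Condorcet kernel: `n` independent voters are each correct with
#' probability `q`; the group is correct if more than half the votes are
#' correct, with ties (even `n`) resolved at random (weight 1/2). Computed
#' from the binomial tail, vectorized over `q`.
#'
#' @param q Per-voter probability of voting correctly, in `[0, 1]`.
#' @param n Group size, `>= 1`.
#' @return Probability (vectorized over `q`) that the majority is correct.
#' @examples
#' majority_prob(0.7, 3) # 0.784
#' @export
majority_prob <- function(q, n) {
  if (any(q < 0) || any(q > 1)) stop("`q` must be in [0, 1]", call. = FALSE)
  check_count(n, "n")
  if (n %% 2 == 1) {
    stats::pbinom((n - 1) / 2, n, q, lower.tail = FALSE)
  } else {
    stats::pbinom(n / 2, n, q, lower.tail = FALSE) +
      0.5 * stats::dbinom(n / 2, n, q)
  }
}

#' Majority probability for heterogeneous voters
#'
#' Exact Poisson-binomial probability that a strict majority of voters are
#' correct, plus half the tie probability, when voter `i` is correct with
#' probability `q[i]`. The vote-count distribution is built by an O(n^2)
#' dynamic program.
#'
#' @param q Vector of per-voter probabilities, each in `[0, 1]`.
#' @return Probability that the majority vote is correct.
#' @examples
#' majority_prob_hetero(c(0.9, 0.6, 0.5)) # 0.75
#' @export
majority_prob_hetero <- function(q) {
  if (length(q) == 0) stop("`q` must be non-empty", call. = FALSE)
  if (any(q < 0) || any(q > 1)) stop("`q` must be in [0, 1]", call. = FALSE)
  n <- length(q)
  # pmf[k+1] = P(k correct votes among the first i voters)
  pmf <- c(1, numeric(n))
  for (i in seq_len(n)) {
    pmf <- c(pmf[seq_len(i)] * (1 - q[i]), 0) +
      c(0, pmf[seq_len(i)] * q[i])
    pmf <- c(pmf, numeric(n + 1 - length(pmf)))
  }
  k <- 0:n
  correct <- sum(pmf[2 * k > n])
  if (n %% 2 == 0) correct <- correct + 0.5 * pmf[k == n / 2]
  correct
}

# per-voter correctness probabilities conditional on the shared signal being
# correct (q1) or wrong (q0), for conflict-following probability p
voter_competence <- function(p, env) {
  list(q1 = 1 - (1 - env$r_low) * p, q0 = env$r_low * p)
}

#' Collective accuracy of a voting behavior
#'
#' Exact probability that a group of `n` individuals, each following the
#' low-correlation cue with probability `p` under cue conflict (and always
#' following agreeing cues), selects the superior option under simple
#' majority rule with random tie-break. Obtained by conditioning on whether
#' the shared high-correlation signal is correct: voters are then
#' conditionally independent with competence `q1 = 1 - (1 - r_low) * p` (shared
#' signal correct) or `q0 = r_low * p` (shared signal wrong), so
#' `A(p) = r_high * majority_prob(q1, n) + (1 - r_high) * majority_prob(q0, n)`.
#'
#' @param p Probability of following the low-correlation cue under conflict
#'   (vectorized).
#' @param n Group size.
#' @param env An [env_config()].
#' @return Collective accuracy (vectorized over `p`).
#' @examples
#' collective_accuracy(0.5, 3, env_config(0.7, 0.8)) # 0.80775
#' @export
collective_accuracy <- function(p, n, env) {
  stopifnot(inherits(env, "env_config"))
  if (any(p < 0) || any(p > 1)) stop("`p` must be in [0, 1]", call. = FALSE)
  q <- voter_competence(p, env)
  env$r_high * majority_prob(q$q1, n) +
    (1 - env$r_high) * majority_prob(q$q0, n)
}

#' Collective accuracy for heterogeneous voting behavior
#'
#' As [collective_accuracy()], but individual `i` follows the low-correlation
#' cue with its own probability `p[i]` — the situation of a group pooling
#' behaviors learned in isolation.
#'
#' @param p Vector of conflict-following probabilities, one per individual.
#' @param env An [env_config()].
#' @return Collective accuracy of the pooled group.
#' @export
collective_accuracy_hetero <- function(p, env) {
  stopifnot(inherits(env, "env_config"))
  if (length(p) == 0) stop("`p` must be non-empty", call. = FALSE)
  if (any(p < 0) || any(p > 1)) stop("`p` must be in [0, 1]", call. = FALSE)
  q <- voter_competence(p, env)
  env$r_high * majority_prob_hetero(q$q1) +
    (1 - env$r_high) * majority_prob_hetero(q$q0)
}

#' Accuracy landscape over voting behaviors
#'
#' Evaluates [collective_accuracy()] on a uniform grid of `p` values including
#' both endpoints.
#'
#' @param n Group size.
#' @param env An [env_config()].
#' @param resolution Number of grid points (`>= 10`).
#' @return A data frame of class `accuracy_landscape` with columns `p` and
#'   `accuracy`.
#' @export
accuracy_landscape <- function(n, env, resolution = 1001) {
  check_count(resolution, "resolution", min = 10)
  p <- seq(0, 1, length.out = resolution)
  out <- data.frame(p = p, accuracy = collective_accuracy(p, n, env))
  class(out) <- c("accuracy_landscape", "data.frame")
  out
}

# maximize a scalar function of p over [0,1]: coarse grid (step `step`) then
# local refinement with optimize() to ~1e-7
maximize_over_p <- function(f, step = 1e-3) {
  grid <- seq(0, 1, by = step)
  vals <- f(grid)
  i <- which.max(vals)
  lo <- max(0, grid[i] - step)
  hi <- min(1, grid[i] + step)
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
  if (opt$objective >= vals[i]) {
    list(p = opt$maximum, value = opt$objective)
  } else {
    list(p = grid[i], value = vals[i])
  }
}

#' Optimal voting behavior
#'
#' Finds the conflict-following probability `p*` that maximizes
#' [collective_accuracy()] for a given group size and environment, by a coarse
#' grid search (step 1e-3) refined locally to `|dp| <= 1e-6`. The result is
#' labelled by regime: `low_exclusive` (`p* = 1`, rely only on the
#' low-correlation cue), `high_exclusive` (`p* = 0`) or `mixed` (interior
#' probabilistic strategy).
#'
#' @param n Group size.
#' @param env An [env_config()].
#' @param tol Boundary tolerance used for the regime label, in `(0, 1e-3]`.
#' @return A list of class `policy_result` with elements `p_star`, `a_star`
#'   and `regime`.
#' @examples
#' optimal_policy(5, env_config(0.7, 0.8))
#' @export
optimal_policy <- function(n, env, tol = 1e-6) {
  stopifnot(inherits(env, "env_config"))
  check_count(n, "n")
  if (!is.numeric(tol) || tol <= 0 || tol > 1e-3) {
    stop("`tol` must be in (0, 1e-3]", call. = FALSE)
  }
  opt <- maximize_over_p(function(p) collective_accuracy(p, n, env))
  p_star <- opt$p
  # snap to a boundary when it is at least as good: the landscape can be
  # extremely flat near p = 0/1 and the labels should then be exclusive
  for (b in c(0, 1)) {
    if (abs(p_star - b) <= 1e-3 &&
        collective_accuracy(b, n, env) >= opt$value - 1e-12) {
      p_star <- b
      opt$value <- collective_accuracy(b, n, env)
    }
  }
  regime <- if (p_star >= 1 - tol) "low_exclusive"
            else if (p_star <= tol) "high_exclusive"
            else "mixed"
  structure(list(p_star = p_star, a_star = opt$value, regime = regime,
                 n = n, env = env),
            class = "policy_result")
}

#' @export
print.policy_result <- function(x, ...) {
  cat(sprintf("<policy_result> n = %d, r_low = %g, r_high = %g\n",
              x$n, x$env$r_low, x$env$r_high))
  cat(sprintf("  p* = %.6f  accuracy = %.6f  regime = %s\n",
              x$p_star, x$a_star, x$regime))
  invisible(x)
}

# exact accuracy of the supermajority threshold rule: the group is correct
# when at least m of n votes back the superior option; deadlocks (neither
# option reaches m) are resolved at random
threshold_accuracy_q <- function(q, n, m) {
  correct <- stats::pbinom(m - 1, n, q, lower.tail = FALSE)
  deadlock <- stats::pbinom(m - 1, n, q) - stats::pbinom(n - m, n, q)
  correct + 0.5 * deadlock
}

#' Exact accuracy of a supermajority threshold rule
#'
#' Collective accuracy when the group adopts an option only if it gathers at
#' least `m` votes (with `m > n/2`), random deadlock resolution, and every
#' individual follows the low-correlation cue with probability `p` under
#' conflict.
#'
#' @param p Conflict-following probability (vectorized).
#' @param n Group size.
#' @param env An [env_config()].
#' @param m Supermajority threshold, `ceiling((n + 1) / 2) <= m <= n`.
#' @return Collective accuracy (vectorized over `p`).
#' @export
threshold_accuracy <- function(p, n, env, m) {
  stopifnot(inherits(env, "env_config"))
  check_count(n, "n")
  check_count(m, "m")
  if (m < ceiling((n + 1) / 2) || m > n) {
    stop("`m` must be a supermajority threshold in [ceiling((n+1)/2), n]",
         call. = FALSE)
  }
  if (any(p < 0) || any(p > 1)) stop("`p` must be in [0, 1]", call. = FALSE)
  q <- voter_competence(p, env)
  env$r_high * threshold_accuracy_q(q$q1, n, m) +
    (1 - env$r_high) * threshold_accuracy_q(q$q0, n, m)
}

#' Full-information Bayes accuracy bound
#'
#' Accuracy of the optimal weighted aggregation (Nitzan-Paroush) of all raw
#' signals: each low-correlation signal carries log-odds weight
#' `log(r_low / (1 - r_low))` and the shared high-correlation signal
#' `log(r_high / (1 - r_high))`; the option with the larger total weight is
#' chosen (exact ties split 1/2). No voting rule can exceed this bound. A
#' reliability of exactly 1 is handled in the limit: that signal dictates the
#' decision and the bound is 1.
#'
#' @param n Group size.
#' @param env An [env_config()].
#' @return Probability the full-information rule picks the superior option.
#' @examples
#' bayes_upper_bound(5, env_config(0.7, 0.8)) # 0.88102
#' @export
bayes_upper_bound <- function(n, env) {
  stopifnot(inherits(env, "env_config"))
  check_count(n, "n")
  if (env$r_low == 1 || env$r_high == 1) return(1)
  w_l <- log(env$r_low / (1 - env$r_low))
  w_h <- log(env$r_high / (1 - env$r_high))
  k <- 0:n # number of correct low-correlation signals
  step_fun <- function(x) ifelse(x > 0, 1, ifelse(x == 0, 0.5, 0))
  sum(stats::dbinom(k, n, env$r_low) *
        (env$r_high * step_fun((2 * k - n) * w_l + w_h) +
           (1 - env$r_high) * step_fun((2 * k - n) * w_l - w_h)))
}

#' Benchmark the restricted rule against the globally optimal rule
#'
#' Compares three exact accuracies: `restricted_accuracy`, the best achievable
#' under simple majority by optimizing the individual behavior `p`;
#' `global_accuracy`, the best over both `p` and an integer supermajority
#' threshold `m` (random deadlock resolution); and `bayes_bound`, the
#' full-information upper bound. The ordering
#' `restricted <= global <= bayes` always holds because the threshold family
#' contains simple majority and no aggregation rule beats the Bayes rule.
#'
#' @param n Group size.
#' @param env An [env_config()].
#' @return A list of class `benchmark_result` with elements
#'   `restricted_accuracy`, `global_accuracy`, `bayes_bound`, `best_m` and
#'   `best_p` (the maximizers of the global family).
#' @export
global_optimal_accuracy <- function(n, env) {
  stopifnot(inherits(env, "env_config"))
  check_count(n, "n")
  restricted <- optimal_policy(n, env)
  best <- list(value = -Inf, m = NA_integer_, p = NA_real_)
  for (m in seq(ceiling((n + 1) / 2), n)) {
    opt <- maximize_over_p(function(p) threshold_accuracy(p, n, env, m))
    if (opt$value > best$value) {
      best <- list(value = opt$value, m = m, p = opt$p)
    }
  }
  structure(list(restricted_accuracy = restricted$a_star,
                 global_accuracy = best$value,
                 bayes_bound = bayes_upper_bound(n, env),
                 best_m = best$m, best_p = best$p,
                 n = n, env = env),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> n = %d, r_low = %g, r_high = %g\n",
              x$n, x$env$r_low, x$env$r_high))
  cat(sprintf("  simple majority + optimal p : %.6f\n", x$restricted_accuracy))
  cat(sprintf("  best (p, threshold m = %d)  : %.6f\n",
              x$best_m, x$global_accuracy))
  cat(sprintf("  full-information Bayes bound: %.6f\n", x$bayes_bound))
  invisible(x)
}

#' Regret of keeping a stale behavior after a group-size change
#'
#' Entry `(i, j)` is the accuracy of using the behavior optimal for group size
#' `n_start[i]` in a group of size `n_end[j]`, minus the accuracy of the
#' behavior optimal for `n_end[j]` itself. All entries are `<= 0`; the
#' diagonal of a square map with `n_start == n_end` is 0.
#'
#' @param env An [env_config()].
#' @param n_start,n_end Vectors of group sizes.
#' @return A matrix of accuracy differences with `n_start` rows and `n_end`
#'   columns (dimnames give the sizes).
#' @export
regret_group_size_map <- function(env, n_start, n_end) {
  stopifnot(inherits(env, "env_config"))
  p_start <- vapply(n_start, function(n) optimal_policy(n, env)$p_star, 0)
  opt_end <- vapply(n_end, function(n) optimal_policy(n, env)$a_star, 0)
  out <- matrix(NA_real_, length(n_start), length(n_end),
                dimnames = list(n_start = n_start, n_end = n_end))
  for (j in seq_along(n_end)) {
    out[, j] <- vapply(p_start, function(p)
      collective_accuracy(p, n_end[j], env), 0) - opt_end[j]
  }
  out
}

#' Regret of keeping a stale behavior after a reliability change
#'
#' Entry `(i, j)` is the accuracy of using the behavior optimal for
#' low-correlation reliability `r_low_start[i]` in an environment whose
#' low-correlation reliability is `r_low_end[j]` (the high-correlation
#' reliability `r_high` held fixed), minus the accuracy of the behavior
#' optimal for `r_low_end[j]`. All entries are `<= 0`.
#'
#' @param n Group size.
#' @param r_high Fixed reliability of the high-correlation cue.
#' @param r_low_start,r_low_end Vectors of low-correlation reliabilities.
#' @return A matrix of accuracy differences.
#' @export
regret_reliability_map <- function(n, r_high, r_low_start, r_low_end) {
  p_start <- vapply(r_low_start, function(r)
    optimal_policy(n, env_config(r, r_high))$p_star, 0)
  out <- matrix(NA_real_, length(r_low_start), length(r_low_end),
                dimnames = list(r_low_start = r_low_start,
                                r_low_end = r_low_end))
  for (j in seq_along(r_low_end)) {
    env_end <- env_config(r_low_end[j], r_high)
    opt_end <- optimal_policy(n, env_end)$a_star
    out[, j] <- vapply(p_start, function(p)
      collective_accuracy(p, n, env_end), 0) - opt_end
  }
  out
}

#' Restricted-to-global accuracy ratio across a parameter grid
#'
#' For every combination of group size and cue reliabilities, computes the
#' percentage of the globally optimal (joint `p` and supermajority threshold)
#' accuracy that simple majority rule achieves with individually optimized
#' `p`. The default grid spans odd group sizes 1-31 and both reliabilities
#' over 0.55-0.95 in steps of 0.05.
#'
#' @param group_sizes Vector of group sizes.
#' @param r_low_values,r_high_values Vectors of cue reliabilities.
#' @return A data frame with one row per grid cell and columns `n`, `r_low`,
#'   `r_high`, `restricted_accuracy`, `global_accuracy`, `bayes_bound` and
#'   `pct_of_global`.
#' @export
global_rule_comparison <- function(group_sizes = seq(1, 31, by = 2),
                                   r_low_values = seq(0.55, 0.95, by = 0.05),
                                   r_high_values = seq(0.55, 0.95, by = 0.05)) {
  cells <- expand.grid(n = group_sizes, r_low = r_low_values,
                       r_high = r_high_values, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    bench <- global_optimal_accuracy(cells$n[i],
                                     env_config(cells$r_low[i],
                                                cells$r_high[i]))
    data.frame(restricted_accuracy = bench$restricted_accuracy,
               global_accuracy = bench$global_accuracy,
               bayes_bound = bench$bayes_bound)
  })
  out <- cbind(cells, do.call(rbind, res))
  out$pct_of_global <- 100 * out$restricted_accuracy / out$global_accuracy
  out
}
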