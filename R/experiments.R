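# Simulation protocols: environment x group-size sweeps, isolated-learning
# versus collective-learning comparison, and dynamic context transitions.

#' Sweep collective learning over environments and group sizes
#'
#' Runs one training experiment per combination of group size and cue
#' reliabilities, summarizes the learned behavior over the final window, and
#' joins the exact optimum for each cell. `fraction_of_max` is the achieved
#' collective accuracy (the exact accuracy of the learned mean behavior) as a
#' fraction of the maximum attainable accuracy for that cell.
#'
#' @param group_sizes Vector of group sizes.
#' @param r_low_values,r_high_values Vectors of cue reliabilities.
#' @param learning A [learning_config()].
#' @param voting A [voting_rule()].
#' @param consensus A [consensus_rule()].
#' @param seed Optional integer seed for the whole sweep.
#' @return A data frame with one row per cell: `n`, `r_low`, `r_high`,
#'   `learned_p`, `achieved_accuracy`, `optimal_p`, `optimal_accuracy`,
#'   `fraction_of_max`.
#' @export
sweep_grid <- function(group_sizes, r_low_values, r_high_values,
                       learning = learning_config(),
                       voting = voting_rule("linear"),
                       consensus = consensus_rule("majority"),
                       seed = NULL) {
  if (!length(group_sizes) || !length(r_low_values) || !length(r_high_values)) {
    stop("grids must be non-empty", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(n = group_sizes, r_low = r_low_values,
                       r_high = r_high_values, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    env <- env_config(cells$r_low[i], cells$r_high[i])
    traj <- run_training(env, cells$n[i], learning, voting, consensus)
    s <- summarize_learned(traj)
    opt <- optimal_policy(cells$n[i], env)
    data.frame(n = cells$n[i], r_low = cells$r_low[i],
               r_high = cells$r_high[i],
               learned_p = s$learned_p,
               achieved_accuracy = s$achieved_accuracy,
               optimal_p = opt$p_star,
               optimal_accuracy = opt$a_star,
               fraction_of_max = s$achieved_accuracy / opt$a_star)
  })
  do.call(rbind, rows)
}

#' Compare isolated-then-pooled learning with collective learning
#'
#' Trains agents in isolation (group size 1), freezes their learned conflict
#' behaviors, and pools `n` of them into a group whose exact majority-vote
#' accuracy is computed with [collective_accuracy_hetero()]. This is compared
#' with agents that learned collectively at group size `n` (evaluated the same
#' exact way on their final per-agent behaviors) and with the optimal
#' accuracy. Isolated learners never experience the shared outcome of a group
#' decision, so they underweight the low-correlation cue relative to what the
#' group needs.
#'
#' @param env An [env_config()].
#' @param n Group size of the pooled group, `>= 1`.
#' @param learning A [learning_config()]; `n_reps` sets the number of
#'   independent pools (and of collective replicates).
#' @param seed Optional integer seed.
#' @return A list of class `pooling_comparison` with `pooled_accuracy`,
#'   `collective_accuracy`, `optimal_accuracy`, the mean learned behaviors
#'   `isolated_mean_p` / `collective_mean_p`, and the two fractions of max.
#' @export
run_isolated_then_pooled <- function(env, n, learning = learning_config(),
                                     seed = NULL) {
  stopifnot(inherits(env, "env_config"), inherits(learning, "learning_config"))
  check_count(n, "n")
  if (!is.null(seed)) set.seed(seed)
  n_pools <- learning$n_reps
  # train n_pools x n isolated agents in one vectorized run at group size 1
  iso_cfg <- learning_config(alpha = learning$alpha, v_init = learning$v_init,
                             n_trials = learning$n_trials,
                             n_reps = n_pools * n, window = learning$window)
  iso <- run_training(env, 1, iso_cfg)
  p_iso <- p_from_strengths(iso$final_v_low[, 1], iso$final_v_high[, 1])
  pools <- matrix(p_iso, nrow = n_pools) # each row: one pooled group of n
  pooled_acc <- mean(apply(pools, 1, collective_accuracy_hetero, env = env))
  col_cfg <- learning_config(alpha = learning$alpha, v_init = learning$v_init,
                             n_trials = learning$n_trials,
                             n_reps = n_pools, window = learning$window)
  col <- run_training(env, n, col_cfg)
  p_col <- p_from_strengths(col$final_v_low, col$final_v_high)
  collective_acc <- mean(vapply(seq_len(n_pools), function(r)
    collective_accuracy_hetero(p_col[r, ], env), 0))
  opt <- optimal_policy(n, env)
  structure(list(pooled_accuracy = pooled_acc,
                 collective_accuracy = collective_acc,
                 optimal_accuracy = opt$a_star,
                 isolated_mean_p = mean(p_iso),
                 collective_mean_p = mean(p_col),
                 pooled_fraction_of_max = pooled_acc / opt$a_star,
                 collective_fraction_of_max = collective_acc / opt$a_star,
                 n = n, env = env),
            class = "pooling_comparison")
}

#' @export
print.pooling_comparison <- function(x, ...) {
  cat(sprintf("<pooling_comparison> n = %d, r_low = %g, r_high = %g\n",
              x$n, x$env$r_low, x$env$r_high))
  cat(sprintf("  pooled isolated learners : %.4f (%.1f%% of max)\n",
              x$pooled_accuracy, 100 * x$pooled_fraction_of_max))
  cat(sprintf("  collective learners      : %.4f (%.1f%% of max)\n",
              x$collective_accuracy, 100 * x$collective_fraction_of_max))
  cat(sprintf("  optimal                  : %.4f\n", x$optimal_accuracy))
  invisible(x)
}

#' Specify a mid-run context change
#'
#' Describes an abrupt change, after `change_trial` trials, in either group
#' size (`n_before` to `n_after`, reliabilities fixed) or in the reliability
#' of the low-correlation cue (`r_low_before` to `r_low_after`, `r_high` and
#' group size fixed).
#'
#' @param change_trial Trial index after which the context changes; must be
#'   strictly inside the run.
#' @param n_before,n_after Group sizes for a group-size transition.
#' @param r_low_before,r_low_after Reliabilities for a reliability transition.
#' @return An object of class `transition_spec`.
#' @export
transition_spec <- function(change_trial, n_before = NULL, n_after = NULL,
                            r_low_before = NULL, r_low_after = NULL) {
  check_count(change_trial, "change_trial")
  size_change <- !is.null(n_before) && !is.null(n_after)
  rel_change <- !is.null(r_low_before) && !is.null(r_low_after)
  if (size_change == rel_change) {
    stop(paste("specify either `n_before`/`n_after` or",
               "`r_low_before`/`r_low_after`"), call. = FALSE)
  }
  if (size_change) {
    check_count(n_before, "n_before")
    check_count(n_after, "n_after")
  } else {
    check_probability(r_low_before, "r_low_before", lower = 0.5)
    check_probability(r_low_after, "r_low_after", lower = 0.5)
  }
  structure(list(change_trial = change_trial,
                 type = if (size_change) "group_size" else "reliability",
                 n_before = n_before, n_after = n_after,
                 r_low_before = r_low_before, r_low_after = r_low_after),
            class = "transition_spec")
}

#' Train through an abrupt context change
#'
#' Phase 1 trains as usual up to `change_trial`; the context then switches and
#' learning continues for the remaining trials. For a group-size increase,
#' each phase-2 group of `n_after` agents is assembled by pooling agents from
#' `ceiling(n_after / n_before)` independently trained phase-1 groups (keeping
#' a uniformly sampled subset of `n_after` of them); for a decrease, a
#' uniformly sampled subset of `n_after` agents is kept. For a reliability
#' transition the same agents continue under the new `r_low`.
#'
#' @param env An [env_config()]. For a reliability transition only its
#'   `r_high` is used; the phase-1 and phase-2 `r_low` come from the
#'   transition specification.
#' @param spec A [transition_spec()].
#' @param n Group size for a reliability transition (ignored for group-size
#'   transitions, which carry their own sizes).
#' @param learning A [learning_config()]; `n_trials` is the total length of
#'   both phases and must exceed `change_trial`.
#' @param voting A [voting_rule()].
#' @param consensus A [consensus_rule()].
#' @param seed Optional integer seed.
#' @return A `trajectory` spanning both phases (`mean_p` and `success` have
#'   length `n_trials`), with extra fields `change_trial`, `env_after`, `n`
#'   (the phase-2 group size) and `optimal_accuracy_after`, the exact optimum
#'   of the new context against which phase-2 success should be judged.
#' @export
run_transition <- function(env, spec, n = NULL, learning = learning_config(),
                           voting = voting_rule("linear"),
                           consensus = consensus_rule("majority"),
                           seed = NULL) {
  stopifnot(inherits(env, "env_config"), inherits(spec, "transition_spec"),
            inherits(learning, "learning_config"))
  if (spec$change_trial >= learning$n_trials) {
    stop("`change_trial` must be strictly less than `n_trials`", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  reps <- learning$n_reps
  trials2 <- learning$n_trials - spec$change_trial

  if (spec$type == "group_size") {
    n1 <- spec$n_before
    n2 <- spec$n_after
    k <- ceiling(n2 / n1) # phase-1 groups pooled per phase-2 group
    v0 <- matrix(learning$v_init, reps * k, n1)
    ph1 <- train_core(v0, v0, n1, env, spec$change_trial, learning$alpha,
                      voting, consensus)
    # reshaping pools, for replicate r, the k independent phase-1 groups in
    # rows r, r + reps, ..., r + (k-1) * reps; then a uniform subset of n2
    # pooled agents is kept
    pool_low <- matrix(ph1$v_low, reps, k * n1)
    pool_high <- matrix(ph1$v_high, reps, k * n1)
    keep <- sample(k * n1, n2)
    v_low <- pool_low[, keep, drop = FALSE]
    v_high <- pool_high[, keep, drop = FALSE]
    env1 <- env2 <- env
  } else {
    if (is.null(n)) {
      stop("`n` is required for a reliability transition", call. = FALSE)
    }
    check_count(n, "n")
    n1 <- n2 <- n
    env1 <- env_config(spec$r_low_before, env$r_high)
    env2 <- env_config(spec$r_low_after, env$r_high)
    v0 <- matrix(learning$v_init, reps, n1)
    ph1 <- train_core(v0, v0, n1, env1, spec$change_trial, learning$alpha,
                      voting, consensus)
    v_low <- ph1$v_low
    v_high <- ph1$v_high
  }

  ph2 <- train_core(v_low, v_high, n2, env2, trials2, learning$alpha,
                    voting, consensus)
  traj <- new_trajectory(ph2, env1, n2, learning,
                         list(seed = seed, change_trial = spec$change_trial,
                              env_after = env2,
                              optimal_accuracy_after =
                                optimal_policy(n2, env2)$a_star))
  traj$mean_p <- c(ph1$mean_p, ph2$mean_p)
  traj$success <- c(ph1$success, ph2$success)
  traj
}
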