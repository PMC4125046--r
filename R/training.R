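# Vectorized training engine: all replicate groups advance through the trial
# loop together, with agents' associative strengths held as reps x n matrices.
# Options are encoded 0 = A, 1 = B internally.

# one consensus decision per replicate from the counts of votes for option 1
consensus_core <- function(votes1, n, rule) {
  reps <- length(votes1)
  switch(rule$kind,
    majority = {
      chosen <- ifelse(2 * votes1 > n, 1L, 0L)
      tie <- 2 * votes1 == n
      if (any(tie)) chosen[tie] <- stats::rbinom(sum(tie), 1, 0.5)
      chosen
    },
    threshold = {
      m <- rule$threshold_votes
      votes0 <- n - votes1
      if (m > n / 2) {
        chosen <- rep(NA_integer_, reps)
        chosen[votes1 >= m] <- 1L
        chosen[votes0 >= m] <- 0L
        dead <- is.na(chosen)
        if (any(dead)) chosen[dead] <- stats::rbinom(sum(dead), 1, 0.5)
        chosen
      } else {
        reach1 <- votes1 >= m
        reach0 <- votes0 >= m
        chosen <- rep(NA_integer_, reps)
        chosen[reach1 & !reach0] <- 1L
        chosen[reach0 & !reach1] <- 0L
        both <- reach1 & reach0
        if (any(both)) {
          maj <- ifelse(2 * votes1[both] > n, 1L, 0L)
          tie <- 2 * votes1[both] == n
          if (any(tie)) maj[tie] <- stats::rbinom(sum(tie), 1, 0.5)
          chosen[both] <- maj
        }
        dead <- is.na(chosen)
        if (any(dead)) chosen[dead] <- stats::rbinom(sum(dead), 1, 0.5)
        chosen
      }
    },
    logistic = {
      # probability of picking option 1 rises logistically in its vote share
      stats::rbinom(reps, 1, stats::plogis(rule$steepness * (votes1 / n - 0.5)))
    },
    stop("unknown consensus rule", call. = FALSE))
}

# advance `n_trials` trials from the given strength matrices (reps x n);
# returns updated strengths plus per-trial mean behavior and success rate
train_core <- function(v_low, v_high, n, env, n_trials, alpha, voting,
                       consensus) {
  reps <- nrow(v_low)
  mean_p <- numeric(n_trials)
  success <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    superior <- stats::rbinom(reps, 1, 0.5)
    high <- ifelse(stats::runif(reps) < env$r_high, superior, 1L - superior)
    low_correct <- matrix(stats::runif(reps * n) < env$r_low, reps, n)
    low <- ifelse(low_correct, superior, 1L - superior)
    p <- follow_low_prob(v_low, v_high, voting)
    agree <- low == high
    take_low <- matrix(stats::runif(reps * n), reps, n) < p
    votes <- ifelse(agree | take_low, low, high)
    chosen <- consensus_core(rowSums(votes), n, consensus)
    outcome <- as.numeric(chosen == superior)
    upd_low <- low == chosen
    upd_high <- high == chosen
    error <- outcome - (v_low + v_high)
    v_low <- clamp01(v_low + alpha * error * upd_low)
    v_high <- clamp01(v_high + alpha * error * upd_high)
    mean_p[t] <- mean(p)
    success[t] <- mean(outcome)
  }
  list(v_low = v_low, v_high = v_high, mean_p = mean_p, success = success)
}

new_trajectory <- function(core, env, n, learning, extra = list()) {
  structure(c(list(mean_p = core$mean_p, success = core$success,
                   final_v_low = core$v_low, final_v_high = core$v_high,
                   env = env, n = n, learning = learning), extra),
            class = "trajectory")
}

#' Run a collective-learning training experiment
#'
#' Simulates `n_reps` independent replicate groups of `n` agents for
#' `n_trials` decision trials. Each trial: sample the superior option and the
#' cue signals, each agent votes, the consensus rule picks an option, and
#' every agent updates the associative strength of each cue whose signal
#' indicated the chosen option toward the shared binary outcome (1 if the
#' chosen option was superior). All agents start with identical very small
#' strengths, so the initial conflict behavior is p = 0.5.
#'
#' @param env An [env_config()].
#' @param n Group size.
#' @param learning A [learning_config()].
#' @param voting A [voting_rule()].
#' @param consensus A [consensus_rule()].
#' @param seed Optional integer seed; identical seeds reproduce the trajectory
#'   bit-for-bit.
#' @return An object of class `trajectory`: per-trial `mean_p` (mean over
#'   agents and replicates of the conflict-following probability) and
#'   `success` (fraction of replicate groups choosing the superior option),
#'   plus `final_v_low` / `final_v_high` strength matrices (replicates x
#'   agents).
#' @examples
#' traj <- run_training(env_config(0.9, 0.55), n = 1,
#'                      learning = learning_config(n_trials = 200, n_reps = 50,
#'                                                 window = 50),
#'                      seed = 1)
#' summarize_learned(traj)
#' @export
run_training <- function(env, n, learning = learning_config(),
                         voting = voting_rule("linear"),
                         consensus = consensus_rule("majority"),
                         seed = NULL) {
  stopifnot(inherits(env, "env_config"), inherits(learning, "learning_config"),
            inherits(voting, "voting_rule"),
            inherits(consensus, "consensus_rule"))
  check_count(n, "n")
  if (!is.null(seed)) set.seed(seed)
  v0 <- matrix(learning$v_init, learning$n_reps, n)
  core <- train_core(v0, v0, n, env, learning$n_trials, learning$alpha,
                     voting, consensus)
  new_trajectory(core, env, n, learning, list(seed = seed))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> n = %d, r_low = %g, r_high = %g, %d trials x %d replicates\n",
              x$n, x$env$r_low, x$env$r_high, length(x$mean_p),
              nrow(x$final_v_low)))
  s <- summarize_learned(x)
  cat(sprintf("  learned p (last %d trials) = %.4f, success rate = %.4f\n",
              min(x$learning$window, length(x$mean_p)), s$learned_p,
              s$achieved_success))
  invisible(x)
}

#' Summarize the end of a training run
#'
#' Means of the per-trial behavior and success over the final `window` trials
#' of a [run_training()] trajectory, plus the exact collective accuracy of the
#' learned behavior: `achieved_accuracy` evaluates
#' [collective_accuracy()] at the learned mean `p` (deterministic, unlike the
#' empirical `achieved_success`).
#'
#' @param trajectory A `trajectory` from [run_training()] or
#'   [run_transition()].
#' @param window Number of final trials to average; defaults to the run's
#'   configured window.
#' @return A list with `learned_p`, `achieved_success` (empirical) and
#'   `achieved_accuracy` (exact accuracy of the learned mean behavior).
#' @export
summarize_learned <- function(trajectory, window = trajectory$learning$window) {
  stopifnot(inherits(trajectory, "trajectory"))
  n_trials <- length(trajectory$mean_p)
  check_count(window, "window")
  if (window > n_trials) {
    stop("`window` must not exceed the trajectory length", call. = FALSE)
  }
  idx <- seq(n_trials - window + 1, n_trials)
  learned_p <- mean(trajectory$mean_p[idx])
  env <- if (!is.null(trajectory$env_after)) trajectory$env_after
         else trajectory$env
  list(learned_p = learned_p,
       achieved_success = mean(trajectory$success[idx]),
       achieved_accuracy = collective_accuracy(learned_p, trajectory$n, env))
}
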