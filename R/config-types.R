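#' Environment configuration
#'
#' Describes the informational environment: two binary cues that each point at
#' one of two options (`"A"` or `"B"`). The high-correlation cue produces a
#' single shared signal per trial (all group members see the same draw); the
#' low-correlation cue produces one independent signal per individual. A cue's
#' reliability is the probability that its signal points at the truly superior
#' option on a trial.
#'
#' @param r_low Reliability of the low-correlation cue, in `[0.5, 1]`.
#' @param r_high Reliability of the high-correlation cue, in `[0.5, 1]`.
#' @return An object of class `env_config`.
#' @examples
#' env_config(r_low = 0.7, r_high = 0.8)
#' @export
env_config <- function(r_low, r_high) {
  check_probability(r_low, "r_low", lower = 0.5)
  check_probability(r_high, "r_high", lower = 0.5)
  structure(list(r_low = r_low, r_high = r_high), class = "env_config")
}

#' @export
print.env_config <- function(x, ...) {
  cat(sprintf("<env_config> r_low = %g, r_high = %g\n", x$r_low, x$r_high))
  invisible(x)
}

#' Learning configuration
#'
#' Parameters of the prediction-error learning protocol. Defaults follow the
#' standard training protocol: learning rate 0.1, 1000 training trials, 500
#' independent replicate runs, with the mean behavior of the last 100 trials
#' reported. Initial associative strengths are identical and very small
#' (`v_init = 0.01`), which makes the initial conflict behavior p = 0.5.
#'
#' @param alpha Learning rate in `[0, 1]`; 0 disables learning (a useful
#'   control).
#' @param v_init Initial associative strength for both cues, in `(0, 0.1]`.
#' @param n_trials Number of training trials per run.
#' @param n_reps Number of independent replicate runs.
#' @param window Number of final trials used when summarizing a run.
#' @return An object of class `learning_config`.
#' @export
learning_config <- function(alpha = 0.1, v_init = 0.01, n_trials = 1000,
                            n_reps = 500, window = 100) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("`alpha` must be a single number in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(v_init) || length(v_init) != 1 || is.na(v_init) ||
      v_init <= 0 || v_init > 0.1) {
    stop("`v_init` must be a single number in (0, 0.1]", call. = FALSE)
  }
  check_count(n_trials, "n_trials")
  check_count(n_reps, "n_reps")
  check_count(window, "window")
  if (window > n_trials) {
    stop("`window` must not exceed `n_trials`", call. = FALSE)
  }
  structure(list(alpha = alpha, v_init = v_init, n_trials = n_trials,
                 n_reps = n_reps, window = window),
            class = "learning_config")
}

#' @export
print.learning_config <- function(x, ...) {
  cat(sprintf(
    "<learning_config> alpha = %g, v_init = %g, %d trials x %d replicates, window = %d\n",
    x$alpha, x$v_init, x$n_trials, x$n_reps, x$window))
  invisible(x)
}

#' Individual voting rule
#'
#' How an agent maps its two associative strengths into the probability of
#' following the low-correlation cue when the two cues conflict. The `linear`
#' rule is probability matching: follow the low cue with probability
#' `v_low / (v_low + v_high)`. The `logistic` rule follows the low cue with
#' probability `plogis(steepness * d)` where
#' `d = (v_low - v_high) / (v_low + v_high)` is the normalized strength
#' difference; large steepness approaches deterministic argmax of strengths.
#'
#' @param kind `"linear"` or `"logistic"`.
#' @param steepness Positive steepness of the logistic rule (ignored for
#'   `linear`).
#' @return An object of class `voting_rule`.
#' @export
voting_rule <- function(kind = c("linear", "logistic"), steepness = 10) {
  kind <- match.arg(kind)
  if (kind == "logistic") {
    if (!is.numeric(steepness) || length(steepness) != 1 ||
        is.na(steepness) || steepness <= 0) {
      stop("`steepness` must be a single positive number", call. = FALSE)
    }
  }
  structure(list(kind = kind, steepness = steepness), class = "voting_rule")
}

#' @export
print.voting_rule <- function(x, ...) {
  if (x$kind == "logistic") {
    cat(sprintf("<voting_rule> logistic, steepness = %g\n", x$steepness))
  } else {
    cat("<voting_rule> linear (probability matching)\n")
  }
  invisible(x)
}

#' Consensus rule
#'
#' How individual votes are aggregated into a single group decision.
#' `majority` picks the option with strictly more votes and resolves ties
#' uniformly at random. `threshold` requires at least `threshold_votes` votes
#' for an option; unresolved deadlocks are broken uniformly at random (see
#' [threshold_decide()] for sub- vs supermajority semantics). `logistic`
#' chooses option A with probability `plogis(steepness * (f_A - 0.5))` where
#' `f_A` is the fraction of votes for A; large steepness recovers majority
#' rule.
#'
#' @param kind `"majority"`, `"threshold"` or `"logistic"`.
#' @param threshold_votes Integer vote threshold m (used by `threshold`).
#' @param steepness Positive steepness (used by `logistic`).
#' @return An object of class `consensus_rule`.
#' @export
consensus_rule <- function(kind = c("majority", "threshold", "logistic"),
                           threshold_votes = NULL, steepness = 10) {
  kind <- match.arg(kind)
  if (kind == "threshold") {
    if (is.null(threshold_votes)) {
      stop("`threshold_votes` is required for the threshold rule", call. = FALSE)
    }
    check_count(threshold_votes, "threshold_votes")
  }
  if (kind == "logistic") {
    if (!is.numeric(steepness) || length(steepness) != 1 ||
        is.na(steepness) || steepness <= 0) {
      stop("`steepness` must be a single positive number", call. = FALSE)
    }
  }
  structure(list(kind = kind, threshold_votes = threshold_votes,
                 steepness = steepness), class = "consensus_rule")
}

#' @export
print.consensus_rule <- function(x, ...) {
  switch(x$kind,
    majority = cat("<consensus_rule> simple majority, random tie-break\n"),
    threshold = cat(sprintf("<consensus_rule> vote threshold m = %d\n",
                            x$threshold_votes)),
    logistic = cat(sprintf("<consensus_rule> logistic, steepness = %g\n",
                           x$steepness)))
  invisible(x)
}

#' Agent state
#'
#' One learner's two associative strengths: `v_low` for the low-correlation
#' cue and `v_high` for the high-correlation (shared) cue. Strengths updated
#' by [update_strengths()] stay in `[0, 1]` whenever initialized there.
#'
#' @param v_low,v_high Non-negative associative strengths.
#' @return An object of class `agent_state`.
#' @export
agent_state <- function(v_low, v_high) {
  if (!is.numeric(v_low) || !is.numeric(v_high) ||
      length(v_low) != 1 || length(v_high) != 1 ||
      is.na(v_low) || is.na(v_high) || v_low < 0 || v_high < 0) {
    stop("associative strengths must be single non-negative numbers",
         call. = FALSE)
  }
  structure(list(v_low = v_low, v_high = v_high), class = "agent_state")
}

#' @export
print.agent_state <- function(x, ...) {
  cat(sprintf("<agent_state> v_low = %g, v_high = %g (p = %g)\n",
              x$v_low, x$v_high, p_from_strengths(x$v_low, x$v_high)))
  invisible(x)
}

# input checkers shared across constructors
check_probability <- function(x, name, lower = 0, upper = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%g, %g]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(x)
}
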