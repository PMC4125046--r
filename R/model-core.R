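# Core generative model: trial sampling, individual voting, consensus rules
# and the prediction-error learning update. Options are labelled "A" and "B".

OPTIONS <- c("A", "B")
# below this total strength, 0/0 is replaced by indifference (p = 0.5)
DEGENERACY_FLOOR <- 1e-12

other_option <- function(x) ifelse(x == "A", "B", "A")

#' Sample one decision trial
#'
#' Draws the hidden superior option (uniform over A/B), one shared signal from
#' the high-correlation cue, and `n` independent signals from the
#' low-correlation cue. Each signal points at the superior option with
#' probability equal to its cue's reliability.
#'
#' @param env An [env_config()].
#' @param n Group size (number of individuals), `>= 1`.
#' @return A list of class `trial_observations` with elements `superior`
#'   (length-1 character), `high_signal` (length-1 character, shared by all
#'   individuals) and `low_signals` (character vector of length `n`).
#' @examples
#' set.seed(1)
#' sample_trial(env_config(0.7, 0.8), n = 5)
#' @export
sample_trial <- function(env, n) {
  stopifnot(inherits(env, "env_config"))
  check_count(n, "n")
  superior <- sample(OPTIONS, 1)
  high_signal <- if (stats::runif(1) < env$r_high) superior else
    other_option(superior)
  low_correct <- stats::runif(n) < env$r_low
  low_signals <- ifelse(low_correct, superior, other_option(superior))
  structure(list(superior = superior, high_signal = high_signal,
                 low_signals = low_signals),
            class = "trial_observations")
}

#' Probability of following the low-correlation cue under conflict
#'
#' The probability-matching map from associative strengths to behavior:
#' `v_low / (v_low + v_high)`. When the total strength falls below the
#' degeneracy floor (1e-12, e.g. after long runs of unrewarded updates) the
#' ratio is undefined and indifference (0.5) is returned.
#'
#' @param v_low,v_high Non-negative associative strengths (vectorized), or an
#'   [agent_state()] as the first argument.
#' @return Probability (or vector of probabilities) in `[0, 1]`.
#' @examples
#' p_from_strengths(0.3, 0.1) # 0.75
#' @export
p_from_strengths <- function(v_low, v_high = NULL) {
  if (inherits(v_low, "agent_state")) {
    v_high <- v_low$v_high
    v_low <- v_low$v_low
  }
  if (any(v_low < 0) || any(v_high < 0)) {
    stop("associative strengths must be non-negative", call. = FALSE)
  }
  total <- v_low + v_high
  ifelse(total < DEGENERACY_FLOOR, 0.5, v_low / total)
}

# conflict-case probability of following the low cue, vectorized over
# strength matrices/vectors; shared by vote() and the training engine
follow_low_prob <- function(v_low, v_high, rule) {
  if (rule$kind == "linear") {
    p_from_strengths(v_low, v_high)
  } else {
    total <- v_low + v_high
    d <- ifelse(total < DEGENERACY_FLOOR, 0, (v_low - v_high) / total)
    stats::plogis(rule$steepness * d)
  }
}

#' Cast one individual's vote
#'
#' When both cues indicate the same option the individual always votes for
#' it. Under conflict, the linear rule follows the low-correlation cue with
#' probability [p_from_strengths()]; the logistic rule with probability
#' `plogis(steepness * (v_low - v_high) / (v_low + v_high))`.
#'
#' @param agent An [agent_state()].
#' @param high_signal,low_signal Option labels `"A"`/`"B"` observed from the
#'   two cues.
#' @param rule A [voting_rule()].
#' @return A single option label.
#' @export
vote <- function(agent, high_signal, low_signal,
                 rule = voting_rule("linear")) {
  stopifnot(inherits(agent, "agent_state"), inherits(rule, "voting_rule"))
  stopifnot(high_signal %in% OPTIONS, low_signal %in% OPTIONS)
  if (low_signal == high_signal) {
    return(low_signal)
  }
  p <- follow_low_prob(agent$v_low, agent$v_high, rule)
  if (stats::runif(1) < p) low_signal else high_signal
}

#' Simple majority consensus
#'
#' Returns the option with strictly more votes; a tie is a deadlock that the
#' group resolves by choosing an option uniformly at random.
#'
#' @param votes_a,votes_b Non-negative vote counts for options A and B.
#' @return A single option label.
#' @examples
#' majority_decide(5, 2) # "A"
#' @export
majority_decide <- function(votes_a, votes_b) {
  check_votes(votes_a, votes_b)
  if (votes_a > votes_b) return("A")
  if (votes_b > votes_a) return("B")
  sample(OPTIONS, 1)
}

#' Vote-threshold consensus
#'
#' Requires at least `m` votes before the group adopts an option. With a
#' supermajority threshold (`m > n/2`) at most one option can qualify; if
#' neither does, the deadlock is resolved uniformly at random. With a
#' submajority threshold (`m <= n/2`) both options may qualify, in which case
#' the decision falls back to simple majority; if neither qualifies the
#' deadlock is again random.
#'
#' @param votes_a,votes_b Non-negative vote counts for options A and B.
#' @param m Integer vote threshold, `1 <= m <= votes_a + votes_b`.
#' @return A single option label.
#' @export
threshold_decide <- function(votes_a, votes_b, m) {
  check_votes(votes_a, votes_b)
  n <- votes_a + votes_b
  check_count(m, "m")
  if (m > n) stop("`m` must not exceed the group size", call. = FALSE)
  reach_a <- votes_a >= m
  reach_b <- votes_b >= m
  if (m > n / 2) {
    if (reach_a) return("A")
    if (reach_b) return("B")
    return(sample(OPTIONS, 1))
  }
  if (reach_a && reach_b) return(majority_decide(votes_a, votes_b))
  if (reach_a) return("A")
  if (reach_b) return("B")
  sample(OPTIONS, 1)
}

#' Logistic consensus
#'
#' A smooth family of collective decision rules: the group chooses option A
#' with probability `plogis(s * (f_A - 0.5))` where `f_A` is the fraction of
#' votes for A. As the steepness `s` grows the rule converges to simple
#' majority with random tie-break.
#'
#' @param votes_a Votes for option A.
#' @param n Group size (total votes).
#' @param s Positive steepness.
#' @return A single option label.
#' @export
logistic_consensus_decide <- function(votes_a, n, s) {
  check_votes(votes_a, n - votes_a)
  if (!is.numeric(s) || length(s) != 1 || is.na(s) || s <= 0) {
    stop("`s` must be a single positive number", call. = FALSE)
  }
  p_a <- stats::plogis(s * (votes_a / n - 0.5))
  if (stats::runif(1) < p_a) "A" else "B"
}

#' Prediction-error update of associative strengths
#'
#' After the group decision, every individual observes the shared binary
#' outcome (`outcome = 1` if the chosen option was superior, else 0) and
#' updates the associative strength of each cue whose signal indicated the
#' chosen option, Rescorla-Wagner style with the compound prediction error:
#' `v <- v + alpha * (outcome - (v_low + v_high))`, clamped to `[0, 1]`. The
#' error is measured against the individual's total prediction from both
#' perceived cues, so the two strengths compete for a limited total
#' association; when the other cue's strength is zero this reduces to the
#' textbook single-cue form `v + alpha * (outcome - v)`. Cues that indicated
#' the non-chosen option are left unchanged; both cues update (sharing the
#' same error) when they agreed and their option was chosen.
#'
#' The competition is what makes collective learning effective: a cue whose
#' agreement with the group's choices predicts reward less well than the
#' other cue's is driven toward zero and the learned conflict behavior can
#' reach exclusive reliance on a single cue.
#'
#' @param agent An [agent_state()].
#' @param high_signal,low_signal The individual's observed signals.
#' @param chosen Option selected by the group.
#' @param outcome 1 if the chosen option was superior, 0 otherwise.
#' @param alpha Learning rate in `(0, 1]`.
#' @return The updated [agent_state()].
#' @examples
#' a <- agent_state(0.5, 0.2)
#' update_strengths(a, "A", "A", chosen = "A", outcome = 1, alpha = 0.1)
#' @export
update_strengths <- function(agent, high_signal, low_signal, chosen, outcome,
                             alpha) {
  stopifnot(inherits(agent, "agent_state"))
  stopifnot(high_signal %in% OPTIONS, low_signal %in% OPTIONS,
            chosen %in% OPTIONS)
  if (!outcome %in% c(0, 1)) {
    stop("`outcome` must be 0 or 1", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop("`alpha` must be in (0, 1]", call. = FALSE)
  }
  v_low <- agent$v_low
  v_high <- agent$v_high
  error <- outcome - (v_low + v_high) # compound error, from pre-update state
  if (low_signal == chosen) v_low <- clamp01(v_low + alpha * error)
  if (high_signal == chosen) v_high <- clamp01(v_high + alpha * error)
  agent_state(v_low, v_high)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

check_votes <- function(votes_a, votes_b) {
  if (!is.numeric(votes_a) || !is.numeric(votes_b) ||
      length(votes_a) != 1 || length(votes_b) != 1 ||
      is.na(votes_a) || is.na(votes_b) ||
      votes_a < 0 || votes_b < 0 ||
      votes_a != as.integer(votes_a) || votes_b != as.integer(votes_b)) {
    stop("vote counts must be single non-negative integers", call. = FALSE)
  }
  if (votes_a + votes_b < 1) {
    stop("at least one vote is required", call. = FALSE)
  }
  invisible(NULL)
}
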