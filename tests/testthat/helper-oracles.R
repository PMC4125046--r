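# Independent oracles: everything here avoids the package's analytic code
# paths (explicit choose() sums, exhaustive enumeration, brute-force
# simulation) so the tests compare two independent routes.

# majority-correct probability from the explicit binomial sum
oracle_majority <- function(q, n) {
  k <- 0:n
  pmf <- choose(n, k) * q^k * (1 - q)^(n - k)
  sum(pmf[2 * k > n]) + if (n %% 2 == 0) 0.5 * pmf[k == n / 2] else 0
}

# heterogeneous majority probability by exhaustive enumeration (n <= ~12)
oracle_majority_hetero <- function(q) {
  n <- length(q)
  outcomes <- as.matrix(expand.grid(rep(list(0:1), n)))
  prob <- apply(outcomes, 1, function(x) prod(ifelse(x == 1, q, 1 - q)))
  k <- rowSums(outcomes)
  sum(prob[2 * k > n]) + sum(0.5 * prob[2 * k == n])
}

# collective accuracy via the explicit sum, built on oracle_majority
oracle_accuracy <- function(p, n, r_low, r_high) {
  r_high * oracle_majority(1 - (1 - r_low) * p, n) +
    (1 - r_high) * oracle_majority(r_low * p, n)
}

# grid-search optimum at 1e-4 resolution, built entirely on the oracle
oracle_optimum <- function(n, r_low, r_high, step = 1e-4) {
  grid <- seq(0, 1, by = step)
  vals <- vapply(grid, oracle_accuracy, 0, n = n, r_low = r_low,
                 r_high = r_high)
  i <- which.max(vals)
  list(p = grid[i], value = vals[i])
}

# brute-force single-trial Monte-Carlo of the generative model: n voters with
# fixed conflict-following probability p, simple majority, random tie-break
oracle_mc_accuracy <- function(p, n, r_low, r_high, trials) {
  superior <- stats::rbinom(trials, 1, 0.5)
  high <- ifelse(stats::runif(trials) < r_high, superior, 1L - superior)
  low <- matrix(stats::rbinom(trials * n, 1, r_low), trials, n)
  low <- ifelse(low == 1, superior, 1L - superior)
  agree <- low == high
  take_low <- matrix(stats::runif(trials * n), trials, n) < p
  votes <- ifelse(agree | take_low, low, high)
  votes1 <- rowSums(votes)
  chosen <- ifelse(2 * votes1 > n, 1L, ifelse(2 * votes1 < n, 0L, NA))
  if (anyNA(chosen)) {
    chosen[is.na(chosen)] <- stats::rbinom(sum(is.na(chosen)), 1, 0.5)
  }
  mean(chosen == superior)
}

# iterate the learning update outside the package (scalar reference)
oracle_iterate_update <- function(v0, other, outcome, alpha, t) {
  v <- v0
  for (i in seq_len(t)) v <- min(max(v + alpha * (outcome - (v + other)), 0), 1)
  v
}

make_bout <- function(arrivals, fraction = 0.5, steps = 10L) {
  structure(list(arrivals = arrivals, steps_elapsed = steps,
                 fraction_preferring_a = fraction),
            class = "spatial_bout")
}
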