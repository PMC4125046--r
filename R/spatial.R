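# Minimal zonal collective-motion model: repulsion inside an inner zone,
# attraction to and alignment with neighbors in an outer zone, blended with an
# innate preference for one of two targets. Used to show that cohesive spatial
# groups with conflicting preferences behave like simple-majority voters.

#' Zonal model configuration
#'
#' All lengths are in body lengths, angles in radians, time in steps. Defaults
#' follow common zonal-model conventions, placed in the cohesive schooling
#' regime: unit inner (repulsion) zone, outer (attraction/alignment) zone of
#' 10 body lengths, unit speed, bounded turning rate, small angular noise,
#' and two targets 50 body lengths away separated by 60 degrees.
#'
#' @param n Group size.
#' @param r_repulsion Inner zone radius.
#' @param r_attraction Outer zone radius (`> r_repulsion`).
#' @param speed Displacement per time step.
#' @param max_turn Maximum heading change per step.
#' @param noise_sd Standard deviation of Gaussian angular noise.
#' @param pref_weight Weight of the target preference against the (unit)
#'   social vector.
#' @param target_distance Distance from the start point to each target.
#' @param target_separation_angle Angle between the two target directions.
#' @param capture_radius Arrival distance from a target.
#' @param max_steps Bout length limit.
#' @param dt Time step.
#' @param warmup Equilibration steps run before target preferences are
#'   switched on, letting the school self-organize from its random initial
#'   headings; without it, groups fragment in the first few steps and bouts
#'   no longer probe consensus among cohesive groups.
#' @return An object of class `spatial_config`.
#' @export
spatial_config <- function(n = 10, r_repulsion = 1, r_attraction = 10,
                           speed = 1, max_turn = 0.35, noise_sd = 0.05,
                           pref_weight = 0.5, target_distance = 50,
                           target_separation_angle = pi / 3,
                           capture_radius = 8, max_steps = 2000, dt = 1,
                           warmup = 50) {
  check_count(n, "n")
  if (!(r_repulsion > 0 && r_attraction > r_repulsion)) {
    stop("need 0 < r_repulsion < r_attraction", call. = FALSE)
  }
  if (speed <= 0 || max_turn <= 0 || capture_radius <= 0 || dt <= 0) {
    stop("`speed`, `max_turn`, `capture_radius` and `dt` must be positive",
         call. = FALSE)
  }
  if (noise_sd < 0 || pref_weight < 0 || target_distance <= 0 ||
      target_separation_angle <= 0) {
    stop("invalid spatial parameter", call. = FALSE)
  }
  check_count(max_steps, "max_steps")
  check_count(warmup, "warmup", min = 0)
  structure(list(n = n, r_repulsion = r_repulsion,
                 r_attraction = r_attraction, speed = speed,
                 max_turn = max_turn, noise_sd = noise_sd,
                 pref_weight = pref_weight, target_distance = target_distance,
                 target_separation_angle = target_separation_angle,
                 capture_radius = capture_radius, max_steps = max_steps,
                 dt = dt, warmup = warmup),
            class = "spatial_config")
}

#' @export
print.spatial_config <- function(x, ...) {
  cat(sprintf(
    "<spatial_config> n = %d, zones %g/%g BL, speed %g, targets %g BL apart at %g BL\n",
    x$n, x$r_repulsion, x$r_attraction, x$speed,
    2 * x$target_distance * sin(x$target_separation_angle / 2),
    x$target_distance))
  invisible(x)
}

target_positions <- function(cfg) {
  half <- cfg$target_separation_angle / 2
  rbind(A = cfg$target_distance * c(cos(half), sin(half)),
        B = cfg$target_distance * c(cos(half), -sin(half)))
}

wrap_angle <- function(a) ((a + pi) %% (2 * pi)) - pi

#' Advance the zonal model by one time step
#'
#' Per individual: neighbors inside the inner zone trigger pure repulsion
#' (overriding all other forces, including the target preference); otherwise
#' the desired direction blends attraction to and alignment with neighbors in
#' the outer zone with `pref_weight` times the unit vector toward the
#' preferred target. The heading rotates toward the desired direction by at
#' most `max_turn`, Gaussian angular noise is added, and the position advances
#' by `speed * dt`.
#'
#' @param positions `n x 2` matrix of coordinates.
#' @param headings Length-`n` vector of heading angles.
#' @param preferences `n x 2` matrix of preferred-target coordinates; a row of
#'   `NA` means no preference.
#' @param cfg A [spatial_config()].
#' @return A list with updated `positions` and `headings`.
#' @export
spatial_step <- function(positions, headings, preferences, cfg) {
  stopifnot(inherits(cfg, "spatial_config"))
  n <- nrow(positions)
  stopifnot(length(headings) == n, nrow(preferences) == n)
  dx <- outer(positions[, 1], positions[, 1], "-") # dx[i, j] = x_i - x_j
  dy <- outer(positions[, 2], positions[, 2], "-")
  d <- sqrt(dx^2 + dy^2)
  diag(d) <- Inf
  ux <- -dx / d # unit vector from i toward j
  uy <- -dy / d
  in_rep <- d < cfg$r_repulsion
  in_att <- d >= cfg$r_repulsion & d < cfg$r_attraction
  hx <- cos(headings)
  hy <- sin(headings)
  desired <- headings
  for (i in seq_len(n)) {
    if (any(in_rep[i, ])) {
      vx <- -sum(ux[i, in_rep[i, ]])
      vy <- -sum(uy[i, in_rep[i, ]])
    } else {
      vx <- vy <- 0
      if (any(in_att[i, ])) {
        sx <- sum(ux[i, in_att[i, ]]) + sum(hx[in_att[i, ]])
        sy <- sum(uy[i, in_att[i, ]]) + sum(hy[in_att[i, ]])
        nrm <- sqrt(sx^2 + sy^2)
        if (nrm > 0) {
          vx <- sx / nrm
          vy <- sy / nrm
        }
      }
      if (!is.na(preferences[i, 1])) {
        px <- preferences[i, 1] - positions[i, 1]
        py <- preferences[i, 2] - positions[i, 2]
        nrm <- sqrt(px^2 + py^2)
        if (nrm > 0) {
          vx <- vx + cfg$pref_weight * px / nrm
          vy <- vy + cfg$pref_weight * py / nrm
        }
      }
    }
    if (vx != 0 || vy != 0) desired[i] <- atan2(vy, vx)
  }
  delta <- wrap_angle(desired - headings)
  delta <- pmax(pmin(delta, cfg$max_turn), -cfg$max_turn)
  headings <- wrap_angle(headings + delta +
                           stats::rnorm(n, 0, cfg$noise_sd))
  positions <- positions +
    cfg$speed * cfg$dt * cbind(cos(headings), sin(headings))
  list(positions = positions, headings = headings)
}

#' Simulate one decision bout
#'
#' Initializes a compact polarized school (positions uniform in a disc of
#' radius 4 body lengths around the start point, headings toward the arena
#' with small dispersion), lets it school for `warmup` steps with no target
#' preferences, then assigns
#' `round(fraction_preferring_a * n)` individuals a preference for target A
#' and the rest for target B and advances the zonal model until every
#' individual is within `capture_radius` of a target or `max_steps` elapse.
#' Individuals freeze on arrival but remain visible to the others.
#'
#' @param cfg A [spatial_config()].
#' @param fraction_preferring_a Fraction of the group preferring target A.
#' @return A list of class `spatial_bout` with `arrivals` (per-individual
#'   `"A"`, `"B"` or `"none"`), `steps_elapsed` and `fraction_preferring_a`.
#' @export
run_bout <- function(cfg, fraction_preferring_a) {
  stopifnot(inherits(cfg, "spatial_config"))
  check_probability(fraction_preferring_a, "fraction_preferring_a")
  n <- cfg$n
  targets <- target_positions(cfg)
  n_a <- round(fraction_preferring_a * n)
  pref_label <- sample(c(rep("A", n_a), rep("B", n - n_a)))
  preferences <- targets[pref_label, , drop = FALSE]
  radius <- 4 * sqrt(stats::runif(n))
  angle <- stats::runif(n, 0, 2 * pi)
  positions <- cbind(radius * cos(angle), radius * sin(angle))
  headings <- stats::rnorm(n, 0, 0.2) # polarized toward the targets' midline
  no_pref <- matrix(NA_real_, n, 2)
  for (i in seq_len(cfg$warmup)) {
    upd <- spatial_step(positions, headings, no_pref, cfg)
    positions <- upd$positions
    headings <- upd$headings
  }
  # recentre the equilibrated school on the start point
  positions <- sweep(positions, 2, colMeans(positions))
  arrivals <- rep("none", n)
  steps <- 0L
  while (any(arrivals == "none") && steps < cfg$max_steps) {
    moving <- arrivals == "none"
    upd <- spatial_step(positions, headings, preferences, cfg)
    positions[moving, ] <- upd$positions[moving, ]
    headings[moving] <- upd$headings[moving]
    d_a <- sqrt(rowSums((positions - matrix(targets["A", ], n, 2,
                                            byrow = TRUE))^2))
    d_b <- sqrt(rowSums((positions - matrix(targets["B", ], n, 2,
                                            byrow = TRUE))^2))
    arrivals[moving & d_a <= cfg$capture_radius] <- "A"
    arrivals[moving & arrivals == "none" & d_b <= cfg$capture_radius] <- "B"
    steps <- steps + 1L
  }
  structure(list(arrivals = arrivals, steps_elapsed = steps,
                 fraction_preferring_a = fraction_preferring_a),
            class = "spatial_bout")
}

#' Run repeated bouts across preference fractions
#'
#' @param cfg A [spatial_config()].
#' @param fractions Vector of fractions of the group preferring target A.
#' @param n_bouts Bouts per fraction.
#' @param seed Optional integer seed.
#' @return A list of `spatial_bout` objects (class `spatial_bout_set`).
#' @export
run_bouts <- function(cfg, fractions, n_bouts, seed = NULL) {
  stopifnot(inherits(cfg, "spatial_config"))
  check_count(n_bouts, "n_bouts")
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (f in fractions) {
    out <- c(out, lapply(seq_len(n_bouts), function(i) run_bout(cfg, f)))
  }
  structure(out, class = "spatial_bout_set")
}

#' Summarize decision bouts
#'
#' Cohesion is the fraction of bouts whose per-individual arrival outcomes are
#' unanimous (all `"A"`, all `"B"`, or all `"none"`). The majority-following
#' curve gives, per preference fraction, the probability that the group
#' (majority of arrived individuals) reached target A among decided bouts;
#' bouts where no individual arrived, or arrivals tie, are undecided and are
#' excluded from the curve but counted in `n_undecided`.
#'
#' @param results A list of `spatial_bout` objects (e.g. from [run_bouts()]).
#' @return A list of class `bout_summary`: `cohesion`, and a data frame
#'   `curve` with columns `fraction`, `prop_a`, `n_decided`, `n_undecided`.
#' @export
summarize_bouts <- function(results) {
  if (length(results) == 0) stop("`results` must be non-empty", call. = FALSE)
  stopifnot(all(vapply(results, inherits, TRUE, "spatial_bout")))
  unanimous <- vapply(results, function(b)
    length(unique(b$arrivals)) == 1, TRUE)
  fraction <- vapply(results, function(b) b$fraction_preferring_a, 0)
  outcome <- vapply(results, function(b) {
    n_a <- sum(b$arrivals == "A")
    n_b <- sum(b$arrivals == "B")
    if (n_a + n_b == 0 || n_a == n_b) "undecided"
    else if (n_a > n_b) "A" else "B"
  }, "")
  curve <- do.call(rbind, lapply(sort(unique(fraction)), function(f) {
    dec <- outcome[fraction == f & outcome != "undecided"]
    data.frame(fraction = f,
               prop_a = if (length(dec)) mean(dec == "A") else NA_real_,
               n_decided = length(dec),
               n_undecided = sum(fraction == f & outcome == "undecided"))
  }))
  structure(list(cohesion = mean(unanimous), curve = curve),
            class = "bout_summary")
}

#' @export
print.bout_summary <- function(x, ...) {
  cat(sprintf("<bout_summary> cohesion = %.3f over %d bouts\n",
              x$cohesion, sum(x$curve$n_decided) + sum(x$curve$n_undecided)))
  print(x$curve, row.names = FALSE)
  invisible(x)
}
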