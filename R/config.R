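# Run configuration: YAML/JSON files plus flag overrides, validated into the
# package's config objects before any run starts.

config_defaults <- function() {
  list(experiment = "train", r_low = 0.7, r_high = 0.8, n = 5,
       alpha = 0.1, v_init = 0.01, n_trials = 1000, n_reps = 500,
       window = 100,
       voting = list(kind = "linear", steepness = 10),
       consensus = list(kind = "majority", threshold_votes = NULL,
                        steepness = 10),
       transition = NULL, spatial = NULL,
       group_sizes = NULL, r_low_values = NULL, r_high_values = NULL,
       fractions = NULL, n_bouts = NULL,
       seed = NULL, output = NULL)
}

known_experiments <- c("train", "sweep", "optimal", "landscape",
                       "global-compare", "transition", "isolated-pooled",
                       "spatial-validate")

#' Load and validate a run configuration
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) configuration file, applies
#' flag overrides (flags win over file values), and fills everything else with
#' the default training protocol (learning rate 0.1, 1000 trials, 500
#' replicates, 100-trial summary window). Every sub-configuration is validated
#' by its own constructor before anything runs; unknown keys and out-of-range
#' values raise errors naming the offending key.
#'
#' @param path Optional path to a YAML or JSON config file.
#' @param flags Named list of overrides (e.g. `list(r_low = 0.7, n = 5)`).
#' @return A validated list of class `run_config` whose elements include the
#'   constructed `env` ([env_config()]), `learning` ([learning_config()]),
#'   `voting` and `consensus` rules, and any `transition`/`spatial` specs.
#' @export
load_config <- function(path = NULL, flags = list()) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop(sprintf("config file not found: %s", path), call. = FALSE)
    }
    ext <- tolower(tools::file_ext(path))
    file_cfg <- switch(ext,
      yaml = ,
      yml = yaml::read_yaml(path),
      json = jsonlite::read_json(path, simplifyVector = TRUE),
      stop(sprintf("unsupported config format: .%s (use YAML or JSON)", ext),
           call. = FALSE))
    # YAML 1.1 parses a bare `n:` key as the boolean FALSE; map it back
    if (!is.null(names(file_cfg))) {
      names(file_cfg)[names(file_cfg) == "FALSE"] <- "n"
    }
    cfg <- merge_config(cfg, file_cfg, source = path)
  }
  cfg <- merge_config(cfg, flags, source = "flags")
  validate_run_config(cfg)
}

merge_config <- function(base, new, source) {
  if (is.null(new)) return(base)
  if (!is.list(new)) stop("configuration must be a named list", call. = FALSE)
  unknown <- setdiff(names(new), names(base))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s) in %s: %s", source,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (key in names(new)) {
    if (is.list(new[[key]]) && is.list(base[[key]])) {
      base[[key]] <- merge_config(base[[key]], new[[key]],
                                  paste0(source, "$", key))
    } else {
      base[[key]] <- new[[key]]
    }
  }
  base
}

validate_run_config <- function(cfg) {
  if (!cfg$experiment %in% known_experiments) {
    stop(sprintf("unknown experiment `%s` (one of: %s)", cfg$experiment,
                 paste(known_experiments, collapse = ", ")), call. = FALSE)
  }
  out <- cfg
  out$env <- env_config(cfg$r_low, cfg$r_high)
  check_count(cfg$n, "n")
  out$learning <- learning_config(alpha = cfg$alpha, v_init = cfg$v_init,
                                  n_trials = cfg$n_trials,
                                  n_reps = cfg$n_reps, window = cfg$window)
  out$voting <- voting_rule(cfg$voting$kind,
                            steepness = cfg$voting$steepness %||% 10)
  out$consensus <- consensus_rule(cfg$consensus$kind,
                                  threshold_votes = cfg$consensus$threshold_votes,
                                  steepness = cfg$consensus$steepness %||% 10)
  if (!is.null(cfg$transition)) {
    out$transition <- do.call(transition_spec, cfg$transition)
  }
  if (!is.null(cfg$spatial)) {
    out$spatial <- do.call(spatial_config, cfg$spatial)
  }
  if (!is.null(cfg$seed)) check_count(cfg$seed, "seed", min = 0)
  class(out) <- "run_config"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> experiment = %s, n = %d, r_low = %g, r_high = %g\n",
              x$experiment, x$n, x$r_low, x$r_high))
  invisible(x)
}
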