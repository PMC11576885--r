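#' Configure a bounded random walk
#'
#' The latent outcome probabilities \eqn{P^{Self}} and \eqn{P^{Other}} of the
#' p-FBT each follow a bounded random walk on \eqn{[0, 1]}. The default
#' mechanism takes a step of \eqn{\pm} `step_size` with equal probability and
#' reflects at the bounds; a Gaussian-step alternative (SD = `step_size`,
#' reflected) is available via `mechanism`.
#'
#' @param n_steps Number of steps (one per sampling trial).
#' @param step_size Step magnitude on the probability scale. Default 0.025.
#' @param lower,upper Reflecting bounds. Defaults 0 and 1.
#' @param start Starting probability. Default 0.5 (chance level).
#' @param mechanism `"binary"` (default) for \eqn{\pm}`step_size` steps, or
#'   `"gaussian"` for Normal(0, `step_size`) steps.
#' @return A list of class `pfbt_walk_config`.
#' @export
walk_config <- function(n_steps = 360L, step_size = 0.025, lower = 0,
                        upper = 1, start = 0.5,
                        mechanism = c("binary", "gaussian")) {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(n_steps) || length(n_steps) != 1 || n_steps < 1) {
    abort("`n_steps` must be a positive integer.", class = "pfbt_config_error")
  }
  if (step_size <= 0) {
    abort("`step_size` must be positive.", class = "pfbt_config_error")
  }
  if (lower >= upper) {
    abort("`lower` must be below `upper`.", class = "pfbt_config_error")
  }
  if (start < lower || start > upper) {
    abort("`start` must lie within the bounds.", class = "pfbt_config_error")
  }
  structure(
    list(n_steps = as.integer(n_steps), step_size = step_size, lower = lower,
         upper = upper, start = start, mechanism = mechanism),
    class = "pfbt_walk_config"
  )
}

reflect_into <- function(x, lower, upper) {
  # reflect a single proposed value back into [lower, upper]
  while (x < lower || x > upper) {
    if (x < lower) x <- 2 * lower - x
    if (x > upper) x <- 2 * upper - x
  }
  x
}

#' Generate a bounded random walk
#'
#' @param config A [walk_config()].
#' @param seed Optional integer seed; when supplied the walk is reproducible
#'   and the caller's RNG state is left untouched.
#' @return A numeric vector of length `n_steps`, each value within the bounds
#'   and within `step_size` of its predecessor.
#' @examples
#' w <- generate_random_walk(walk_config(n_steps = 10), seed = 1)
#' all(abs(diff(w)) <= 0.025 + 1e-12)
#' @export
generate_random_walk <- function(config = walk_config(), seed = NULL) {
  stopifnot(inherits(config, "pfbt_walk_config"))
  if (!is.null(seed)) withr::local_seed(seed)
  n <- config$n_steps
  x <- numeric(n)
  cur <- config$start
  steps <- if (config$mechanism == "binary") {
    sample(c(-1, 1), n, replace = TRUE) * config$step_size
  } else {
    stats::rnorm(n, 0, config$step_size)
  }
  for (i in seq_len(n)) {
    cur <- reflect_into(cur + steps[i], config$lower, config$upper)
    x[i] <- cur
  }
  x
}

#' Configure a p-FBT sequence
#'
#' Defines the generative structure of one task run: two independent bounded
#' random walks for \eqn{P^{Self}} and \eqn{P^{Other}}, `n_trials` Bernoulli
#' sampling trials of three types, and probe trials inserted every 4--9
#' sampling trials.
#'
#' Privileged samples are drawn from the \eqn{P^{Self}} walk, decoy samples
#' from the \eqn{P^{Other}} walk, and shared samples from either walk with
#' equal probability (the walk used is recorded). The default trial-type mix
#' keeps shared trials rare (5%) so that, under fully agent-specific updating,
#' the Self and Other belief trajectories stay uncorrelated: shared samples
#' are the only common input to the two belief streams, and a large shared
#' fraction would mechanically correlate them even without leakage.
#'
#' @param n_trials Number of sampling trials. Default 360.
#' @param type_probs Named probabilities for `shared`, `privileged`, `decoy`
#'   sampling trials; must sum to 1.
#' @param probe_gap Integer range (inclusive) of sampling trials between
#'   successive probes. Default `c(4, 9)`, gaps drawn uniformly.
#' @param probe_scheme `"random"` (default) assigns each probe to Self or
#'   Other with equal probability; `"alternate"` strictly alternates.
#' @param walk_self,walk_other [walk_config()]s for the two latent walks.
#' @return A list of class `pfbt_task_config`.
#' @export
task_config <- function(n_trials = 360L,
                        type_probs = c(shared = 0.05, privileged = 0.475,
                                       decoy = 0.475),
                        probe_gap = c(4L, 9L),
                        probe_scheme = c("random", "alternate"),
                        walk_self = walk_config(n_steps = n_trials),
                        walk_other = walk_config(n_steps = n_trials)) {
  probe_scheme <- match.arg(probe_scheme)
  if (!setequal(names(type_probs), c("shared", "privileged", "decoy"))) {
    abort("`type_probs` must be named shared, privileged, decoy.",
          class = "pfbt_config_error")
  }
  if (abs(sum(type_probs) - 1) > 1e-8) {
    abort("`type_probs` must sum to 1.", class = "pfbt_config_error")
  }
  if (any(type_probs < 0)) {
    abort("`type_probs` must be non-negative.", class = "pfbt_config_error")
  }
  if (length(probe_gap) != 2 || probe_gap[1] < 1 || probe_gap[1] > probe_gap[2]) {
    abort("`probe_gap` must be an increasing pair of positive integers.",
          class = "pfbt_config_error")
  }
  structure(
    list(n_trials = as.integer(n_trials),
         type_probs = type_probs[c("shared", "privileged", "decoy")],
         probe_gap = as.integer(probe_gap), probe_scheme = probe_scheme,
         walk_self = walk_self, walk_other = walk_other),
    class = "pfbt_task_config"
  )
}

new_pfbt_sequence <- function(df, config, seed) {
  attr(df, "config") <- config
  attr(df, "seed") <- seed
  class(df) <- c("pfbt_sequence", class(tibble::tibble()))
  df
}

#' Generate a p-FBT trial sequence
#'
#' Produces the interleaved stream of sampling and probe trials, with the
#' latent walk probabilities, the Bernoulli outcomes and their provenance
#' (which walk each outcome was drawn from), and the probe schedule.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the sequence is bit-reproducible from
#'   (config, seed).
#' @return A tibble of class `pfbt_sequence` with one row per trial in the
#'   interleaved stream and columns `trial_index`, `phase`
#'   (`sampling`/`probe`), `trial_type`, `outcome`, `probe_agent`, `p_self`,
#'   `p_other`, `walk_used`. The configuration and seed are kept as
#'   attributes and serialized alongside the CSV by [write_sequence()].
#' @examples
#' seq <- generate_task_sequence(task_config(n_trials = 60), seed = 1)
#' dplyr::count(seq, phase)
#' @export
generate_task_sequence <- function(config = task_config(), seed = 1L) {
  stopifnot(inherits(config, "pfbt_task_config"))
  withr::local_seed(seed)
  n <- config$n_trials
  p_self <- generate_random_walk(config$walk_self)
  p_other <- generate_random_walk(config$walk_other)
  trial_type <- sample(names(config$type_probs), n, replace = TRUE,
                       prob = config$type_probs)
  walk_used <- dplyr::case_when(
    trial_type == "privileged" ~ "self",
    trial_type == "decoy" ~ "other",
    TRUE ~ sample(c("self", "other"), n, replace = TRUE)
  )
  p_used <- ifelse(walk_used == "self", p_self, p_other)
  outcome <- rbinom(n, 1L, p_used)

  # probe positions: gaps uniform on probe_gap[1]..probe_gap[2]
  gaps <- integer(0)
  total <- 0L
  repeat {
    g <- sample(seq(config$probe_gap[1], config$probe_gap[2]), 1L)
    if (total + g > n) break
    gaps <- c(gaps, g)
    total <- total + g
  }
  probe_after <- cumsum(gaps)
  n_probes <- length(probe_after)
  probe_agent <- if (config$probe_scheme == "random") {
    sample(c("self", "other"), n_probes, replace = TRUE)
  } else {
    rep_len(c("self", "other"), n_probes)
  }

  sampling <- tibble::tibble(
    phase = "sampling", trial_type = trial_type, outcome = as.integer(outcome),
    probe_agent = NA_character_, p_self = p_self, p_other = p_other,
    walk_used = walk_used, sampling_index = seq_len(n)
  )
  probes <- tibble::tibble(
    phase = "probe", trial_type = NA_character_, outcome = NA_integer_,
    probe_agent = probe_agent,
    p_self = p_self[probe_after], p_other = p_other[probe_after],
    walk_used = NA_character_, sampling_index = probe_after
  )
  # interleave: probe rows come immediately after their preceding sampling trial
  df <- dplyr::bind_rows(sampling, probes)
  df <- df[order(df$sampling_index, df$phase == "probe"), ]
  df <- dplyr::mutate(df, trial_index = dplyr::row_number(), .before = 1)
  df$sampling_index <- NULL
  new_pfbt_sequence(df, config, seed)
}

#' Extract sampling trials from a sequence
#'
#' @param sequence A `pfbt_sequence` (or a data frame with its schema).
#' @return A tibble of sampling trials with a 1-based `sampling_index`.
#' @export
sampling_trials <- function(sequence) {
  sequence |>
    tibble::as_tibble() |>
    dplyr::filter(.data$phase == "sampling") |>
    dplyr::mutate(sampling_index = dplyr::row_number())
}

#' Extract probe trials from a sequence
#'
#' @inheritParams sampling_trials
#' @return A tibble of probe trials with `probe_index` (order in the probe
#'   stream) and `after_sampling_index` (the 1-based index of the preceding
#'   sampling trial).
#' @export
probe_trials <- function(sequence) {
  df <- tibble::as_tibble(sequence)
  n_sampling_before <- cumsum(df$phase == "sampling")
  df |>
    dplyr::mutate(after_sampling_index = n_sampling_before) |>
    dplyr::filter(.data$phase == "probe") |>
    dplyr::mutate(probe_index = dplyr::row_number()) |>
    dplyr::select("probe_index", "trial_index", "after_sampling_index",
                  "probe_agent", "p_self", "p_other")
}

sequence_columns <- c("trial_index", "phase", "trial_type", "outcome",
                      "probe_agent", "p_self", "p_other", "walk_used")

#' Write / read a task sequence
#'
#' `write_sequence()` stores the trial table as CSV plus a JSON sidecar
#' (`<path>.json`) holding the full generation configuration and seed;
#' `read_sequence()` restores and validates it. Reading a file whose probe
#' gaps fall outside the configured 4--9 range raises a warning; malformed
#' rows (unknown `trial_type`, `outcome` outside \{0, 1\}) are errors naming
#' the offending row.
#'
#' @param sequence A `pfbt_sequence`.
#' @param path CSV file path.
#' @return `read_sequence()` returns a `pfbt_sequence`; `write_sequence()`
#'   returns `path` invisibly.
#' @export
write_sequence <- function(sequence, path) {
  df <- tibble::as_tibble(sequence)[, sequence_columns]
  readr::write_csv(df, path, na = "NA")
  cfg <- attr(sequence, "config")
  sidecar <- list(
    seed = attr(sequence, "seed"),
    n_trials = cfg$n_trials, type_probs = as.list(cfg$type_probs),
    probe_gap = cfg$probe_gap, probe_scheme = cfg$probe_scheme,
    walk_self = unclass(cfg$walk_self), walk_other = unclass(cfg$walk_other)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sequence
#' @export
read_sequence <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          trial_index = readr::col_integer(),
                          phase = readr::col_character(),
                          trial_type = readr::col_character(),
                          outcome = readr::col_integer(),
                          probe_agent = readr::col_character(),
                          p_self = readr::col_double(),
                          p_other = readr::col_double(),
                          walk_used = readr::col_character()
                        ))
  attr(df, "spec") <- NULL
  attr(df, "problems") <- NULL
  validate_sequence(df)
  cfg_path <- paste0(path, ".json")
  config <- NULL
  seed <- NULL
  if (file.exists(cfg_path)) {
    sc <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    wcfg <- function(w) walk_config(w$n_steps, w$step_size, w$lower, w$upper,
                                    w$start, w$mechanism)
    config <- task_config(
      n_trials = sc$n_trials, type_probs = unlist(sc$type_probs),
      probe_gap = sc$probe_gap, probe_scheme = sc$probe_scheme,
      walk_self = wcfg(sc$walk_self), walk_other = wcfg(sc$walk_other)
    )
    seed <- sc$seed
  }
  new_pfbt_sequence(df, config, seed)
}

#' Validate a task-sequence table
#'
#' @param df A data frame with the sequence CSV schema.
#' @return `df` invisibly; errors name the first offending row.
#' @export
validate_sequence <- function(df) {
  missing_cols <- setdiff(sequence_columns, names(df))
  if (length(missing_cols)) {
    abort(paste0("Sequence is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "pfbt_validation_error")
  }
  sampling <- df$phase == "sampling"
  bad_type <- which(sampling & !df$trial_type %in% c("shared", "privileged", "decoy"))
  if (length(bad_type)) {
    abort(sprintf("Unknown trial_type '%s' in row %d.",
                  df$trial_type[bad_type[1]], bad_type[1]),
          class = "pfbt_validation_error")
  }
  bad_outcome <- which(sampling & !df$outcome %in% c(0L, 1L))
  if (length(bad_outcome)) {
    abort(sprintf("outcome must be 0 or 1; row %d has '%s'.",
                  bad_outcome[1], df$outcome[bad_outcome[1]]),
          class = "pfbt_validation_error")
  }
  bad_phase <- which(!df$phase %in% c("sampling", "probe"))
  if (length(bad_phase)) {
    abort(sprintf("Unknown phase '%s' in row %d.",
                  df$phase[bad_phase[1]], bad_phase[1]),
          class = "pfbt_validation_error")
  }
  if (any(!sampling)) {
    n_before <- cumsum(sampling)
    gaps <- diff(c(0L, n_before[!sampling]))
    if (any(gaps < 4 | gaps > 9)) {
      warn(sprintf("%d probe gap(s) outside the 4-9 sampling-trial range.",
                   sum(gaps < 4 | gaps > 9)),
           class = "pfbt_validation_warning")
    }
  }
  invisible(df)
}
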