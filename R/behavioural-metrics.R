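pertinent_types <- function(agent) {
  switch(agent, self = c("shared", "privileged"), other = c("shared", "decoy"),
         abort("`agent` must be 'self' or 'other'.", class = "pfbt_domain_error"))
}

#' Recency-weighted outcome averages at probe times
#'
#' Computes the exponential recency-weighted average \eqn{O} of the outcomes
#' pertinent to an agent (Self: shared + privileged samples; Other: shared +
#' decoy samples), updated as \eqn{O \leftarrow O + w (outcome - O)} over the
#' pertinent stream, and sampled at each probe. \eqn{O} is used instead of
#' the true generating probability to absorb sampling error in the observed
#' outcomes.
#'
#' @param sequence A `pfbt_sequence`.
#' @param agent `"self"` or `"other"`.
#' @param weight Recency weight in (0, 1). Default 0.1.
#' @param initial Starting value, used (and flagged) for probes preceding
#'   any pertinent outcome. Default 0.5.
#' @return A tibble, one row per probe: `probe_index`,
#'   `after_sampling_index`, `probe_agent`, `o` and `before_first_outcome`.
#' @export
recency_weighted_outcomes <- function(sequence, agent, weight = 0.1,
                                      initial = 0.5) {
  if (weight <= 0 || weight >= 1) {
    abort("`weight` must lie strictly inside (0, 1).",
          class = "pfbt_domain_error")
  }
  st <- sampling_trials(sequence)
  pert <- st$trial_type %in% pertinent_types(agent)
  # running O over all sampling trials, updated only on pertinent ones
  o_run <- numeric(nrow(st))
  o <- initial
  for (i in seq_len(nrow(st))) {
    if (pert[i]) o <- o + weight * (st$outcome[i] - o)
    o_run[i] <- o
  }
  any_seen <- cumsum(pert) > 0
  pr <- probe_trials(sequence)
  idx <- pr$after_sampling_index
  flagged <- idx == 0 | !any_seen[pmax(idx, 1)]
  if (any(flagged)) {
    warn(sprintf("%d probe(s) precede the first pertinent outcome; initial O used.",
                 sum(flagged)), class = "pfbt_metric_warning")
  }
  tibble::tibble(
    probe_index = pr$probe_index, after_sampling_index = idx,
    probe_agent = pr$probe_agent,
    o = ifelse(idx > 0, o_run[pmax(idx, 1)], initial),
    before_first_outcome = flagged
  )
}

probe_pairs <- function(responses, sequence, weight, initial) {
  o_self <- recency_weighted_outcomes(sequence, "self", weight, initial)
  o_other <- recency_weighted_outcomes(sequence, "other", weight, initial)
  pr <- probe_trials(sequence)
  if (nrow(responses) != nrow(pr)) {
    abort(sprintf("Got %d responses for %d probes.", nrow(responses), nrow(pr)),
          class = "pfbt_domain_error")
  }
  o_probed <- ifelse(pr$probe_agent == "self", o_self$o, o_other$o)
  tibble::tibble(
    probe_index = pr$probe_index, probe_agent = pr$probe_agent,
    o_self = o_self$o, o_other = o_other$o,
    o_probed = o_probed,
    response = responses$response
  )
}

safe_cor <- function(x, y, min_n = 3) {
  if (length(x) < min_n || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Model-free outcome-belief correlations
#'
#' Pearson correlations between recency-weighted outcome averages and
#' reported beliefs, computed on probe-aligned pairs:
#' * `performance`: pooled over all probes, each paired with the probed
#'   agent's own outcome average (the per-participant task-performance
#'   statistic);
#' * `within_self` / `within_other`: \eqn{(O^{Self}, B^{Self})} on Self
#'   probes and \eqn{(O^{Other}, B^{Other})} on Other probes;
#' * `idiocentric`: \eqn{(O^{Self}, B^{Other})} on Other probes — outcomes
#'   seen by Self leaking into beliefs attributed to the Other;
#' * `allocentric`: \eqn{(O^{Other}, B^{Self})} on Self probes.
#'
#' Correlations with fewer than 3 pairs or zero variance on either side are
#' `NA` (undefined), never silently 0.
#'
#' @param responses A response table aligned to the sequence's probes.
#' @inheritParams recency_weighted_outcomes
#' @return A one-row tibble with the five correlations and the pair counts.
#' @export
outcome_belief_correlations <- function(responses, sequence, weight = 0.1,
                                        initial = 0.5) {
  pairs <- probe_pairs(responses, sequence, weight, initial)
  s <- pairs[pairs$probe_agent == "self", ]
  o <- pairs[pairs$probe_agent == "other", ]
  tibble::tibble(
    performance = safe_cor(pairs$o_probed, pairs$response),
    within_self = safe_cor(s$o_self, s$response),
    within_other = safe_cor(o$o_other, o$response),
    idiocentric = safe_cor(o$o_self, o$response),
    allocentric = safe_cor(s$o_other, s$response),
    n_self_probes = nrow(s), n_other_probes = nrow(o)
  )
}

#' Null distribution of the performance statistic under random responding
#'
#' Simulates `n_sims` sets of uniform random responses on the sequence's
#' probe schedule and recomputes the pooled outcome-belief correlation for
#' each, giving the chance-level reference distribution for that sequence.
#'
#' @inheritParams outcome_belief_correlations
#' @param n_sims Number of simulated random-response sets (default 1000).
#' @param seed Integer seed.
#' @return A list: `draws` (the simulated correlations), `mean`, `sd`,
#'   `p95` (95th percentile), `n_sims`.
#' @export
null_distribution <- function(sequence, n_sims = 1000, seed = 1L,
                              weight = 0.1, initial = 0.5) {
  if (n_sims < 100) {
    abort("`n_sims` must be at least 100.", class = "pfbt_domain_error")
  }
  pr <- probe_trials(sequence)
  o_probed <- probe_pairs(
    tibble::tibble(response = rep(0.5, nrow(pr))), sequence, weight, initial
  )$o_probed
  withr::local_seed(seed)
  R <- matrix(runif(nrow(pr) * n_sims), nrow(pr), n_sims)
  draws <- suppressWarnings(as.vector(cor(o_probed, R)))
  list(draws = draws, mean = mean(draws), sd = sd(draws),
       p95 = quantile(draws, 0.95, names = FALSE), n_sims = n_sims)
}

#' Null-referenced task performance
#'
#' Expresses the raw pooled outcome-belief correlation relative to the
#' random-responding null for the same sequence: the score is the raw
#' statistic minus the null mean, so zero indicates chance-level responding.
#' A participant counts as above chance only when the raw statistic exceeds
#' the null's 95th percentile.
#'
#' @inheritParams outcome_belief_correlations
#' @param null A [null_distribution()] for the same sequence (computed here
#'   when `NULL`).
#' @param n_sims,seed Used when `null` is `NULL`.
#' @return A one-row tibble: `raw`, `score`, `above_chance`, `null_mean`,
#'   `null_sd`, `null_p95`.
#' @export
relative_performance <- function(responses, sequence, null = NULL,
                                 n_sims = 1000, seed = 1L, weight = 0.1,
                                 initial = 0.5) {
  null <- null %||% null_distribution(sequence, n_sims, seed, weight, initial)
  raw <- outcome_belief_correlations(responses, sequence, weight,
                                     initial)$performance
  tibble::tibble(
    raw = raw, score = raw - null$mean,
    above_chance = !is.na(raw) && raw > null$p95,
    null_mean = null$mean, null_sd = null$sd, null_p95 = null$p95
  )
}

#' Full model-free metric report for one participant
#'
#' Bundles [outcome_belief_correlations()] and [relative_performance()] into
#' the per-participant metric row used by the study harness.
#'
#' @inheritParams relative_performance
#' @return A one-row tibble combining the correlation metrics with the
#'   null-referenced performance score.
#' @export
task_metrics <- function(responses, sequence, n_sims = 1000, seed = 1L,
                         weight = 0.1, initial = 0.5) {
  cors <- outcome_belief_correlations(responses, sequence, weight, initial)
  perf <- relative_performance(responses, sequence, n_sims = n_sims,
                               seed = seed, weight = weight, initial = initial)
  dplyr::bind_cols(
    dplyr::rename(perf, performance_raw = "raw", performance_score = "score"),
    dplyr::select(cors, -"performance")
  )
}
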