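#' Model parameters for the dual-agent leakage learner
#'
#' The learner maintains two beliefs about the drifting outcome probability:
#' the subject's own belief \eqn{B^{Self}} and the belief the subject
#' attributes to the other agent, \eqn{B^{Other}}. On each sampling trial both
#' are updated by their own prediction error plus a *leaked* fraction of the
#' other agent's prediction error:
#' \deqn{B^{Self}_t = B^{Self}_{t-1} + \alpha^{Self}(PE^{Self}_t +
#'   \lambda^{Other} PE^{Other}_t) + \delta(0.5 - B^{Self}_{t-1})}
#' \deqn{B^{Other}_t = B^{Other}_{t-1} + \alpha^{Other}(PE^{Other}_t +
#'   \lambda^{Self} PE^{Self}_t) + \delta(0.5 - B^{Other}_{t-1})}
#' with beliefs clipped to \eqn{[0, 1]} after each update.
#'
#' @param alpha Learning rate in (0, 1) for the Self belief (and for Other
#'   when `alpha_other` is `NULL`, the shared-learning-rate case).
#' @param delta Memory decay rate in (0, 1): beliefs drift towards chance
#'   level 0.5 on every sampling trial.
#' @param tau Response variance of the Beta likelihood, in (0.001, 0.08).
#'   The upper bound produces a near-uniform Beta, i.e. random responding.
#' @param lambda_self Idiocentric leakage in (-1, 1): how much the subject's
#'   own prediction errors update the belief attributed to the Other.
#' @param lambda_other Allocentric leakage in (-1, 1): how much the Other's
#'   prediction errors update the subject's own belief.
#' @param alpha_other Optional separate learning rate for the Other belief.
#' @return A list of class `pfbt_params`.
#' @export
model_params <- function(alpha = 0.1, delta = 0.05, tau = 0.02,
                         lambda_self = 0, lambda_other = 0,
                         alpha_other = NULL) {
  p <- list(alpha = alpha, delta = delta, tau = tau,
            lambda_self = lambda_self, lambda_other = lambda_other,
            alpha_other = alpha_other %||% alpha)
  validate_params(p)
  structure(p, class = "pfbt_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_params <- function(p) {
  chk <- function(x, lo, hi, name, closed = FALSE) {
    bad <- !is.numeric(x) || length(x) != 1 || is.na(x) ||
      (if (closed) x < lo || x > hi else x <= lo || x >= hi)
    if (bad) {
      abort(sprintf("`%s` must lie in %s%g, %g%s.", name,
                    if (closed) "[" else "(", lo, hi,
                    if (closed) "]" else ")"),
            class = "pfbt_domain_error")
    }
  }
  chk(p$alpha, 0, 1, "alpha")
  chk(p$alpha_other, 0, 1, "alpha_other")
  chk(p$delta, -1e-12, 1, "delta")       # delta = 0 (no decay) is admissible
  chk(p$tau, 0.001, 0.08, "tau", closed = TRUE)
  chk(p$lambda_self, -1, 1, "lambda_self")
  chk(p$lambda_other, -1, 1, "lambda_other")
  invisible(p)
}

#' Specify one of the six model variants
#'
#' The model set crosses three leakage patterns with two learning-rate
#' patterns: leakage unrestricted (\eqn{\lambda^{Self}} and
#' \eqn{\lambda^{Other}} free), symmetric
#' (\eqn{\lambda^{Self}=\lambda^{Other}}), or zero (fully agent-specific);
#' learning rate shared across agents or free per agent.
#'
#' @param leakage One of `"unrestricted"`, `"symmetric"`, `"zero"`.
#' @param learning_rate One of `"shared"`, `"per_agent"`.
#' @return A list of class `pfbt_spec` with a `label` and the free-parameter
#'   names in fitting order.
#' @export
model_spec <- function(leakage = c("unrestricted", "symmetric", "zero"),
                       learning_rate = c("shared", "per_agent")) {
  leakage <- match.arg(leakage)
  learning_rate <- match.arg(learning_rate)
  lr_terms <- if (learning_rate == "shared") "alpha" else c("alpha", "alpha_other")
  lk_terms <- switch(leakage, unrestricted = c("lambda_self", "lambda_other"),
                     symmetric = "lambda", zero = character(0))
  structure(
    list(leakage = leakage, learning_rate = learning_rate,
         terms = c(lr_terms, "delta", "tau", lk_terms),
         label = paste(leakage, learning_rate, sep = "_")),
    class = "pfbt_spec"
  )
}

#' The six-model set
#'
#' @return A tibble with one row per model variant: `label`, `leakage`,
#'   `learning_rate`, `n_params`, and the `spec` object as a list column.
#' @export
model_set <- function() {
  grid <- tidyr::expand_grid(
    leakage = c("unrestricted", "symmetric", "zero"),
    learning_rate = c("shared", "per_agent")
  )
  grid |>
    dplyr::mutate(
      spec = purrr::map2(.data$leakage, .data$learning_rate, model_spec),
      label = purrr::map_chr(.data$spec, "label"),
      n_params = purrr::map_int(.data$spec, ~ length(.x$terms))
    ) |>
    dplyr::select("label", "leakage", "learning_rate", "n_params", "spec")
}

type_codes <- function(trial_type) {
  code <- match(trial_type, c("shared", "privileged", "decoy")) - 1L
  if (anyNA(code)) {
    abort("trial_type must be shared, privileged or decoy.",
          class = "pfbt_domain_error")
  }
  code
}

#' Agent-specific prediction errors
#'
#' \eqn{PE^{Self} = outcome - B^{Self}} except on decoy trials (the subject
#' knows the decoy sample is uninformative, so \eqn{PE^{Self} = 0});
#' \eqn{PE^{Other} = outcome - B^{Other}} except on privileged trials (the
#' other agent does not see the sample, so \eqn{PE^{Other} = 0}).
#'
#' @param b_self,b_other Current beliefs in \eqn{[0, 1]}.
#' @param outcome Binary outcome (1 = umbrella, 0 = sunshade).
#' @param trial_type `"shared"`, `"privileged"` or `"decoy"` (vectorised).
#' @return A tibble with columns `pe_self`, `pe_other`.
#' @export
prediction_errors <- function(b_self, b_other, outcome, trial_type) {
  code <- type_codes(trial_type)
  tibble::tibble(
    pe_self = ifelse(code == 2L, 0, outcome - b_self),
    pe_other = ifelse(code == 1L, 0, outcome - b_other)
  )
}

#' One belief update
#'
#' Applies the dual-agent update described in [model_params()] for a single
#' sampling trial, from the pre-trial belief state.
#'
#' @inheritParams prediction_errors
#' @param params A [model_params()].
#' @return A one-row tibble: `b_self`, `b_other` (post-update, clipped to
#'   \eqn{[0,1]}), `pe_self`, `pe_other`.
#' @examples
#' update_beliefs(0.5, 0.5, outcome = 1, trial_type = "shared",
#'                params = model_params(alpha = 0.1, delta = 0.001))
#' @export
update_beliefs <- function(b_self, b_other, outcome, trial_type, params) {
  validate_params(params)
  pe <- prediction_errors(b_self, b_other, outcome, trial_type)
  new_self <- b_self + params$alpha * (pe$pe_self + params$lambda_other * pe$pe_other) +
    params$delta * (0.5 - b_self)
  new_other <- b_other + params$alpha_other * (pe$pe_other + params$lambda_self * pe$pe_self) +
    params$delta * (0.5 - b_other)
  tibble::tibble(b_self = clamp01(new_self), b_other = clamp01(new_other),
                 pe_self = pe$pe_self, pe_other = pe$pe_other)
}

#' Simulate a belief trajectory over a task sequence
#'
#' Runs the dual-agent learner deterministically over the sampling trials of
#' a sequence, from the initial state (0.5, 0.5) unless overridden.
#'
#' @param sequence A `pfbt_sequence` (or data frame with its schema).
#' @param params A [model_params()].
#' @param init Initial beliefs `c(b_self, b_other)`. Default chance level.
#' @return A tibble of class `pfbt_trajectory`, one row per sampling trial:
#'   `sampling_index`, `trial_type`, `outcome`, `b_self`, `b_other`
#'   (post-update), `pe_self`, `pe_other`.
#' @export
simulate_trajectory <- function(sequence, params, init = c(0.5, 0.5)) {
  validate_params(params)
  st <- sampling_trials(sequence)
  if (nrow(st) == 0) {
    abort("Sequence contains no sampling trials.", class = "pfbt_domain_error")
  }
  m <- cpp_trajectory(as.integer(st$outcome), type_codes(st$trial_type),
                      params$alpha, params$alpha_other, params$delta,
                      params$lambda_self, params$lambda_other,
                      init[1], init[2])
  out <- tibble::tibble(
    sampling_index = st$sampling_index, trial_type = st$trial_type,
    outcome = st$outcome, b_self = m[, 1], b_other = m[, 2],
    pe_self = m[, 3], pe_other = m[, 4]
  )
  attr(out, "params") <- params
  attr(out, "init") <- init
  class(out) <- c("pfbt_trajectory", class(out))
  out
}

#' Simulate probe responses from model-derived beliefs
#'
#' For each probe trial, draws a response from the Beta distribution whose
#' mode is the probed agent's current model belief and whose variance is
#' `tau` (see [beta_shapes()]).
#'
#' @inheritParams simulate_trajectory
#' @param seed Integer seed; draws are reproducible given the seed.
#' @param trajectory Optionally, a precomputed [simulate_trajectory()] result
#'   for this sequence and `params`.
#' @param eps Modes are clamped into `[eps, 1 - eps]` so the Beta mode stays
#'   interior. Default `1e-4`.
#' @return A tibble with one row per probe: `probe_index`,
#'   `after_sampling_index`, `probe_agent`, `belief` (the Beta mode used) and
#'   `response` in \eqn{[0, 1]}.
#' @export
simulate_responses <- function(sequence, params, seed = NULL,
                               trajectory = NULL, eps = 1e-4) {
  validate_params(params)
  traj <- trajectory %||% simulate_trajectory(sequence, params)
  pr <- probe_trials(sequence)
  belief_at <- function(idx, agent) {
    col <- if (agent == "self") traj$b_self else traj$b_other
    init <- attr(traj, "init") %||% c(0.5, 0.5)
    if (idx > 0) col[idx] else if (agent == "self") init[1] else init[2]
  }
  modes <- clamp01(purrr::map2_dbl(pr$after_sampling_index, pr$probe_agent,
                                   belief_at), eps)
  shapes <- beta_shapes(modes, rep(params$tau, length(modes)))
  if (!is.null(seed)) withr::local_seed(seed)
  tibble::tibble(
    probe_index = pr$probe_index,
    after_sampling_index = pr$after_sampling_index,
    probe_agent = pr$probe_agent,
    belief = modes,
    response = rbeta(length(modes), shapes$shape1, shapes$shape2)
  )
}

#' Write / read a probe-response table
#'
#' The response CSV schema is `probe_index, probe_agent, response` with
#' `response` in \eqn{[0, 1]}.
#'
#' @param responses A tibble with at least those columns.
#' @param path CSV file path.
#' @export
write_responses <- function(responses, path) {
  readr::write_csv(responses[, c("probe_index", "probe_agent", "response")],
                   path)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          probe_index = readr::col_integer(),
                          probe_agent = readr::col_character(),
                          response = readr::col_double()
                        ))
  bad <- which(df$response < 0 | df$response > 1)
  if (length(bad)) {
    abort(sprintf("response must lie in [0, 1]; row %d has %g.",
                  bad[1], df$response[bad[1]]),
          class = "pfbt_validation_error")
  }
  df
}
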