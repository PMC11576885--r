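#' Beta shape parameters from mode and variance
#'
#' Solves for the `shape1`, `shape2` of a Beta distribution with the given
#' interior mode and variance, constrained to shapes >= 1 so that the mode is
#' unique and interior. Writing `shape1 = 1 + m*k`, `shape2 = 1 + (1-m)*k`
#' fixes the mode at `m` for every `k >= 0` while the variance falls
#' monotonically from 1/12 (the uniform, `k = 0`) towards 0; the unique `k`
#' is found by bisection. Variances at or above 1/12 have no shapes >= 1
#' solution and are shrunk to the feasible maximum, recorded in the `shrunk`
#' column.
#'
#' @param mode Vector of modes in \eqn{(0, 1)} (clamp with `eps` upstream).
#' @param variance Vector of variances in \eqn{(0, 1/12)}.
#' @return A tibble with columns `shape1`, `shape2`, `shrunk`.
#' @examples
#' beta_shapes(0.5, 0.04) # shape1 = shape2 = 2.625
#' @export
beta_shapes <- function(mode, variance) {
  n <- max(length(mode), length(variance))
  if (length(variance) == 1) variance <- rep(variance, n)
  if (length(mode) == 1) mode <- rep(mode, n)
  if (length(mode) != length(variance)) {
    abort("`mode` and `variance` must have equal length.",
          class = "pfbt_domain_error")
  }
  if (any(mode <= 0 | mode >= 1)) {
    abort("`mode` must lie strictly inside (0, 1).", class = "pfbt_domain_error")
  }
  if (any(variance <= 0)) {
    abort("`variance` must be positive.", class = "pfbt_domain_error")
  }
  res <- cpp_beta_shapes(mode, variance)
  tibble::tibble(shape1 = res$shape1, shape2 = res$shape2,
                 shrunk = res$shrunk)
}

#' Log-likelihood of probe responses under the Beta response model
#'
#' Sums, over probes, the log Beta density of each response, where the Beta
#' mode is the probed agent's model-derived belief at that probe and the
#' variance is `params$tau`. Responses and modes are clamped into
#' `[eps, 1 - eps]`.
#'
#' @param responses A tibble with `after_sampling_index`, `probe_agent`,
#'   `response` (as produced by [simulate_responses()], or aligned to
#'   [probe_trials()] of the sequence).
#' @param trajectory A [simulate_trajectory()] result.
#' @param params A [model_params()] (only `tau` is used here; the beliefs
#'   come from `trajectory`).
#' @param eps Clamping width. Default `1e-4`.
#' @return A finite scalar log-likelihood.
#' @export
response_loglik <- function(responses, trajectory, params, eps = 1e-4) {
  validate_params(params)
  init <- attr(trajectory, "init") %||% c(0.5, 0.5)
  if (any(responses$after_sampling_index > nrow(trajectory))) {
    abort("Responses refer to sampling trials beyond the trajectory.",
          class = "pfbt_domain_error")
  }
  agent <- match(responses$probe_agent, c("self", "other"))
  if (anyNA(agent)) {
    abort("probe_agent must be 'self' or 'other'.", class = "pfbt_domain_error")
  }
  idx <- responses$after_sampling_index
  modes <- ifelse(agent == 1,
                  ifelse(idx > 0, trajectory$b_self[pmax(idx, 1)], init[1]),
                  ifelse(idx > 0, trajectory$b_other[pmax(idx, 1)], init[2]))
  modes <- clamp01(modes, eps)
  shapes <- beta_shapes(modes, params$tau)
  x <- clamp01(responses$response, eps)
  sum(stats::dbeta(x, shapes$shape1, shapes$shape2, log = TRUE))
}

# ---- parameter transforms --------------------------------------------------

# Each natural parameter maps to the unconstrained real line through a scaled
# logistic: alpha, delta via plogis onto (0,1); tau via affine-scaled plogis
# onto (0.001, 0.08); lambda via 2*plogis - 1 onto (-1, 1).
transform_table <- function() {
  tibble::tribble(
    ~term, ~lo, ~hi,
    "alpha", 0, 1,
    "alpha_other", 0, 1,
    "delta", 0, 1,
    "tau", 0.001, 0.08,
    "lambda", -1, 1,
    "lambda_self", -1, 1,
    "lambda_other", -1, 1
  )
}

#' Map unconstrained parameters to their natural scale (and back)
#'
#' Fitting happens on the unconstrained (inverse-sigmoid) scale;
#' `to_natural()` applies the scaled logistic `lo + (hi - lo) * plogis(x)`
#' per term and `to_unconstrained()` inverts it.
#'
#' @param x Named numeric vector (names from the model terms: `alpha`,
#'   `alpha_other`, `delta`, `tau`, `lambda`, `lambda_self`, `lambda_other`).
#' @return A named numeric vector of the same length.
#' @export
to_natural <- function(x) {
  tab <- transform_table()
  i <- match(names(x), tab$term)
  if (anyNA(i)) {
    abort("Unknown parameter name(s) in `x`.", class = "pfbt_domain_error")
  }
  setNames(tab$lo[i] + (tab$hi[i] - tab$lo[i]) * plogis(x), names(x))
}

#' @rdname to_natural
#' @export
to_unconstrained <- function(x) {
  tab <- transform_table()
  i <- match(names(x), tab$term)
  if (anyNA(i)) {
    abort("Unknown parameter name(s) in `x`.", class = "pfbt_domain_error")
  }
  setNames(qlogis((x - tab$lo[i]) / (tab$hi[i] - tab$lo[i])), names(x))
}

# Expand a free-parameter vector (natural scale, names = spec$terms) into a
# full pfbt_params honouring the model variant's constraints.
expand_params <- function(nat, spec) {
  lam <- switch(spec$leakage,
                unrestricted = c(nat[["lambda_self"]], nat[["lambda_other"]]),
                symmetric = rep(nat[["lambda"]], 2),
                zero = c(0, 0))
  a_other <- if (spec$learning_rate == "per_agent") nat[["alpha_other"]] else nat[["alpha"]]
  list(alpha = nat[["alpha"]], alpha_other = a_other, delta = nat[["delta"]],
       tau = nat[["tau"]], lambda_self = lam[1], lambda_other = lam[2])
}

#' Gaussian priors on the unconstrained scale
#'
#' Weakly informative independent Normal priors over each free parameter on
#' its unconstrained scale. The default N(0, 1) centres alpha and delta at
#' 0.5, tau at mid-range and lambda at 0 (agent-specific updating).
#'
#' @param spec A [model_spec()].
#' @param mean,sd Scalars or vectors recycled over the spec's free terms.
#' @return A tibble with columns `term`, `mean`, `sd`.
#' @export
prior_spec <- function(spec = model_spec(), mean = 0, sd = 1) {
  if (any(sd <= 0)) abort("Prior SDs must be positive.",
                          class = "pfbt_domain_error")
  tibble::tibble(term = spec$terms,
                 mean = rep_len(mean, length(spec$terms)),
                 sd = rep_len(sd, length(spec$terms)))
}

# ---- MAP optimisation ------------------------------------------------------

#' Multi-start quasi-Newton maximisation of a log-posterior
#'
#' Generic workhorse behind [fit_map()]: minimises `-log_post(x)` by BFGS
#' with numerical gradients from `n_restarts` start points (the first is
#' `start`; the rest are drawn N(`start`, `start_sd`)), returning the best
#' optimum with its numerically evaluated Hessian (curvature of the negative
#' log-posterior).
#'
#' @param log_post Function of a numeric vector returning a scalar
#'   log-posterior density.
#' @param start Numeric start vector.
#' @param n_restarts Number of starts. Default 10.
#' @param start_sd SD of the random restart displacement.
#' @param seed Integer seed making the restarts reproducible.
#' @param reltol Convergence tolerance passed to [stats::optim()].
#' @param maxit Iteration cap per start.
#' @return A list: `par`, `value` (log-posterior at optimum), `hessian`,
#'   `converged`, `n_restarts_used`.
#' @export
map_optimize <- function(log_post, start, n_restarts = 10, start_sd = 1,
                         seed = 1L, reltol = 1e-8, maxit = 500) {
  d <- length(start)
  withr::local_seed(seed)
  m1 <- n_restarts - 1
  sdv <- rep_len(start_sd, d)
  starts <- rbind(start,
                  if (m1 > 0) {
                    matrix(stats::rnorm(m1 * d, rep(start, each = m1),
                                        rep(sdv, each = m1)), m1, d)
                  })
  neg <- function(x) -log_post(x)
  best <- NULL
  n_ok <- 0L
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], neg, method = "BFGS",
            control = list(reltol = reltol, maxit = maxit)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    abort("All optimisation restarts failed.", class = "pfbt_fit_error")
  }
  H <- tryCatch(optimHess(best$par, neg), error = function(e) NULL)
  list(par = best$par, value = -best$value, hessian = H,
       converged = best$convergence == 0, n_restarts_used = n_ok)
}

#' Laplace approximation to the log model evidence
#'
#' \eqn{\log p(y) \approx \log p(y, \hat\theta) + (d/2)\log 2\pi -
#' \tfrac{1}{2}\log\det H}, where \eqn{\hat\theta} is the MAP and \eqn{H}
#' the curvature (negative Hessian of the log-posterior) there. Exact when
#' the posterior is Gaussian.
#'
#' @param log_posterior Log joint density (likelihood times prior) at the MAP.
#' @param hessian Curvature matrix at the MAP (positive definite).
#' @return Scalar log evidence, or `NA` with attribute `reason` if the
#'   curvature is not positive definite.
#' @export
laplace_evidence <- function(log_posterior, hessian) {
  d <- nrow(hessian)
  ch <- tryCatch(chol(hessian), error = function(e) NULL)
  if (is.null(ch)) {
    return(structure(NA_real_, reason = "curvature not positive definite"))
  }
  log_posterior + d / 2 * log(2 * pi) - sum(log(diag(ch)))
}

#' Fit the dual-agent model by maximum a posteriori estimation
#'
#' Maximises, on the unconstrained scale, the sum of the Beta response
#' log-likelihood ([response_loglik()]) and the Gaussian log-prior
#' ([prior_spec()]), using multi-start BFGS. The Laplace approximation of
#' the log model evidence is computed at the optimum; if the curvature there
#' is not positive definite, a BIC-style evidence
#' (loglik - d/2 log n_probes) is substituted with a warning.
#'
#' @param sequence A `pfbt_sequence`.
#' @param responses Probe responses aligned to the sequence's probes: either
#'   a [simulate_responses()] table, or a `probe_index, probe_agent,
#'   response` table as read by [read_responses()] (alignment by probe
#'   order; agents must match the sequence).
#' @param spec A [model_spec()] selecting the variant to fit.
#' @param prior A [prior_spec()] for the variant.
#' @param n_restarts,seed,reltol,maxit Passed to [map_optimize()].
#' @param eps Response/mode clamping width.
#' @return An object of class `pfbt_fit`: MAP estimates on both scales, the
#'   log-posterior, log-likelihood, Hessian log-determinant and log model
#'   evidence, plus convergence diagnostics. Use [tidy()] and [glance()] to
#'   extract tabular summaries.
#' @export
fit_map <- function(sequence, responses, spec = model_spec(),
                    prior = prior_spec(spec), n_restarts = 10, seed = 1L,
                    reltol = 1e-8, maxit = 500, eps = 1e-4) {
  stopifnot(inherits(spec, "pfbt_spec"))
  if (!identical(prior$term, spec$terms)) {
    abort("`prior` terms must match the model spec's free parameters.",
          class = "pfbt_domain_error")
  }
  pr <- probe_trials(sequence)
  responses <- align_responses(responses, pr)
  st <- sampling_trials(sequence)
  out_i <- as.integer(st$outcome)
  type_i <- type_codes(st$trial_type)
  agent_i <- match(responses$probe_agent, c("self", "other")) - 1L
  after_i <- as.integer(responses$after_sampling_index)
  resp <- responses$response
  d <- length(spec$terms)

  log_post <- function(x) {
    nat <- to_natural(setNames(x, spec$terms))
    p <- expand_params(nat, spec)
    ll <- cpp_response_loglik(out_i, type_i, after_i, agent_i, resp,
                              p$alpha, p$alpha_other, p$delta,
                              p$lambda_self, p$lambda_other, p$tau,
                              0.5, 0.5, eps)
    ll + sum(dnorm(x, prior$mean, prior$sd, log = TRUE))
  }

  opt <- map_optimize(log_post, start = prior$mean, n_restarts = n_restarts,
                      start_sd = prior$sd, seed = seed, reltol = reltol,
                      maxit = maxit)
  map_u <- setNames(opt$par, spec$terms)
  nat <- to_natural(map_u)
  full <- expand_params(nat, spec)
  ll_map <- log_post(opt$par) - sum(dnorm(opt$par, prior$mean, prior$sd, log = TRUE))

  log_ev <- if (!is.null(opt$hessian)) laplace_evidence(opt$value, opt$hessian) else
    structure(NA_real_, reason = "Hessian evaluation failed")
  hessian_logdet <- NA_real_
  evidence_method <- "laplace"
  if (is.na(log_ev)) {
    warn(paste0("Curvature at the MAP is not positive definite; ",
                "falling back to BIC-style evidence."),
         class = "pfbt_evidence_warning")
    log_ev <- ll_map - d / 2 * log(max(nrow(responses), 1L))
    evidence_method <- "bic"
  } else {
    hessian_logdet <- 2 * sum(log(diag(chol(opt$hessian))))
  }

  structure(
    list(spec = spec, prior = prior, map_unconstrained = map_u,
         map_params = do.call(model_params, full[c("alpha", "delta", "tau",
                                                   "lambda_self", "lambda_other",
                                                   "alpha_other")]),
         map_free_natural = nat, log_posterior = opt$value,
         log_lik = ll_map, log_evidence = as.numeric(log_ev),
         evidence_method = evidence_method, hessian = opt$hessian,
         hessian_logdet = hessian_logdet, n_probes = nrow(responses),
         n_restarts_used = opt$n_restarts_used, converged = opt$converged,
         seed = seed),
    class = "pfbt_fit"
  )
}

# Align a response table with the sequence's probe list. Accepts tables that
# already carry after_sampling_index, or plain probe_index/probe_agent/
# response tables which are matched to probes by order.
align_responses <- function(responses, probes) {
  if (nrow(responses) != nrow(probes)) {
    abort(sprintf("Got %d responses for %d probes.", nrow(responses),
                  nrow(probes)), class = "pfbt_domain_error")
  }
  if (nrow(responses) == 0) {
    return(tibble::tibble(after_sampling_index = integer(0),
                          probe_agent = character(0), response = numeric(0)))
  }
  if (!all(responses$probe_agent == probes$probe_agent)) {
    abort("Response probe_agent does not match the sequence's probe schedule.",
          class = "pfbt_domain_error")
  }
  tibble::tibble(after_sampling_index = probes$after_sampling_index,
                 probe_agent = probes$probe_agent,
                 response = responses$response)
}

#' @export
print.pfbt_fit <- function(x, ...) {
  cat("<pfbt_fit> model:", x$spec$label, "\n")
  est <- signif(unlist(x$map_free_natural), 4)
  cat(paste0("  ", names(est), " = ", est, collapse = "\n"), "\n")
  cat(sprintf("  log evidence = %.3f (%s), %d probes, converged: %s\n",
              x$log_evidence, x$evidence_method, x$n_probes, x$converged))
  invisible(x)
}
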