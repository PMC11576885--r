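#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a MAP fit
#'
#' @param x A `pfbt_fit`.
#' @param ... Unused.
#' @return One row per free parameter: `term`, `estimate` (natural scale),
#'   `unconstrained`.
#' @export
tidy.pfbt_fit <- function(x, ...) {
  tibble::tibble(term = x$spec$terms,
                 estimate = unname(unlist(x$map_free_natural[x$spec$terms])),
                 unconstrained = unname(x$map_unconstrained))
}

#' @rdname tidy.pfbt_fit
#' @return `glance()`: a one-row tibble of fit-level summaries.
#' @export
glance.pfbt_fit <- function(x, ...) {
  tibble::tibble(model = x$spec$label, n_params = length(x$spec$terms),
                 n_probes = x$n_probes, log_lik = x$log_lik,
                 log_posterior = x$log_posterior,
                 log_evidence = x$log_evidence,
                 evidence_method = x$evidence_method,
                 converged = x$converged,
                 n_restarts_used = x$n_restarts_used)
}

#' Tidy a random-effects model comparison
#'
#' @param x A `pfbt_bms`.
#' @param ... Unused.
#' @return One row per model: expected frequency, exceedance and protected
#'   exceedance probabilities.
#' @export
tidy.pfbt_bms <- function(x, ...) {
  tibble::tibble(model = x$models,
                 alpha = unname(x$alpha),
                 expected_frequency = unname(x$expected_frequency),
                 exceedance_probability = unname(x$exceedance_probability),
                 protected_exceedance_probability =
                   unname(x$protected_exceedance_probability))
}

#' @rdname tidy.pfbt_bms
#' @export
glance.pfbt_bms <- function(x, ...) {
  tibble::tibble(n_models = length(x$models),
                 n_participants = nrow(x$assignment_probability),
                 bayes_omnibus_risk = x$bayes_omnibus_risk,
                 free_energy_alternative = x$free_energy[["alternative"]],
                 free_energy_null = x$free_energy[["null"]],
                 n_iter = x$n_iter)
}

#' Tidy a parameter-recovery report
#'
#' @param x A `pfbt_recovery`.
#' @param ... Unused.
#' @return The full generative-by-fitted correlation matrix in long form:
#'   `generative`, `fitted`, `r`, `diagonal`.
#' @export
tidy.pfbt_recovery <- function(x, ...) {
  m <- x$correlations
  tibble::as_tibble(as.table(m), .name_repair = "minimal") |>
    setNames(c("generative", "fitted", "r")) |>
    dplyr::mutate(diagonal = .data$generative == .data$fitted)
}

#' @rdname tidy.pfbt_recovery
#' @export
glance.pfbt_recovery <- function(x, ...) {
  tibble::tibble(model = x$spec$label, n = nrow(x$estimates),
                 n_failed = x$n_failed,
                 r_lambda_self = x$diagonal_r[["lambda_self"]],
                 r_lambda_other = x$diagonal_r[["lambda_other"]],
                 r_alpha = x$diagonal_r[["alpha"]],
                 r_delta = x$diagonal_r[["delta"]],
                 r_tau = x$diagonal_r[["tau"]])
}
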