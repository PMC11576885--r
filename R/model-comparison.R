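as_evidence_matrix <- function(evidence) {
  E <- as.matrix(evidence)
  storage.mode(E) <- "double"
  if (ncol(E) < 2) {
    abort("Model comparison needs at least two models.",
          class = "pfbt_domain_error")
  }
  if (any(!is.finite(E))) {
    abort("Evidence matrix entries must be finite.",
          class = "pfbt_domain_error")
  }
  if (is.null(colnames(E))) colnames(E) <- paste0("model", seq_len(ncol(E)))
  E
}

#' Assemble an evidence matrix from per-participant fits
#'
#' @param fits A list of lists of `pfbt_fit` objects (one inner list per
#'   participant, one fit per model), or a long tibble with columns
#'   `participant`, `model`, `log_evidence`.
#' @return A participants-by-models numeric matrix of log evidences.
#' @export
evidence_matrix <- function(fits) {
  if (is.data.frame(fits)) {
    wide <- tidyr::pivot_wider(fits[, c("participant", "model", "log_evidence")],
                               names_from = "model",
                               values_from = "log_evidence")
    E <- as.matrix(wide[, -1, drop = FALSE])
    rownames(E) <- wide$participant
    return(as_evidence_matrix(E))
  }
  E <- t(vapply(fits, function(fl) {
    vapply(fl, function(f) f$log_evidence, numeric(1))
  }, numeric(length(fits[[1]]))))
  colnames(E) <- vapply(fits[[1]], function(f) f$spec$label, character(1))
  as_evidence_matrix(E)
}

#' Fixed-effects model comparison
#'
#' Sums log evidences over participants per model; the fixed-effect Bayes
#' factor for model i over model j is `exp(sum_i - sum_j)`.
#'
#' @param evidence A participants-by-models matrix (or data frame) of log
#'   evidences.
#' @return A list with `summed_log_evidence` (named vector), `log_bf` and
#'   `bf` (models-by-models matrices of pairwise log Bayes factors and Bayes
#'   factors), and `best_model`.
#' @examples
#' E <- cbind(a = c(-50, -50), b = c(-51, -52))
#' fixed_effects_compare(E)$bf["a", "b"] # exp(3)
#' @export
fixed_effects_compare <- function(evidence) {
  E <- as_evidence_matrix(evidence)
  s <- colSums(E)
  log_bf <- outer(s, s, "-")
  list(summed_log_evidence = s, log_bf = log_bf, bf = exp(log_bf),
       best_model = names(s)[which.max(s)])
}

#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across participants with a
#' Dirichlet prior on model frequencies, estimated by variational Bayes.
#' Reports expected model frequencies, exceedance probabilities (Monte Carlo
#' over the Dirichlet posterior), the Bayes omnibus risk (posterior
#' probability that all models are equally frequent, from the free-energy
#' comparison of the null and alternative hypotheses), and protected
#' exceedance probabilities `PXP = EP * (1 - BOR) + BOR / K`.
#'
#' @inheritParams fixed_effects_compare
#' @param alpha0 Dirichlet prior counts (scalar or length-K). Default 1
#'   (uniform prior over models).
#' @param n_draws Monte Carlo draws for the exceedance probabilities.
#' @param seed Seed for those draws.
#' @param tol,max_iter Convergence control of the variational iteration.
#' @return An object of class `pfbt_bms`: `alpha` (posterior Dirichlet
#'   counts), `expected_frequency`, `exceedance_probability`,
#'   `bayes_omnibus_risk`, `protected_exceedance_probability`,
#'   `assignment_probability` (participants x models), `free_energy`
#'   (alternative and null) and iteration diagnostics.
#' @export
random_effects_bms <- function(evidence, alpha0 = 1, n_draws = 1e6,
                               seed = 1L, tol = 1e-8, max_iter = 1e4) {
  E <- as_evidence_matrix(evidence)
  K <- ncol(E)
  n <- nrow(E)
  a0 <- rep_len(alpha0, K)
  alpha <- a0 + n / K
  g <- matrix(1 / K, n, K)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    elog_r <- digamma(alpha) - digamma(sum(alpha))
    u <- sweep(E, 2, elog_r, "+")
    u <- exp(u - apply(u, 1, max))
    g <- u / rowSums(u)
    alpha_new <- a0 + colSums(g)
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol) break
    if (iter >= max_iter) {
      abort(sprintf("Variational iteration did not converge in %d steps (last change %.3g).",
                    max_iter, delta), class = "pfbt_fit_error")
    }
  }
  r <- alpha / sum(alpha)

  # exceedance probabilities by Dirichlet Monte Carlo
  withr::local_seed(seed)
  draws <- matrix(rgamma(n_draws * K, shape = rep(alpha, each = n_draws)),
                  n_draws, K)
  ep <- tabulate(max.col(draws, ties.method = "first"), K) / n_draws

  # free energies of the alternative (estimated frequencies) and the null
  # (all frequencies fixed equal); BOR is the null's posterior probability.
  logC <- function(a) lgamma(sum(a)) - sum(lgamma(a))
  f1 <- sum(g * (E - log(pmax(g, 1e-300)))) + logC(a0) - logC(alpha)
  f0 <- sum(apply(E, 1, logsumexp) - log(K))
  bor <- 1 / (1 + exp(f1 - f0))
  pxp <- ep * (1 - bor) + bor / K

  structure(
    list(models = colnames(E), alpha = setNames(alpha, colnames(E)),
         expected_frequency = setNames(r, colnames(E)),
         exceedance_probability = setNames(ep, colnames(E)),
         bayes_omnibus_risk = bor,
         protected_exceedance_probability = setNames(pxp, colnames(E)),
         assignment_probability = g,
         free_energy = c(alternative = f1, null = f0),
         n_iter = iter, n_draws = n_draws, seed = seed),
    class = "pfbt_bms"
  )
}

#' @export
print.pfbt_bms <- function(x, ...) {
  cat("<pfbt_bms>", length(x$models), "models,",
      nrow(x$assignment_probability), "participants\n")
  df <- tibble::tibble(model = x$models,
                       expected_frequency = round(x$expected_frequency, 3),
                       pxp = round(x$protected_exceedance_probability, 3))
  print(df)
  cat(sprintf("Bayes omnibus risk: %.3f\n", x$bayes_omnibus_risk))
  invisible(x)
}

#' Best-fitting model counts across participants
#'
#' Counts, per model, how often it has the row-wise maximal evidence. Ties
#' are broken towards the model with fewer free parameters (the nested,
#' more parsimonious variant) and recorded in the `n_ties` attribute.
#'
#' @inheritParams fixed_effects_compare
#' @param n_params Optional named vector of free-parameter counts per model
#'   (defaults to the six-model set's counts when the column names match
#'   [model_set()] labels, else to column order).
#' @param tol Evidence differences below `tol` count as ties.
#' @return A tibble `model`, `n_params`, `count`, `proportion`.
#' @export
best_model_frequency <- function(evidence, n_params = NULL, tol = 1e-9) {
  E <- as_evidence_matrix(evidence)
  if (is.null(n_params)) {
    ms <- model_set()
    n_params <- if (all(colnames(E) %in% ms$label)) {
      setNames(ms$n_params, ms$label)[colnames(E)]
    } else {
      setNames(seq_len(ncol(E)), colnames(E))
    }
  }
  order_key <- rank(n_params, ties.method = "first")
  n_ties <- 0L
  winners <- apply(E, 1, function(row) {
    best <- which(row >= max(row) - tol)
    if (length(best) > 1) n_ties <<- n_ties + 1L
    best[which.min(order_key[best])]
  })
  counts <- tabulate(winners, ncol(E))
  structure(
    tibble::tibble(model = colnames(E), n_params = as.integer(n_params),
                   count = counts, proportion = counts / nrow(E)),
    n_ties = n_ties
  )
}
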