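# Independent reference implementations used as oracles. Deliberately naive
# (plain R loops, quadrature) and kept separate from the package's own code
# paths.

# Naive loop over the dual-agent update equations.
naive_trajectory <- function(trial_type, outcome, alpha, alpha_other, delta,
                             lambda_self, lambda_other,
                             b_self0 = 0.5, b_other0 = 0.5) {
  n <- length(outcome)
  bs <- b_self0
  bo <- b_other0
  out <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("b_self", "b_other", "pe_self", "pe_other")))
  for (t in seq_len(n)) {
    pe_s <- if (trial_type[t] == "decoy") 0 else outcome[t] - bs
    pe_o <- if (trial_type[t] == "privileged") 0 else outcome[t] - bo
    bs_new <- bs + alpha * (pe_s + lambda_other * pe_o) + delta * (0.5 - bs)
    bo_new <- bo + alpha_other * (pe_o + lambda_self * pe_s) + delta * (0.5 - bo)
    bs <- min(1, max(0, bs_new))
    bo <- min(1, max(0, bo_new))
    out[t, ] <- c(bs, bo, pe_s, pe_o)
  }
  out
}

# Log Beta density by quadrature normalisation of the kernel, avoiding
# dbeta()/lbeta().
quadrature_log_beta_density <- function(x, shape1, shape2) {
  kernel <- function(u) u^(shape1 - 1) * (1 - u)^(shape2 - 1)
  z <- stats::integrate(kernel, 0, 1, rel.tol = 1e-12)$value
  log(kernel(x)) - log(z)
}

# Mode of a Beta(shape1, shape2) by grid search over the density.
grid_beta_mode <- function(shape1, shape2, n_grid = 200001) {
  g <- seq(1e-6, 1 - 1e-6, length.out = n_grid)
  g[which.max(stats::dbeta(g, shape1, shape2))]
}

# Random sampling-trial table for property tests.
random_trial_table <- function(n) {
  tibble::tibble(
    trial_type = sample(c("shared", "privileged", "decoy"), n, replace = TRUE),
    outcome = sample(0:1, n, replace = TRUE)
  )
}

# Random valid model parameters (full range, including extremes).
random_params <- function() {
  model_params(
    alpha = runif(1, 0.01, 0.99), delta = runif(1, 0.001, 0.9),
    tau = runif(1, 0.0011, 0.0799),
    lambda_self = runif(1, -0.99, 0.99), lambda_other = runif(1, -0.99, 0.99),
    alpha_other = runif(1, 0.01, 0.99)
  )
}

# Wrap a bare sampling-trial table in the sequence schema (no probes).
as_sequence_df <- function(trials) {
  n <- nrow(trials)
  tibble::tibble(
    trial_index = seq_len(n), phase = "sampling",
    trial_type = trials$trial_type, outcome = as.integer(trials$outcome),
    probe_agent = NA_character_, p_self = 0.5, p_other = 0.5,
    walk_used = ifelse(trials$trial_type == "decoy", "other", "self")
  )
}
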