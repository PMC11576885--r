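test_that("beta shape solving matches the symmetric closed form", {
  # symmetric case: variance = 1 / (4 (2a + 1))
  sh <- beta_shapes(0.5, 0.04)
  expect_equal(sh$shape1, 2.625, tolerance = 1e-8)
  expect_equal(sh$shape2, 2.625, tolerance = 1e-8)
  sh <- beta_shapes(0.5, 0.08)
  expect_equal(sh$shape1, 1.0625, tolerance = 1e-8)
  expect_equal(sh$shape2, 1.0625, tolerance = 1e-8)
})

test_that("beta shapes reproduce mode and variance across a grid", {
  grid <- tidyr::expand_grid(mode = seq(0.05, 0.95, 0.05),
                             variance = c(0.001, 0.005, 0.02, 0.05, 0.08))
  sh <- beta_shapes(grid$mode, grid$variance)
  a <- sh$shape1
  b <- sh$shape2
  expect_true(all(a >= 1 & b >= 1))
  expect_false(any(sh$shrunk))
  expect_lt(max(abs((a - 1) / (a + b - 2) - grid$mode)), 1e-8)
  expect_lt(max(abs(a * b / ((a + b)^2 * (a + b + 1)) - grid$variance)), 1e-8)
})

test_that("solved shapes place the density maximum at the mode", {
  sh <- beta_shapes(0.7, 0.02)
  expect_lt(abs(grid_beta_mode(sh$shape1, sh$shape2) - 0.7), 1e-4)
})

test_that("infeasible variances are shrunk and flagged", {
  sh <- beta_shapes(0.5, 0.0832)  # just under 1/12, still feasible
  expect_false(sh$shrunk)
  sh <- beta_shapes(0.5, 0.09)
  expect_true(sh$shrunk)
  expect_error(beta_shapes(0.5, -0.1), class = "pfbt_domain_error")
  expect_error(beta_shapes(1.2, 0.02), class = "pfbt_domain_error")
})

fixed_trajectory <- function(b_self, b_other) {
  out <- tibble::tibble(b_self = b_self, b_other = b_other)
  attr(out, "init") <- c(0.5, 0.5)
  out
}

test_that("response log-likelihood matches a quadrature oracle", {
  traj <- fixed_trajectory(b_self = c(0.3, 0.55, 0.8),
                           b_other = c(0.6, 0.45, 0.2))
  resp <- tibble::tibble(after_sampling_index = 1:3,
                         probe_agent = c("self", "other", "self"),
                         response = c(0.35, 0.5, 0.7))
  p <- model_params(tau = 0.04)
  ll <- response_loglik(resp, traj, p)
  oracle <- sum(purrr::map_dbl(1:3, function(i) {
    mode <- c(0.3, 0.45, 0.8)[i]  # probed agent's belief
    sh <- beta_shapes(mode, 0.04)
    quadrature_log_beta_density(resp$response[i], sh$shape1, sh$shape2)
  }))
  expect_equal(ll, oracle, tolerance = 1e-6)
})

test_that("a response at the mode attains the per-probe density maximum", {
  traj <- fixed_trajectory(0.62, 0.4)
  p <- model_params(tau = 0.02)
  at_mode <- response_loglik(tibble::tibble(after_sampling_index = 1,
                                            probe_agent = "self",
                                            response = 0.62), traj, p)
  for (x in c(0.1, 0.4, 0.55, 0.7, 0.95)) {
    ll <- response_loglik(tibble::tibble(after_sampling_index = 1,
                                         probe_agent = "self", response = x),
                          traj, p)
    expect_lte(ll, at_mode)
  }
})

test_that("at the upper tau bound the likelihood is nearly flat", {
  traj <- fixed_trajectory(rep(0.5, 5), rep(0.5, 5))
  resp <- tibble::tibble(after_sampling_index = 1:5, probe_agent = "self",
                         response = c(0.05, 0.3, 0.5, 0.7, 0.95))
  ll <- response_loglik(resp, traj, model_params(tau = 0.08))
  expect_lt(abs(ll) / 5, 0.05)  # ~0 log density per probe, as for a uniform
})

test_that("log-likelihood is invariant to probe order", {
  seq <- generate_task_sequence(task_config(n_trials = 120), seed = 3)
  p <- model_params(alpha = 0.15, delta = 0.02, tau = 0.03,
                    lambda_self = 0.3)
  traj <- simulate_trajectory(seq, p)
  resp <- simulate_responses(seq, p, seed = 9)
  ll <- response_loglik(resp, traj, p)
  perm <- resp[sample(nrow(resp)), ]
  expect_equal(response_loglik(perm, traj, p), ll, tolerance = 1e-12)
})

test_that("misaligned responses are rejected", {
  seq <- generate_task_sequence(task_config(n_trials = 60), seed = 3)
  resp <- simulate_responses(seq, model_params(), seed = 1)
  expect_error(fit_map(seq, resp[-1, ]), class = "pfbt_domain_error")
  swapped <- resp
  swapped$probe_agent <- rev(swapped$probe_agent)
  if (!all(swapped$probe_agent == resp$probe_agent)) {
    expect_error(fit_map(seq, swapped), class = "pfbt_domain_error")
  }
})

test_that("parameter transforms round-trip at random points", {
  set.seed(23)
  terms <- c("alpha", "alpha_other", "delta", "tau", "lambda",
             "lambda_self", "lambda_other")
  for (i in 1:100) {
    x <- setNames(rnorm(length(terms), 0, 2), terms)
    nat <- to_natural(x)
    expect_equal(to_unconstrained(nat), x, tolerance = 1e-10)
  }
  # natural values respect the bounds
  x <- setNames(rnorm(7, 0, 10), terms)
  nat <- to_natural(x)
  expect_true(nat[["tau"]] > 0.001 && nat[["tau"]] < 0.08)
  expect_true(abs(nat[["lambda"]]) < 1)
})

test_that("with no data the MAP is the transformed prior mean", {
  cfg <- task_config(n_trials = 12, probe_gap = c(9L, 9L))
  seq <- generate_task_sequence(cfg, seed = 2)
  pr <- probe_trials(seq)
  # keep only sampling trials: a sequence with zero probes
  seq0 <- tibble::as_tibble(seq)[tibble::as_tibble(seq)$phase == "sampling", ]
  fit <- fit_map(seq0, tibble::tibble(probe_index = integer(0),
                                      probe_agent = character(0),
                                      response = numeric(0)),
                 n_restarts = 2)
  expect_equal(unname(fit$map_unconstrained), rep(0, 5), tolerance = 1e-4)
  expect_equal(fit$map_params$alpha, 0.5, tolerance = 1e-4)
  expect_equal(fit$map_params$lambda_self, 0, tolerance = 1e-4)
  # Laplace evidence of a pure standard-normal posterior is exact: log 1 = 0
  expect_equal(fit$log_evidence, 0, tolerance = 1e-4)
})

test_that("constrained variants fix their constrained parameters", {
  seq <- generate_task_sequence(task_config(n_trials = 120), seed = 6)
  gen <- model_params(alpha = 0.15, delta = 0.02, tau = 0.01,
                      lambda_self = 0.4, lambda_other = 0.4)
  resp <- simulate_responses(seq, gen, seed = 4)
  f0 <- fit_map(seq, resp, spec = model_spec("zero", "shared"),
                n_restarts = 3)
  expect_identical(f0$map_params$lambda_self, 0)
  expect_identical(f0$map_params$lambda_other, 0)
  fs <- fit_map(seq, resp, spec = model_spec("symmetric", "shared"),
                n_restarts = 3)
  expect_identical(fs$map_params$lambda_self, fs$map_params$lambda_other)
  fp <- fit_map(seq, resp, spec = model_spec("zero", "per_agent"),
                n_restarts = 3)
  expect_length(fp$spec$terms, 4)
})

test_that("fitting recovers strong leakage from low-noise data", {
  cfg <- task_config(n_trials = 360, probe_gap = c(4L, 5L))  # ~80 probes
  seq <- generate_task_sequence(cfg, seed = 17)
  gen <- model_params(alpha = 0.1, delta = 0.01, tau = 0.002,
                      lambda_self = 0.5)
  resp <- simulate_responses(seq, gen, seed = 18)
  fit <- fit_map(seq, resp, n_restarts = 5, seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$map_params$lambda_self - 0.5), 0.15)
  # deterministic given the seed
  fit2 <- fit_map(seq, resp, n_restarts = 5, seed = 1)
  expect_identical(fit$map_unconstrained, fit2$map_unconstrained)
})

test_that("Laplace evidence is exact for a Gaussian toy model", {
  # y ~ N(theta, 1), theta ~ N(0, 1): marginal y ~ N(0, 2)
  y <- 0.7
  log_post <- function(x) dnorm(y, x, 1, log = TRUE) + dnorm(x, 0, 1, log = TRUE)
  opt <- map_optimize(log_post, start = 0, n_restarts = 3, seed = 1)
  expect_equal(laplace_evidence(opt$value, opt$hessian),
               dnorm(y, 0, sqrt(2), log = TRUE), tolerance = 1e-6)
})

test_that("model evidence penalises complexity and conflicting data", {
  seq <- generate_task_sequence(task_config(n_trials = 180), seed = 30)
  gen <- model_params(alpha = 0.12, delta = 0.02, tau = 0.01)  # no leakage
  resp <- simulate_responses(seq, gen, seed = 31)
  fit_simple <- fit_map(seq, resp, spec = model_spec("zero", "shared"),
                        n_restarts = 4)
  fit_complex <- fit_map(seq, resp, spec = model_spec("unrestricted", "per_agent"),
                         n_restarts = 4)
  expect_lte(fit_complex$log_evidence, fit_simple$log_evidence)

  # duplicating a datum with a contradictory value lowers the evidence
  traj <- simulate_trajectory(seq, gen)
  base <- tibble::tibble(after_sampling_index = rep(10L, 1),
                         probe_agent = "self", response = 0.9)
  seq_small <- generate_task_sequence(task_config(n_trials = 60), seed = 8)
  r0 <- simulate_responses(seq_small, gen, seed = 2)
  f0 <- fit_map(seq_small, r0, n_restarts = 3)
  r_conf <- r0
  r_conf$response[1] <- 1 - r0$response[1]  # contradict probe 1
  f1 <- fit_map(seq_small, r_conf, n_restarts = 3)
  expect_lt(f1$log_evidence, f0$log_evidence)
})

test_that("tidy and glance summarise fits", {
  seq <- generate_task_sequence(task_config(n_trials = 60), seed = 3)
  resp <- simulate_responses(seq, model_params(), seed = 1)
  fit <- fit_map(seq, resp, n_restarts = 2)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "unconstrained"))
  expect_equal(td$term, fit$spec$terms)
  gl <- glance(fit)
  expect_equal(gl$n_probes, nrow(resp))
  expect_true(is.finite(gl$log_evidence))
})
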