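test_that("prediction errors are zeroed for the unobserving agent", {
  pe <- prediction_errors(0.5, 0.5, outcome = 1, trial_type = "shared")
  expect_equal(c(pe$pe_self, pe$pe_other), c(0.5, 0.5))
  pe <- prediction_errors(0.5, 0.9, outcome = 1, trial_type = "privileged")
  expect_equal(c(pe$pe_self, pe$pe_other), c(0.5, 0))
  pe <- prediction_errors(0.7, 0.6, outcome = 0, trial_type = "decoy")
  expect_equal(c(pe$pe_self, pe$pe_other), c(0, -0.6))
})

test_that("single belief updates reproduce hand-worked arithmetic", {
  # no leakage, no decay: symmetric step of alpha * PE
  u <- update_beliefs(0.5, 0.5, 1, "shared",
                      model_params(alpha = 0.1, delta = 0, tau = 0.02))
  expect_equal(c(u$b_self, u$b_other), c(0.55, 0.55))

  # idiocentric leakage: Other updated by lambda_self * PE_self
  u <- update_beliefs(0.5, 0.5, 1, "privileged",
                      model_params(alpha = 0.1, delta = 0, tau = 0.02,
                                   lambda_self = 0.8))
  expect_equal(c(u$b_self, u$b_other), c(0.55, 0.54))

  # negative allocentric leakage on a decoy trial
  u <- update_beliefs(0.7, 0.6, 0, "decoy",
                      model_params(alpha = 0.2, delta = 0, tau = 0.02,
                                   lambda_other = -0.5))
  expect_equal(c(u$b_self, u$b_other), c(0.76, 0.48))

  # pure decay towards chance for the non-observing agent
  u <- update_beliefs(0.5, 0.8, 1, "privileged",
                      model_params(alpha = 0.1, delta = 0.1, tau = 0.02))
  expect_equal(u$b_other, 0.77)
})

test_that("trajectories match the naive reference implementation", {
  set.seed(41)
  for (i in 1:25) {
    trials <- random_trial_table(n = sample(20:80, 1))
    p <- random_params()
    ref <- naive_trajectory(trials$trial_type, trials$outcome, p$alpha,
                            p$alpha_other, p$delta, p$lambda_self,
                            p$lambda_other)
    traj <- simulate_trajectory(as_sequence_df(trials), p)
    expect_lt(max(abs(traj$b_self - ref[, "b_self"])), 1e-12)
    expect_lt(max(abs(traj$b_other - ref[, "b_other"])), 1e-12)
    expect_lt(max(abs(traj$pe_self - ref[, "pe_self"])), 1e-12)
    expect_lt(max(abs(traj$pe_other - ref[, "pe_other"])), 1e-12)
  }
})

test_that("a five-trial sequence reproduces hand-computed beliefs exactly", {
  trials <- tibble::tibble(
    trial_type = c("shared", "privileged", "decoy", "shared", "privileged"),
    outcome = c(1L, 0L, 1L, 0L, 1L)
  )
  p <- model_params(alpha = 0.2, delta = 0.1, tau = 0.02,
                    lambda_self = 0.5, lambda_other = -0.25)
  traj <- simulate_trajectory(as_sequence_df(trials), p)
  expect_equal(traj$b_self,
               c(0.575, 0.4525, 0.436125, 0.388, 0.5216),
               tolerance = 1e-12)
  expect_equal(traj$b_other,
               c(0.65, 0.5775, 0.65425, 0.4643625, 0.52912625),
               tolerance = 1e-12)
})

test_that("beliefs stay in [0, 1] for extreme parameters and sequences", {
  set.seed(7)
  for (i in 1:20) {
    trials <- tibble::tibble(
      trial_type = sample(c("shared", "privileged", "decoy"), 200, TRUE),
      outcome = rep(sample(0:1, 1), 200)  # runs of identical outcomes
    )
    p <- model_params(alpha = 0.95, delta = 0.001, tau = 0.02,
                      lambda_self = sample(c(-0.99, 0.99), 1),
                      lambda_other = sample(c(-0.99, 0.99), 1))
    traj <- simulate_trajectory(as_sequence_df(trials), p)
    expect_true(all(traj$b_self >= 0 & traj$b_self <= 1))
    expect_true(all(traj$b_other >= 0 & traj$b_other <= 1))
  }
})

test_that("without leakage or decay the update is exactly Rescorla-Wagner", {
  set.seed(13)
  outcomes <- rbinom(300, 1, 0.8)
  trials <- tibble::tibble(trial_type = "shared", outcome = outcomes)
  alpha <- 0.15
  p <- model_params(alpha = alpha, delta = 0, tau = 0.02)
  traj <- simulate_trajectory(as_sequence_df(trials), p)
  # closed-form exponentially weighted average
  t_idx <- seq_along(outcomes)
  closed <- vapply(t_idx, function(t) {
    (1 - alpha)^t * 0.5 + alpha * sum((1 - alpha)^(t - seq_len(t)) * outcomes[seq_len(t)])
  }, numeric(1))
  expect_equal(traj$b_self, closed, tolerance = 1e-12)
  expect_equal(traj$b_other, closed, tolerance = 1e-12)
  # converges in mean to the outcome rate
  expect_lt(abs(mean(traj$b_self[200:300]) - mean(outcomes)), 0.1)
})

test_that("leakage moves the other agent's belief towards unseen outcomes", {
  trials <- tibble::tibble(trial_type = rep("privileged", 60),
                           outcome = rep(1L, 60))
  base <- simulate_trajectory(
    as_sequence_df(trials),
    model_params(alpha = 0.1, delta = 0, tau = 0.02, lambda_self = 0))
  leak <- simulate_trajectory(
    as_sequence_df(trials),
    model_params(alpha = 0.1, delta = 0, tau = 0.02, lambda_self = 0.6))
  expect_true(all(base$b_other == 0.5))        # PE_other zeroed throughout
  expect_true(all(diff(leak$b_other) > 0))     # strictly towards the outcomes
  # and symmetrically for allocentric leakage on decoy-only sequences
  trials <- tibble::tibble(trial_type = rep("decoy", 60), outcome = rep(0L, 60))
  leak2 <- simulate_trajectory(
    as_sequence_df(trials),
    model_params(alpha = 0.1, delta = 0, tau = 0.02, lambda_other = 0.6))
  expect_true(all(diff(leak2$b_self) < 0))
})

test_that("probe responses honour the Beta mode/variance contract", {
  cfg <- task_config(n_trials = 120)
  seq <- generate_task_sequence(cfg, seed = 21)

  # tau at the lower bound: responses hug the beliefs
  p_low <- model_params(alpha = 0.1, delta = 0, tau = 0.001)
  r1 <- simulate_responses(seq, p_low, seed = 1)
  expect_lt(abs(sd(r1$response - r1$belief) - sqrt(0.001)), 0.2 * sqrt(0.001))

  # deterministic given the seed
  expect_identical(r1, simulate_responses(seq, p_low, seed = 1))

  # tau at the upper bound: near-uniform responding
  sh <- beta_shapes(0.5, 0.08)
  withr::with_seed(5, {
    draws <- rbeta(200, sh$shape1, sh$shape2)
  })
  expect_gt(stats::ks.test(draws, "punif")$p.value, 0.01)
})

test_that("response draws concentrate at the model belief", {
  sh <- beta_shapes(0.7, 0.02)
  withr::with_seed(8, draws <- rbeta(10000, sh$shape1, sh$shape2))
  # sample mode via method-of-moments shapes from the draws themselves
  m <- mean(draws)
  s <- m * (1 - m) / var(draws) - 1
  est_mode <- (m * s - 1) / (s - 2)
  expect_lt(abs(est_mode - 0.7), 0.03)
  # and the sample variance honours the requested variance
  expect_lt(abs(var(draws) - 0.02), 0.002)
})

test_that("responses round-trip through CSV and are validated", {
  seq <- generate_task_sequence(task_config(n_trials = 60), seed = 4)
  r <- simulate_responses(seq, model_params(), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(r, path)
  back <- read_responses(path)
  expect_equal(back$response, r$response, tolerance = 1e-12)
  bad <- r
  bad$response[1] <- 1.5
  write_responses(bad, path)
  expect_error(read_responses(path), class = "pfbt_validation_error")
})

test_that("parameters outside their domains are rejected", {
  expect_error(model_params(alpha = 1.2), class = "pfbt_domain_error")
  expect_error(model_params(tau = 0.2), class = "pfbt_domain_error")
  expect_error(model_params(lambda_self = -1), class = "pfbt_domain_error")
  # boundary values the model set actually uses are admissible
  expect_silent(model_params(delta = 0, tau = 0.001))
  expect_silent(model_params(tau = 0.08))
})
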