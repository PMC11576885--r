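#' Parameter samplers for simulated cohorts
#'
#' `sampler_table()` resamples rows, with replacement and independently per
#' parameter, from a table of plausible parameter values (default: the
#' packaged synthetic table `plausible_params_synthetic.csv`, a stand-in for
#' an empirical MAP table). `sampler_uniform()` draws each parameter
#' uniformly within the given ranges; `sampler_fixed()` repeats one setting.
#' All samplers are functions `f(n)` returning an n-row tibble with columns
#' `alpha`, `delta`, `tau`, `lambda_self`, `lambda_other`.
#'
#' @param table A data frame with the five parameter columns, or a CSV path.
#' @return A function of `n`.
#' @export
sampler_table <- function(table = NULL) {
  if (is.null(table)) {
    table <- readr::read_csv(
      system.file("extdata", "plausible_params_synthetic.csv", package = "pfbt"),
      show_col_types = FALSE
    )
  } else if (is.character(table)) {
    table <- readr::read_csv(table, show_col_types = FALSE)
  }
  cols <- c("alpha", "delta", "tau", "lambda_self", "lambda_other")
  stopifnot(all(cols %in% names(table)))
  function(n) {
    purrr::map_dfc(cols, function(cl) {
      tibble::tibble(!!cl := sample(table[[cl]], n, replace = TRUE))
    })
  }
}

#' @rdname sampler_table
#' @param alpha,delta,tau,lambda_self,lambda_other Length-2 ranges (or
#'   scalars for a fixed value).
#' @export
sampler_uniform <- function(alpha = c(0.05, 0.4), delta = c(0.001, 0.2),
                            tau = c(0.002, 0.078),
                            lambda_self = c(-0.8, 0.8),
                            lambda_other = c(-0.8, 0.8)) {
  rng <- function(r) if (length(r) == 1) c(r, r) else r
  ranges <- list(alpha = rng(alpha), delta = rng(delta), tau = rng(tau),
                 lambda_self = rng(lambda_self), lambda_other = rng(lambda_other))
  function(n) {
    purrr::map_dfc(names(ranges), function(cl) {
      r <- ranges[[cl]]
      tibble::tibble(!!cl := runif(n, r[1], r[2]))
    })
  }
}

#' @rdname sampler_table
#' @param params A [model_params()] to repeat for every participant.
#' @export
sampler_fixed <- function(params = model_params()) {
  function(n) {
    tibble::tibble(alpha = rep(params$alpha, n), delta = params$delta,
                   tau = params$tau, lambda_self = params$lambda_self,
                   lambda_other = params$lambda_other)
  }
}

check_sampled_params <- function(draws) {
  bounds <- list(alpha = c(0, 1), delta = c(0, 1), tau = c(0.001, 0.08),
                 lambda_self = c(-1, 1), lambda_other = c(-1, 1))
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (any(draws[[nm]] <= b[1] | draws[[nm]] >= b[2])) {
      abort(sprintf("Sampler produced out-of-bounds values for `%s`.", nm),
            class = "pfbt_domain_error")
    }
  }
  invisible(draws)
}

#' Simulate a cohort of task participants
#'
#' Draws generative parameters from `sampler`, generates a task sequence per
#' participant (fresh walks for each by default, or one shared sequence),
#' simulates belief trajectories and probe responses, and returns one row
#' per participant. Fully reproducible from `base_seed`: per-participant
#' sequence and response seeds are derived from it.
#'
#' @param n Number of participants.
#' @param sampler A sampler function (see [sampler_table()]).
#' @param task A [task_config()].
#' @param sequence_policy `"fresh"` (default) or `"shared"`.
#' @param base_seed Integer base seed.
#' @return A tibble with columns `participant`, the five generative
#'   parameters, and list columns `sequence`, `responses`.
#' @export
simulate_cohort <- function(n, sampler = sampler_table(),
                            task = task_config(),
                            sequence_policy = c("fresh", "shared"),
                            base_seed = 1L) {
  sequence_policy <- match.arg(sequence_policy)
  withr::local_seed(base_seed)
  draws <- sampler(n)
  check_sampled_params(draws)
  seq_seeds <- sample.int(.Machine$integer.max - 1L, n)
  resp_seeds <- sample.int(.Machine$integer.max - 1L, n)
  if (sequence_policy == "shared") seq_seeds <- rep(seq_seeds[1], n)
  shared_seq <- if (sequence_policy == "shared") {
    generate_task_sequence(task, seed = seq_seeds[1])
  }
  rows <- purrr::map(seq_len(n), function(i) {
    p <- do.call(model_params, as.list(draws[i, ]))
    sq <- shared_seq %||% generate_task_sequence(task, seed = seq_seeds[i])
    resp <- simulate_responses(sq, p, seed = resp_seeds[i])
    tibble::tibble(participant = i, !!!draws[i, ],
                   sequence = list(sq), responses = list(resp))
  })
  dplyr::bind_rows(rows)
}

#' Parameter-recovery experiment
#'
#' Fits the given model variant to every simulated participant and
#' correlates generative with fitted parameters: the diagonal of the
#' generative-by-fitted Pearson correlation matrix measures recoverability,
#' the off-diagonal terms measure confusability. Results are additionally
#' stratified by quartile of generative choice noise `tau`, since leakage is
#' less reliably estimable when responding is noisier.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param spec The [model_spec()] to fit (default: leakage unrestricted,
#'   shared learning rate — the variant of primary interest).
#' @param prior A [prior_spec()] for that variant.
#' @param n_restarts,seed Fitting controls per participant (see [fit_map()]).
#' @return An object of class `pfbt_recovery`: `estimates` (per participant,
#'   generative `*_gen` and fitted `*_fit` columns plus fit diagnostics),
#'   `correlations` (generative x fitted matrix), `diagonal_r`,
#'   `by_tau_quartile` (diagonal r within each generative-tau quartile),
#'   `n_failed` (fits excluded after errors).
#' @export
parameter_recovery <- function(cohort, spec = model_spec("unrestricted", "shared"),
                               prior = prior_spec(spec), n_restarts = 10,
                               seed = 1L) {
  fit_one <- function(sq, resp, i) {
    tryCatch(fit_map(sq, resp, spec = spec, prior = prior,
                     n_restarts = n_restarts, seed = seed + i),
             error = function(e) NULL)
  }
  fits <- purrr::pmap(list(cohort$sequence, cohort$responses,
                           cohort$participant), fit_one)
  failed <- purrr::map_lgl(fits, is.null)
  if (any(failed)) {
    warn(sprintf("%d fit(s) failed and were excluded.", sum(failed)),
         class = "pfbt_fit_warning")
  }
  gen_cols <- c("alpha", "delta", "tau", "lambda_self", "lambda_other")
  est <- cohort[!failed, c("participant", gen_cols)] |>
    dplyr::rename_with(~ paste0(.x, "_gen"), dplyr::all_of(gen_cols))
  fitted_tab <- purrr::map_dfr(fits[!failed], function(f) {
    p <- f$map_params
    tibble::tibble(alpha_fit = p$alpha, delta_fit = p$delta, tau_fit = p$tau,
                   lambda_self_fit = p$lambda_self,
                   lambda_other_fit = p$lambda_other,
                   log_evidence = f$log_evidence, converged = f$converged)
  })
  est <- dplyr::bind_cols(est, fitted_tab)

  cor_block <- function(df) {
    suppressWarnings(cor(as.matrix(df[, paste0(gen_cols, "_gen")]),
                         as.matrix(df[, paste0(gen_cols, "_fit")])))
  }
  cors <- cor_block(est)
  dimnames(cors) <- list(generative = gen_cols, fitted = gen_cols)
  brk <- unique(quantile(est$tau_gen, probs = seq(0, 1, 0.25)))
  quart <- if (length(brk) > 2) {
    cut(est$tau_gen, breaks = brk, include.lowest = TRUE,
        labels = paste0("Q", seq_len(length(brk) - 1)))
  } else {
    factor(rep("Q1", nrow(est)))
  }
  by_q <- purrr::map_dfr(levels(quart), function(q) {
    sub <- est[quart == q, ]
    cc <- cor_block(sub)
    tibble::tibble(tau_quartile = q, n = nrow(sub),
                   term = gen_cols, r = diag(cc))
  })
  structure(
    list(estimates = est, correlations = cors,
         diagonal_r = setNames(diag(cors), gen_cols),
         by_tau_quartile = by_q, n_failed = sum(failed), spec = spec),
    class = "pfbt_recovery"
  )
}

#' @export
print.pfbt_recovery <- function(x, ...) {
  cat("<pfbt_recovery>", nrow(x$estimates), "participants, model",
      x$spec$label, "\n")
  print(round(x$correlations, 3))
  invisible(x)
}

#' Model-recovery experiment
#'
#' Simulates replicate cohorts from a generating model variant, fits each
#' candidate variant to every cohort, and counts which candidate wins the
#' summed-evidence (fixed-effects) comparison — a confusion analysis showing
#' whether the evidence-based comparison, with its complexity penalty,
#' identifies the true model.
#'
#' @param generating_spec The [model_spec()] data are simulated from.
#' @param candidate_specs A list of candidate [model_spec()]s (default: the
#'   six-model set).
#' @param n_cohorts Number of replicate cohorts.
#' @param n_per_cohort Participants per cohort.
#' @param sampler Generative parameter sampler; parameters not free in
#'   `generating_spec` are constrained (lambdas zeroed / tied) before
#'   simulation.
#' @param task A [task_config()].
#' @param base_seed Integer base seed.
#' @param n_restarts Restarts per fit.
#' @return A tibble: `candidate`, `wins`, `proportion`, plus attributes with
#'   the per-cohort summed evidences.
#' @export
model_recovery <- function(generating_spec, candidate_specs = model_set()$spec,
                           n_cohorts = 5, n_per_cohort = 12,
                           sampler = sampler_table(), task = task_config(),
                           base_seed = 1L, n_restarts = 5) {
  if (length(candidate_specs) < 1) {
    abort("Need at least one candidate model.", class = "pfbt_domain_error")
  }
  constrain <- function(draws) {
    if (generating_spec$leakage == "zero") {
      draws$lambda_self <- 0
      draws$lambda_other <- 0
    } else if (generating_spec$leakage == "symmetric") {
      draws$lambda_other <- draws$lambda_self
    }
    draws
  }
  constrained_sampler <- function(n) constrain(sampler(n))
  labels <- purrr::map_chr(candidate_specs, "label")
  per_cohort <- purrr::map(seq_len(n_cohorts), function(ci) {
    cohort <- simulate_cohort(n_per_cohort, sampler = constrained_sampler,
                              task = task, base_seed = base_seed + ci)
    sums <- purrr::map_dbl(candidate_specs, function(sp) {
      evs <- purrr::map_dbl(seq_len(n_per_cohort), function(i) {
        fit_map(cohort$sequence[[i]], cohort$responses[[i]], spec = sp,
                prior = prior_spec(sp), n_restarts = n_restarts,
                seed = base_seed + ci * 1000L + i)$log_evidence
      })
      sum(evs)
    })
    setNames(sums, labels)
  })
  wins <- purrr::map_chr(per_cohort, ~ names(.x)[which.max(.x)])
  counts <- table(factor(wins, levels = labels))
  out <- tibble::tibble(candidate = labels, wins = as.integer(counts),
                        proportion = as.integer(counts) / n_cohorts)
  attr(out, "summed_evidence") <- per_cohort
  attr(out, "generating") <- generating_spec$label
  out
}

#' Two-sample and one-sample group contrasts
#'
#' Convenience statistics for comparing fitted parameters between simulated
#' groups: pooled-SD two-sample t test (equal-variance, as appropriate for
#' matched-design contrasts) with Cohen's d = (mean(a) - mean(b)) / pooled
#' SD, and the corresponding one-sample test against a reference value.
#' A degenerate pooled SD of zero yields `d = ±Inf` and a `degenerate` flag
#' rather than an error.
#'
#' @param a,b Numeric vectors (n >= 2 each).
#' @param conf Confidence level for the CI. Default 0.95.
#' @return A one-row tibble: `mean_diff` (or `mean`), `ci_lo`, `ci_hi`, `t`,
#'   `df`, `p`, `cohens_d` (two-sample only), `degenerate`.
#' @examples
#' group_contrast(c(1, 2, 3), c(2, 3, 4)) # |d| = 1 with pooled SD 1
#' @export
group_contrast <- function(a, b, conf = 0.95) {
  if (length(a) < 2 || length(b) < 2) {
    abort("Each group needs at least two observations.",
          class = "pfbt_domain_error")
  }
  n1 <- length(a)
  n2 <- length(b)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / df
  sp <- sqrt(sp2)
  diff <- mean(a) - mean(b)
  se <- sp * sqrt(1 / n1 + 1 / n2)
  degenerate <- sp == 0
  t_stat <- if (degenerate) sign(diff) * Inf else diff / se
  if (degenerate && diff == 0) t_stat <- 0
  d <- if (degenerate) sign(diff) * Inf else diff / sp
  if (degenerate && diff == 0) d <- 0
  crit <- qt(1 - (1 - conf) / 2, df)
  tibble::tibble(
    mean_diff = diff,
    ci_lo = diff - crit * se, ci_hi = diff + crit * se,
    t = t_stat, df = df,
    p = if (degenerate) ifelse(diff == 0, 1, 0) else 2 * pt(-abs(t_stat), df),
    cohens_d = d, degenerate = degenerate
  )
}

#' @rdname group_contrast
#' @param x Numeric vector.
#' @param reference Reference value tested against. Default 0.
#' @export
one_sample_contrast <- function(x, reference = 0, conf = 0.95) {
  if (length(x) < 2) {
    abort("Need at least two observations.", class = "pfbt_domain_error")
  }
  n <- length(x)
  s <- sd(x)
  m <- mean(x)
  degenerate <- s == 0
  se <- s / sqrt(n)
  t_stat <- if (degenerate) {
    if (m == reference) 0 else sign(m - reference) * Inf
  } else (m - reference) / se
  crit <- qt(1 - (1 - conf) / 2, n - 1)
  tibble::tibble(
    mean = m, ci_lo = m - crit * se, ci_hi = m + crit * se,
    t = t_stat, df = n - 1,
    p = if (degenerate) ifelse(m == reference, 1, 0) else 2 * pt(-abs(t_stat), n - 1),
    degenerate = degenerate
  )
}
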