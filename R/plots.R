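#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a task sequence
#'
#' Shows the two latent walks over sampling trials, the observed outcomes
#' (as rug marks coloured by trial type), and the probe schedule.
#'
#' @param object A `pfbt_sequence`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pfbt_sequence <- function(object, ...) {
  st <- sampling_trials(object)
  pr <- probe_trials(object)
  walks <- st |>
    dplyr::select("sampling_index", "p_self", "p_other") |>
    tidyr::pivot_longer(c("p_self", "p_other"), names_to = "walk",
                        values_to = "p")
  ggplot2::ggplot(walks, ggplot2::aes(.data$sampling_index, .data$p,
                                      colour = .data$walk)) +
    ggplot2::geom_line() +
    ggplot2::geom_rug(data = st,
                      ggplot2::aes(x = .data$sampling_index,
                                   y = NULL, colour = NULL,
                                   linetype = .data$trial_type),
                      sides = "b", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = pr$after_sampling_index,
                        linetype = "dotted", alpha = 0.3) +
    ggplot2::labs(x = "Sampling trial", y = "P(umbrella)",
                  colour = "Latent walk", linetype = "Trial type") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a belief trajectory
#'
#' Self and Other model beliefs over sampling trials, with the latent walks
#' for reference when the sequence is supplied.
#'
#' @param object A `pfbt_trajectory`.
#' @param sequence Optional originating `pfbt_sequence` (adds the latent
#'   walks as dashed lines).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pfbt_trajectory <- function(object, sequence = NULL, ...) {
  beliefs <- tibble::as_tibble(object) |>
    dplyr::select("sampling_index", "b_self", "b_other") |>
    tidyr::pivot_longer(c("b_self", "b_other"), names_to = "agent",
                        values_to = "belief") |>
    dplyr::mutate(agent = ifelse(.data$agent == "b_self", "Self", "Other"))
  p <- ggplot2::ggplot(beliefs, ggplot2::aes(.data$sampling_index,
                                             .data$belief,
                                             colour = .data$agent)) +
    ggplot2::geom_line()
  if (!is.null(sequence)) {
    walks <- sampling_trials(sequence) |>
      dplyr::select("sampling_index", Self = "p_self", Other = "p_other") |>
      tidyr::pivot_longer(c("Self", "Other"), names_to = "agent",
                          values_to = "belief")
    p <- p + ggplot2::geom_line(data = walks, linetype = "dashed",
                                alpha = 0.5)
  }
  p + ggplot2::labs(x = "Sampling trial", y = "Belief  P(umbrella)",
                    colour = "Agent") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a random-effects model comparison
#'
#' @param object A `pfbt_bms`.
#' @param ... Unused.
#' @return A ggplot of protected exceedance probabilities and expected
#'   frequencies per model.
#' @export
autoplot.pfbt_bms <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("expected_frequency",
                          "protected_exceedance_probability"),
                        names_to = "statistic", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$model, .data$value,
                                   fill = .data$statistic)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a parameter-recovery report
#'
#' Generative versus fitted estimates, one facet per parameter, with the
#' identity line.
#'
#' @param object A `pfbt_recovery`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pfbt_recovery <- function(object, ...) {
  gen_cols <- c("alpha", "delta", "tau", "lambda_self", "lambda_other")
  df <- purrr::map_dfr(gen_cols, function(cl) {
    tibble::tibble(term = cl,
                   generative = object$estimates[[paste0(cl, "_gen")]],
                   fitted = object$estimates[[paste0(cl, "_fit")]])
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$generative, .data$fitted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         alpha = 0.5) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "Generative", y = "Fitted") +
    ggplot2::theme_minimal()
}

#' Plot the random-responding null with an observed score
#'
#' @param null A [null_distribution()] result.
#' @param raw Optional observed raw performance correlation to overlay.
#' @return A ggplot of the null histogram with the 95th percentile marked.
#' @export
plot_null_distribution <- function(null, raw = NULL) {
  df <- tibble::tibble(r = null$draws)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$r)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = null$p95, linetype = "dashed") +
    ggplot2::labs(x = "Outcome-belief correlation under random responding",
                  y = "Count") +
    ggplot2::theme_minimal()
  if (!is.null(raw)) {
    p <- p + ggplot2::geom_vline(xintercept = raw, colour = "red")
  }
  p
}
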