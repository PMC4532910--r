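#' Plot observed and fitted psychometric curves
#'
#' Shows the observed proportion of "comparison judged longer" per
#' comparison duration and condition together with the fitted
#' lapse-augmented cumulative Gaussians.
#'
#' @param object A [fit_psychometric()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psychfit <- function(object, ...) {
  cells <- object$cells %>%
    dplyr::mutate(prop = .data$n_longer / .data$n)
  grid <- tidyr::expand_grid(
    condition = object$conditions,
    comp_duration_ms = seq(100, 1100, by = 10)
  ) %>%
    dplyr::mutate(
      p = psychometric_prob(
        log(.data$comp_duration_ms),
        unname(object$b[.data$condition]),
        unname(object$sigma[.data$condition]),
        object$lambda
      )
    )
  ggplot2::ggplot(cells,
                  ggplot2::aes(x = .data$comp_duration_ms,
                               colour = .data$condition)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$prop, size = .data$n),
                        alpha = 0.6) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p)) +
    ggplot2::geom_vline(xintercept = 600, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "comparison duration (ms, log scale)",
                  y = "p(comparison judged longer)", size = "trials",
                  colour = "condition") +
    ggplot2::theme_minimal()
}

#' Plot model-predicted psychometric curves by display order
#'
#' Computes choice probabilities on a duration lattice for one condition
#' and both display orders, re-expressed as "comparison judged longer", and
#' plots them. Useful for visualizing the order effect that only models
#' with both memory decay and a non-flat prior can produce.
#'
#' @param trials Schedule supplying the condition and priors.
#' @param model,params,priors As in [choice_probability()].
#' @param condition Condition label to plot.
#' @return A ggplot object.
#' @export
plot_order_effect <- function(trials, model, params, priors = NULL,
                              condition = trials$condition[1]) {
  curves <- predicted_curves(trials, model, params, priors, condition)
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$comp_duration_ms,
                               y = .data$p_comp_longer,
                               colour = .data$order)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 600, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "comparison duration (ms, log scale)",
                  y = "p(comparison judged longer)", colour = "order",
                  title = paste(condition, "-", format(model))) +
    ggplot2::theme_minimal()
}

# Predicted p(comparison longer) per duration and order for one condition.
predicted_curves <- function(trials, model, params, priors = NULL,
                             condition, durations = duration_grid()) {
  row <- trials %>%
    dplyr::filter(.data$condition == !!condition) %>%
    dplyr::distinct(.data$experiment_id, .data$condition, .data$ref_type,
                    .data$comp_type) %>%
    head(1)
  if (nrow(row) == 0) abort(paste("condition not in trials:", condition))
  if (is.null(priors)) {
    priors <- build_priors(trials, model$prior, kappa = params$kappa)
  }
  lattice <- tidyr::expand_grid(
    order = c("r-c", "c-r"),
    comp_duration_ms = durations
  ) %>%
    dplyr::mutate(
      experiment_id = row$experiment_id, condition = row$condition,
      ref_type = row$ref_type, comp_type = row$comp_type,
      ref_duration_ms = REF_MS, response = NA_character_
    )
  out <- choice_probability(lattice, model, params, priors)
  out %>%
    dplyr::mutate(
      p_comp_longer = ifelse(.data$order == "r-c", .data$p_second_longer,
                             1 - .data$p_second_longer)
    ) %>%
    dplyr::select("condition", "order", "comp_duration_ms", "p_comp_longer")
}

#' Bar plot of cross-validated log-likelihood differences
#'
#' @param comparison Output of [compare_models()].
#' @return A ggplot object.
#' @export
plot_cvll <- function(comparison) {
  delta_col <- if ("mean_delta_cvll" %in% names(comparison)) {
    "mean_delta_cvll"
  } else {
    "delta_cvll"
  }
  comparison$delta <- comparison[[delta_col]]
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = stats::reorder(.data$model_id,
                                                  .data$delta),
                               y = .data$delta)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "delta CVLL vs best model") +
    ggplot2::theme_minimal()
}
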