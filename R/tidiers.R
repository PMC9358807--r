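#' @exportS3Method generics::tidy
tidy.trial_weight_fit <- function(x, ...) {
  tibble(term = names(x$alpha), estimate = unname(x$alpha))
}

#' @exportS3Method generics::glance
glance.trial_weight_fit <- function(x, ...) {
  tibble(
    n = x$n, ess = x$ess, objective = x$objective,
    grad_norm = x$grad_norm, converged = x$converged
  )
}

#' @exportS3Method generics::tidy
tidy.propensity_fit <- function(x, ...) {
  s <- stats::coef(summary(x$model))
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "z value"],
    p.value = s[, "Pr(>|z|)"]
  )
}

#' @exportS3Method generics::glance
glance.propensity_fit <- function(x, ...) {
  tibble(
    n = length(x$scores),
    n_treated = sum(x$treatment == 1),
    deviance = x$model$deviance,
    aic = x$model$aic
  )
}

#' @exportS3Method generics::tidy
tidy.maic_estimate <- function(x, ...) {
  tibble(
    method = x$method, estimate = x$estimate,
    std.error = sqrt(x$variance), scale = x$scale
  )
}

#' @exportS3Method generics::glance
glance.maic_estimate <- function(x, ...) {
  tibble(
    method = x$method, estimate = x$estimate, variance = x$variance,
    scale = x$scale, n_boot = x$n_boot, ess = x$ess,
    n_redrawn = x$n_redrawn, original_estimate = x$original_estimate
  )
}

#' @exportS3Method generics::tidy
tidy.indirect_comparison <- function(x, ...) {
  tibble(
    method = x$method, estimate = x$estimate,
    std.error = sqrt(x$variance),
    ci_lower = x$ci_lower, ci_upper = x$ci_upper,
    alpha = x$alpha, scale = x$scale
  )
}

#' Weight distribution plot
#'
#' Histogram of the weights rescaled to mean one (weights are defined
#' only up to proportionality), annotated with the effective sample size.
#'
#' @param object A `weight_set`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.weight_set <- function(object, bins = 30, ...) {
  df <- tibble(weight = object$values / mean(object$values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::labs(
      x = "weight (rescaled to mean 1)", y = "subjects",
      title = sprintf("%s weights%s", object$stage,
                      if (object$truncated) " (truncated)" else ""),
      subtitle = sprintf("n = %d, ESS = %.1f", length(object$values),
                         object$ess)
    )
}

#' Performance summary plot
#'
#' Dot-and-error-bar panels (one per metric) of the per-method
#' performance measures across scenarios, error bars at +/- 1.96 Monte
#' Carlo standard errors.
#'
#' @param object A `performance_summary` from [summarize_performance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.performance_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("scenario_id", "index_n", "overlap", "method",
                        "bias", "bias_mcse", "ese", "ese_mcse",
                        "mse", "mse_mcse", "coverage", "coverage_mcse")],
    cols = c("bias", "ese", "mse", "coverage"),
    names_to = "metric", values_to = "value"
  )
  long$mcse <- dplyr::case_when(
    long$metric == "bias" ~ long$bias_mcse,
    long$metric == "ese" ~ long$ese_mcse,
    long$metric == "mse" ~ long$mse_mcse,
    TRUE ~ long$coverage_mcse
  )
  long$cell <- sprintf("n=%d, %s", long$index_n, long$overlap)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$method, y = .data$value, colour = .data$cell
  )) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$value - 1.96 * .data$mcse,
                   ymax = .data$value + 1.96 * .data$mcse),
      width = 0.2, position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = "scenario") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
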