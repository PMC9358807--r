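#' Bias of a simulation estimator
#'
#' Mean of the replicate estimates minus the true value, with Monte Carlo
#' standard error `sd(estimates)/sqrt(N)`.
#'
#' @param estimates Numeric vector of replicate estimates (length >= 2).
#' @param truth True value of the estimand.
#'
#' @return A one-row tibble with `value` and `mcse`.
#' @export
sim_bias <- function(estimates, truth) {
  check_estimates(estimates)
  tibble(value = mean(estimates) - truth,
         mcse = sd(estimates) / sqrt(length(estimates)))
}

#' Empirical standard error over replicates
#'
#' Sample standard deviation (N - 1 divisor) of the replicate estimates;
#' MCSE is `ese / sqrt(2 (N - 1))`.
#'
#' @inheritParams sim_bias
#' @return A one-row tibble with `value` and `mcse`.
#' @export
sim_ese <- function(estimates) {
  check_estimates(estimates)
  e <- sd(estimates)
  tibble(value = e, mcse = e / sqrt(2 * (length(estimates) - 1)))
}

#' Mean square error over replicates
#'
#' Mean squared deviation from the truth; MCSE is the standard deviation
#' of the squared deviations over `sqrt(N)`.
#'
#' @inheritParams sim_bias
#' @return A one-row tibble with `value` and `mcse`.
#' @export
sim_mse <- function(estimates, truth) {
  check_estimates(estimates)
  sq <- (estimates - truth)^2
  tibble(value = mean(sq), mcse = sd(sq) / sqrt(length(sq)))
}

#' Empirical coverage of interval estimates
#'
#' Proportion of closed intervals containing the truth; MCSE is
#' `sqrt(p (1 - p) / N)`.
#'
#' @param ci_lower,ci_upper Paired interval bounds.
#' @inheritParams sim_bias
#' @return A one-row tibble with `value` and `mcse`.
#' @export
sim_coverage <- function(ci_lower, ci_upper, truth) {
  if (length(ci_lower) != length(ci_upper)) {
    stop_shape("interval bounds must be paired")
  }
  if (length(ci_lower) < 1) stop_shape("no intervals supplied")
  if (any(ci_lower > ci_upper)) stop_shape("ci_lower exceeds ci_upper")
  p <- mean(ci_lower <= truth & truth <= ci_upper)
  tibble(value = p, mcse = sqrt(p * (1 - p) / length(ci_lower)))
}

check_estimates <- function(estimates) {
  if (length(estimates) < 2 || anyNA(estimates)) {
    stop_shape("need at least 2 non-missing estimates")
  }
  invisible(estimates)
}

#' Monte Carlo significance band around a nominal coverage rate
#'
#' The interval `nominal +/- 1.96 sqrt(nominal (1 - nominal) / n_sim)`,
#' rounded to three decimals: empirical coverage outside this band is
#' statistically distinguishable from the nominal rate.
#'
#' @param nominal Nominal coverage in (0, 1).
#' @param n_sim Number of simulation replicates.
#'
#' @return Named numeric vector `c(low, high)`.
#' @export
#' @examples
#' coverage_band(0.95, 5000) # c(0.944, 0.956)
coverage_band <- function(nominal, n_sim) {
  if (nominal <= 0 || nominal >= 1) stop_domain("nominal must lie in (0, 1)")
  hw <- 1.96 * sqrt(nominal * (1 - nominal) / n_sim)
  round(c(low = nominal - hw, high = nominal + hw), 3)
}

#' Summarize estimator performance over simulation replicates
#'
#' Computes, per scenario and method, the four frequentist performance
#' measures (bias, empirical standard error, mean square error, empirical
#' coverage of the Wald intervals) with their Monte Carlo standard errors.
#' Replicates whose status is not `"ok"` (e.g. discarded for separation)
#' are excluded from the metric denominators and counted separately.
#'
#' @param replicates Replicate tibble from [run_study()].
#' @param truth True value of the A-vs-B estimand (zero under the
#'   replication data-generating mechanism).
#'
#' @return A `performance_summary` tibble, one row per
#'   (scenario, method).
#' @export
summarize_performance <- function(replicates, truth = 0) {
  required <- c("scenario_id", "method", "estimate", "ci_lower", "ci_upper",
                "status")
  missing_cols <- setdiff(required, names(replicates))
  if (length(missing_cols) > 0) {
    stop_shape(paste("replicate table lacks columns:",
                     paste(missing_cols, collapse = ", ")))
  }
  keys <- intersect(
    c("scenario_id", "index_n", "index_cov_mean", "overlap", "method"),
    names(replicates)
  )
  counts <- replicates |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_replicates = sum(.data$status == "ok"),
      n_discarded = sum(.data$status == "discarded_separation"),
      n_failed = sum(!.data$status %in% c("ok", "discarded_separation")),
      .groups = "drop"
    )
  ok <- dplyr::filter(replicates, .data$status == "ok")
  metrics <- ok |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      bias = mean(.data$estimate) - truth,
      bias_mcse = sd(.data$estimate) / sqrt(dplyr::n()),
      ese = sd(.data$estimate),
      ese_mcse = sd(.data$estimate) / sqrt(2 * (dplyr::n() - 1)),
      mse = mean((.data$estimate - truth)^2),
      mse_mcse = sd((.data$estimate - truth)^2) / sqrt(dplyr::n()),
      coverage = mean(.data$ci_lower <= truth & truth <= .data$ci_upper),
      coverage_mcse = sqrt(coverage * (1 - coverage) / dplyr::n()),
      mean_ess = if ("ess" %in% names(replicates)) mean(.data$ess) else NA_real_,
      .groups = "drop"
    )
  out <- dplyr::left_join(metrics, counts, by = keys)
  class(out) <- c("performance_summary", class(out))
  out
}
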