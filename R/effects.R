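#' Weighted marginal mean outcomes by treatment arm
#'
#' Estimates the marginal mean outcome that each arm of the index trial
#' would have in the competitor-study population, as the weighted average
#' of observed outcomes within the arm.
#'
#' @param data Index-trial data frame.
#' @param ws A `weight_set` or bare numeric weights.
#' @param outcome,treatment Names of the outcome and 0/1 treatment columns.
#'
#' @return A tibble with columns `treatment` (1 then 0), `mean` and
#'   `total_weight`.
#' @export
weighted_arm_means <- function(data, ws, outcome = "outcome",
                               treatment = "treatment") {
  y <- data[[outcome]]
  if (is.null(y)) stop_shape(sprintf("column '%s' not found", outcome))
  t <- check_treatment(data[[treatment]] %||%
                         stop_shape(sprintf("column '%s' not found", treatment)))
  w <- if (inherits(ws, "weight_set")) ws$values else as.numeric(ws)
  if (length(w) != length(y)) stop_shape("weights and data have different lengths")
  mu <- .arm_means(as.numeric(y), t, w)
  tibble(
    treatment = c(1, 0),
    mean = c(mu[["mu1"]], mu[["mu0"]]),
    total_weight = c(sum(w[t == 1]), sum(w[t == 0]))
  )
}

#' Marginal contrast of two mean outcomes on a linear-predictor scale
#'
#' @param mu1,mu0 Marginal mean outcomes under active treatment and
#'   comparator.
#' @param scale `"mean_difference"` (identity link), `"log_odds_ratio"`
#'   (logit link), `"log_risk_ratio"` (log link) or `"risk_difference"`.
#'
#' @return The contrast `g(mu1) - g(mu0)`.
#' @export
#' @examples
#' marginal_contrast(8.4, 8.6) # -0.2
#' marginal_contrast(0.75, 0.5, "log_odds_ratio") # log(3)
marginal_contrast <- function(mu1, mu0, scale = "mean_difference") {
  .link_contrast(mu1, mu0, scale)
}

#' Weighted regression of outcome on treatment
#'
#' Fits the marginal (treatment-only) outcome model by weighted maximum
#' likelihood and returns the treatment coefficient.  With the identity
#' link this equals the difference of weighted arm means exactly; with the
#' logit link it equals the log odds ratio of the weighted arm
#' proportions.
#'
#' @inheritParams weighted_arm_means
#' @param scale `"mean_difference"` or `"log_odds_ratio"`.
#'
#' @return The estimated marginal treatment coefficient.
#' @export
weighted_outcome_regression <- function(data, ws, outcome = "outcome",
                                        treatment = "treatment",
                                        scale = "mean_difference") {
  y <- as.numeric(data[[outcome]] %||%
                    stop_shape(sprintf("column '%s' not found", outcome)))
  t <- check_treatment(data[[treatment]] %||%
                         stop_shape(sprintf("column '%s' not found", treatment)))
  w <- if (inherits(ws, "weight_set")) ws$values else as.numeric(ws)
  df <- data.frame(..y = y, ..t = t, ..w = w)
  fit <- switch(scale,
    mean_difference = lm(..y ~ ..t, data = df, weights = ..w),
    log_odds_ratio = suppressWarnings(
      stats::glm(..y ~ ..t, data = df, weights = ..w,
                 family = stats::quasibinomial())
    ),
    stop_domain(sprintf("unsupported scale '%s' for weighted regression", scale))
  )
  unname(coef(fit)[2])
}

new_maic_estimate <- function(estimate, variance, scale, method,
                              n_boot = NA_integer_, ess = NA_real_,
                              n_redrawn = NA_integer_,
                              original_estimate = NA_real_,
                              boot_estimates = NULL) {
  structure(
    list(
      estimate = estimate, variance = variance, scale = scale,
      method = method, n_boot = n_boot, ess = ess, n_redrawn = n_redrawn,
      original_estimate = original_estimate, boot_estimates = boot_estimates
    ),
    class = "maic_estimate"
  )
}

#' @export
print.maic_estimate <- function(x, ...) {
  cat(sprintf("<maic_estimate: %s, scale %s>\n", x$method, x$scale))
  cat(sprintf("  estimate %.4f (variance %.4f, SE %.4f)\n",
              x$estimate, x$variance, sqrt(x$variance)))
  if (!is.na(x$n_boot)) {
    cat(sprintf("  bootstrap: %d resamples, %d redrawn\n",
                x$n_boot, x$n_redrawn))
  }
  if (!is.na(x$ess)) cat(sprintf("  ESS after weighting: %.1f\n", x$ess))
  invisible(x)
}

#' Population-adjusted A-vs-C effect with bootstrap inference
#'
#' Runs one of the four weighting estimators (MAIC, 2SMAIC, T-MAIC,
#' T-2SMAIC) on index-trial IPD against competitor-trial aggregate data,
#' with ordinary non-parametric bootstrap inference.  Index-trial rows are
#' resampled with replacement; each resample re-estimates the
#' trial-assignment model (and the propensity model for the two-stage
#' methods) before recomputing the marginal A-vs-C contrast.  The point
#' estimate is the mean over resamples and the variance is the squared
#' standard deviation over resamples; the single original-sample estimate
#' is also returned.
#'
#' @param data Index-trial data frame.
#' @param ald A [competitor_ald()] (only its covariate means are used
#'   here; combine with the B-vs-C effect via [indirect_comparison()]).
#' @param effect_modifiers Columns balanced across trials.
#' @param covariates Columns entering the propensity model for the
#'   two-stage methods (defaults to `effect_modifiers`).
#' @param outcome,treatment Outcome and 0/1 treatment column names.
#' @param method One of `"MAIC"`, `"2SMAIC"`, `"T-MAIC"`, `"T-2SMAIC"`.
#' @param scale Linear-predictor scale of the contrast.
#' @param n_boot Number of bootstrap resamples (the simulation protocol
#'   uses 2000).
#' @param truncation_percentile Percentile cutpoint for the truncated
#'   methods.
#' @param seed Optional integer seed making the resampling reproducible.
#' @param point_estimate `"bootstrap_mean"` (default) or `"original"`,
#'   which reports the original-sample estimate instead while keeping the
#'   bootstrap variance.
#' @param stratified Resample within arms instead of over the whole IPD.
#'
#' @return A `maic_estimate` for the A-vs-C marginal effect in the
#'   competitor population.
#' @export
maic <- function(data, ald, effect_modifiers,
                 covariates = effect_modifiers,
                 outcome = "outcome", treatment = "treatment",
                 method = c("MAIC", "2SMAIC", "T-MAIC", "T-2SMAIC"),
                 scale = "mean_difference",
                 n_boot = 2000L, truncation_percentile = 95,
                 seed = NULL,
                 point_estimate = c("bootstrap_mean", "original"),
                 stratified = FALSE) {
  method <- match.arg(method)
  point_estimate <- match.arg(point_estimate)
  if (n_boot < 2) stop_domain("n_boot must be at least 2")
  y <- as.numeric(data[[outcome]] %||%
                    stop_shape(sprintf("column '%s' not found", outcome)))
  t <- check_treatment(data[[treatment]] %||%
                         stop_shape(sprintf("column '%s' not found", treatment)))
  x <- pull_columns(data, covariates, "covariate")
  zstar <- center_covariates(data, effect_modifiers, ald)
  feas <- check_feasibility(zstar)
  if (!attr(feas, "feasible")) {
    stop_separation(feas$covariate[feas$separated])
  }
  if (!is.null(seed)) set.seed(seed)
  orig <- .method_estimates(zstar, x, t, y, method, truncation_percentile,
                            scale, return_weights = TRUE)
  if (is.null(orig)) {
    stop_domain("estimation failed on the original sample")
  }
  boot <- .bootstrap_methods(zstar, x, t, y, n_boot, method,
                             truncation_percentile, scale,
                             stratified = stratified)
  bm <- boot$estimates[, 1]
  est <- if (point_estimate == "bootstrap_mean") mean(bm) else
    unname(orig$estimates[1])
  new_maic_estimate(
    estimate = est,
    variance = var(bm),
    scale = scale,
    method = method,
    n_boot = as.integer(n_boot),
    ess = .ess_num(orig$weights[[method]]),
    n_redrawn = boot$n_redrawn,
    original_estimate = unname(orig$estimates[1]),
    boot_estimates = bm
  )
}

#' Unadjusted marginal effect from a two-arm trial
#'
#' Simple ordinary least squares of outcome on treatment; the treatment
#' coefficient and its nominal model-based squared standard error mimic
#' what a published trial report provides.
#'
#' @inheritParams weighted_arm_means
#' @param data Two-arm trial data frame with a continuous outcome.
#'
#' @return A `maic_estimate` with method `"unadjusted"`.
#' @export
unadjusted_effect <- function(data, outcome = "outcome",
                              treatment = "treatment") {
  y <- as.numeric(data[[outcome]] %||%
                    stop_shape(sprintf("column '%s' not found", outcome)))
  t <- check_treatment(data[[treatment]] %||%
                         stop_shape(sprintf("column '%s' not found", treatment)))
  fit <- lm(y ~ t)
  new_maic_estimate(
    estimate = unname(coef(fit)[2]),
    variance = unname(vcov(fit)[2, 2]),
    scale = "mean_difference",
    method = "unadjusted"
  )
}

#' Anchored indirect comparison through the common comparator
#'
#' Combines the A-vs-C estimate (from the index trial, transported into
#' the competitor population) with the published B-vs-C estimate into the
#' A-vs-B contrast: the point estimates are differenced and, because the
#' two within-study estimates are independent, their variances are
#' summed.  A Wald normal confidence interval is attached.
#'
#' @param ac A `maic_estimate` for A vs. C.
#' @param bc The B-vs-C evidence: a `competitor_ald` or a `maic_estimate`.
#' @param alpha Two-sided error rate for the Wald interval.
#'
#' @return An object of class `indirect_comparison`.
#' @export
indirect_comparison <- function(ac, bc, alpha = 0.05) {
  stopifnot(inherits(ac, "maic_estimate"))
  if (inherits(bc, "competitor_ald")) {
    bc <- new_maic_estimate(bc$effect_estimate, bc$effect_variance,
                            bc$scale, "unadjusted")
  }
  stopifnot(inherits(bc, "maic_estimate"))
  if (!identical(ac$scale, bc$scale)) {
    abort(
      sprintf("cannot combine effects on different scales ('%s' vs '%s')",
              ac$scale, bc$scale),
      class = "maic2s_scale"
    )
  }
  if (alpha <= 0 || alpha >= 1) stop_domain("alpha must lie in (0, 1)")
  est <- ac$estimate - bc$estimate
  v <- ac$variance + bc$variance
  hw <- qnorm(1 - alpha / 2) * sqrt(v)
  structure(
    list(
      estimate = est, variance = v,
      ci_lower = est - hw, ci_upper = est + hw,
      alpha = alpha, scale = ac$scale, method = ac$method
    ),
    class = "indirect_comparison"
  )
}

#' @export
print.indirect_comparison <- function(x, ...) {
  cat(sprintf("<indirect_comparison: A vs B via common comparator, %s>\n",
              x$method))
  cat(sprintf("  estimate %.4f (%s), %d%% CI [%.4f, %.4f]\n",
              x$estimate, x$scale, round(100 * (1 - x$alpha)),
              x$ci_lower, x$ci_upper))
  invisible(x)
}
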