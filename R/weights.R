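#' Aggregate-level data from the competitor trial
#'
#' Bundles the published summaries available for the competitor (B vs. C)
#' study: baseline covariate means, the unadjusted marginal effect estimate
#' for B vs. C, and its variance.  This is the only competitor-study
#' information the anchored comparison is allowed to see.
#'
#' @param covariate_means Named numeric vector of published covariate means
#'   (names must match the index-trial covariate columns they summarize).
#' @param effect_estimate Marginal B-vs-C effect estimate on the linear
#'   predictor scale.
#' @param effect_variance Its variance (non-negative).
#' @param sample_size Optional competitor-trial sample size.
#' @param scale Effect scale label; one of `"mean_difference"`,
#'   `"log_odds_ratio"`, `"log_risk_ratio"`, `"risk_difference"`.
#'
#' @return An object of class `competitor_ald`.
#' @export
#' @examples
#' competitor_ald(c(x1 = 0.6, x2 = 0.6, x3 = 0.6), -0.2, 0.05, 300)
competitor_ald <- function(covariate_means, effect_estimate, effect_variance,
                           sample_size = NULL, scale = "mean_difference") {
  if (!is.numeric(covariate_means) || anyNA(covariate_means) ||
      any(!is.finite(covariate_means))) {
    stop_shape("covariate_means must be finite numeric values")
  }
  if (is.null(names(covariate_means)) || any(names(covariate_means) == "")) {
    stop_shape("covariate_means must be a named vector")
  }
  if (!is.numeric(effect_variance) || effect_variance < 0) {
    stop_domain("effect_variance must be non-negative")
  }
  structure(
    list(
      covariate_means = covariate_means,
      effect_estimate = as.numeric(effect_estimate),
      effect_variance = as.numeric(effect_variance),
      sample_size = sample_size,
      scale = scale
    ),
    class = "competitor_ald"
  )
}

#' @export
print.competitor_ald <- function(x, ...) {
  cat("<competitor_ald>\n")
  cat("  covariate means:",
      paste(sprintf("%s=%.4g", names(x$covariate_means), x$covariate_means),
            collapse = ", "), "\n")
  cat(sprintf("  B vs C effect: %.4g (variance %.4g, scale %s)\n",
              x$effect_estimate, x$effect_variance, x$scale))
  if (!is.null(x$sample_size)) cat("  sample size:", x$sample_size, "\n")
  invisible(x)
}

#' Center index-trial effect modifiers on competitor-study means
#'
#' Subtracts the published competitor-trial mean from each selected
#' effect-modifier column, producing the centered matrix the
#' method-of-moments weight solver works on.
#'
#' @param data Index-trial data frame (one row per subject).
#' @param effect_modifiers Character vector of effect-modifier columns.
#' @param target_means Numeric vector of competitor means, one per effect
#'   modifier (a `competitor_ald` is also accepted; its means are matched
#'   by name).
#'
#' @return A numeric matrix with one column per effect modifier.
#' @export
center_covariates <- function(data, effect_modifiers, target_means) {
  z <- pull_columns(data, effect_modifiers, "effect modifier")
  theta <- resolve_targets(target_means, effect_modifiers)
  sweep(z, 2, theta)
}

resolve_targets <- function(target_means, effect_modifiers) {
  if (inherits(target_means, "competitor_ald")) {
    target_means <- target_means$covariate_means
  }
  if (!is.null(names(target_means))) {
    missing_means <- setdiff(effect_modifiers, names(target_means))
    if (length(missing_means) > 0) {
      stop_shape(sprintf(
        "no target mean supplied for effect modifier(s): %s",
        paste(missing_means, collapse = ", ")
      ))
    }
    target_means <- target_means[effect_modifiers]
  }
  if (length(target_means) != length(effect_modifiers)) {
    stop_shape(sprintf(
      "%d target means supplied for %d effect modifiers",
      length(target_means), length(effect_modifiers)
    ))
  }
  as.numeric(target_means)
}

#' Feasibility of the method-of-moments weighting problem
#'
#' A feasible solution exists only if, for every effect modifier, the
#' observed index-trial values straddle the competitor-study mean.  A
#' column whose centered values are all strictly positive or all strictly
#' negative (total separation) makes the objective function unbounded
#' from attaining its moment condition.
#'
#' @param centered Centered effect-modifier matrix from
#'   [center_covariates()].
#'
#' @return A tibble with one row per covariate (`covariate`, `n_below`,
#'   `n_above`, `separated`) and an attribute `feasible`.
#' @export
check_feasibility <- function(centered) {
  centered <- as.matrix(centered)
  if (anyNA(centered) || any(!is.finite(centered))) {
    stop_shape("centered matrix must be finite")
  }
  sep <- .separated_columns(centered)
  out <- tibble(
    covariate = colnames(centered) %||% paste0("z", seq_len(ncol(centered))),
    n_below = colSums(centered < 0),
    n_above = colSums(centered > 0),
    separated = unname(sep)
  )
  attr(out, "feasible") <- !any(sep)
  out
}

#' Trial-assignment odds weights by method of moments
#'
#' Fits the logistic trial-assignment model whose coefficients cannot be
#' estimated by maximum likelihood (competitor IPD are unavailable) by
#' minimizing the convex objective `Q(alpha) = sum_i exp(z*_i alpha)` over
#' the centered effect modifiers `z*`.  The resulting odds weights
#' `w_i = exp(z*_i alpha)` balance the weighted index-trial effect-modifier
#' means onto the competitor-study means.  Weights are defined only up to a
#' positive constant, so the intercept of the trial-assignment model is not
#' estimated.
#'
#' @inheritParams center_covariates
#' @param tol Convergence tolerance on the relative gradient norm, which
#'   equals the largest absolute balance gap on the centered scale.
#' @param max_iter Maximum number of BFGS iterations.
#'
#' @return An object of class `trial_weight_fit` with elements `alpha`,
#'   `weights`, `objective`, `grad_norm`, `converged`, `centered`, `ess`.
#' @export
#' @examples
#' ipd <- data.frame(x1 = c(0, 1), t = c(0, 1), y = c(1, 2))
#' fit <- fit_trial_weights(ipd, "x1", c(x1 = 0.75))
#' fit$alpha # log(3)
fit_trial_weights <- function(data, effect_modifiers, target_means,
                              tol = 1e-8, max_iter = 500L) {
  centered <- center_covariates(data, effect_modifiers, target_means)
  feas <- check_feasibility(centered)
  if (!attr(feas, "feasible")) {
    stop_separation(feas$covariate[feas$separated])
  }
  fit <- .maic_alpha(centered, tol = tol, max_iter = max_iter)
  if (!fit$converged) stop_convergence(fit$grad_norm, max_iter)
  structure(
    list(
      alpha = setNames(fit$alpha, effect_modifiers),
      weights = fit$weights,
      objective = fit$value,
      grad_norm = fit$grad_norm,
      converged = fit$converged,
      centered = centered,
      effect_modifiers = effect_modifiers,
      target_means = resolve_targets(target_means, effect_modifiers),
      ess = .ess_num(fit$weights),
      n = nrow(centered)
    ),
    class = "trial_weight_fit"
  )
}

#' @export
print.trial_weight_fit <- function(x, ...) {
  cat("<trial_weight_fit>\n")
  cat("  alpha:", paste(sprintf("%s=%.4f", names(x$alpha), x$alpha),
                        collapse = ", "), "\n")
  cat(sprintf("  n = %d, ESS after weighting = %.1f\n", x$n, x$ess))
  cat(sprintf("  objective = %.6g, balance gap = %.2e\n",
              x$objective, x$grad_norm))
  invisible(x)
}

#' Propensity scores for treatment assignment in the index trial
#'
#' Plain maximum-likelihood logistic regression of treatment on the
#' baseline covariates, giving each subject's estimated probability of
#' assignment to the active arm.  Used by the second stage of 2SMAIC to
#' correct chance covariate imbalances between the index trial's arms.
#'
#' @param data Index-trial data frame.
#' @param covariates Character vector of covariate columns (may be empty,
#'   giving an intercept-only model).
#' @param treatment Name of the 0/1 treatment column.
#'
#' @return An object of class `propensity_fit` with elements `beta0`,
#'   `beta1`, `scores`, and the underlying `glm` fit.
#' @export
fit_propensity <- function(data, covariates, treatment = "treatment") {
  t <- check_treatment(data[[treatment]] %||%
                         stop_shape(sprintf("column '%s' not found", treatment)))
  if (length(covariates) > 0) {
    x <- pull_columns(data, covariates, "covariate")
    df <- data.frame(..t = t, x, check.names = FALSE)
    form <- stats::reformulate(covariates, response = "..t")
  } else {
    x <- matrix(numeric(0), nrow = length(t), ncol = 0)
    df <- data.frame(..t = t)
    form <- ..t ~ 1
  }
  fit <- withCallingHandlers(
    stats::glm(form, family = binomial(), data = df),
    warning = function(w) {
      # separation is detected and reported below as a classed error
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  e <- fit$fitted.values
  if (any(e <= 1e-12 | e >= 1 - 1e-12)) {
    worst <- if (length(covariates) > 0) {
      covariates[which.max(abs(coef(fit)[-1]))]
    } else {
      "(intercept)"
    }
    abort(
      sprintf(
        "propensity model separates the treatment arms (direction dominated by '%s'); fitted probabilities reach 0/1",
        worst
      ),
      class = "maic2s_separation", covariates = worst
    )
  }
  cf <- coef(fit)
  structure(
    list(
      beta0 = unname(cf[1]),
      beta1 = if (length(cf) > 1) cf[-1] else setNames(numeric(0), NULL),
      scores = unname(e),
      treatment = t,
      covariates = covariates,
      model = fit
    ),
    class = "propensity_fit"
  )
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("<propensity_fit>\n")
  cat(sprintf("  logistic model of treatment on %d covariate(s), n = %d\n",
              length(x$covariates), length(x$scores)))
  cat(sprintf("  propensity scores in [%.3f, %.3f], mean %.3f\n",
              min(x$scores), max(x$scores), mean(x$scores)))
  invisible(x)
}

#' Construct a weight set
#'
#' Container for per-subject analysis weights with provenance (which
#' estimation stage produced them, whether they were truncated) and the
#' effective sample size.
#'
#' @param values Positive numeric weights.
#' @param stage `"trial_only"` (MAIC odds weights) or `"two_stage"`
#'   (odds weights rescaled by inverse probability of treatment weights).
#'
#' @return An object of class `weight_set`.
#' @export
weight_set <- function(values, stage = c("trial_only", "two_stage")) {
  stage <- match.arg(stage)
  if (!is.numeric(values) || anyNA(values) || any(values <= 0)) {
    stop_domain("weights must be strictly positive")
  }
  structure(
    list(values = as.numeric(values), stage = stage,
         truncated = FALSE, percentile = NA_real_,
         ess = .ess_num(values)),
    class = "weight_set"
  )
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("<weight_set: %s%s>\n", x$stage,
              if (x$truncated) sprintf(", truncated at %gth percentile", x$percentile) else ""))
  cat(sprintf("  n = %d, ESS = %.1f, range [%.3g, %.3g]\n",
              length(x$values), x$ess, min(x$values), max(x$values)))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.weight_set <- function(x, ...) {
  tibble(subject = seq_along(x$values), weight = x$values)
}

#' Extract trial-only weights from a fitted trial-assignment model
#'
#' @param fit A `trial_weight_fit`.
#' @return A `weight_set` with stage `"trial_only"`.
#' @export
trial_weight_set <- function(fit) {
  stopifnot(inherits(fit, "trial_weight_fit"))
  weight_set(fit$weights, "trial_only")
}

#' Combine trial-assignment and treatment-assignment weights
#'
#' Rescales the method-of-moments odds weights by the estimated inverse
#' probability of treatment weights: subject i receives
#' `w_i / e_i` on the active arm and `w_i / (1 - e_i)` on the comparator
#' arm.  The combined weights balance effect modifiers across studies and
#' covariates between the index trial's arms.
#'
#' @param trial_fit A `trial_weight_fit`.
#' @param propensity_fit A `propensity_fit` on the same subjects.
#'
#' @return A `weight_set` with stage `"two_stage"`.
#' @export
combine_weights <- function(trial_fit, propensity_fit) {
  stopifnot(inherits(trial_fit, "trial_weight_fit"),
            inherits(propensity_fit, "propensity_fit"))
  w <- trial_fit$weights
  e <- propensity_fit$scores
  t <- propensity_fit$treatment
  if (length(w) != length(e)) {
    stop_shape("trial and propensity fits cover different numbers of subjects")
  }
  if (any(e <= 0 | e >= 1)) {
    stop_domain("propensity scores must lie strictly inside (0, 1)")
  }
  weight_set(.combine_weights_num(w, e, t), "two_stage")
}

#' Truncate extreme weights at a percentile of the pooled weight vector
#'
#' All weights above the chosen percentile (default the 95th, computed by
#' linear interpolation on the pooled weights across both arms) are
#' replaced by the value of that percentile.  Truncation trades balance
#' for stability: it reduces the influence of extreme weights at the cost
#' of bias.
#'
#' @param ws A `weight_set`.
#' @param percentile Percentile cutpoint in (0, 100].
#'
#' @return A `weight_set` flagged as truncated.
#' @export
truncate_weights <- function(ws, percentile = 95) {
  stopifnot(inherits(ws, "weight_set"))
  if (!is.numeric(percentile) || percentile <= 0 || percentile > 100) {
    stop_domain("percentile must lie in (0, 100]")
  }
  out <- weight_set(.truncate_num(ws$values, percentile), ws$stage)
  out$truncated <- TRUE
  out$percentile <- percentile
  out
}

#' Effective sample size of a weighted sample
#'
#' `(sum w)^2 / sum(w^2)`: equals `n` for uniform weights, is invariant to
#' rescaling all weights by a positive constant, and shrinks as weight
#' concentration grows.  A standard one-number overlap diagnostic.
#'
#' @param w Non-negative numeric weights (not all zero), or a `weight_set`.
#' @return The effective sample size.
#' @export
#' @examples
#' ess(c(1, 1, 1, 1)) # 4
#' ess(c(1, 3)) # 1.6
ess <- function(w) {
  if (inherits(w, "weight_set")) {
    return(w$ess)
  }
  if (!is.numeric(w) || anyNA(w) || any(w < 0)) {
    stop_domain("weights must be non-negative")
  }
  if (all(w == 0)) stop_domain("weights must not all be zero")
  .ess_num(w)
}

#' Weighted covariate balance versus the competitor-study targets
#'
#' @inheritParams center_covariates
#' @param ws A `weight_set` (or bare numeric weights).
#'
#' @return A tibble with per-effect-modifier unweighted mean, weighted
#'   mean, target mean and absolute gap.
#' @export
balance_table <- function(data, ws, effect_modifiers, target_means) {
  z <- pull_columns(data, effect_modifiers, "effect modifier")
  w <- if (inherits(ws, "weight_set")) ws$values else as.numeric(ws)
  if (length(w) != nrow(z)) stop_shape("weights and data have different lengths")
  theta <- resolve_targets(target_means, effect_modifiers)
  wmean <- colSums(z * w) / sum(w)
  tibble(
    covariate = effect_modifiers,
    unweighted_mean = unname(colMeans(z)),
    weighted_mean = unname(wmean),
    target = theta,
    gap = abs(unname(wmean) - theta)
  )
}
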