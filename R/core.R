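# Fast matrix-level internals shared by the user-facing estimators and the
# simulation engine.  All functions here assume validated inputs.

.binomial_family <- binomial()

# Method-of-moments trial-assignment weights: minimize
#   Q(alpha) = sum_i exp(z*_i alpha)
# over alpha, where z* holds the effect modifiers centered on the
# competitor-study means.  Q is convex with a unique finite minimum under
# feasibility; at the optimum the weighted means of z equal the targets.
# BFGS (with the analytic gradient sum_i exp(z*_i alpha) z*_i) does the
# bulk of the work; a handful of Newton steps with the analytic Hessian
# then polishes the solution so the relative gradient norm -- which is
# exactly the weighted-mean balance gap -- drops below `tol`.
.maic_alpha <- function(zstar, tol = 1e-8, max_iter = 500L) {
  q_fun <- function(a) sum(exp(zstar %*% a))
  q_grad <- function(a) crossprod(zstar, exp(zstar %*% a))[, 1]
  opt <- optim(
    par = rep(0, ncol(zstar)), fn = q_fun, gr = q_grad, method = "BFGS",
    control = list(maxit = max_iter, reltol = 1e-12)
  )
  alpha <- opt$par
  rel_grad <- Inf
  for (it in seq_len(10L)) {
    w <- exp(zstar %*% alpha)[, 1]
    g <- crossprod(zstar, w)[, 1]
    rel_grad <- max(abs(g)) / sum(w)
    if (rel_grad < tol * 1e-2 && it > 1L) break
    hess <- crossprod(zstar * w, zstar)
    step <- tryCatch(solve(hess, g), error = function(e) g / diag(hess))
    alpha <- alpha - step
  }
  w <- exp(zstar %*% alpha)[, 1]
  g <- crossprod(zstar, w)[, 1]
  rel_grad <- max(abs(g)) / sum(w)
  list(
    alpha = alpha, weights = w, value = sum(w),
    grad_norm = rel_grad, converged = rel_grad < tol,
    iterations = opt$counts[["function"]]
  )
}

# strict one-sided columns => no feasible method-of-moments solution
.separated_columns <- function(zstar) {
  n <- nrow(zstar)
  colSums(zstar > 0) == n | colSums(zstar < 0) == n
}

.propensity_scores <- function(x, t) {
  fit <- glm.fit(cbind(`(Intercept)` = 1, x), t, family = .binomial_family)
  fit$fitted.values
}

.combine_weights_num <- function(w, e, t) {
  w * (t / e + (1 - t) / (1 - e))
}

.truncate_num <- function(w, percentile) {
  pmin(w, quantile(w, percentile / 100, type = 7, names = FALSE))
}

.ess_num <- function(w) sum(w)^2 / sum(w^2)

.arm_means <- function(y, t, w) {
  i1 <- t == 1
  s1 <- sum(w[i1])
  s0 <- sum(w[!i1])
  if (!(s1 > 0) || !(s0 > 0)) {
    stop_domain("an arm has zero total weight; marginal means are undefined")
  }
  c(mu1 = sum(y[i1] * w[i1]) / s1, mu0 = sum(y[!i1] * w[!i1]) / s0)
}

.link_contrast <- function(mu1, mu0, scale) {
  switch(scale,
    mean_difference = mu1 - mu0,
    risk_difference = {
      .check_prob(c(mu1, mu0))
      mu1 - mu0
    },
    log_odds_ratio = {
      .check_prob(c(mu1, mu0))
      log(mu1 / (1 - mu1)) - log(mu0 / (1 - mu0))
    },
    log_risk_ratio = {
      .check_prob(c(mu1, mu0))
      log(mu1) - log(mu0)
    },
    stop_domain(sprintf("unknown scale '%s'", scale))
  )
}

.check_prob <- function(mu) {
  if (any(mu <= 0 | mu >= 1)) {
    stop_domain("marginal means must lie in (0, 1) for this link")
  }
  invisible(mu)
}

# Point estimates of the A-vs-C marginal contrast for the requested methods
# on one dataset.  `zstar` are centered effect modifiers, `x` the full
# covariate matrix for the propensity stage.  Returns NULL when the
# method-of-moments problem is infeasible (caller decides the policy).
.method_estimates <- function(zstar, x, t, y, methods, percentile, scale,
                              return_weights = FALSE) {
  if (length(unique(t)) < 2) {
    return(NULL)
  }
  if (any(.separated_columns(zstar))) {
    return(NULL)
  }
  fit <- .maic_alpha(zstar)
  if (!fit$converged) {
    return(NULL)
  }
  w <- fit$weights
  need_two_stage <- any(methods %in% c("2SMAIC", "T-2SMAIC"))
  omega <- NULL
  if (need_two_stage) {
    e <- .propensity_scores(x, t)
    if (any(e <= 1e-12 | e >= 1 - 1e-12)) {
      return(NULL)
    }
    omega <- .combine_weights_num(w, e, t)
  }
  weight_list <- list()
  est <- vapply(methods, function(m) {
    wm <- switch(m,
      "MAIC" = w,
      "2SMAIC" = omega,
      "T-MAIC" = .truncate_num(w, percentile),
      "T-2SMAIC" = .truncate_num(omega, percentile),
      stop_domain(sprintf("unknown method '%s'", m))
    )
    if (return_weights) weight_list[[m]] <<- wm
    mu <- .arm_means(y, t, wm)
    .link_contrast(mu[["mu1"]], mu[["mu0"]], scale)
  }, numeric(1))
  out <- list(estimates = est)
  if (return_weights) out$weights <- weight_list
  out
}

# Ordinary non-parametric bootstrap over index-trial rows: each resample
# re-estimates the trial-assignment model (and, for the two-stage methods,
# the propensity model) before recomputing the A-vs-C contrast.  All
# requested methods are evaluated on the same resamples.  Resamples that
# hit separation or a degenerate fit are redrawn, up to `max_redraw * B`
# attempts in total.
.bootstrap_methods <- function(zstar, x, t, y, B, methods, percentile, scale,
                               stratified = FALSE, max_redraw = 10L) {
  n <- length(t)
  est <- matrix(NA_real_, nrow = B, ncol = length(methods),
                dimnames = list(NULL, methods))
  idx1 <- which(t == 1)
  idx0 <- which(t == 0)
  b <- 0L
  attempts <- 0L
  max_attempts <- max_redraw * B
  while (b < B && attempts < max_attempts) {
    attempts <- attempts + 1L
    idx <- if (stratified) {
      c(sample(idx1, length(idx1), replace = TRUE),
        sample(idx0, length(idx0), replace = TRUE))
    } else {
      sample.int(n, n, replace = TRUE)
    }
    r <- .method_estimates(
      zstar[idx, , drop = FALSE], x[idx, , drop = FALSE],
      t[idx], y[idx], methods, percentile, scale
    )
    if (is.null(r)) next
    b <- b + 1L
    est[b, ] <- r$estimates
  }
  if (b < B) {
    stop_domain(sprintf(
      "bootstrap failed: only %d of %d resamples produced estimates after %d attempts",
      b, B, attempts
    ))
  }
  list(estimates = est, n_redrawn = attempts - B)
}
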