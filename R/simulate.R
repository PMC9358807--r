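#' Outcome-model coefficients for the simulation engine
#'
#' The data-generating outcome model for both trials is
#' `y = b0 + x b1 + (bt + x b2) 1(t = 1) + e`, with `e ~ N(0, error_sd^2)`:
#' every covariate is prognostic (`b1`) and modifies the treatment effect
#' through a first-order covariate-treatment interaction (`b2`).  The
#' defaults are the replication configuration: three covariates, strong
#' prognostic effects (2), notable effect modification (1), a strong
#' baseline conditional treatment effect (-2), intercept 5 and unit error.
#'
#' @param intercept Outcome-model intercept.
#' @param prognostic Length-k vector of covariate main effects.
#' @param interaction Length-k vector of covariate-treatment interactions.
#' @param treatment_main Conditional treatment effect at covariate zero.
#' @param error_sd Standard deviation of the normal error term.
#'
#' @return An object of class `dgm_coefficients`.
#' @export
dgm_coefficients <- function(intercept = 5, prognostic = rep(2, 3),
                             interaction = rep(1, 3), treatment_main = -2,
                             error_sd = 1) {
  if (length(prognostic) != length(interaction)) {
    stop_shape("prognostic and interaction coefficient vectors must have equal length")
  }
  if (error_sd < 0) stop_domain("error_sd must be non-negative")
  structure(
    list(intercept = intercept, prognostic = prognostic,
         interaction = interaction, treatment_main = treatment_main,
         error_sd = error_sd, k = length(prognostic)),
    class = "dgm_coefficients"
  )
}

#' Simulate correlated baseline covariates
#'
#' Draws an n-by-k covariate matrix from a multivariate normal
#' distribution with common marginal mean and standard deviation and a
#' common pairwise correlation (compound-symmetric covariance).
#'
#' @param n Number of subjects.
#' @param mean Common covariate mean.
#' @param sd Common covariate standard deviation.
#' @param corr Common pairwise correlation.
#' @param k Number of covariates.
#'
#' @return A numeric matrix with columns `x1, ..., xk`.
#' @export
sim_covariates <- function(n, mean, sd = 0.4, corr = 0.2, k = 3) {
  sigma <- matrix(corr * sd^2, k, k)
  diag(sigma) <- sd^2
  ok <- tryCatch({
    chol(sigma)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_domain("covariance matrix is not positive definite")
  x <- MASS::mvrnorm(n, mu = rep(mean, k), Sigma = sigma)
  x <- matrix(x, nrow = n, ncol = k)
  colnames(x) <- paste0("x", seq_len(k))
  x
}

#' Assign treatment under a 1:1 allocation
#'
#' Default is a fixed exact split: `floor(n/2)` subjects on the active arm
#' and the rest on the comparator, in a random order.  A Bernoulli(0.5)
#' mode is available behind a flag.
#'
#' @param n Number of subjects (at least 2).
#' @param method `"permutation"` (fixed arm sizes) or `"bernoulli"`.
#'
#' @return An integer 0/1 vector of length n.
#' @export
sim_treatment <- function(n, method = c("permutation", "bernoulli")) {
  method <- match.arg(method)
  if (n < 2) stop_domain("n must be at least 2")
  if (method == "bernoulli") {
    return(stats::rbinom(n, 1L, 0.5))
  }
  sample(rep(c(1L, 0L), c(n %/% 2, n - n %/% 2)))
}

#' Simulate outcomes from the linear interaction model
#'
#' @param x Covariate matrix.
#' @param treatment 0/1 vector.
#' @param coef A [dgm_coefficients()] object.
#'
#' @return Numeric outcome vector.
#' @export
#' @examples
#' coef <- dgm_coefficients(error_sd = 0)
#' x <- matrix(0.6, 1, 3)
#' sim_outcomes(x, 1L, coef) # 8.4
sim_outcomes <- function(x, treatment, coef = dgm_coefficients()) {
  x <- as.matrix(x)
  if (ncol(x) != coef$k) stop_shape("covariate matrix and coefficients disagree on k")
  if (nrow(x) != length(treatment)) stop_shape("x and treatment have different lengths")
  lp <- coef$intercept + drop(x %*% coef$prognostic) +
    (coef$treatment_main + drop(x %*% coef$interaction)) * (treatment == 1)
  lp + rnorm(nrow(x), 0, coef$error_sd)
}

#' Simulate one two-arm trial
#'
#' @inheritParams sim_covariates
#' @param coef A [dgm_coefficients()] object.
#' @param allocation Treatment allocation mode, see [sim_treatment()].
#'
#' @return A tibble with covariate columns, `treatment` and `outcome`.
#' @export
sim_trial <- function(n, mean, coef = dgm_coefficients(), sd = 0.4,
                      corr = 0.2, allocation = "permutation") {
  x <- sim_covariates(n, mean, sd = sd, corr = corr, k = coef$k)
  t <- sim_treatment(n, allocation)
  y <- sim_outcomes(x, t, coef)
  out <- as_tibble(as.data.frame(x))
  out$treatment <- t
  out$outcome <- y
  out
}

#' Aggregate a competitor trial into published-style summaries
#'
#' Reduces competitor-trial IPD to the aggregate-level data an analyst
#' would find in the study publication: realized covariate sample means
#' plus the unadjusted OLS estimate of the marginal B-vs-C mean difference
#' with its nominal variance.  The returned object carries no
#' subject-level records, enforcing the data constraint under which the
#' anchored comparison operates.
#'
#' @param trial Competitor-trial tibble from [sim_trial()].
#' @param covariates Covariate columns to summarize (default: all `x*`).
#' @param outcome,treatment Outcome and treatment column names.
#'
#' @return A [competitor_ald()].
#' @export
aggregate_ald <- function(trial, covariates = NULL, outcome = "outcome",
                          treatment = "treatment") {
  if (is.null(covariates)) {
    covariates <- grep("^x[0-9]+$", names(trial), value = TRUE)
  }
  x <- pull_columns(trial, covariates, "covariate")
  eff <- unadjusted_effect(trial, outcome = outcome, treatment = treatment)
  competitor_ald(
    covariate_means = colMeans(x),
    effect_estimate = eff$estimate,
    effect_variance = eff$variance,
    sample_size = nrow(trial)
  )
}

#' True effects implied by the data-generating mechanism
#'
#' Under the linear interaction model the conditional treatment effect in
#' a population with covariate means `m` is
#' `treatment_main + sum(interaction * m)`; mean differences are
#' collapsible, so marginal and conditional effects coincide.  Both active
#' treatments share the effect modifiers and interaction coefficients, so
#' the A-vs-B effect in the competitor population is zero by construction.
#'
#' @param coef A [dgm_coefficients()] object.
#' @param competitor_cov_mean Covariate mean(s) of the competitor
#'   population (scalar recycled across covariates, or length-k vector).
#'
#' @return A tibble with `delta_AC`, `delta_BC` and `delta_AB`.
#' @export
#' @examples
#' true_effects() # -0.2, -0.2, 0
true_effects <- function(coef = dgm_coefficients(),
                         competitor_cov_mean = 0.6) {
  m <- rep_len(competitor_cov_mean, coef$k)
  d <- coef$treatment_main + sum(coef$interaction * m)
  tibble(delta_AC = d, delta_BC = d, delta_AB = 0)
}

#' One simulation scenario
#'
#' @param scenario_id Integer label.
#' @param index_n Index-trial sample size.
#' @param index_cov_mean Index-trial covariate mean (0.5, 0.4, 0.3 give
#'   strong, moderate and poor overlap against the competitor mean 0.6).
#' @param competitor_n,competitor_cov_mean Competitor-trial size and mean.
#' @param cov_sd,cov_corr,k Covariate scale, correlation, and count.
#' @param n_sim Number of simulation replicates.
#' @param n_boot Bootstrap resamples per replicate.
#' @param truncation_percentile Truncation cutpoint for T-MAIC/T-2SMAIC.
#' @param base_seed Base seed of the scenario's deterministic seed stream.
#'
#' @return A one-row tibble.
#' @export
scenario_spec <- function(scenario_id, index_n, index_cov_mean,
                          competitor_n = 300L, competitor_cov_mean = 0.6,
                          cov_sd = 0.4, cov_corr = 0.2, k = 3L,
                          n_sim = 5000L, n_boot = 2000L,
                          truncation_percentile = 95, base_seed = 1L) {
  if (index_n < 2 || competitor_n < 2) stop_domain("trial sizes must be at least 2")
  if (abs(cov_corr) >= 1) stop_domain("cov_corr must lie in (-1, 1)")
  overlap <- if (index_cov_mean >= 0.5) {
    "strong"
  } else if (index_cov_mean >= 0.4) "moderate" else "poor"
  tibble(
    scenario_id = as.integer(scenario_id),
    index_n = as.integer(index_n),
    index_cov_mean = index_cov_mean,
    overlap = overlap,
    competitor_n = as.integer(competitor_n),
    competitor_cov_mean = competitor_cov_mean,
    cov_sd = cov_sd, cov_corr = cov_corr, k = as.integer(k),
    n_sim = as.integer(n_sim), n_boot = as.integer(n_boot),
    truncation_percentile = truncation_percentile,
    base_seed = as.integer(base_seed)
  )
}

#' The six-scenario factorial grid
#'
#' Two index-trial sample sizes (140, 200) crossed with three overlap
#' settings (index covariate means 0.5, 0.4, 0.3 against the competitor
#' mean 0.6).  The `"paper"` preset uses 5000 replicates and 2000
#' bootstrap resamples; the `"scaled"` preset, used by the package's own
#' checks, uses 500 and 200.
#'
#' @param preset `"paper"` or `"scaled"`.
#' @param n_sim,n_boot Override the preset sizes.
#' @param base_seed Base seed shared by the grid.
#'
#' @return A six-row scenario tibble.
#' @export
scenario_grid <- function(preset = c("paper", "scaled"), n_sim = NULL,
                          n_boot = NULL, base_seed = 1L) {
  preset <- match.arg(preset)
  n_sim <- n_sim %||% switch(preset, paper = 5000L, scaled = 500L)
  n_boot <- n_boot %||% switch(preset, paper = 2000L, scaled = 200L)
  cells <- expand.grid(index_n = c(140L, 200L),
                       index_cov_mean = c(0.5, 0.4, 0.3))
  dplyr::bind_rows(purrr::pmap(
    list(seq_len(nrow(cells)), cells$index_n, cells$index_cov_mean),
    function(id, n, m) {
      scenario_spec(id, n, m, n_sim = n_sim, n_boot = n_boot,
                    base_seed = base_seed)
    }
  ))
}

#' Run one simulation replicate
#'
#' Draws an index trial and a competitor trial, aggregates the competitor
#' trial to ALD, and analyzes the index IPD with the requested methods,
#' all sharing the same unadjusted B-vs-C estimate.  If the original index
#' sample is infeasible for the method-of-moments weights (total
#' separation on a covariate) the replicate is discarded.  The replicate's
#' random stream is derived deterministically from
#' `(base_seed, scenario_id, replicate_id)`.
#'
#' @param spec A one-row scenario tibble from [scenario_spec()].
#' @param replicate_id Replicate number within the scenario.
#' @param coef A [dgm_coefficients()] object.
#' @param methods Methods to run.
#' @param alpha Wald interval error rate.
#'
#' @return A tibble with one row per method: estimates, variance, Wald CI
#'   for the A-vs-B effect, A-vs-C estimate, ESS, status and bookkeeping.
#' @export
run_replicate <- function(spec, replicate_id, coef = dgm_coefficients(),
                          methods = c("MAIC", "2SMAIC", "T-MAIC", "T-2SMAIC"),
                          alpha = 0.05) {
  seed <- child_seed(spec$base_seed, spec$scenario_id, replicate_id)
  set.seed(seed)
  base <- tibble(
    scenario_id = spec$scenario_id, replicate_id = as.integer(replicate_id),
    seed = seed, method = methods
  )
  index <- sim_trial(spec$index_n, spec$index_cov_mean, coef,
                     sd = spec$cov_sd, corr = spec$cov_corr)
  competitor <- sim_trial(spec$competitor_n, spec$competitor_cov_mean, coef,
                          sd = spec$cov_sd, corr = spec$cov_corr)
  ald <- aggregate_ald(competitor)
  covs <- paste0("x", seq_len(spec$k))
  x <- pull_columns(index, covs, "covariate")
  zstar <- sweep(x, 2, ald$covariate_means)
  t <- as.numeric(index$treatment)
  y <- index$outcome
  empty <- function(status) {
    dplyr::mutate(base,
      estimate = NA_real_, variance = NA_real_,
      ci_lower = NA_real_, ci_upper = NA_real_,
      estimate_AC = NA_real_, ess = NA_real_,
      n_redrawn = NA_integer_, status = status
    )
  }
  if (any(.separated_columns(zstar))) {
    return(empty("discarded_separation"))
  }
  orig <- .method_estimates(zstar, x, t, y, methods,
                            spec$truncation_percentile, "mean_difference",
                            return_weights = TRUE)
  if (is.null(orig)) {
    return(empty("failed"))
  }
  boot <- tryCatch(
    .bootstrap_methods(zstar, x, t, y, spec$n_boot, methods,
                       spec$truncation_percentile, "mean_difference"),
    error = function(e) NULL
  )
  if (is.null(boot)) {
    return(empty("failed"))
  }
  d10 <- colMeans(boot$estimates)
  v10 <- apply(boot$estimates, 2, var)
  d12 <- d10 - ald$effect_estimate
  v12 <- v10 + ald$effect_variance
  hw <- qnorm(1 - alpha / 2) * sqrt(v12)
  dplyr::mutate(base,
    estimate = unname(d12), variance = unname(v12),
    ci_lower = unname(d12 - hw), ci_upper = unname(d12 + hw),
    estimate_AC = unname(d10),
    ess = vapply(orig$weights[methods], .ess_num, numeric(1)),
    n_redrawn = boot$n_redrawn, status = "ok"
  )
}

#' Run the full simulation study
#'
#' Executes every replicate of every scenario in the grid and stacks the
#' per-method results.  Discarded and failed replicates are kept as rows
#' with `status != "ok"` so downstream accounting can report them.
#'
#' @param grid Scenario tibble from [scenario_grid()] (or a subset of its
#'   rows).
#' @param coef A [dgm_coefficients()] object.
#' @param methods Methods to run in each replicate.
#' @param progress Print a line as each scenario finishes.
#'
#' @return A tibble of replicate-by-method results, carrying the scenario
#'   descriptors (`index_n`, `index_cov_mean`, `overlap`) as columns.
#' @export
run_study <- function(grid, coef = dgm_coefficients(),
                      methods = c("MAIC", "2SMAIC", "T-MAIC", "T-2SMAIC"),
                      progress = FALSE) {
  if (nrow(grid) < 1) stop_shape("scenario grid is empty")
  res <- purrr::map(seq_len(nrow(grid)), function(i) {
    spec <- grid[i, ]
    rows <- purrr::map(seq_len(spec$n_sim), function(r) {
      run_replicate(spec, r, coef = coef, methods = methods)
    })
    out <- dplyr::bind_rows(rows)
    out$index_n <- spec$index_n
    out$index_cov_mean <- spec$index_cov_mean
    out$overlap <- spec$overlap
    if (progress) {
      message(sprintf("scenario %d/%d done (%d replicates)",
                      i, nrow(grid), spec$n_sim))
    }
    out
  })
  dplyr::bind_rows(res)
}
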