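test_that("centering subtracts the competitor means and catches shape errors", {
  d <- data.frame(x1 = c(0.5, 0.7))
  expect_equal(center_covariates(d, "x1", c(x1 = 0.6))[, 1], c(-0.1, 0.1))

  d2 <- data.frame(x1 = c(0.2, 0.4), x2 = c(1, 3))
  z <- center_covariates(d2, c("x1", "x2"), c(x1 = 0.3, x2 = 2))
  expect_equal(unname(colMeans(z)), c(0, 0))

  expect_error(center_covariates(d2, c("x1", "x2"), 0.3),
               class = "maic2s_shape")
  expect_error(center_covariates(d2, "x3", c(x3 = 1)),
               class = "maic2s_shape")

  set.seed(11)
  x <- sim_covariates(5000, 0.3)
  zc <- center_covariates(as.data.frame(x), colnames(x),
                          setNames(rep(0.6, 3), colnames(x)))
  expect_true(all(abs(colMeans(zc) + 0.3) < 4 * 0.4 / sqrt(5000)))
})

test_that("feasibility detector flags one-sided covariates", {
  z <- cbind(a = c(0.1, 0.2, 0.3), b = c(-0.1, 0.2, 0.1))
  rep <- check_feasibility(z)
  expect_equal(rep$separated, c(TRUE, FALSE))
  expect_false(attr(rep, "feasible"))
  expect_true(attr(check_feasibility(cbind(c(-0.1, 0.2))), "feasible"))
  # the discarded-replicate situation: a covariate entirely below its target
  d <- make_index(140, 0.3, seed = 3)
  z2 <- center_covariates(d, "x1", c(x1 = 10))
  expect_false(attr(check_feasibility(z2), "feasible"))
})

test_that("method-of-moments weights satisfy their defining conditions", {
  # sample means already on target -> alpha = 0, unit weights
  d <- data.frame(x1 = c(0.4, 0.8), treatment = 0:1, outcome = 1:2)
  f0 <- fit_trial_weights(d, "x1", c(x1 = 0.6))
  expect_equal(unname(f0$alpha), 0, tolerance = 1e-8)
  expect_equal(f0$weights, c(1, 1), tolerance = 1e-8)

  # closed-form 2-point oracle: solve 0.25 e^{0.25a} = 0.75 e^{-0.75a}
  d2 <- data.frame(x1 = c(0, 1))
  f <- fit_trial_weights(d2, "x1", c(x1 = 0.75))
  expect_equal(unname(f$alpha), log(3), tolerance = 1e-7)
  expect_equal(f$weights, c(0.4386913, 1.3160740), tolerance = 1e-6)
  expect_equal(sum(f$weights * c(0, 1)) / sum(f$weights), 0.75,
               tolerance = 1e-8)

  # moment matching + gradient-zero + convexity across random draws
  for (seed in 1:5) {
    idx <- make_index(60, 0.4, seed = seed)
    targets <- setNames(rep(0.6, 3), paste0("x", 1:3))
    fit <- fit_trial_weights(idx, paste0("x", 1:3), targets)
    bal <- balance_table(idx, trial_weight_set(fit), paste0("x", 1:3), targets)
    expect_true(all(bal$gap < 1e-6))
    expect_lt(fit$grad_norm, 1e-8)
    # Q is convex: perturbing alpha never drops below the optimum
    z <- fit$centered
    q <- function(a) sum(exp(z %*% a))
    for (j in 1:3) {
      e <- rep(0, 3); e[j] <- 0.05
      expect_gte(q(fit$alpha + e) + 1e-10, fit$objective)
      expect_gte(q(fit$alpha - e) + 1e-10, fit$objective)
    }
  }

  # separation raises a classed error naming the covariate
  expect_error(
    fit_trial_weights(data.frame(x1 = c(0.1, 0.2)), "x1", c(x1 = 0.5)),
    class = "maic2s_separation"
  )
  expect_match(
    tryCatch(fit_trial_weights(data.frame(x1 = c(0.1, 0.2)), "x1",
                               c(x1 = 0.5)),
             error = conditionMessage),
    "x1"
  )
})

test_that("1-D solver agrees with a bisection oracle at tiny n", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(2:5, 1)
    z <- runif(n)
    theta <- runif(1, min(z) + 0.01, max(z) - 0.01)
    d <- data.frame(x1 = z)
    fit <- fit_trial_weights(d, "x1", c(x1 = theta))
    oracle <- bisect_alpha(z - theta)
    expect_equal(unname(fit$alpha), oracle, tolerance = 1e-6)
  }
})

test_that("propensity scores obey the logistic score equations", {
  idx <- make_index(140, 0.5, seed = 7)
  pf <- fit_propensity(idx, paste0("x", 1:3))
  t <- idx$treatment
  x <- as.matrix(idx[paste0("x", 1:3)])
  expect_lt(abs(sum(t - pf$scores)), 1e-6)
  expect_true(all(abs(colSums((t - pf$scores) * x)) < 1e-6))
  expect_equal(mean(pf$scores), mean(t), tolerance = 1e-8)
  expect_true(all(pf$scores > 0 & pf$scores < 1))
  # scores reproduce expit of the linear predictor
  lp <- pf$beta0 + drop(x %*% pf$beta1)
  expect_equal(pf$scores, plogis(lp), tolerance = 1e-8)

  # intercept-only model: every score equals the treated fraction
  p0 <- fit_propensity(idx, character(0))
  expect_equal(p0$scores, rep(mean(t), nrow(idx)), tolerance = 1e-8)

  # randomized design: no covariate truly predicts treatment, so every
  # coefficient stays within sampling error of zero
  big <- make_index(4000, 0.5, seed = 8)
  pb <- fit_propensity(big, paste0("x", 1:3))
  se <- sqrt(diag(vcov(pb$model)))[-1]
  expect_true(all(abs(pb$beta1) < 4 * se))
  expect_equal(mean(pb$scores), 0.5, tolerance = 0.01)

  # perfect separation is reported as an error
  sepd <- data.frame(x1 = c(1, 2, 3, 10, 11, 12),
                     treatment = c(0, 0, 0, 1, 1, 1))
  expect_error(fit_propensity(sepd, "x1"), class = "maic2s_separation")
})

test_that("combined weights follow the two-stage formula", {
  idx <- make_index(40, 0.5, seed = 9)
  tw <- fit_trial_weights(idx, paste0("x", 1:3),
                          setNames(rep(0.55, 3), paste0("x", 1:3)))
  pf <- fit_propensity(idx, paste0("x", 1:3))
  cw <- combine_weights(tw, pf)
  t <- idx$treatment
  manual <- t * tw$weights / pf$scores +
    (1 - t) * tw$weights / (1 - pf$scores)
  expect_equal(cw$values, manual)
  expect_identical(cw$stage, "two_stage")
  expect_true(all(cw$values > 0))

  # spot arithmetic: treated w=0.5 e=0.25 -> 2; control w=0.5 e=0.25 -> 2/3
  expect_equal(0.5 * (1 / 0.25), 2)
  expect_equal(.5 / (1 - 0.25), 2 / 3, tolerance = 1e-12)
})

test_that("uniform propensity scores reduce two-stage to one-stage", {
  idx <- make_index(60, 0.5, seed = 10)
  targets <- setNames(rep(0.55, 3), paste0("x", 1:3))
  tw <- fit_trial_weights(idx, paste0("x", 1:3), targets)
  pf <- fit_propensity(idx, character(0)) # e_i = 1/2 under the 1:1 split
  cw <- combine_weights(tw, pf)
  expect_equal(cw$values, 2 * tw$weights, tolerance = 1e-8)
  m1 <- weighted_arm_means(idx, trial_weight_set(tw))
  m2 <- weighted_arm_means(idx, cw)
  expect_equal(m1$mean, m2$mean, tolerance = 1e-10)
  expect_equal(ess(cw), ess(trial_weight_set(tw)), tolerance = 1e-8)
})

test_that("truncation caps at the pooled percentile and nothing else", {
  ws <- weight_set(rep(2, 10))
  expect_equal(truncate_weights(ws)$values, ws$values)

  w <- c(rep(1, 20), 100)
  cap <- unname(quantile(w, 0.95, type = 7))
  tr <- truncate_weights(weight_set(w), 95)
  expect_equal(tr$values, pmin(w, cap))
  expect_equal(max(tr$values), cap)
  expect_true(all(tr$values <= w))
  expect_equal(sum(tr$values < w), 1) # only the outlier is capped

  expect_equal(truncate_weights(weight_set(w), 100)$values, w)
  expect_error(truncate_weights(weight_set(w), 0), class = "maic2s_domain")
  expect_true(tr$truncated)
  expect_equal(tr$percentile, 95)
})

test_that("effective sample size has its closed form and invariances", {
  expect_equal(ess(c(1, 1, 1, 1)), 4)
  expect_equal(ess(c(2, 2)), 2)
  expect_equal(ess(c(1, 3)), 1.6)
  set.seed(2)
  w <- rexp(50)
  expect_equal(ess(w), ess(3.7 * w), tolerance = 1e-12)
  expect_lte(ess(w), 50)
  expect_error(ess(rep(0, 3)), class = "maic2s_domain")
  expect_error(ess(c(-1, 2)), class = "maic2s_domain")
})

test_that("balance diagnostics report weighted and target means", {
  idx <- make_index(50, 0.5, seed = 12)
  targets <- setNames(rep(0.6, 3), paste0("x", 1:3))
  # unit weights reproduce the sample means
  b0 <- balance_table(idx, rep(1, 50), paste0("x", 1:3), targets)
  expect_equal(b0$weighted_mean, b0$unweighted_mean)
  # converged fit: gaps vanish
  tw <- fit_trial_weights(idx, paste0("x", 1:3), targets)
  b1 <- balance_table(idx, trial_weight_set(tw), paste0("x", 1:3), targets)
  expect_true(all(b1$gap < 1e-6))
  # truncated weights on a poor-overlap draw sacrifice balance
  poor <- make_index(140, 0.3, seed = 13)
  twp <- fit_trial_weights(poor, paste0("x", 1:3), targets)
  trp <- truncate_weights(trial_weight_set(twp), 95)
  b2 <- balance_table(poor, trp, paste0("x", 1:3), targets)
  # oracle: direct weighted means
  xm <- as.matrix(poor[paste0("x", 1:3)])
  expect_equal(b2$weighted_mean,
               unname(colSums(xm * trp$values) / sum(trp$values)))
  expect_true(any(b2$gap > 1e-4))
})
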