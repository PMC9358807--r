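test_that("weighted marginal means are weighted arm averages", {
  d <- data.frame(outcome = c(1, 3, 2, 4), treatment = c(1, 1, 0, 0))
  m <- weighted_arm_means(d, c(1, 3, 1, 1))
  expect_equal(m$mean[m$treatment == 1], (1 + 9) / 4) # 2.5
  expect_equal(m$mean[m$treatment == 0], 3)
  # unit weights give arithmetic means
  m0 <- weighted_arm_means(d, rep(1, 4))
  expect_equal(m0$mean, c(2, 3))
  # constant outcome is weight-invariant
  dc <- data.frame(outcome = rep(7, 4), treatment = c(1, 1, 0, 0))
  expect_equal(weighted_arm_means(dc, c(5, 1, 2, 9))$mean, c(7, 7))
})

test_that("marginal contrasts apply the link functions", {
  expect_equal(marginal_contrast(8.4, 8.6), -0.2)
  expect_equal(marginal_contrast(0.5, 0.5, "log_odds_ratio"), 0)
  expect_equal(marginal_contrast(0.75, 0.5, "log_odds_ratio"), log(3))
  expect_equal(marginal_contrast(0.4, 0.2, "log_risk_ratio"), log(2))
  expect_equal(marginal_contrast(0.4, 0.1, "risk_difference"), 0.3)
  expect_error(marginal_contrast(1.2, 0.5, "log_odds_ratio"),
               class = "maic2s_domain")
})

test_that("weighted regression equals the weighted-mean contrast", {
  idx <- make_index(80, 0.5, seed = 21)
  # exact identity on the identity link, for any weight set
  for (seed in 1:5) {
    set.seed(seed)
    w <- rexp(80) + 0.05
    m <- weighted_arm_means(idx, w)
    expect_equal(
      weighted_outcome_regression(idx, w),
      m$mean[1] - m$mean[2],
      tolerance = 1e-10
    )
  }
  # weighted logistic matches the logit contrast of weighted proportions
  set.seed(31)
  db <- data.frame(
    outcome = rbinom(200, 1, 0.4),
    treatment = rep(c(1, 0), each = 100)
  )
  w <- rexp(200) + 0.05
  mb <- weighted_arm_means(db, w)
  expect_equal(
    weighted_outcome_regression(db, w, scale = "log_odds_ratio"),
    marginal_contrast(mb$mean[1], mb$mean[2], "log_odds_ratio"),
    tolerance = 1e-6
  )
})

test_that("unadjusted effect is the OLS treatment coefficient", {
  d <- data.frame(outcome = c(3, 3, 5, 5), treatment = c(0, 0, 1, 1))
  # suppress lm's perfect-fit note on this contrived zero-residual table
  u <- suppressWarnings(unadjusted_effect(d))
  expect_equal(u$estimate, 2)
  expect_equal(u$variance, 0) # zero residual variance
  # seeded competitor draw recovers the truth within 3 nominal SEs
  set.seed(22)
  comp <- sim_trial(300, 0.6, dgm_coefficients())
  uc <- unadjusted_effect(comp)
  expect_lt(abs(uc$estimate - (-0.2)), 3 * sqrt(uc$variance))
  expect_error(
    unadjusted_effect(data.frame(outcome = 1:3, treatment = c(1, 1, 1))),
    class = "maic2s_shape"
  )
})

test_that("anchored comparison differences estimates and sums variances", {
  ac <- maic2s:::new_maic_estimate(-0.2, 0.04, "mean_difference", "MAIC")
  bc <- maic2s:::new_maic_estimate(-0.2, 0.05, "mean_difference", "unadjusted")
  cmp <- indirect_comparison(ac, bc)
  expect_equal(cmp$estimate, 0)
  expect_equal(cmp$variance, 0.09)
  expect_equal(cmp$ci_upper - cmp$estimate, 1.96 * 0.3, tolerance = 1e-3)
  expect_true(cmp$ci_lower <= cmp$estimate && cmp$estimate <= cmp$ci_upper)

  # null competitor evidence reduces to the A-vs-C estimate
  bc0 <- maic2s:::new_maic_estimate(0, 0, "mean_difference", "unadjusted")
  cmp0 <- indirect_comparison(ac, bc0)
  expect_equal(cmp0$estimate, ac$estimate)
  expect_equal(cmp0$variance, ac$variance)

  # larger alpha shrinks the interval
  wide <- indirect_comparison(ac, bc, alpha = 0.05)
  narrow <- indirect_comparison(ac, bc, alpha = 0.2)
  expect_lt(narrow$ci_upper - narrow$ci_lower,
            wide$ci_upper - wide$ci_lower)

  # scale mismatch refuses to combine
  bcl <- maic2s:::new_maic_estimate(-0.2, 0.05, "log_odds_ratio", "unadjusted")
  expect_error(indirect_comparison(ac, bcl), class = "maic2s_scale")
})

test_that("bootstrap estimation is deterministic and well-behaved", {
  idx <- make_index(100, 0.5, seed = 23)
  ald <- make_ald(seed = 24)
  em <- paste0("x", 1:3)

  r1 <- maic(idx, ald, em, method = "2SMAIC", n_boot = 60, seed = 99)
  r2 <- maic(idx, ald, em, method = "2SMAIC", n_boot = 60, seed = 99)
  expect_identical(r1$estimate, r2$estimate)
  expect_identical(r1$variance, r2$variance)
  r3 <- maic(idx, ald, em, method = "2SMAIC", n_boot = 60, seed = 100)
  expect_false(identical(r1$estimate, r3$estimate))

  # constant outcome: zero contrast, zero variance
  idc <- idx
  idc$outcome <- 5
  rc <- maic(idc, ald, em, method = "MAIC", n_boot = 30, seed = 1)
  expect_equal(rc$estimate, 0)
  expect_equal(rc$variance, 0)

  # bootstrap mean stays within 3 bootstrap SEs of the original estimate
  big <- make_index(200, 0.5, seed = 25)
  rb <- maic(big, ald, em, method = "MAIC", n_boot = 200, seed = 5)
  expect_lt(abs(rb$estimate - rb$original_estimate), 3 * sqrt(rb$variance))
  # the "original" point-estimate option reports the single-sample fit
  ro <- maic(big, ald, em, method = "MAIC", n_boot = 50, seed = 5,
             point_estimate = "original")
  expect_equal(ro$estimate, ro$original_estimate)

  # arm-stratified resampling is available behind its flag and is
  # deterministic too, but draws a different bootstrap distribution
  rs1 <- maic(idx, ald, em, method = "MAIC", n_boot = 40, seed = 7,
              stratified = TRUE)
  rs2 <- maic(idx, ald, em, method = "MAIC", n_boot = 40, seed = 7,
              stratified = TRUE)
  ru <- maic(idx, ald, em, method = "MAIC", n_boot = 40, seed = 7)
  expect_identical(rs1$estimate, rs2$estimate)
  expect_false(identical(rs1$estimate, ru$estimate))

  expect_error(maic(idx, ald, em, n_boot = 1), class = "maic2s_domain")
})

test_that("tidiers return one-row summaries with the expected columns", {
  idx <- make_index(60, 0.5, seed = 26)
  targets <- setNames(rep(0.55, 3), paste0("x", 1:3))
  tw <- fit_trial_weights(idx, paste0("x", 1:3), targets)
  expect_named(tidy(tw), c("term", "estimate"))
  expect_equal(nrow(tidy(tw)), 3)
  expect_true(glance(tw)$converged)
  pf <- fit_propensity(idx, paste0("x", 1:3))
  expect_named(tidy(pf),
               c("term", "estimate", "std.error", "statistic", "p.value"))
  ald <- make_ald(seed = 27)
  est <- maic(idx, ald, paste0("x", 1:3), method = "T-MAIC", n_boot = 30,
              seed = 2)
  td <- tidy(est)
  expect_equal(td$method, "T-MAIC")
  expect_equal(td$std.error, sqrt(est$variance))
  cmp <- indirect_comparison(est, ald)
  expect_named(tidy(cmp), c("method", "estimate", "std.error", "ci_lower",
                            "ci_upper", "alpha", "scale"))
})
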