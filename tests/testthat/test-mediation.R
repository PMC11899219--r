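# Mediator screening and two-step mediation arithmetic.

est <- function(beta, p = 1e-4, se = 0.05) {
  mr_estimate("test", beta, se, 10, pvalue = p)
}

test_that("the adiposity-like pattern passes all three screening steps", {
  dec <- screen_mediator(
    forward = est(-0.29, p = 1e-7),
    reverse = est(0.01, p = 0.3),
    reverse_intercept_p = 0.5,
    m_on_o_unadj = est(log(1.42), p = 1e-4),
    m_on_o_adj = est(log(1.34), p = 1e-3),
    total = est(log(0.68), p = 1e-3),
    alpha = 0.05, mediator = "adiposity")
  expect_true(dec$step1)
  expect_true(dec$step2)
  expect_true(dec$step3)
  expect_true(dec$final)
  expect_length(dec$reasons, 0)
})

test_that("a urate-like pattern fails at step 2", {
  dec <- screen_mediator(
    forward = est(0.12, p = 1e-5),
    reverse = est(0.01, p = 0.6),
    reverse_intercept_p = 0.5,
    m_on_o_unadj = est(0.05, p = 0.4),
    m_on_o_adj = est(0.04, p = 0.5),
    total = est(log(0.68), p = 1e-3))
  expect_true(dec$step1)
  expect_false(dec$step2)
  expect_false(dec$final)
  expect_match(paste(dec$reasons, collapse = " "), "inconsistent")
})

test_that("a significant reverse effect is discounted only when its Egger
           intercept signals pleiotropy", {
  base <- list(
    forward = est(-0.29, p = 1e-7),
    m_on_o_unadj = est(log(1.4), p = 1e-4),
    m_on_o_adj = est(log(1.3), p = 1e-3),
    total = est(log(0.68), p = 1e-3))
  # credible reverse effect -> bidirectional, excluded
  dec1 <- do.call(screen_mediator, c(base, list(
    reverse = est(0.1, p = 0.001), reverse_intercept_p = 0.5)))
  expect_false(dec1$step1)
  expect_match(paste(dec1$reasons, collapse = " "), "bidirectional")
  # same reverse effect but pleiotropy-driven -> discounted, step 1 passes
  dec2 <- do.call(screen_mediator, c(base, list(
    reverse = est(0.1, p = 0.001), reverse_intercept_p = 0.004)))
  expect_true(dec2$step1)
  expect_true(dec2$final)
})

test_that("an indirect path opposing the total effect fails step 3", {
  dec <- screen_mediator(
    forward = est(0.2, p = 1e-6),       # exposure raises the mediator
    reverse = est(0, p = 0.9), reverse_intercept_p = 0.5,
    m_on_o_unadj = est(-0.3, p = 1e-4), # mediator lowers risk
    m_on_o_adj = est(-0.25, p = 1e-4),
    total = est(log(0.68), p = 1e-3))   # protective total
  # indirect = 0.2 * -0.25 < 0 matches the protective total: passes;
  # flip the mediator-outcome sign to break it
  expect_true(dec$step3)
  dec2 <- screen_mediator(
    forward = est(0.2, p = 1e-6),
    reverse = est(0, p = 0.9), reverse_intercept_p = 0.5,
    m_on_o_unadj = est(0.3, p = 1e-4),
    m_on_o_adj = est(0.25, p = 1e-4),
    total = est(log(0.68), p = 1e-3))
  expect_false(dec2$step3)
  expect_match(paste(dec2$reasons, collapse = " "), "opposes")
})

test_that("a zero total effect voids the decision with its reason", {
  dec <- screen_mediator(
    forward = est(0.2), reverse = NULL, reverse_intercept_p = NA,
    m_on_o_unadj = est(0.3), m_on_o_adj = est(0.25), total = est(0))
  expect_false(dec$final)
  expect_identical(dec$reasons, "zero total effect")
})

test_that("product-of-coefficients arithmetic and delta limits are exact", {
  m <- mediate_single(beta1 = -0.29, sigma1 = 0.033, beta2 = log(1.34),
                      sigma2 = 0.079, total = log(0.68), se_total = 0.100)
  expect_equal(m$indirect, -0.29 * log(1.34), tolerance = 1e-12)
  expect_equal(m$proportion, (-0.29 * log(1.34)) / log(0.68),
               tolerance = 1e-12)
  expect_equal(m$se_indirect,
               sqrt(log(1.34)^2 * 0.033^2 + 0.29^2 * 0.079^2),
               tolerance = 1e-12)
  expect_equal(m$ci_low, m$proportion - 1.959964 * m$se_proportion)

  # sigma1 = 0 collapses the delta SE to |beta1| * sigma2
  m1 <- mediate_single(-0.29, 0, 0.3, 0.05, -0.4, 0.1)
  expect_equal(m1$se_indirect, 0.29 * 0.05, tolerance = 1e-12)

  # a null mediator path gives zero indirect effect and proportion
  m2 <- mediate_single(-0.29, 0.03, 0, 0.05, -0.4, 0.1)
  expect_identical(m2$indirect, 0)
  expect_identical(m2$proportion, 0)
  expect_equal(m2$se_indirect, 0.29 * 0.05, tolerance = 1e-12)

  expect_error(mediate_single(0.1, 0.01, 0.1, 0.01, 0, 0.1), "zero")
  # optional exact product-variance cross-term
  m3 <- mediate_single(-0.29, 0.03, 0.3, 0.05, -0.4, 0.1, cross_term = TRUE)
  expect_equal(m3$se_indirect^2,
               0.3^2 * 0.03^2 + 0.29^2 * 0.05^2 + 0.03^2 * 0.05^2,
               tolerance = 1e-12)
})

test_that("difference-method mediation handles no-mediation and suppression", {
  tot <- est(-0.4, se = 0.05)
  m0 <- mediate_combined(tot, est(-0.4, se = 0.04))
  expect_identical(m0$indirect, 0)
  expect_identical(m0$proportion, 0)
  expect_equal(m0$se_indirect, sqrt(0.05^2 + 0.04^2), tolerance = 1e-12)

  # direct effect overshooting past zero: proportion above 1
  expect_warning(ms <- mediate_combined(tot, est(0.1, se = 0.04)),
                 "suppression")
  expect_gt(ms$proportion, 1)
  expect_true(ms$suppression)
  # direct effect larger than the total in magnitude: negative proportion
  expect_warning(mn <- mediate_combined(tot, est(-0.55, se = 0.04)),
                 "suppression")
  expect_lt(mn$proportion, 0)
  expect_true(mn$suppression)
})

test_that("delta-method SE of the indirect effect matches the empirical SD", {
  set.seed(12)
  b1 <- -0.29; s1 <- 0.033; b2 <- log(1.34); s2 <- 0.079
  draws <- rnorm(1000, b1, s1) * rnorm(1000, b2, s2)
  delta <- mediate_single(b1, s1, b2, s2, log(0.68), 0.1)$se_indirect
  expect_equal(sd(draws) / delta, 1, tolerance = 0.1)
})

test_that("product and difference mediation agree within propagated
           uncertainty in the synthetic model", {
  agree <- sapply(1:60, function(i) {
    p <- mediation_pass(causal_scenario(seed = 3000 + i))
    comb <- suppressWarnings(mediate_combined(p$total, p$direct))
    d <- abs(p$mediation$indirect - comb$indirect)
    d < 2 * sqrt(p$mediation$se_indirect^2 + comb$se_indirect^2)
  })
  expect_gte(mean(agree), 0.95)
})
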