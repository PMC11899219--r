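# Univariable estimators: IVW, Egger, weighted median, Cochran's Q.

test_that("single-variant IVW is the Wald ratio", {
  s <- make_hset(bx = 0.2, by = 0.1, so = 0.05)
  est <- mr_ivw(s)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.25)
  expect_equal(est$n_snps, 1)
})

test_that("homogeneous ratio sets return the common ratio with zero Q", {
  for (c_true in c(0.5, -1.3, 0.01)) {
    s <- make_hset(bx = c(0.1, 0.2, 0.35), by = c_true * c(0.1, 0.2, 0.35),
                   so = c(0.01, 0.02, 0.015))
    est <- mr_ivw(s)
    expect_equal(est$beta, c_true, tolerance = 1e-12)
    q <- cochran_q(s, est$beta)
    expect_equal(q$Q, 0, tolerance = 1e-18)
    expect_equal(q$pvalue, 1)
    # zero heterogeneity means no random-effects inflation
    expect_equal(est$se, 1 / sqrt(sum(s$beta_exposure^2 / s$se_outcome^2)))
  }
})

test_that("IVW equals a brute-force weighted-RSS minimizer", {
  s <- make_hset(bx = c(0.1, 0.2, 0.3), by = c(0.03, 0.08, 0.12),
                 so = c(0.01, 0.01, 0.01))
  oracle <- optimize(function(b) {
    sum((s$beta_outcome - b * s$beta_exposure)^2 / s$se_outcome^2)
  }, c(-5, 5), tol = 1e-12)$minimum
  expect_equal(mr_ivw(s)$beta, oracle, tolerance = 1e-6)

  set.seed(4)
  for (i in 1:10) {
    n <- sample(3:25, 1)
    s <- make_hset(bx = runif(n, 0.05, 0.4), by = rnorm(n, 0, 0.1),
                   so = runif(n, 0.01, 0.1))
    oracle <- optimize(function(b) {
      sum((s$beta_outcome - b * s$beta_exposure)^2 / s$se_outcome^2)
    }, c(-20, 20), tol = 1e-12)$minimum
    expect_equal(mr_ivw(s)$beta, oracle, tolerance = 1e-6)
  }
})

test_that("IVW is invariant to joint sign flips and rejects zero exposure effects", {
  set.seed(8)
  s <- make_hset(bx = runif(10, 0.05, 0.3), by = rnorm(10, 0.1, 0.05),
                 so = runif(10, 0.01, 0.05))
  flip <- rep(c(1, -1), 5)
  s2 <- make_hset(s$beta_exposure * flip, s$beta_outcome * flip,
                  so = s$se_outcome, sx = s$se_exposure)
  expect_equal(mr_ivw(s2)$beta, mr_ivw(s)$beta, tolerance = 1e-12)
  expect_equal(mr_ivw(s2)$se, mr_ivw(s)$se, tolerance = 1e-12)

  s$beta_exposure[3] <- 0
  expect_error(mr_ivw(s), "s03")
})

test_that("Egger recovers an exact linear relationship", {
  bx <- c(0.05, 0.1, 0.18, 0.25, 0.3)
  s <- make_hset(bx, by = 0.02 + 0.05 * bx, so = rep(0.01, 5))
  eg <- mr_egger(s)
  expect_equal(eg$intercept$estimate, 0.02, tolerance = 1e-12)
  expect_equal(eg$slope$beta, 0.05, tolerance = 1e-12)
  expect_equal(eg$Q, 0, tolerance = 1e-18)
  expect_error(mr_egger(make_hset(c(0.1, 0.2), c(0.05, 0.1), c(0.01, 0.01))),
               "insufficient instruments")
})

test_that("Egger recovers the mean directional pleiotropic effect", {
  ints <- sapply(1:40, function(i) {
    sc <- causal_scenario(pleiotropy_mode = "directional",
                          pleiotropy_frac = 1, pleiotropy_sd = 0.05,
                          n_snps_mediator_extra = 0L, seed = 300 + i)
    sim <- simulate_gwas(sc)
    hs <- harmonize(select_instruments(sim$exposure), sim$outcome)
    mr_egger(hs)$intercept$estimate
  })
  expect_lt(abs(mean(ints) - 0.05), 2 * sd(ints) / sqrt(length(ints)) + 0.005)
})

test_that("weighted median interpolates at half the weight mass", {
  s <- make_hset(bx = rep(0.2, 3), by = 0.2 * c(0.1, 0.5, 0.9),
                 so = rep(0.02, 3))
  est <- mr_weighted_median(s, n_boot = 50, seed = 1)
  expect_equal(est$beta, 0.5, tolerance = 1e-12)

  # nearly all weight on one variant -> that variant's ratio
  s2 <- make_hset(bx = c(5, 0.001, 0.001), by = c(5 * 0.7, 0.0002, 0.0009),
                  so = rep(0.02, 3))
  est2 <- mr_weighted_median(s2, n_boot = 50, seed = 1)
  expect_equal(est2$beta, 0.7, tolerance = 1e-6)
})

test_that("weighted median is deterministic under a seed and its bootstrap
           leaves the caller's RNG untouched", {
  s <- planted_ratio_set(1, 10, 4)
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  a <- mr_weighted_median(s, n_boot = 200, seed = 7)
  b <- mr_weighted_median(s, n_boot = 200, seed = 7)
  after <- rnorm(1)
  expect_identical(a, b)
  expect_identical(before, after)
})

test_that("weighted median resists a minority of invalid instruments", {
  res <- sapply(1:150, function(i) {
    s <- planted_ratio_set(i, n_valid = 10, n_invalid = 4)
    c(wm = mr_weighted_median(s, n_boot = 2, seed = 1)$beta,
      ivw = mr_ivw(s)$beta)
  })
  expect_lt(abs(mean(res["wm", ]) - 0.4), 2 * sd(res["wm", ]))
  # plain IVW is pulled toward the invalid ratio
  expect_gt(mean(res["ivw", ]) - 0.4, 2 * sd(res["ivw", ]))
})

test_that("Cochran's Q matches direct summation and is unit-scaled under
           the null", {
  bx <- c(0.1, 0.2, 0.3); by <- c(0.05, 0.09, 0.2); so <- c(0.01, 0.02, 0.03)
  s <- make_hset(bx, by, so)
  b0 <- 0.55
  w <- bx^2 / so^2
  manual <- sum(w * (by / bx - b0)^2)
  q <- cochran_q(s, b0)
  expect_equal(q$Q, manual, tolerance = 1e-12)
  expect_equal(q$df, 2)
  expect_equal(q$pvalue, pchisq(manual, 2, lower.tail = FALSE))

  ratio <- sapply(1:30, function(i) {
    sim <- simulate_gwas(null_scenario(600 + i))
    hs <- harmonize(select_instruments(sim$exposure), sim$outcome)
    q <- cochran_q(hs)
    q$Q / q$df
  })
  expect_equal(mean(ratio), 1, tolerance = 0.1)
})

test_that("the confidence-interval contract holds on every estimate", {
  s <- planted_ratio_set(3, 8, 2)
  for (est in list(mr_ivw(s), mr_egger(s)$slope,
                   mr_weighted_median(s, n_boot = 50, seed = 2))) {
    expect_equal(est$ci_low, est$beta - 1.959964 * est$se)
    expect_equal(est$ci_high, est$beta + 1.959964 * est$se)
    expect_equal(est$or, exp(est$beta))
    expect_equal(est$or_ci_low, exp(est$ci_low))
  }
})
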