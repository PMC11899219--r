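# The summary-statistics generator and its ground-truth accessors.

test_that("scenario accessors satisfy the structural identities exactly", {
  sc <- causal_scenario(theta_direct = -0.30, beta_EM = -0.29,
                        beta_MO = 0.293)
  expect_identical(true_total_effect(sc), -0.30 + (-0.29) * 0.293)
  expect_equal(true_total_effect(sc), -0.38497)
  expect_identical(true_mediated_proportion(sc),
                   (-0.29 * 0.293) / (-0.30 + (-0.29) * 0.293))
  expect_equal(true_mediated_proportion(sc), 0.220, tolerance = 0.005)

  sc0 <- causal_scenario(theta_direct = 0.2, beta_EM = 0, beta_MO = 0)
  expect_identical(true_mediated_proportion(sc0), 0)
  expect_error(
    true_mediated_proportion(causal_scenario(theta_direct = 0.1,
                                             beta_EM = -0.5, beta_MO = 0.2)),
    "zero")
})

test_that("invalid scenario parameters are rejected by name", {
  expect_error(causal_scenario(beta_EM = NaN), "beta_EM")
  expect_error(causal_scenario(h2_exposure = 1.2), "h2_exposure")
  expect_error(causal_scenario(h2_exposure = 0), "h2_exposure")
  expect_error(causal_scenario(pleiotropy_frac = 1.5), "pleiotropy_frac")
  expect_error(causal_scenario(overlap_rho = -0.1), "overlap_rho")
  expect_error(causal_scenario(n_exposure = Inf), "n_exposure")
})

test_that("generation is deterministic under a fixed seed", {
  sc <- causal_scenario(seed = 42)
  a <- simulate_gwas(sc)
  b <- simulate_gwas(sc)
  expect_identical(a, b)

  f1 <- tempfile(); f2 <- tempfile()
  write_sumstats(a$exposure, f1)
  write_sumstats(b$exposure, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))

  # and a different seed changes the draws
  expect_false(identical(a$exposure$beta,
                         simulate_gwas(causal_scenario(seed = 43))$exposure$beta))
})

test_that("generated tables obey the summary-statistic invariants", {
  sim <- simulate_gwas(causal_scenario(seed = 3, pleiotropy_mode = "balanced",
                                       pleiotropy_frac = 0.3,
                                       pleiotropy_sd = 0.01))
  for (tab in sim[c("exposure", "mediator", "outcome")]) {
    expect_true(all(tab$se > 0))
    expect_true(all(tab$eaf > 0 & tab$eaf < 1))
    expect_true(all(tab$effect_allele != tab$other_allele))
    # p consistent with |beta/se| under the two-sided normal test
    expect_equal(tab$pvalue, 2 * pnorm(-abs(tab$beta / tab$se)),
                 tolerance = 1e-6)
    # SEs follow the allele-frequency/sample-size formula
    expect_equal(tab$se, 1 / sqrt(2 * tab$eaf * (1 - tab$eaf) * tab$n),
                 tolerance = 1e-12)
  }
  # variance contributions scale exactly to the requested heritability
  v <- 2 * sim$exposure$eaf * (1 - sim$exposure$eaf)
  expect_equal(sum(v * sim$truth$gamma^2), 0.0184, tolerance = 1e-12)
  # variants are spaced beyond the clumping window by construction
  by_chr <- split(sim$exposure$pos, sim$exposure$chrom)
  expect_true(all(unlist(lapply(by_chr, function(p) diff(sort(p)))) > 1e6))
})

test_that("estimation noise matches its nominal standard error", {
  sc <- causal_scenario(n_snps_exposure = 12000L,
                        n_snps_mediator_extra = 0L, seed = 11)
  sim <- simulate_gwas(sc)
  z <- (sim$exposure$beta - sim$truth$beta_exposure) / sim$exposure$se
  expect_equal(sd(z), 1, tolerance = 0.05)
  z_out <- (sim$outcome$beta - sim$truth$beta_outcome) / sim$outcome$se
  expect_equal(sd(z_out), 1, tolerance = 0.05)
})

test_that("overlap_rho correlates estimation noise across trait panels", {
  sc <- causal_scenario(n_snps_exposure = 12000L,
                        n_snps_mediator_extra = 0L,
                        overlap_rho = 0.6, seed = 12)
  sim <- simulate_gwas(sc)
  zE <- (sim$exposure$beta - sim$truth$beta_exposure) / sim$exposure$se
  zO <- (sim$outcome$beta - sim$truth$beta_outcome) / sim$outcome$se
  expect_equal(cor(zE, zO), 0.6, tolerance = 0.05)
})

test_that("IVW on generated data converges to the true total effect", {
  sc_small <- causal_scenario(n_outcome_eff = 1e4, n_snps_mediator_extra = 0L)
  truth <- true_total_effect(sc_small)
  err <- function(n_out) {
    mean(sapply(1:15, function(i) {
      sc <- causal_scenario(n_outcome_eff = n_out,
                            n_snps_mediator_extra = 0L, seed = 100 + i)
      sim <- simulate_gwas(sc)
      hs <- harmonize(select_instruments(sim$exposure), sim$outcome)
      abs(mr_ivw(hs)$beta - truth)
    }))
  }
  e_small <- err(1e4)
  e_large <- err(1e6)
  expect_lt(e_large, e_small)
})

test_that("the null scenario yields pure noise for the outcome", {
  inside <- sapply(1:500, function(i) {
    sim <- simulate_gwas(null_scenario(i))
    hs <- harmonize(select_instruments(sim$exposure), sim$outcome)
    abs(mr_ivw(hs)$beta / mr_ivw(hs)$se) < 1.959964
  })
  expect_gte(mean(inside), 0.94)
})
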