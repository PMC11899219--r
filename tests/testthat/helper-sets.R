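# Shared fixture builders. Everything is generated in code; no data files.

# Minimal harmonized set from raw vectors.
make_hset <- function(bx, by, so, sx = rep(0.01, length(bx)),
                      ids = sprintf("s%02d", seq_along(bx))) {
  structure(data.frame(
    variant_id = ids,
    beta_exposure = bx, se_exposure = sx,
    beta_outcome = by, se_outcome = so,
    stringsAsFactors = FALSE
  ), class = c("mr_harmonized", "data.frame"))
}

# Multivariable set from an effect matrix, bypassing the builder, for
# algebraic checks.
make_mvset <- function(B, by, so, SE = matrix(0.01, nrow(B), ncol(B)),
                       labels = colnames(B)) {
  if (is.null(labels)) labels <- sprintf("x%d", seq_len(ncol(B)))
  colnames(B) <- colnames(SE) <- labels
  structure(list(
    variant_id = sprintf("s%02d", seq_len(nrow(B))),
    beta_exposure = B, se_exposure = SE,
    beta_outcome = by, se_outcome = so,
    exposures = labels
  ), class = "mv_harmonized")
}

# Wald-ratio set with a planted fraction of invalid instruments whose true
# ratio differs from the valid one.
planted_ratio_set <- function(seed, n_valid, n_invalid,
                              true_ratio = 0.4, bad_ratio = 2.0,
                              sx = 0.01, so = 0.02) {
  set.seed(seed)
  n <- n_valid + n_invalid
  bx <- runif(n, 0.08, 0.25)
  ratio <- c(rep(true_ratio, n_valid), rep(bad_ratio, n_invalid))
  make_hset(rnorm(n, bx, sx), rnorm(n, ratio * bx, so),
            so = rep(so, n), sx = rep(sx, n))
}

# Tiny exposure summary-statistics table for instrument-selection tests.
toy_sumstats <- function(ids, chrom, pos, pvalue, beta = 0.1, se = 0.01,
                         eaf = 0.3, n = 1e5,
                         ea = "A", oa = "G") {
  k <- length(ids)
  data.frame(
    variant_id = ids, chrom = as.character(chrom), pos = as.integer(pos),
    effect_allele = rep_len(ea, k), other_allele = rep_len(oa, k),
    eaf = rep_len(eaf, k), beta = rep_len(beta, k), se = rep_len(se, k),
    pvalue = pvalue, n = rep_len(n, k), stringsAsFactors = FALSE
  )
}

null_scenario <- function(seed, ...) {
  causal_scenario(beta_EM = 0, beta_MO = 0, theta_direct = 0,
                  n_snps_mediator_extra = 0L, seed = seed, ...)
}

# One pass of the two-step mediation workflow on a simulated scenario;
# returns the quantities parameter-recovery checks need.
mediation_pass <- function(scenario) {
  sim <- simulate_gwas(scenario)
  iv <- select_instruments(sim$exposure)
  total <- mr_ivw(harmonize(iv, sim$outcome))
  fwd <- mr_ivw(harmonize(iv, sim$mediator))
  mv <- build_mv_set(list(exposure = sim$exposure, mediator = sim$mediator),
                     sim$outcome)
  fit <- mvmr_ivw(mv)
  med <- suppressWarnings(mediate_single(
    fwd$beta, fwd$se, fit$mediator$beta, fit$mediator$se,
    total$beta, total$se))
  list(total = total, forward = fwd, direct = fit$exposure,
       adjusted = fit$mediator, mediation = med)
}
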