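#' Simulate multi-trait GWAS summary statistics under a known causal model
#'
#' Generates per-variant summary statistics for three traits (exposure,
#' mediator, binary outcome) under the structural model of a
#' [causal_scenario()]. Summary statistics are simulated directly on the
#' standardized scale: no individual-level genotypes are drawn, matching the
#' two-sample setting in which only summary data are available.
#'
#' Per-variant true exposure effects `gamma_j` are drawn from a normal
#' distribution and rescaled so that their variance contribution
#' `sum(2 * eaf * (1 - eaf) * gamma^2)` equals `h2_exposure` exactly; the
#' mediator-specific effects are scaled to `h2_mediator_extra` the same way.
#' Allele frequencies are Uniform(0.05, 0.95). Observed effects equal the true
#' effects plus estimation noise with standard error
#' `1 / sqrt(2 * eaf * (1 - eaf) * n)`; the noise of the three trait panels is
#' correlated with coefficient `overlap_rho` (equicorrelation), modelling
#' participant overlap. Horizontal pleiotropy adds an effect `alpha_j` to the
#' mediator and outcome of a designated fraction of exposure variants: mean 0
#' under balanced pleiotropy, mean `pleiotropy_sd` under directional.
#'
#' Variants are placed at least 2 Mb apart along chromosomes 1-22 so the
#' generated instruments are independent by construction and distance clumping
#' can be exercised without an LD reference. Allele pairs are drawn from
#' non-palindromic combinations with a consistent coding across traits.
#'
#' @param scenario A [causal_scenario()].
#' @return A list with elements `exposure`, `mediator`, `outcome` (each a
#'   summary-statistics `data.frame` with columns `variant_id, chrom, pos,
#'   effect_allele, other_allele, eaf, beta, se, pvalue, n`), `truth` (a
#'   `data.frame` of per-variant true effects) and `scenario`.
#' @export
#' @examples
#' tabs <- simulate_gwas(causal_scenario(seed = 7))
#' head(tabs$exposure)
simulate_gwas <- function(scenario) {
  stopifnot(inherits(scenario, "causal_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    K <- sc$n_snps_exposure
    M <- sc$n_snps_mediator_extra
    n <- K + M

    eaf <- stats::runif(n, 0.05, 0.95)
    v <- 2 * eaf * (1 - eaf)

    # effect alleles are oriented to the exposure-increasing allele, the
    # usual convention, so directional pleiotropy has a well-defined sign
    gamma <- numeric(n)
    g <- abs(stats::rnorm(K))
    gamma[seq_len(K)] <- g * sqrt(sc$h2_exposure / sum(v[seq_len(K)] * g^2))

    delta <- numeric(n)
    if (M > 0 && sc$h2_mediator_extra > 0) {
      d <- stats::rnorm(M)
      delta[K + seq_len(M)] <-
        d * sqrt(sc$h2_mediator_extra / sum(v[K + seq_len(M)] * d^2))
    }

    alpha <- numeric(n)
    if (sc$pleiotropy_mode != "none" && sc$pleiotropy_frac > 0 &&
        sc$pleiotropy_sd > 0) {
      n_pleio <- round(sc$pleiotropy_frac * K)
      if (n_pleio > 0) {
        idx <- sample(seq_len(K), n_pleio)
        mu <- if (sc$pleiotropy_mode == "directional") sc$pleiotropy_sd else 0
        alpha[idx] <- stats::rnorm(n_pleio, mean = mu, sd = sc$pleiotropy_sd)
      }
    }

    beta_E <- gamma
    beta_M <- sc$beta_EM * gamma + delta + alpha
    beta_O <- (sc$theta_direct + sc$beta_EM * sc$beta_MO) * gamma +
      sc$beta_MO * delta + alpha

    se_E <- 1 / sqrt(v * sc$n_exposure)
    se_M <- 1 / sqrt(v * sc$n_mediator)
    se_O <- 1 / sqrt(v * sc$n_outcome_eff)

    # equicorrelated estimation noise across the three panels
    R <- matrix(sc$overlap_rho, 3, 3)
    diag(R) <- 1
    Z <- matrix(stats::rnorm(3L * n), nrow = n, ncol = 3) %*% chol(R)

    obs_E <- beta_E + Z[, 1] * se_E
    obs_M <- beta_M + Z[, 2] * se_M
    obs_O <- beta_O + Z[, 3] * se_O

    pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                      "G", "A", "C", "A", "G", "T", "C", "T"),
                    ncol = 2, byrow = TRUE)
    pick <- sample.int(nrow(pairs), n, replace = TRUE)

    chrom <- as.character(rep_len(1:22, n))
    pos <- as.integer(2e6 * ceiling(seq_len(n) / 22))
    ids <- sprintf("rs%06d", seq_len(n))

    mk <- function(obs, se, nn) {
      data.frame(
        variant_id = ids, chrom = chrom, pos = pos,
        effect_allele = pairs[pick, 1], other_allele = pairs[pick, 2],
        eaf = eaf, beta = obs, se = se,
        pvalue = norm_p(obs, se), n = nn,
        stringsAsFactors = FALSE
      )
    }

    list(
      exposure = mk(obs_E, se_E, sc$n_exposure),
      mediator = mk(obs_M, se_M, sc$n_mediator),
      outcome = mk(obs_O, se_O, sc$n_outcome_eff),
      truth = data.frame(
        variant_id = ids, gamma = gamma, delta = delta, alpha = alpha,
        beta_exposure = beta_E, beta_mediator = beta_M, beta_outcome = beta_O,
        stringsAsFactors = FALSE
      ),
      scenario = sc
    )
  })
}
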