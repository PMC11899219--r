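#' Define a ground-truth causal scenario for synthetic GWAS summary statistics
#'
#' A `causal_scenario` holds the structural parameters of the data-generating
#' model exposure -> mediator -> outcome used by [simulate_gwas()]. Effects are
#' on the standardized scale for quantitative traits (per SD of the trait) and
#' on the log-odds scale for the binary outcome. The true total effect of the
#' exposure on the outcome is `theta_direct + beta_EM * beta_MO`, and the true
#' mediated proportion is `beta_EM * beta_MO / (theta_direct + beta_EM *
#' beta_MO)`; both are exposed by accessors so simulation studies can compare
#' estimates with ground truth.
#'
#' Defaults mirror a large educational-attainment-style exposure GWAS
#' (N = 766,345 with the instruments explaining 1.84% of trait variance), a
#' BMI-scale mediator GWAS (N = 681,275), and a biobank disease outcome with
#' effective sample size 2e5, with a protective direct effect and a
#' risk-increasing mediator path sized like the adiposity pathway of the
#' education-kidney-disease analysis.
#'
#' @param n_snps_exposure Number of variants with true effects on the exposure.
#' @param n_snps_mediator_extra Number of additional variants affecting the
#'   mediator independently of the exposure (instruments for the mediator).
#' @param beta_EM True exposure -> mediator effect (SD units per exposure SD).
#' @param beta_MO True mediator -> outcome effect (log-odds per mediator SD).
#' @param theta_direct True direct exposure -> outcome effect (log-odds per
#'   exposure SD), not passing through the mediator.
#' @param h2_exposure Exposure variance explained jointly by the exposure
#'   variants; must lie in (0, 1).
#' @param h2_mediator_extra Mediator variance explained by the
#'   mediator-specific variants.
#' @param n_exposure,n_mediator,n_outcome_eff (Effective) GWAS sample sizes of
#'   the three trait panels.
#' @param pleiotropy_mode `"none"`, `"balanced"` (pleiotropic effects with mean
#'   zero) or `"directional"` (mean `pleiotropy_sd`).
#' @param pleiotropy_frac Fraction of exposure variants given a horizontal
#'   pleiotropic effect on mediator and outcome.
#' @param pleiotropy_sd SD (and, for directional mode, mean) of the
#'   pleiotropic effects.
#' @param overlap_rho Correlation of estimation noise across the three trait
#'   panels; models participant overlap between GWAS samples.
#' @param seed Integer seed making generation deterministic.
#'
#' @return An object of class `causal_scenario`.
#' @seealso [simulate_gwas()], [true_total_effect()],
#'   [true_mediated_proportion()]
#' @export
#' @examples
#' sc <- causal_scenario(theta_direct = -0.30, beta_EM = -0.29, beta_MO = 0.293)
#' true_total_effect(sc)        # -0.385
#' true_mediated_proportion(sc) # ~0.22
causal_scenario <- function(n_snps_exposure = 150L,
                            n_snps_mediator_extra = 50L,
                            beta_EM = -0.29,
                            beta_MO = 0.293,
                            theta_direct = -0.30,
                            h2_exposure = 0.0184,
                            h2_mediator_extra = 0.05,
                            n_exposure = 766345,
                            n_mediator = 681275,
                            n_outcome_eff = 2e5,
                            pleiotropy_mode = c("none", "balanced", "directional"),
                            pleiotropy_frac = 0,
                            pleiotropy_sd = 0,
                            overlap_rho = 0,
                            seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  check_scalar(n_snps_exposure, "n_snps_exposure", lower = 1)
  check_scalar(n_snps_mediator_extra, "n_snps_mediator_extra", lower = 0)
  check_scalar(beta_EM, "beta_EM")
  check_scalar(beta_MO, "beta_MO")
  check_scalar(theta_direct, "theta_direct")
  check_scalar(h2_exposure, "h2_exposure", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_scalar(h2_mediator_extra, "h2_mediator_extra", lower = 0, upper = 1,
               open_upper = TRUE)
  check_scalar(n_exposure, "n_exposure", lower = 2, open_lower = TRUE)
  check_scalar(n_mediator, "n_mediator", lower = 2, open_lower = TRUE)
  check_scalar(n_outcome_eff, "n_outcome_eff", lower = 2, open_lower = TRUE)
  check_scalar(pleiotropy_frac, "pleiotropy_frac", lower = 0, upper = 1)
  check_scalar(pleiotropy_sd, "pleiotropy_sd", lower = 0)
  check_scalar(overlap_rho, "overlap_rho", lower = 0, upper = 1)
  check_scalar(seed, "seed")

  structure(list(
    n_snps_exposure = as.integer(n_snps_exposure),
    n_snps_mediator_extra = as.integer(n_snps_mediator_extra),
    beta_EM = beta_EM, beta_MO = beta_MO, theta_direct = theta_direct,
    h2_exposure = h2_exposure, h2_mediator_extra = h2_mediator_extra,
    n_exposure = n_exposure, n_mediator = n_mediator,
    n_outcome_eff = n_outcome_eff,
    pleiotropy_mode = pleiotropy_mode,
    pleiotropy_frac = pleiotropy_frac, pleiotropy_sd = pleiotropy_sd,
    overlap_rho = overlap_rho, seed = as.integer(seed)
  ), class = "causal_scenario")
}

#' True total causal effect implied by a scenario
#'
#' The structural identity `theta_direct + beta_EM * beta_MO`: the direct path
#' plus the path through the mediator, on the log-odds scale.
#'
#' @param scenario A [causal_scenario()].
#' @return A number.
#' @export
true_total_effect <- function(scenario) {
  stopifnot(inherits(scenario, "causal_scenario"))
  scenario$theta_direct + scenario$beta_EM * scenario$beta_MO
}

#' True mediated proportion implied by a scenario
#'
#' `beta_EM * beta_MO / total`, defined only when the total effect is nonzero.
#'
#' @param scenario A [causal_scenario()].
#' @return A number in the usual case; errors when the total effect is zero.
#' @export
true_mediated_proportion <- function(scenario) {
  total <- true_total_effect(scenario)
  if (total == 0) {
    stop("true total effect is zero; mediated proportion undefined",
         call. = FALSE)
  }
  scenario$beta_EM * scenario$beta_MO / total
}

#' @export
print.causal_scenario <- function(x, ...) {
  cat("Causal scenario (exposure -> mediator -> outcome)\n")
  cat(sprintf("  SNPs: %d exposure + %d mediator-specific\n",
              x$n_snps_exposure, x$n_snps_mediator_extra))
  cat(sprintf("  beta_EM = %g, beta_MO = %g, theta_direct = %g\n",
              x$beta_EM, x$beta_MO, x$theta_direct))
  cat(sprintf("  true total = %g, mediated proportion = %s\n",
              true_total_effect(x),
              tryCatch(sprintf("%.3f", true_mediated_proportion(x)),
                       error = function(e) "undefined")))
  cat(sprintf("  pleiotropy: %s (frac %g, sd %g); overlap rho %g; seed %d\n",
              x$pleiotropy_mode, x$pleiotropy_frac, x$pleiotropy_sd,
              x$overlap_rho, x$seed))
  invisible(x)
}
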