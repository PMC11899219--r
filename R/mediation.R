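# Three-step mediator screening and two-step MR mediation quantification.

#' Three-step mediator screen
#'
#' Applies the qualitative screening rule deciding whether a candidate trait
#' can be carried into mediation analysis:
#'
#' * **Step 1 (unidirectional):** the exposure must causally affect the
#'   mediator (`forward` significant), and there must be no credible reverse
#'   effect of the mediator on the exposure. A nominally significant reverse
#'   IVW estimate is discounted when its MR-Egger intercept signals
#'   directional pleiotropy (`reverse_intercept_p < alpha`), since the
#'   apparent reverse signal is then attributable to pleiotropic instruments
#'   rather than reverse causation.
#' * **Step 2 (consistent effect on the outcome):** the mediator must affect
#'   the outcome both before and after adjusting for the exposure, with the
#'   same sign.
#' * **Step 3 (direction of mediation):** the product of the
#'   exposure-to-mediator and adjusted mediator-to-outcome effects must share
#'   the sign of the total effect, i.e. the indirect path must act in the
#'   same direction as the total association it is meant to explain.
#'
#' @param forward UVMR estimate of exposure -> mediator (an [mr_estimate()]
#'   or list with `beta`, `pvalue`).
#' @param reverse UVMR estimate of mediator -> exposure; `NULL` when no
#'   reverse instruments exist (treated as no reverse evidence).
#' @param reverse_intercept_p MR-Egger intercept p-value of the reverse
#'   analysis (`NA` treated as no pleiotropy evidence).
#' @param m_on_o_unadj UVMR estimate of mediator -> outcome.
#' @param m_on_o_adj MVMR (exposure-adjusted) estimate of mediator -> outcome.
#' @param total UVMR estimate of the exposure's total effect on the outcome.
#' @param alpha Significance threshold (default 0.05).
#' @param mediator Optional label.
#' @return An object of class `screening_decision`: fields `mediator`,
#'   `step1`, `step2`, `step3`, `final` (`step1 & step2 & step3`) and
#'   `reasons` (character, one entry per failure).
#' @export
screen_mediator <- function(forward, reverse, reverse_intercept_p,
                            m_on_o_unadj, m_on_o_adj, total,
                            alpha = 0.05, mediator = "mediator") {
  check_scalar(alpha, "alpha", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  reasons <- character()

  if (total$beta == 0) {
    return(structure(list(
      mediator = mediator, step1 = NA, step2 = NA, step3 = NA,
      final = FALSE, reasons = "zero total effect"
    ), class = "screening_decision"))
  }

  if (is.na(reverse_intercept_p)) reverse_intercept_p <- 1
  reverse_p <- if (is.null(reverse)) 1 else reverse$pvalue
  credible_reverse <- reverse_p < alpha && reverse_intercept_p >= alpha
  step1 <- forward$pvalue < alpha && !credible_reverse
  if (forward$pvalue >= alpha) {
    reasons <- c(reasons, "no forward effect of exposure on mediator")
  }
  if (credible_reverse) {
    reasons <- c(reasons, "bidirectional association (credible reverse effect)")
  }

  step2 <- m_on_o_unadj$pvalue < alpha && m_on_o_adj$pvalue < alpha &&
    sign(m_on_o_unadj$beta) == sign(m_on_o_adj$beta)
  if (!step2) {
    reasons <- c(reasons,
                 "inconsistent mediator-outcome effect before/after adjustment")
  }

  step3 <- sign(forward$beta * m_on_o_adj$beta) == sign(total$beta)
  if (!step3) {
    reasons <- c(reasons, "indirect path opposes the total effect")
  }

  structure(list(
    mediator = mediator, step1 = step1, step2 = step2, step3 = step3,
    final = step1 && step2 && step3, reasons = reasons
  ), class = "screening_decision")
}

#' @export
print.screening_decision <- function(x, ...) {
  ok <- function(v) if (isTRUE(v)) "pass" else if (isFALSE(v)) "FAIL" else "NA"
  cat(sprintf("Screening '%s': step1 %s, step2 %s, step3 %s -> %s\n",
              x$mediator, ok(x$step1), ok(x$step2), ok(x$step3),
              if (x$final) "RETAIN" else "EXCLUDE"))
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

mediation_result <- function(method, beta1 = NA_real_, sigma1 = NA_real_,
                             beta2 = NA_real_, sigma2 = NA_real_,
                             total, se_total, direct, se_direct,
                             indirect, se_indirect) {
  if (abs(total) < 1e-12) {
    stop("total effect numerically zero; mediated proportion undefined",
         call. = FALSE)
  }
  proportion <- indirect / total
  se_proportion <- if (indirect != 0) {
    abs(proportion) * sqrt((se_indirect / indirect)^2 + (se_total / total)^2)
  } else {
    se_indirect / abs(total)
  }
  suppression <- proportion > 1 || proportion < 0
  if (suppression) {
    warning("mediated proportion outside [0, 1] (suppression/inconsistent ",
            "mediation): direct effect beyond the total effect",
            call. = FALSE)
  }
  structure(list(
    method = method,
    total = total, se_total = se_total,
    direct = direct, se_direct = se_direct,
    beta1 = beta1, sigma1 = sigma1, beta2 = beta2, sigma2 = sigma2,
    indirect = indirect, se_indirect = se_indirect,
    proportion = proportion, se_proportion = se_proportion,
    ci_low = proportion - Z975 * se_proportion,
    ci_high = proportion + Z975 * se_proportion,
    suppression = suppression
  ), class = "mediation_result")
}

#' Two-step MR mediation for a single mediator (product of coefficients)
#'
#' The indirect effect is `beta1 * beta2`: the exposure-to-mediator effect
#' times the exposure-adjusted mediator-to-outcome effect. Its standard error
#' uses the first-order delta method assuming independence of the two steps
#' (distinct GWAS panels): `sqrt(beta2^2 * sigma1^2 + beta1^2 * sigma2^2)`,
#' with the second-order cross-term `sigma1^2 * sigma2^2` available behind
#' `cross_term`. The mediated proportion is `indirect / total`, with
#' delta-method SE treating numerator and denominator as independent, and a
#' normal 95% CI.
#'
#' @param beta1,sigma1 Exposure -> mediator effect (UVMR) and its SE.
#' @param beta2,sigma2 Mediator -> outcome effect adjusted for the exposure
#'   (MVMR) and its SE.
#' @param total,se_total Total effect of the exposure on the outcome (UVMR,
#'   log-odds scale) and its SE.
#' @param cross_term Include the `sigma1^2 * sigma2^2` term in the indirect
#'   SE (exact variance of a product of independent normals)?
#' @return An object of class `mediation_result` with fields `total`,
#'   `direct` (total minus indirect), `beta1`, `beta2`, `indirect`,
#'   `proportion`, their SEs, the proportion's 95% CI, and a `suppression`
#'   flag set when the proportion exceeds 1.
#' @export
#' @examples
#' mediate_single(-0.29, 0.033, log(1.34), 0.079, log(0.68), 0.100)
mediate_single <- function(beta1, sigma1, beta2, sigma2, total, se_total,
                           cross_term = FALSE) {
  check_scalar(sigma1, "sigma1", lower = 0)
  check_scalar(sigma2, "sigma2", lower = 0)
  check_scalar(se_total, "se_total", lower = 0, open_lower = TRUE)
  indirect <- beta1 * beta2
  var_ind <- beta2^2 * sigma1^2 + beta1^2 * sigma2^2
  if (cross_term) var_ind <- var_ind + sigma1^2 * sigma2^2
  se_indirect <- sqrt(var_ind)
  mediation_result(
    "product", beta1 = beta1, sigma1 = sigma1, beta2 = beta2, sigma2 = sigma2,
    total = total, se_total = se_total,
    direct = total - indirect,
    se_direct = sqrt(se_total^2 + var_ind),
    indirect = indirect, se_indirect = se_indirect
  )
}

#' Combined mediation through multiple mediators (difference method)
#'
#' The combined indirect effect is the residual of the total effect (UVMR)
#' after subtracting the direct effect of the exposure from a multivariable
#' model that includes all mediators: `indirect = total - direct`. Its SE is
#' `sqrt(se_total^2 + se_direct^2)` under the documented independence
#' assumption. Proportion and CI as in [mediate_single()].
#'
#' @param total Total-effect estimate ([mr_estimate()] or list with `beta`,
#'   `se`), log-odds scale.
#' @param direct_mv Direct-effect estimate of the exposure from MVMR
#'   adjusting for the mediators, same scale.
#' @return A `mediation_result` (method `"difference"`); the `suppression`
#'   flag is set when the direct effect exceeds the total so the proportion
#'   is above 1.
#' @export
mediate_combined <- function(total, direct_mv) {
  indirect <- total$beta - direct_mv$beta
  se_indirect <- sqrt(total$se^2 + direct_mv$se^2)
  mediation_result(
    "difference",
    total = total$beta, se_total = total$se,
    direct = direct_mv$beta, se_direct = direct_mv$se,
    indirect = indirect, se_indirect = se_indirect
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation (%s method)\n", x$method))
  cat(sprintf("  total    %8.4f (SE %.4f)\n", x$total, x$se_total))
  cat(sprintf("  direct   %8.4f (SE %.4f)\n", x$direct, x$se_direct))
  cat(sprintf("  indirect %8.4f (SE %.4f)\n", x$indirect, x$se_indirect))
  cat(sprintf("  proportion mediated %.1f%% (95%% CI %.1f%%, %.1f%%)%s\n",
              100 * x$proportion, 100 * x$ci_low, 100 * x$ci_high,
              if (x$suppression) " [suppression]" else ""))
  invisible(x)
}
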