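# Univariable MR estimators and heterogeneity statistics.

#' Construct an MR effect estimate
#'
#' Container for a causal-effect estimate: beta with SE, normal 95% CI
#' (multiplier 1.959964), two-sided normal p-value, instrument count and the
#' exponentiated (odds-ratio) scale for binary outcomes.
#'
#' @param method Method label, e.g. `"ivw"`.
#' @param beta,se Estimate and standard error (se > 0 except in degenerate
#'   exact-fit cases).
#' @param n_snps Number of instruments used.
#' @param pvalue Optional p-value; defaults to the two-sided normal test.
#' @return An object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, beta, se, n_snps, pvalue = NULL) {
  if (is.null(pvalue)) pvalue <- norm_p(beta, se)
  structure(list(
    method = method, beta = beta, se = se,
    ci_low = beta - Z975 * se, ci_high = beta + Z975 * se,
    pvalue = pvalue, n_snps = n_snps,
    or = exp(beta), or_ci_low = exp(beta - Z975 * se),
    or_ci_high = exp(beta + Z975 * se)
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "%s: beta %.4f (SE %.4f, 95%% CI %.4f to %.4f), OR %.3f (%.3f-%.3f), p = %.3g, %d SNPs\n",
    x$method, x$beta, x$se, x$ci_low, x$ci_high,
    x$or, x$or_ci_low, x$or_ci_high, x$pvalue, x$n_snps))
  invisible(x)
}

check_harmonized <- function(set, min_snps = 1L, method = "MR") {
  if (!is.data.frame(set) ||
      !all(c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
           %in% names(set))) {
    stop("expected a harmonized set with beta/se columns for both traits",
         call. = FALSE)
  }
  if (nrow(set) < min_snps) {
    stop(sprintf("insufficient instruments for %s: %d < %d", method,
                 nrow(set), min_snps), call. = FALSE)
  }
  if (any(set$se_exposure <= 0) || any(set$se_outcome <= 0)) {
    stop("all standard errors must be positive", call. = FALSE)
  }
  invisible(set)
}

#' Inverse-variance-weighted MR estimate
#'
#' The primary causal estimator: precision-weighted combination of per-variant
#' Wald ratios `beta_outcome / beta_exposure` with weights
#' `beta_exposure^2 / se_outcome^2`, algebraically identical to weighted least
#' squares of the outcome betas on the exposure betas through the origin with
#' weights `1 / se_outcome^2`. The standard error uses a multiplicative
#' random-effects model: the fixed-effect SE inflated by
#' `max(1, sqrt(Q / (n - 1)))`, so heterogeneity widens the interval but can
#' never shrink it below the fixed-effect one.
#'
#' @param set An `mr_harmonized` set (or any data.frame with the four
#'   beta/se columns).
#' @return An [mr_estimate()] with method `"ivw"`.
#' @export
mr_ivw <- function(set) {
  check_harmonized(set, 1L, "IVW")
  bx <- set$beta_exposure
  by <- set$beta_outcome
  so <- set$se_outcome
  zero <- bx == 0
  if (any(zero)) {
    stop(sprintf("zero exposure effect for variant(s): %s",
                 paste(set$variant_id[zero], collapse = ", ")), call. = FALSE)
  }
  w <- bx^2 / so^2
  beta <- sum(w * (by / bx)) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  n <- length(bx)
  Q <- sum(w * (by / bx - beta)^2)
  infl <- if (n >= 2) max(1, sqrt(Q / (n - 1))) else 1
  mr_estimate("ivw", beta, se_fixed * infl, n)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with an intercept,
#' weights `1 / se_outcome^2`, after orienting all exposure betas to be
#' non-negative (flipping the sign of both members of a pair), as the
#' estimator requires. The slope is a pleiotropy-robust causal estimate under
#' the InSIDE assumption; a nonzero intercept indicates directional
#' pleiotropy. Both coefficients use the multiplicative random-effects
#' inflation `max(1, sqrt(Q / (n - 2)))`.
#'
#' @param set An `mr_harmonized` set with at least 3 variants.
#' @return A list with `slope` (an [mr_estimate()], method `"egger_slope"`),
#'   `intercept` (list with `estimate`, `se`, `pvalue`), and the residual
#'   heterogeneity `Q` with `df`.
#' @export
mr_egger <- function(set) {
  check_harmonized(set, 3L, "Egger")
  flip <- sign(set$beta_exposure) < 0
  bx <- abs(set$beta_exposure)
  by <- ifelse(flip, -set$beta_outcome, set$beta_outcome)
  so <- set$se_outcome
  n <- length(bx)
  w <- 1 / so^2
  X <- cbind(intercept = 1, slope = bx)
  A <- crossprod(X, w * X)
  coef <- drop(solve(A, crossprod(X, w * by)))
  resid <- by - drop(X %*% coef)
  Q <- sum(w * resid^2)
  infl <- max(1, sqrt(Q / (n - 2)))
  V <- solve(A) * infl^2
  # regression-style t reference distribution, df = n - 2
  t_p <- function(est, se) 2 * stats::pt(-abs(est / se), df = n - 2)
  se_slope <- sqrt(V["slope", "slope"])
  se_int <- sqrt(V["intercept", "intercept"])
  list(
    slope = mr_estimate("egger_slope", coef[["slope"]], se_slope, n,
                        pvalue = t_p(coef[["slope"]], se_slope)),
    intercept = list(estimate = coef[["intercept"]], se = se_int,
                     pvalue = t_p(coef[["intercept"]], se_int)),
    Q = Q, df = n - 2
  )
}

# Interpolated weighted median of ratio estimates.
weighted_median_est <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  p <- cumsum(weights[ord]) / sum(weights)
  p <- p - weights[ord] / (2 * sum(weights))
  below <- which(p < 0.5)
  if (length(below) == 0) return(r[1])
  i <- max(below)
  if (i == length(r)) return(r[length(r)])
  r[i] + (r[i + 1] - r[i]) * (0.5 - p[i]) / (p[i + 1] - p[i])
}

#' Weighted-median MR estimate
#'
#' Orders the per-variant Wald ratios and interpolates at cumulative
#' normalized inverse-variance weight 0.5. Consistent when instruments
#' carrying more than half of the weight are valid, so it tolerates up to
#' (just under) 50% invalid instruments. The standard error comes from a
#' parametric bootstrap: per-variant exposure and outcome betas are resampled
#' from their normal sampling distributions and the median recomputed.
#'
#' @param set An `mr_harmonized` set with at least 3 variants.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Optional seed for the bootstrap; the caller's RNG state is
#'   left untouched.
#' @return An [mr_estimate()] with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(set, n_boot = 1000L, seed = NULL) {
  check_harmonized(set, 3L, "weighted median")
  check_scalar(n_boot, "n_boot", lower = 2)
  bx <- set$beta_exposure
  by <- set$beta_outcome
  sx <- set$se_exposure
  so <- set$se_outcome
  n <- length(bx)
  est <- weighted_median_est(by / bx, bx^2 / so^2)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bxs <- stats::rnorm(n, bx, sx)
      bys <- stats::rnorm(n, by, so)
      weighted_median_est(bys / bxs, bxs^2 / so^2)
    }, numeric(1))
  })
  mr_estimate("weighted_median", est, stats::sd(boots), n)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j * (ratio_j - at_beta)^2)` with first-order weights
#' `w_j = beta_exposure^2 / se_outcome^2`, compared to a chi-square
#' distribution with `n - 1` degrees of freedom (appropriate when `at_beta`
#' is the IVW estimate of the same set).
#'
#' @param set An `mr_harmonized` set with at least 2 variants.
#' @param at_beta Effect at which heterogeneity is evaluated; defaults to the
#'   set's IVW estimate.
#' @return A list with `Q`, `df` and `pvalue`.
#' @export
cochran_q <- function(set, at_beta = NULL) {
  check_harmonized(set, 2L, "Cochran's Q")
  if (is.null(at_beta)) at_beta <- mr_ivw(set)$beta
  w <- set$beta_exposure^2 / set$se_outcome^2
  Q <- sum(w * (set$beta_outcome / set$beta_exposure - at_beta)^2)
  df <- nrow(set) - 1L
  list(Q = Q, df = df, pvalue = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Heterogeneity and pleiotropy report for a harmonized set
#'
#' Combines Cochran's Q at the IVW estimate with the MR-Egger intercept test
#' (when at least 3 variants are available).
#'
#' @param set An `mr_harmonized` set.
#' @return A list with `Q`, `df`, `pvalue`, `egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_p` (the Egger fields are `NA`
#'   with fewer than 3 variants).
#' @export
heterogeneity <- function(set) {
  q <- cochran_q(set)
  if (nrow(set) >= 3) {
    eg <- mr_egger(set)
    list(Q = q$Q, df = q$df, pvalue = q$pvalue,
         egger_intercept = eg$intercept$estimate,
         egger_intercept_se = eg$intercept$se,
         egger_intercept_p = eg$intercept$pvalue)
  } else {
    list(Q = q$Q, df = q$df, pvalue = q$pvalue,
         egger_intercept = NA_real_, egger_intercept_se = NA_real_,
         egger_intercept_p = NA_real_)
  }
}
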