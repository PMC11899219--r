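# Outlier-aware sensitivity methods: MR-PRESSO and radial MR.

# Leave-one-out IVW slopes (fixed-effect), vectorized over variants.
loo_slopes <- function(bx, by, w) {
  Sxy <- sum(w * bx * by)
  Sxx <- sum(w * bx^2)
  (Sxy - w * bx * by) / (Sxx - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Residual-sum-of-squares based detection of horizontally pleiotropic
#' instruments, with three stages. (1) Global test: the observed RSS
#' `sum(w_j * (beta_out_j - slope_loo(-j) * beta_exp_j)^2)` (weights
#' `1 / se_out^2`, leave-one-out IVW slopes) is compared to its simulated null
#' distribution, obtained by redrawing each variant's exposure and outcome
#' betas from normal sampling distributions centered on the leave-one-out
#' fit. (2) Outlier test: each variant's observed weighted squared residual
#' is compared to its own simulated distribution (two-sided empirical p,
#' Bonferroni-adjusted across variants); variants with adjusted p below
#' `alpha` are flagged. (3) The corrected estimate is IVW on the remaining
#' variants, and a distortion test compares the corrected-minus-full
#' difference against differences from random subsets of the same size.
#'
#' @param set An `mr_harmonized` set with at least 4 variants.
#' @param n_sim Number of simulated replicates for the global/outlier null
#'   distributions (at least 100; default 1000).
#' @param seed Optional seed; results are deterministic given a seed.
#' @param alpha Significance level for the Bonferroni-adjusted outlier test.
#' @param n_distortion Random subsets drawn for the distortion test.
#' @return An object of class `mr_presso` with fields `global_rss`,
#'   `global_p`, `per_snp_p` (named by variant), `outliers` (variant ids),
#'   `corrected` (an [mr_estimate()] on the retained variants) and
#'   `distortion_p` (`NA` when no outliers are found).
#' @export
mr_presso <- function(set, n_sim = 1000L, seed = NULL, alpha = 0.05,
                      n_distortion = 1000L) {
  check_harmonized(set, 4L, "MR-PRESSO")
  check_scalar(n_sim, "n_sim", lower = 100)
  check_scalar(alpha, "alpha", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  bx <- set$beta_exposure
  by <- set$beta_outcome
  sx <- set$se_exposure
  so <- set$se_outcome
  n <- length(bx)
  w <- 1 / so^2
  ids <- if (!is.null(set$variant_id)) set$variant_id else
    sprintf("snp%03d", seq_len(n))

  loo <- loo_slopes(bx, by, w)
  res_obs <- w * (by - loo * bx)^2
  rss_obs <- sum(res_obs)

  full <- mr_ivw(set)

  with_seed(seed, {
    # simulated replicates: rows = replicates, columns = variants
    mu <- rep(loo * bx, each = n_sim)
    bys <- matrix(stats::rnorm(n_sim * n, mu, rep(so, each = n_sim)),
                  nrow = n_sim)
    bxs <- matrix(stats::rnorm(n_sim * n, rep(bx, each = n_sim),
                               rep(sx, each = n_sim)), nrow = n_sim)
    W <- matrix(w, nrow = n_sim, ncol = n, byrow = TRUE)
    Sxy <- rowSums(W * bxs * bys)
    Sxx <- rowSums(W * bxs^2)
    loo_s <- (Sxy - W * bxs * bys) / (Sxx - W * bxs^2)
    res_s <- W * (bys - loo_s * bxs)^2
    rss_s <- rowSums(res_s)
    global_p <- mean(rss_s >= rss_obs)

    ge <- colMeans(res_s >= matrix(res_obs, n_sim, n, byrow = TRUE))
    per_p <- 2 * pmin(ge, 1 - ge)
    per_p_adj <- pmin(1, per_p * n)
    out_idx <- which(per_p_adj < alpha)

    if (length(out_idx) == n) {
      stop("no instruments survive outlier removal", call. = FALSE)
    }
    keep <- setdiff(seq_len(n), out_idx)
    corrected <- mr_ivw(set[keep, , drop = FALSE])

    distortion_p <- NA_real_
    if (length(out_idx) > 0) {
      d_obs <- corrected$beta - full$beta
      m <- length(keep)
      d_sub <- vapply(seq_len(n_distortion), function(b) {
        idx <- sample.int(n, m)
        mr_ivw(set[idx, , drop = FALSE])$beta - full$beta
      }, numeric(1))
      distortion_p <- mean(abs(d_sub) >= abs(d_obs))
    }

    structure(list(
      global_rss = rss_obs, global_p = global_p,
      per_snp_p = stats::setNames(per_p, ids),
      outliers = ids[out_idx],
      corrected = corrected, full = full,
      distortion_p = distortion_p, n_sim = n_sim
    ), class = "mr_presso")
  })
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS %.3f, global p = %.3g (%d sims)\n",
              x$global_rss, x$global_p, x$n_sim))
  if (length(x$outliers) > 0) {
    cat(sprintf("  outliers (%d): %s; distortion p = %.3g\n",
                length(x$outliers), paste(x$outliers, collapse = ", "),
                x$distortion_p))
  } else {
    cat("  no outliers detected\n")
  }
  print(x$corrected)
  invisible(x)
}

#' Radial (modified second-order free) IVW with per-variant Q outliers
#'
#' Reparameterizes IVW as a regression of `sqrt(w_j) * ratio_j` on
#' `sqrt(w_j)` through the origin with first-order weights
#' `w_j = beta_exposure^2 / se_outcome^2`; the slope equals the IVW estimate
#' exactly. Each variant's contribution to Cochran's Q,
#' `Q_j = w_j * (ratio_j - slope)^2`, is referred to a chi-square(1)
#' distribution; variants with `p < per_snp_alpha` (unadjusted, the radial
#' convention) are flagged and the slope refitted without them.
#'
#' @param set An `mr_harmonized` set with at least 2 variants.
#' @param per_snp_alpha Per-variant significance level for outlier flagging.
#' @return A list with `estimate` (radial IVW, an [mr_estimate()]),
#'   `q_stats` (named per-variant Q), `per_snp_p`, `outliers` (variant ids)
#'   and `corrected` (refit without outliers; equals `estimate` when none).
#' @export
radial_ivw <- function(set, per_snp_alpha = 0.05) {
  check_harmonized(set, 2L, "radial MR")
  check_scalar(per_snp_alpha, "per_snp_alpha", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  bx <- set$beta_exposure
  by <- set$beta_outcome
  so <- set$se_outcome
  n <- length(bx)
  ids <- if (!is.null(set$variant_id)) set$variant_id else
    sprintf("snp%03d", seq_len(n))
  w <- bx^2 / so^2
  r <- by / bx
  slope <- sum(w * r) / sum(w)
  Qj <- w * (r - slope)^2
  infl <- if (n >= 2) max(1, sqrt(sum(Qj) / (n - 1))) else 1
  est <- mr_estimate("radial_ivw", slope, infl / sqrt(sum(w)), n)
  pj <- stats::pchisq(Qj, df = 1, lower.tail = FALSE)
  out_idx <- which(pj < per_snp_alpha)
  corrected <- if (length(out_idx) > 0 && length(out_idx) < n) {
    keep <- set[-out_idx, , drop = FALSE]
    wk <- keep$beta_exposure^2 / keep$se_outcome^2
    rk <- keep$beta_outcome / keep$beta_exposure
    sl <- sum(wk * rk) / sum(wk)
    Qk <- sum(wk * (rk - sl)^2)
    ik <- if (nrow(keep) >= 2) max(1, sqrt(Qk / (nrow(keep) - 1))) else 1
    mr_estimate("radial_ivw", sl, ik / sqrt(sum(wk)), nrow(keep))
  } else {
    est
  }
  list(estimate = est,
       q_stats = stats::setNames(Qj, ids),
       per_snp_p = stats::setNames(pj, ids),
       outliers = ids[out_idx],
       corrected = corrected)
}
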