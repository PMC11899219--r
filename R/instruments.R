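# Instrument selection, allele harmonization and strength diagnostics.

complement_allele <- function(a) chartr("ACGT", "TGCA", a)

is_palindromic <- function(effect_allele, other_allele) {
  effect_allele == complement_allele(other_allele)
}

# Orientation of a second allele coding relative to a reference coding:
# +1 aligned (directly or after strand complement), -1 effect/other swapped
# (directly or after complement), NA irreconcilable.
allele_orientation <- function(ea_ref, oa_ref, ea, oa) {
  same <- ea == ea_ref & oa == oa_ref
  swap <- ea == oa_ref & oa == ea_ref
  cea <- complement_allele(ea)
  coa <- complement_allele(oa)
  fsame <- cea == ea_ref & coa == oa_ref
  fswap <- cea == oa_ref & coa == ea_ref
  ifelse(same | fsame, 1, ifelse(swap | fswap, -1, NA_real_))
}

#' Select independent genome-wide-significant instruments
#'
#' Keeps variants with `pvalue < p_threshold` and applies greedy distance
#' clumping: variants are visited in ascending p-value order (ties broken by
#' `variant_id`, ascending) and a variant is discarded if a previously kept
#' variant lies within `window_bp` on the same chromosome. The default
#' thresholds are the conventional genome-wide significance level 5e-8 and a
#' 1 Mb clumping window. LD-based pruning (r^2 thresholds) requires a
#' reference panel and is not performed; an LD matrix hook can be layered on
#' top by pre-filtering the input table.
#'
#' @param tab Summary-statistics `data.frame` for the exposure.
#' @param p_threshold Significance threshold; variants at or above it are
#'   removed.
#' @param window_bp Clumping window in base pairs (> 0); a candidate within
#'   this distance of a kept variant is discarded.
#' @return The kept rows, ordered by ascending p-value (ties by variant id).
#'   Errors with a "no instruments" message when nothing passes the
#'   threshold, so pipelines cannot silently proceed.
#' @export
select_instruments <- function(tab, p_threshold = 5e-8, window_bp = 1e6) {
  validate_sumstats(tab, "exposure")
  check_scalar(p_threshold, "p_threshold", lower = 0, upper = 1,
               open_lower = TRUE)
  check_scalar(window_bp, "window_bp", lower = 0, open_lower = TRUE)
  cand <- tab[tab$pvalue < p_threshold, , drop = FALSE]
  if (nrow(cand) == 0) {
    stop(sprintf("no instruments: no variant passes p < %g", p_threshold),
         call. = FALSE)
  }
  cand <- cand[order(cand$pvalue, cand$variant_id), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    prev <- which(keep & cand$chrom == cand$chrom[i])
    keep[i] <- !any(abs(cand$pos[prev] - cand$pos[i]) <= window_bp)
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Harmonize exposure and outcome summary statistics to a common effect allele
#'
#' Matches variants by id and aligns the outcome effects to the exposure's
#' effect-allele coding: when the outcome records the alleles swapped
#' (directly or on the opposite strand), the outcome beta's sign is flipped
#' and its allele frequency replaced by its complement. Palindromic variants
#' (A/T or C/G), whose strand cannot be resolved from alleles alone, are
#' dropped when `drop_palindromic = TRUE` (the default, strict mode).
#' Variants with irreconcilable alleles, or absent from the outcome table,
#' are dropped with a logged reason.
#'
#' @param exposure_rows Exposure summary statistics (typically the selected
#'   instruments).
#' @param outcome_rows Outcome summary statistics.
#' @param drop_palindromic Drop palindromic variants (strict mode)?
#' @return An object of class `mr_harmonized`: a `data.frame` with columns
#'   `variant_id, chrom, pos, eaf, beta_exposure, se_exposure, beta_outcome,
#'   se_outcome, eaf_outcome, flipped`, plus a `dropped` attribute recording
#'   every removed variant and its reason.
#' @export
harmonize <- function(exposure_rows, outcome_rows, drop_palindromic = TRUE) {
  validate_sumstats(exposure_rows, "exposure")
  validate_sumstats(outcome_rows, "outcome")
  shared <- intersect(exposure_rows$variant_id, outcome_rows$variant_id)
  unmatched <- setdiff(exposure_rows$variant_id, shared)
  if (length(shared) == 0) {
    stop("no shared variants between exposure and outcome tables",
         call. = FALSE)
  }
  ex <- exposure_rows[match(shared, exposure_rows$variant_id), , drop = FALSE]
  ou <- outcome_rows[match(shared, outcome_rows$variant_id), , drop = FALSE]

  pal <- is_palindromic(ex$effect_allele, ex$other_allele) |
    is_palindromic(ou$effect_allele, ou$other_allele)
  orient <- allele_orientation(ex$effect_allele, ex$other_allele,
                               ou$effect_allele, ou$other_allele)

  reason <- rep(NA_character_, length(shared))
  if (drop_palindromic) reason[pal] <- "palindromic"
  reason[is.na(orient) & is.na(reason)] <- "irreconcilable alleles"
  keep <- is.na(reason)
  if (!any(keep)) {
    stop("no variants remain after harmonization", call. = FALSE)
  }

  o <- orient[keep]
  out <- data.frame(
    variant_id = shared[keep],
    chrom = ex$chrom[keep], pos = ex$pos[keep],
    eaf = ex$eaf[keep],
    beta_exposure = ex$beta[keep], se_exposure = ex$se[keep],
    beta_outcome = ou$beta[keep] * o, se_outcome = ou$se[keep],
    eaf_outcome = ifelse(o < 0, 1 - ou$eaf[keep], ou$eaf[keep]),
    flipped = o < 0,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  dropped <- data.frame(
    variant_id = c(shared[!keep], unmatched),
    reason = c(reason[!keep], rep("absent from outcome", length(unmatched))),
    stringsAsFactors = FALSE
  )
  structure(out, dropped = dropped,
            class = c("mr_harmonized", "data.frame"))
}

#' F statistic for instrument strength
#'
#' `F = (N - K - 1) / K * R2 / (1 - R2)`, the standard approximation from the
#' exposure sample size `N`, the number of instruments `K` and the variance
#' explained `R2`.
#'
#' @param N Exposure GWAS sample size (must exceed `K + 1`).
#' @param K Number of instruments.
#' @param R2 Proportion of exposure variance explained, in `[0, 1)`.
#' @return The F statistic (>= 0).
#' @export
#' @examples
#' f_statistic(766345, 257, 0.0184)  # ~55.9
f_statistic <- function(N, K, R2) {
  check_scalar(K, "K", lower = 1)
  check_scalar(N, "N", lower = K + 1, open_lower = TRUE)
  check_scalar(R2, "R2", lower = 0)
  if (R2 >= 1) {
    stop("R2 >= 1: exposure betas are not on the standardized scale",
         call. = FALSE)
  }
  (N - K - 1) / K * R2 / (1 - R2)
}

#' Instrument-strength diagnostics
#'
#' Variance explained by the instruments, `R2 = sum(2 * eaf * (1 - eaf) *
#' beta^2)` (betas on the standardized trait scale), and the mean F statistic
#' from [f_statistic()]. F > 10 is the conventional threshold below which
#' weak-instrument bias becomes a concern; the classification is exposed as
#' the `strong` flag.
#'
#' @param exposure_rows Selected instrument rows with `eaf` and `beta`.
#' @param N Exposure GWAS sample size.
#' @return An object of class `instrument_diagnostics` with fields `K`, `N`,
#'   `R2`, `F` and `strong`.
#' @export
instrument_strength <- function(exposure_rows, N) {
  validate_sumstats(exposure_rows, "exposure")
  K <- nrow(exposure_rows)
  R2 <- sum(2 * exposure_rows$eaf * (1 - exposure_rows$eaf) *
              exposure_rows$beta^2)
  if (R2 >= 1) {
    stop("R2 >= 1: exposure betas are not on the standardized scale",
         call. = FALSE)
  }
  F_stat <- f_statistic(N, K, R2)
  structure(list(K = K, N = N, R2 = R2, F = F_stat, strong = F_stat > 10),
            class = "instrument_diagnostics")
}

#' @export
print.instrument_diagnostics <- function(x, ...) {
  cat(sprintf(
    "Instruments: K = %d, N = %g, R2 = %.4g (%.2f%%), F = %.1f (%s)\n",
    x$K, x$N, x$R2, 100 * x$R2, x$F,
    if (x$strong) "weak-instrument bias unlikely" else "weak instruments"))
  invisible(x)
}
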