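# Multivariable MR: direct effects of several exposures on one outcome.

#' Assemble a multivariable MR design from per-trait summary statistics
#'
#' Builds the union-of-instruments design: instruments are selected per
#' exposure (genome-wide significance + distance clumping), the union is
#' re-clumped across exposures by distance with the best (minimum across
#' exposures) p-value winning, and every retained variant must be present in
#' every exposure table and in the outcome table; rows missing any trait are
#' dropped with a logged count. All traits are harmonized to the first
#' exposure's effect-allele coding; palindromic variants are dropped.
#'
#' @param exposure_tables Named list (>= 2 unless `allow_single = TRUE`) of
#'   full summary-statistics tables, one per exposure. The first exposure
#'   defines the allele reference.
#' @param outcome_table Outcome summary statistics.
#' @param p_threshold,window_bp Instrument selection parameters, as in
#'   [select_instruments()].
#' @param allow_single Permit a single exposure (used for equivalence checks
#'   against univariable IVW).
#' @return An object of class `mv_harmonized`: list with `variant_id`,
#'   `beta_exposure` (variants x exposures matrix), `se_exposure` (matrix),
#'   `beta_outcome`, `se_outcome`, `exposures` (labels) and a `dropped`
#'   attribute.
#' @export
build_mv_set <- function(exposure_tables, outcome_table,
                         p_threshold = 5e-8, window_bp = 1e6,
                         allow_single = FALSE) {
  if (!is.list(exposure_tables) || is.data.frame(exposure_tables)) {
    stop("'exposure_tables' must be a list of summary-statistics tables",
         call. = FALSE)
  }
  p <- length(exposure_tables)
  if (p < 2 && !allow_single) {
    stop("multivariable MR needs at least 2 exposures", call. = FALSE)
  }
  labels <- names(exposure_tables)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- sprintf("exposure%d", seq_len(p))
  }
  for (i in seq_len(p)) validate_sumstats(exposure_tables[[i]], labels[i])
  validate_sumstats(outcome_table, "outcome")

  iv <- lapply(exposure_tables, select_instruments,
               p_threshold = p_threshold, window_bp = window_bp)
  union_ids <- unique(unlist(lapply(iv, `[[`, "variant_id")))

  # one row per union variant carrying its best p across exposures
  ref <- exposure_tables[[1]]
  first_hit <- do.call(rbind, lapply(iv, function(tab) {
    tab[, c("variant_id", "chrom", "pos", "pvalue")]
  }))
  best_p <- tapply(first_hit$pvalue, first_hit$variant_id, min)
  meta <- first_hit[!duplicated(first_hit$variant_id), , drop = FALSE]
  meta$pvalue <- as.numeric(best_p[meta$variant_id])
  meta <- meta[order(meta$pvalue, meta$variant_id), , drop = FALSE]
  keep <- logical(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    prev <- which(keep & meta$chrom == meta$chrom[i])
    keep[i] <- !any(abs(meta$pos[prev] - meta$pos[i]) <= window_bp)
  }
  clump_dropped <- meta$variant_id[!keep]
  ids <- meta$variant_id[keep]

  dropped <- if (length(clump_dropped) > 0) {
    data.frame(variant_id = clump_dropped, reason = "cross-exposure clump",
               stringsAsFactors = FALSE)
  } else {
    data.frame(variant_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  }

  # completeness: variant must be present in every trait table
  tables <- c(exposure_tables, list(.outcome = outcome_table))
  present <- Reduce(`&`, lapply(tables, function(tab) ids %in% tab$variant_id))
  if (any(!present)) {
    dropped <- rbind(dropped, data.frame(
      variant_id = ids[!present], reason = "missing from a trait table",
      stringsAsFactors = FALSE))
    ids <- ids[present]
  }

  # allele reference = first exposure's coding
  ref_rows <- ref[match(ids, ref$variant_id), , drop = FALSE]
  pal <- is_palindromic(ref_rows$effect_allele, ref_rows$other_allele)
  if (any(pal)) {
    dropped <- rbind(dropped, data.frame(
      variant_id = ids[pal], reason = "palindromic", stringsAsFactors = FALSE))
    ids <- ids[!pal]
    ref_rows <- ref_rows[!pal, , drop = FALSE]
  }

  align <- function(tab) {
    rows <- tab[match(ids, tab$variant_id), , drop = FALSE]
    o <- allele_orientation(ref_rows$effect_allele, ref_rows$other_allele,
                            rows$effect_allele, rows$other_allele)
    list(beta = rows$beta * o, se = rows$se, bad = is.na(o))
  }
  aligned <- lapply(tables, align)
  bad <- Reduce(`|`, lapply(aligned, `[[`, "bad"))
  if (any(bad)) {
    dropped <- rbind(dropped, data.frame(
      variant_id = ids[bad], reason = "irreconcilable alleles",
      stringsAsFactors = FALSE))
    ids <- ids[!bad]
    aligned <- lapply(aligned, function(a) {
      list(beta = a$beta[!bad], se = a$se[!bad])
    })
  }

  if (length(ids) < p + 2) {
    stop(sprintf("under-identified MVMR: %d variants for %d exposures",
                 length(ids), p), call. = FALSE)
  }

  B <- do.call(cbind, lapply(aligned[seq_len(p)], `[[`, "beta"))
  SE <- do.call(cbind, lapply(aligned[seq_len(p)], `[[`, "se"))
  colnames(B) <- colnames(SE) <- labels
  if (any(apply(B, 2, function(col) all(col == 0)))) {
    stop("an exposure has all-zero effects across the retained variants",
         call. = FALSE)
  }
  structure(list(
    variant_id = ids,
    beta_exposure = B, se_exposure = SE,
    beta_outcome = aligned$.outcome$beta,
    se_outcome = aligned$.outcome$se,
    exposures = labels
  ), dropped = dropped, class = "mv_harmonized")
}

check_mv <- function(set, extra_df = 1L, what = "MVMR") {
  if (!inherits(set, "mv_harmonized")) {
    stop("expected an 'mv_harmonized' set from build_mv_set()", call. = FALSE)
  }
  n <- length(set$beta_outcome)
  p <- ncol(set$beta_exposure)
  if (n <= p + extra_df) {
    stop(sprintf("too few variants (%d) for %s with %d exposures",
                 n, what, p), call. = FALSE)
  }
  invisible(set)
}

mv_wls <- function(X, y, w, dfree) {
  A <- crossprod(X, w * X)
  if (qr(A)$rank < ncol(X)) stop("collinear exposures", call. = FALSE)
  coef <- unname(drop(solve(A, crossprod(X, w * y))))
  resid <- y - drop(X %*% coef)
  Q <- sum(w * resid^2)
  infl <- max(1, sqrt(Q / dfree))
  V <- solve(A) * infl^2
  list(coef = coef, se = unname(sqrt(diag(V))), Q = Q, df = dfree)
}

#' Multivariable IVW: direct effects of each exposure
#'
#' Weighted least squares of the outcome betas on the matrix of exposure
#' betas without intercept, weights `1 / se_outcome^2`. Each coefficient is
#' the direct effect of that exposure conditional on the others. Standard
#' errors carry the multiplicative overdispersion inflation
#' `max(1, sqrt(Q / (n - p)))`.
#'
#' @param set An `mv_harmonized` set from [build_mv_set()].
#' @return A named list of [mr_estimate()] objects (method `"mvmr_ivw"`),
#'   one per exposure, with the fit's `Q` and `df` attached as attributes.
#' @export
mvmr_ivw <- function(set) {
  check_mv(set, 1L, "MVMR-IVW")
  n <- length(set$beta_outcome)
  p <- ncol(set$beta_exposure)
  fit <- mv_wls(set$beta_exposure, set$beta_outcome,
                1 / set$se_outcome^2, n - p)
  out <- lapply(seq_len(p), function(j) {
    mr_estimate("mvmr_ivw", fit$coef[j], fit$se[j], n)
  })
  names(out) <- set$exposures
  attr(out, "Q") <- fit$Q
  attr(out, "df") <- fit$df
  out
}

#' Multivariable MR-Egger
#'
#' As [mvmr_ivw()] with an intercept column, after orienting every variant so
#' the first exposure's beta is non-negative (the whole row, including the
#' outcome, flips sign together). The intercept tests directional pleiotropy
#' in the multivariable model.
#'
#' @param set An `mv_harmonized` set from [build_mv_set()].
#' @return A named list of per-exposure [mr_estimate()] objects (method
#'   `"mvmr_egger"`) with an `intercept` attribute (list with `estimate`,
#'   `se`, `pvalue`) plus `Q` and `df`.
#' @export
mvmr_egger <- function(set) {
  check_mv(set, 2L, "MVMR-Egger")
  n <- length(set$beta_outcome)
  p <- ncol(set$beta_exposure)
  flip <- sign(set$beta_exposure[, 1]) < 0
  B <- set$beta_exposure * ifelse(flip, -1, 1)
  y <- set$beta_outcome * ifelse(flip, -1, 1)
  X <- cbind(`(intercept)` = 1, B)
  fit <- mv_wls(X, y, 1 / set$se_outcome^2, n - p - 1)
  t_p <- function(est, se) 2 * stats::pt(-abs(est / se), df = n - p - 1)
  out <- lapply(seq_len(p), function(j) {
    mr_estimate("mvmr_egger", fit$coef[j + 1], fit$se[j + 1], n,
                pvalue = t_p(fit$coef[j + 1], fit$se[j + 1]))
  })
  names(out) <- set$exposures
  attr(out, "intercept") <- list(estimate = fit$coef[1], se = fit$se[1],
                                 pvalue = t_p(fit$coef[1], fit$se[1]))
  attr(out, "Q") <- fit$Q
  attr(out, "df") <- fit$df
  out
}
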