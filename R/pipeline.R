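# Study orchestration: config handling, the full two-step MR mediation
# workflow, the sensitivity-acceptance rule, and overlap-bias diagnostics.

default_config <- function() {
  list(
    exposure = NULL, outcome = NULL, mediators = list(),
    p_threshold = 5e-8, window_bp = 1e6, alpha = 0.05,
    drop_palindromic = TRUE,
    methods = c("ivw", "egger", "wmedian", "radial", "presso"),
    n_boot = 1000L, presso_n_sim = 1000L, seed = 1L
  )
}

#' Read / write a study configuration
#'
#' Plain-text YAML `key: value` configuration for [run_study()]. Unknown keys
#' are rejected; missing keys take package defaults. The round trip through
#' the file format is lossless.
#'
#' @param path File path.
#' @return `read_config()` returns the validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config A configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(validate_config(config), path)
  invisible(path)
}

validate_config <- function(config) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$exposure) || is.null(cfg$outcome)) {
    stop("config must name 'exposure' and 'outcome' summary-statistics files",
         call. = FALSE)
  }
  check_scalar(cfg$p_threshold, "p_threshold", lower = 0, upper = 1,
               open_lower = TRUE)
  check_scalar(cfg$window_bp, "window_bp", lower = 1)
  check_scalar(cfg$alpha, "alpha", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_scalar(cfg$n_boot, "n_boot", lower = 1)
  check_scalar(cfg$presso_n_sim, "presso_n_sim", lower = 1)
  check_scalar(cfg$seed, "seed")
  bad <- setdiff(cfg$methods, c("ivw", "egger", "wmedian", "radial", "presso"))
  if (length(bad) > 0) {
    stop(sprintf("unknown method(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  cfg
}

est_row <- function(analysis, exposure, outcome, est) {
  data.frame(
    analysis = analysis, exposure = exposure, outcome = outcome,
    method = est$method, n_snps = est$n_snps,
    beta = est$beta, se = est$se,
    ci_low = est$ci_low, ci_high = est$ci_high, pvalue = est$pvalue,
    or = est$or, or_ci_low = est$or_ci_low, or_ci_high = est$or_ci_high,
    stringsAsFactors = FALSE
  )
}

# Run the univariable estimator suite on a harmonized set.
uvmr_suite <- function(hs, methods, alpha, n_boot, n_sim, seed) {
  out <- list(ivw = mr_ivw(hs))
  het <- if (nrow(hs) >= 2) heterogeneity(hs) else NULL
  if ("egger" %in% methods && nrow(hs) >= 3) {
    out$egger <- mr_egger(hs)$slope
  }
  if ("wmedian" %in% methods && nrow(hs) >= 3) {
    out$wmedian <- mr_weighted_median(hs, n_boot = n_boot, seed = seed)
  }
  if ("radial" %in% methods && nrow(hs) >= 2) {
    out$radial <- radial_ivw(hs)$estimate
  }
  presso <- NULL
  if ("presso" %in% methods && nrow(hs) >= 4) {
    presso <- mr_presso(hs, n_sim = n_sim, seed = seed + 1L, alpha = alpha)
    out$presso <- presso$corrected
    out$presso$method <- "presso_corrected"
  }
  sens <- out[setdiff(names(out), "ivw")]
  accept <- if (length(sens) > 0) {
    accept_estimate(out$ivw, sens,
                    if (is.null(het)) NA_real_ else het$egger_intercept_p,
                    alpha)
  } else {
    list(pass = NA, reasons = "no sensitivity estimates")
  }
  list(estimates = out, het = het, presso = presso, accept = accept)
}

#' Run the full two-step MR mediation study
#'
#' Orchestrates the complete workflow on summary-statistics files named in a
#' configuration (list or YAML path): instrument selection for the exposure,
#' harmonization with the outcome, the univariable estimator suite for the
#' total effect, per-mediator forward and reverse univariable MR,
#' multivariable MR for exposure-adjusted mediator effects, the three-step
#' screen, per-mediator product-of-coefficients mediation, and combined
#' mediation (difference method) through all retained mediators. Every
#' filtered variant and screening decision is logged; results are
#' deterministic under a fixed config seed. Any stage error aborts with the
#' stage name and cause.
#'
#' @param config Configuration list or YAML file path; see [read_config()].
#' @param out_dir Optional directory: when given, `estimates.tsv`,
#'   `screening.tsv`, `mediation.tsv` and `log.txt` are written there.
#' @return An object of class `mr_study`: list with `estimates` (one row per
#'   analysis x method), `screening`, `mediation`, `diagnostics`, `accept`,
#'   `log` and `config`.
#' @export
run_study <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_config(config) else
    validate_config(config)
  log <- character()
  note <- function(...) log[[length(log) + 1L]] <<- sprintf(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  exposure <- stage("read exposure", read_sumstats(cfg$exposure))
  outcome <- stage("read outcome", read_sumstats(cfg$outcome))
  mediators <- stage("read mediators",
                     lapply(cfg$mediators, read_sumstats))

  iv <- stage("instrument selection",
              select_instruments(exposure, cfg$p_threshold, cfg$window_bp))
  note("exposure instruments: %d of %d variants kept (p < %g, %g bp clump)",
       nrow(iv), nrow(exposure), cfg$p_threshold, cfg$window_bp)
  diagnostics <- stage("instrument strength",
                       instrument_strength(iv, N = stats::median(iv$n)))

  hs <- stage("harmonization", harmonize(iv, outcome, cfg$drop_palindromic))
  dr <- attr(hs, "dropped")
  note("exposure-outcome harmonization: %d kept, %d dropped (%s)",
       nrow(hs), nrow(dr),
       if (nrow(dr) == 0) "none" else
         paste(names(table(dr$reason)), table(dr$reason), collapse = ", "))

  total_suite <- stage("total effect", uvmr_suite(
    hs, cfg$methods, cfg$alpha, cfg$n_boot, cfg$presso_n_sim, cfg$seed))
  total <- total_suite$estimates$ivw

  estimates <- do.call(rbind, lapply(total_suite$estimates, function(e) {
    est_row("total", "exposure", "outcome", e)
  }))

  screening <- data.frame(
    mediator = character(), step1 = logical(), step2 = logical(),
    step3 = logical(), final = logical(), reasons = character(),
    stringsAsFactors = FALSE)
  mediation <- data.frame(
    mediator = character(), method = character(),
    beta1 = numeric(), se_beta1 = numeric(),
    beta2 = numeric(), se_beta2 = numeric(),
    total = numeric(), se_total = numeric(),
    direct = numeric(), se_direct = numeric(),
    indirect = numeric(), se_indirect = numeric(),
    proportion = numeric(), se_proportion = numeric(),
    prop_ci_low = numeric(), prop_ci_high = numeric(),
    suppression = logical(), stringsAsFactors = FALSE)

  passed <- character()
  for (m in names(mediators)) {
    med_tab <- mediators[[m]]

    fwd_hs <- stage(paste0("forward MR ", m),
                    harmonize(iv, med_tab, cfg$drop_palindromic))
    forward <- mr_ivw(fwd_hs)
    estimates <- rbind(estimates, est_row("forward", "exposure", m, forward))

    reverse <- NULL
    rev_int_p <- NA_real_
    rev_iv <- tryCatch(
      select_instruments(med_tab, cfg$p_threshold, cfg$window_bp),
      error = function(e) NULL)
    if (is.null(rev_iv)) {
      note("mediator %s: no reverse instruments at p < %g", m, cfg$p_threshold)
    } else {
      rev_hs <- stage(paste0("reverse MR ", m),
                      harmonize(rev_iv, exposure, cfg$drop_palindromic))
      reverse <- mr_ivw(rev_hs)
      if (nrow(rev_hs) >= 3) rev_int_p <- mr_egger(rev_hs)$intercept$pvalue
      estimates <- rbind(estimates, est_row("reverse", m, "exposure", reverse))

      mo_hs <- stage(paste0("mediator-outcome MR ", m),
                     harmonize(rev_iv, outcome, cfg$drop_palindromic))
      unadj <- mr_ivw(mo_hs)
      estimates <- rbind(estimates,
                         est_row("mediator_outcome_unadjusted", m, "outcome",
                                 unadj))
    }

    mv <- stage(paste0("MVMR exposure+", m), build_mv_set(
      stats::setNames(list(exposure, med_tab), c("exposure", m)),
      outcome, cfg$p_threshold, cfg$window_bp))
    mv_fit <- mvmr_ivw(mv)
    adj <- mv_fit[[m]]
    direct_single <- mv_fit[["exposure"]]
    estimates <- rbind(estimates,
                       est_row("mediator_outcome_adjusted", m, "outcome", adj),
                       est_row("direct_single", "exposure", "outcome",
                               direct_single))

    dec <- screen_mediator(
      forward = forward, reverse = reverse, reverse_intercept_p = rev_int_p,
      m_on_o_unadj = if (is.null(rev_iv)) adj else unadj,
      m_on_o_adj = adj, total = total, alpha = cfg$alpha, mediator = m)
    screening <- rbind(screening, data.frame(
      mediator = m, step1 = dec$step1, step2 = dec$step2, step3 = dec$step3,
      final = dec$final,
      reasons = paste(dec$reasons, collapse = "; "),
      stringsAsFactors = FALSE))
    note("screen %s: %s%s", m, if (dec$final) "retain" else "exclude",
         if (length(dec$reasons) > 0)
           paste0(" (", paste(dec$reasons, collapse = "; "), ")") else "")

    med <- suppressWarnings(mediate_single(
      forward$beta, forward$se, adj$beta, adj$se, total$beta, total$se))
    mediation <- rbind(mediation, data.frame(
      mediator = m, method = "product",
      beta1 = med$beta1, se_beta1 = med$sigma1,
      beta2 = med$beta2, se_beta2 = med$sigma2,
      total = med$total, se_total = med$se_total,
      direct = med$direct, se_direct = med$se_direct,
      indirect = med$indirect, se_indirect = med$se_indirect,
      proportion = med$proportion, se_proportion = med$se_proportion,
      prop_ci_low = med$ci_low, prop_ci_high = med$ci_high,
      suppression = med$suppression, stringsAsFactors = FALSE))

    if (dec$final) passed <- c(passed, m)
  }

  if (length(passed) > 0) {
    mv_all <- stage("combined MVMR", build_mv_set(
      c(list(exposure = exposure), mediators[passed]),
      outcome, cfg$p_threshold, cfg$window_bp))
    mv_all_fit <- mvmr_ivw(mv_all)
    direct_all <- mv_all_fit[["exposure"]]
    estimates <- rbind(estimates,
                       est_row("direct_combined", "exposure", "outcome",
                               direct_all))
    comb <- suppressWarnings(mediate_combined(total, direct_all))
    mediation <- rbind(mediation, data.frame(
      mediator = paste(passed, collapse = "+"), method = "difference",
      beta1 = NA_real_, se_beta1 = NA_real_,
      beta2 = NA_real_, se_beta2 = NA_real_,
      total = comb$total, se_total = comb$se_total,
      direct = comb$direct, se_direct = comb$se_direct,
      indirect = comb$indirect, se_indirect = comb$se_indirect,
      proportion = comb$proportion, se_proportion = comb$se_proportion,
      prop_ci_low = comb$ci_low, prop_ci_high = comb$ci_high,
      suppression = comb$suppression, stringsAsFactors = FALSE))
  }

  rownames(estimates) <- NULL
  result <- structure(list(
    estimates = estimates, screening = screening, mediation = mediation,
    diagnostics = diagnostics, accept = total_suite$accept,
    heterogeneity = total_suite$het, retained_mediators = passed,
    log = log, config = cfg
  ), class = "mr_study")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, file) {
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
      utils::write.table(df, file.path(out_dir, file), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    wr(estimates, "estimates.tsv")
    wr(screening, "screening.tsv")
    wr(mediation, "mediation.tsv")
    writeLines(log, file.path(out_dir, "log.txt"))
  }
  result
}

#' @export
print.mr_study <- function(x, ...) {
  cat("Two-step MR mediation study\n")
  print(x$diagnostics)
  tot <- x$estimates[x$estimates$analysis == "total" &
                       x$estimates$method == "ivw", ]
  cat(sprintf("Total effect (IVW): OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              tot$or, tot$or_ci_low, tot$or_ci_high, tot$pvalue))
  if (nrow(x$screening) > 0) {
    cat(sprintf("Mediators retained: %s\n",
                if (length(x$retained_mediators) > 0)
                  paste(x$retained_mediators, collapse = ", ") else "none"))
  }
  invisible(x)
}

#' Sensitivity-acceptance rule for a primary IVW estimate
#'
#' An IVW estimate is accepted only when at least one sensitivity method
#' agrees with it in direction and is itself significant, and the MR-Egger
#' intercept shows no pleiotropy (`egger_intercept_p > alpha`). Adding a
#' corroborating sensitivity estimate can never flip a pass into a fail.
#'
#' @param primary Primary [mr_estimate()] (IVW).
#' @param sensitivity List of sensitivity [mr_estimate()] objects.
#' @param egger_intercept_p MR-Egger intercept p-value (`NA` treated as no
#'   evidence of pleiotropy).
#' @param alpha Significance threshold.
#' @return List with `pass` (flag) and `reasons` (character, empty on pass).
#' @export
accept_estimate <- function(primary, sensitivity, egger_intercept_p,
                            alpha = 0.05) {
  if (length(sensitivity) < 1) {
    stop("at least one sensitivity estimate is required", call. = FALSE)
  }
  reasons <- character()
  corroborated <- any(vapply(sensitivity, function(e) {
    sign(e$beta) == sign(primary$beta) && e$pvalue < alpha
  }, logical(1)))
  if (!corroborated) reasons <- c(reasons, "no corroborating method")
  if (!is.na(egger_intercept_p) && egger_intercept_p <= alpha) {
    reasons <- c(reasons, "pleiotropy")
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Expected bias and type-I error under sample overlap
#'
#' Diagnostic approximation for bias from overlapping participants between
#' the exposure and outcome GWAS: the expected bias of the causal estimate is
#' `overlap_fraction * confounded_assoc / F_bar` (the confounded
#' observational association leaking into the estimate in proportion to the
#' overlap, attenuated by instrument strength). The type-I error is the
#' two-sided rejection probability of a nominal `alpha`-level normal test of
#' zero effect when the estimator is centered at that bias with its nominal
#' standard error `se`. This is a diagnostic, not a correction.
#'
#' @param F_bar Mean instrument F statistic (> 0).
#' @param overlap_fraction Fraction of shared participants, in `[0, 1]`.
#' @param confounded_assoc Observational (confounded) exposure-outcome
#'   association.
#' @param alpha Nominal test level.
#' @param se Nominal standard error of the causal estimate; with the default
#'   1, `confounded_assoc` is interpreted in SE units.
#' @return List with `bias` and `type1_error`.
#' @export
overlap_bias <- function(F_bar, overlap_fraction, confounded_assoc,
                         alpha = 0.05, se = 1) {
  check_scalar(F_bar, "F_bar", lower = 0, open_lower = TRUE)
  check_scalar(overlap_fraction, "overlap_fraction", lower = 0, upper = 1)
  check_scalar(alpha, "alpha", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_scalar(se, "se", lower = 0, open_lower = TRUE)
  bias <- overlap_fraction * confounded_assoc / F_bar
  z <- stats::qnorm(1 - alpha / 2)
  lambda <- bias / se
  type1 <- stats::pnorm(-z - lambda) + stats::pnorm(-z + lambda)
  list(bias = bias, type1_error = type1)
}
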