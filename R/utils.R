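# Internal helpers shared across modules.

# 97.5% normal quantile used for every 95% CI in the package.
Z975 <- 1.959964

# Two-sided normal p-value for an estimate/SE pair.
norm_p <- function(beta, se) {
  p <- 2 * stats::pnorm(-abs(beta / se))
  p[se == 0 & beta == 0] <- 1
  p
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("parameter '%s' must be a single finite number", name),
         call. = FALSE)
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf("parameter '%s' = %g is outside its allowed range", name, x),
         call. = FALSE)
  }
  invisible(x)
}

# Extract beta/se/pvalue from an mr_estimate or a bare list.
est_beta <- function(x) if (inherits(x, "mr_estimate") || is.list(x)) x$beta else x
est_se <- function(x) x$se
est_p <- function(x) x$pvalue
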