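# Reading and writing tab-delimited GWAS summary statistics.

SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "eaf", "beta", "se", "pvalue", "n")
SUMSTATS_NUMERIC <- c("pos", "eaf", "beta", "se", "pvalue", "n")

validate_sumstats <- function(tab, what = "summary statistics") {
  if (!is.data.frame(tab)) {
    stop(sprintf("%s must be a data.frame", what), call. = FALSE)
  }
  missing <- setdiff(SUMSTATS_COLS, names(tab))
  if (length(missing) > 0) {
    stop(sprintf("%s table lacks required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(tab)
}

#' Write GWAS summary statistics to a tab-delimited file
#'
#' Writes the standard ten-column format (`variant_id, chrom, pos,
#' effect_allele, other_allele, eaf, beta, se, pvalue, n`) with a header row.
#' Numeric values are written with 15 significant digits so that a
#' write/read round trip is lossless well beyond 12 significant digits.
#'
#' @param tab A summary-statistics `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_sumstats()]
#' @export
write_sumstats <- function(tab, path) {
  validate_sumstats(tab)
  out <- tab[, SUMSTATS_COLS, drop = FALSE]
  for (col in SUMSTATS_NUMERIC) {
    out[[col]] <- sprintf("%.15g", as.numeric(out[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Expects the header produced by [write_sumstats()]. Extra columns are
#' retained; missing required columns or non-numeric entries in numeric
#' columns raise an error naming the offending column (and row).
#'
#' @param path File path.
#' @return A summary-statistics `data.frame`.
#' @export
read_sumstats <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("summary-statistics file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(SUMSTATS_COLS, names(raw))
  if (length(missing) > 0) {
    stop(sprintf("file '%s' lacks required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in SUMSTATS_NUMERIC) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(val) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' in column '%s', row %d of '%s'",
                   raw[[col]][bad[1]], col, bad[1], path), call. = FALSE)
    }
    raw[[col]] <- val
  }
  raw$pos <- as.integer(raw$pos)
  raw
}
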