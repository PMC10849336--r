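# Effective coverage: fraction of panel sites covered, lambda_eff, and
# duplication rate.

#' Fraction of panel sites covered by at least one passing read
#'
#' A site counts as covered when it has at least one unique (deduplicated)
#' read that passed the base-quality filter. Pileup counts are already
#' quality- and duplicate-filtered at construction time (by
#' [simulate_pileup()] or [read_mpileup()], both defaulting to a minimum
#' Phred base quality of 13), so this function only inspects the counts.
#'
#' @param pileups A `site_pileup` data.frame covering every panel site
#'   (zero-depth sites must be present as zero-count rows).
#' @param exclude_duplicates If `TRUE` (default) duplicate reads never count
#'   toward coverage; if `FALSE` a site with only duplicate reads counts as
#'   covered.
#' @return The covered fraction in \[0, 1\].
#' @export
fraction_covered <- function(pileups, exclude_duplicates = TRUE) {
  if (!is.data.frame(pileups) || nrow(pileups) == 0L) {
    stop("`pileups` must be a non-empty site_pileup data.frame")
  }
  passing <- pileups$ref_count + pileups$alt_count + pileups$other_count
  if (!exclude_duplicates) passing <- passing + pileups$dup_count
  mean(passing > 0L)
}

#' Effective coverage from the covered fraction
#'
#' The effective coverage of a low-pass sample is
#' `lambda_eff = -ln(1 - f_covered)`, the Poisson rate whose probability of
#' leaving a site uncovered equals the observed uncovered fraction. Unlike
#' nominal coverage it is insensitive to extra reads piled on already-covered
#' sites, so it measures the evenness-adjusted information content of a
#' library.
#'
#' @param f_covered Fraction of panel sites covered, in \[0, 1).
#' @return `-log(1 - f_covered)`.
#' @examples
#' effective_coverage(1 - exp(-1)) # == 1
#' @export
effective_coverage <- function(f_covered) {
  if (any(f_covered < 0 | f_covered > 1)) stop("`f_covered` must be in [0, 1]")
  if (any(f_covered == 1)) {
    stop("f_covered = 1: effective coverage saturated (infinite); ",
         "clamp to 1 - 1/(2 * n_sites) explicitly if intended")
  }
  -log1p(-f_covered)
}

#' Duplication rate from a raw read tally
#'
#' @param raw_tally A `raw_read_tally` (list with `total_reads` and
#'   `dup_reads`), as returned by [simulate_pileup()].
#' @return Fraction of raw reads flagged as duplicates.
#' @export
duplication_rate <- function(raw_tally) {
  if (is.null(raw_tally$total_reads) || raw_tally$total_reads < 1) {
    stop("duplication rate undefined: no raw reads")
  }
  raw_tally$dup_reads / raw_tally$total_reads
}

#' Summarize coverage for one sample
#'
#' Composes [fraction_covered()], [effective_coverage()] and
#' [duplication_rate()] into a one-sample coverage summary.
#'
#' In simulation mode (the default) nominal coverage is the mean raw read
#' count per panel site. For real data pass `nominal_coverage` explicitly as
#' total sequenced bases divided by genome size (e.g. 3,101,804,739 for
#' hs37).
#'
#' @param pileups A `site_pileup` data.frame over all panel sites.
#' @param raw_tally The matching `raw_read_tally`.
#' @param nominal_coverage Optional explicit nominal coverage; when `NULL`,
#'   computed as `total_reads / n_sites`.
#' @param exclude_duplicates Passed to [fraction_covered()].
#' @return An object of class `coverage_summary`: `nominal_coverage`,
#'   `f_covered`, `lambda_eff`, `eff_to_nominal_ratio`, `dup_rate`, `mode`.
#' @export
summarize_coverage <- function(pileups, raw_tally, nominal_coverage = NULL,
                               exclude_duplicates = TRUE) {
  f <- fraction_covered(pileups, exclude_duplicates = exclude_duplicates)
  mode <- if (is.null(nominal_coverage)) "simulation" else "real"
  if (is.null(nominal_coverage)) {
    nominal_coverage <- raw_tally$total_reads / nrow(pileups)
  }
  lam <- if (f == 0) 0 else effective_coverage(f)
  structure(
    list(
      nominal_coverage = nominal_coverage,
      f_covered = f,
      lambda_eff = lam,
      eff_to_nominal_ratio = if (nominal_coverage > 0) lam / nominal_coverage else NA_real_,
      dup_rate = duplication_rate(raw_tally),
      mode = mode
    ),
    class = "coverage_summary"
  )
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Coverage summary (%s mode):\n",
           "  nominal coverage      %.4f\n",
           "  fraction covered      %.4f\n",
           "  effective coverage    %.4f\n",
           "  effective/nominal     %.4f\n",
           "  duplication rate      %.4f%%\n"),
    x$mode, x$nominal_coverage, x$f_covered, x$lambda_eff,
    x$eff_to_nominal_ratio, 100 * x$dup_rate))
  invisible(x)
}

#' @export
as.data.frame.coverage_summary <- function(x, ...) {
  data.frame(
    nominal_coverage = x$nominal_coverage,
    f_covered = x$f_covered,
    lambda_eff = x$lambda_eff,
    eff_to_nominal_ratio = x$eff_to_nominal_ratio,
    dup_rate = x$dup_rate,
    stringsAsFactors = FALSE
  )
}
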