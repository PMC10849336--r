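# Non-reference concordance between an imputed call set and truth,
# overall and stratified by panel allele frequency.

#' Non-reference concordance (NRC)
#'
#' Genotype concordance between two call sets computed on the intersection
#' of called sites, after dropping sites at which both call sets are
#' homozygous reference. NRC is preferred over overall concordance for
#' imputed genotypes because most sites in a large panel are homozygous
#' reference in any one individual, which inflates overall concordance.
#'
#' Sites with `NA` in either call set (uncalled, or removed by the
#' confidence filter) are excluded from the intersection.
#'
#' @param imputed,truth Integer vectors of genotypes in 0:2 (`NA` = not
#'   called), aligned site-by-site.
#' @return An object of class `concordance_report`: `n_intersect`,
#'   `n_both_homref`, `n_match_nonref`, `n_denom`, `nrc` (`NA` when the
#'   denominator is empty, with `undefined = TRUE`).
#' @examples
#' nrc(c(1L, 2L, 0L), c(1L, 2L, 0L))$nrc  # 1: both-hom-ref site dropped
#' @export
nrc <- function(imputed, truth) {
  if (length(imputed) != length(truth)) stop("call sets must be aligned")
  ok_i <- !is.na(imputed)
  ok_t <- !is.na(truth)
  both <- ok_i & ok_t
  if (any(!imputed[ok_i] %in% 0:2) || any(!truth[ok_t] %in% 0:2)) {
    stop("genotype calls must be in {0, 1, 2}")
  }
  i <- imputed[both]
  t <- truth[both]
  n_intersect <- length(i)
  both_homref <- i == 0L & t == 0L
  n_both_homref <- sum(both_homref)
  n_match_nonref <- sum(i == t & !both_homref)
  n_denom <- n_intersect - n_both_homref
  structure(
    list(
      n_intersect = n_intersect,
      n_both_homref = n_both_homref,
      n_match_nonref = n_match_nonref,
      n_denom = n_denom,
      nrc = if (n_denom > 0) n_match_nonref / n_denom else NA_real_,
      undefined = n_denom == 0L
    ),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Non-reference concordance\n")
  cat(sprintf("  intersecting sites       %d\n", x$n_intersect))
  cat(sprintf("  both hom-ref (dropped)   %d\n", x$n_both_homref))
  if (x$undefined) {
    cat("  NRC                      undefined (empty denominator)\n")
  } else {
    cat(sprintf("  NRC                      %d / %d = %.4f\n",
                x$n_match_nonref, x$n_denom, x$nrc))
  }
  if (!is.null(x$per_bin)) {
    cat("  by allele-frequency bin:\n")
    print(x$per_bin, row.names = FALSE)
  }
  invisible(x)
}

#' Default minor-allele-frequency bin edges
#'
#' Logarithmically spaced MAF edges standard in imputation-accuracy
#' reporting.
#' @return Numeric vector of bin edges.
#' @export
default_af_bins <- function() c(0, 0.001, 0.005, 0.01, 0.05, 0.1, 0.2, 0.5)

#' NRC stratified by panel allele frequency
#'
#' Assigns every site to exactly one half-open frequency bin `[lo, hi)` (the
#' last bin is closed above) and computes the NRC rule within each bin, plus
#' the overall report. By default the alternate-allele frequency is folded
#' to the minor-allele frequency, since panel alternate AF may exceed 0.5.
#'
#' @param imputed,truth Aligned genotype vectors as in [nrc()].
#' @param af Per-site panel alternate-allele frequency.
#' @param bin_edges Strictly increasing bin edges spanning the AF range
#'   (default [default_af_bins()]).
#' @param fold_af Fold `af` to `pmin(af, 1 - af)` before binning (default
#'   `TRUE`).
#' @return A `concordance_report` with an additional `per_bin` data.frame
#'   (`af_lo`, `af_hi`, `n_sites`, `n_denom`, `nrc`); empty bins have
#'   `n_sites = 0` and `NA` NRC.
#' @export
nrc_by_af_bin <- function(imputed, truth, af, bin_edges = default_af_bins(),
                          fold_af = TRUE) {
  if (length(af) != length(imputed)) stop("`af` must align with the call sets")
  if (length(bin_edges) < 2L || is.unsorted(bin_edges, strictly = TRUE)) {
    stop("`bin_edges` must be strictly increasing")
  }
  x <- if (fold_af) pmin(af, 1 - af) else af
  if (any(x < bin_edges[1L] | x > bin_edges[length(bin_edges)])) {
    stop("allele frequencies fall outside `bin_edges`")
  }
  overall <- nrc(imputed, truth)
  nb <- length(bin_edges) - 1L
  # half-open [lo, hi); top edge inclusive
  bin <- findInterval(x, bin_edges, rightmost.closed = TRUE)
  per_bin <- do.call(rbind, lapply(seq_len(nb), function(k) {
    sel <- bin == k
    r <- nrc(imputed[sel], truth[sel])
    data.frame(
      af_lo = bin_edges[k], af_hi = bin_edges[k + 1L],
      n_sites = r$n_intersect, n_denom = r$n_denom, nrc = r$nrc
    )
  }))
  overall$per_bin <- per_bin
  overall
}
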