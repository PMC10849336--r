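# Synthetic data: haplotype panels, recombinant truth individuals, and
# low-pass pileup simulation.

#' Generate a synthetic haplotype reference panel
#'
#' Builds a phased biallelic-SNP haplotype panel with a configurable site
#' frequency spectrum (SFS) and tunable linkage disequilibrium. Per-site
#' alternate-allele counts are drawn from the chosen spectrum restricted to
#' polymorphic counts (1 to `n_haplotypes - 1`), so no site is monomorphic.
#' Linkage disequilibrium is induced by a carrier-copying construction: with
#' probability `ld_strength` the carrier set at a site is obtained by
#' minimally editing the previous site's carrier set to the new allele
#' count; otherwise carriers are drawn afresh.
#'
#' @param n_haplotypes Number of phased haplotypes; must be even and >= 4
#'   (leave-one-out imputation removes two).
#' @param n_sites Number of biallelic SNP sites (>= 2).
#' @param sfs_shape `"neutral"` draws the derived-allele count i with
#'   probability proportional to 1/i (the standard neutral SFS);
#'   `"uniform"` draws i uniformly on 1..(n_haplotypes - 1).
#' @param ld_strength Probability in \[0, 1\] that a site inherits (a minimal
#'   edit of) the previous site's carrier set; 0 gives linkage equilibrium,
#'   values near 1 give strong LD.
#' @param seed Optional integer seed for reproducibility.
#' @param chrom Chromosome label used for all sites.
#' @param pos_spacing Distance in bp between adjacent sites.
#'
#' @return An object of class `haplotype_panel`: a list with elements
#'   `sites` (data.frame with `chrom`, `pos`, `ref`, `alt`), `alleles`
#'   (0/1 matrix, one row per haplotype, one column per site), `af`
#'   (per-site alternate-allele frequency) and `genetic_dist` (per-interval
#'   recombination distance on a unitless probability scale, default 1).
#' @examples
#' p <- generate_panel(20, 100, seed = 1)
#' range(p$af)
#' @export
generate_panel <- function(n_haplotypes, n_sites,
                           sfs_shape = c("neutral", "uniform"),
                           ld_strength = 0.9, seed = NULL,
                           chrom = "1", pos_spacing = 1000L) {
  sfs_shape <- match.arg(sfs_shape)
  if (!is.numeric(n_haplotypes) || length(n_haplotypes) != 1L ||
      n_haplotypes < 4 || n_haplotypes %% 2 != 0) {
    stop("`n_haplotypes` must be an even integer >= 4")
  }
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 2) {
    stop("`n_sites` must be an integer >= 2")
  }
  if (!is.numeric(ld_strength) || ld_strength < 0 || ld_strength > 1) {
    stop("`ld_strength` must be in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  n_haplotypes <- as.integer(n_haplotypes)
  n_sites <- as.integer(n_sites)

  # derived-allele counts from the configured spectrum, polymorphic only
  counts_support <- seq_len(n_haplotypes - 1L)
  w <- switch(sfs_shape,
    neutral = 1 / counts_support,
    uniform = rep(1, length(counts_support))
  )
  ac <- sample(counts_support, n_sites, replace = TRUE, prob = w / sum(w))

  alleles <- matrix(0L, nrow = n_haplotypes, ncol = n_sites)
  carriers <- sample.int(n_haplotypes, ac[1L])
  alleles[carriers, 1L] <- 1L
  for (j in seq_len(n_sites)[-1L]) {
    if (stats::runif(1) < ld_strength) {
      # minimal edit of the previous carrier set to the new allele count
      delta <- ac[j] - length(carriers)
      if (delta > 0) {
        pool <- setdiff(seq_len(n_haplotypes), carriers)
        carriers <- c(carriers, pool[sample.int(length(pool), delta)])
      } else if (delta < 0) {
        carriers <- carriers[sample.int(length(carriers), ac[j])]
      }
    } else {
      carriers <- sample.int(n_haplotypes, ac[j])
    }
    alleles[carriers, j] <- 1L
  }

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  sites <- data.frame(
    chrom = rep(chrom, n_sites),
    pos = as.integer(seq_len(n_sites)) * as.integer(pos_spacing),
    ref = ref, alt = unname(alt),
    stringsAsFactors = FALSE
  )

  panel <- structure(
    list(
      sites = sites,
      alleles = alleles,
      af = colMeans(alleles),
      genetic_dist = rep(1, n_sites - 1L)
    ),
    class = "haplotype_panel"
  )
  validate_panel(panel)
  panel
}

#' Validate a haplotype panel
#'
#' Checks the structural invariants of a [generate_panel()] object: biallelic
#' SNP sites with strictly increasing positions per chromosome, a 0/1 allele
#' matrix whose column means equal the stored allele frequencies, and an even
#' haplotype count of at least four.
#'
#' @param panel A `haplotype_panel`.
#' @return `panel`, invisibly; errors if an invariant is violated.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  s <- panel$sites
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(s))) {
    stop("panel$sites must have chrom, pos, ref, alt")
  }
  if (any(nchar(s$ref) != 1L) || any(nchar(s$alt) != 1L) ||
      any(s$ref == s$alt)) {
    stop("panel sites must be biallelic SNPs")
  }
  by_chrom <- split(s$pos, s$chrom)
  if (!all(vapply(by_chrom, function(p) all(diff(p) > 0), logical(1)))) {
    stop("positions must be strictly increasing within a chromosome")
  }
  a <- panel$alleles
  if (!all(a %in% c(0L, 1L))) stop("allele matrix must be 0/1")
  if (nrow(a) < 4L || nrow(a) %% 2 != 0) {
    stop("panel must have an even number of haplotypes, >= 4")
  }
  if (ncol(a) != nrow(s)) stop("allele matrix / site list mismatch")
  if (max(abs(colMeans(a) - panel$af)) > 1e-12) {
    stop("stored allele frequencies disagree with the allele matrix")
  }
  if (length(panel$genetic_dist) != ncol(a) - 1L) {
    stop("genetic_dist must have one entry per adjacent-site interval")
  }
  invisible(panel)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("Haplotype panel:", nrow(x$alleles), "haplotypes x",
      ncol(x$alleles), "biallelic SNP sites\n")
  cat(sprintf("  alt-allele frequency: min %.4f, median %.4f, max %.4f\n",
              min(x$af), stats::median(x$af), max(x$af)))
  invisible(x)
}

#' Simulate a diploid truth individual as a recombinant panel mosaic
#'
#' Each of the two haplotypes starts as a copy of a randomly chosen panel
#' haplotype and, at each adjacent-site interval, switches with probability
#' `recomb_rate` to a uniformly chosen source haplotype; each copied allele is
#' flipped with probability `mutation_rate`. The two initial source rows are
#' recorded in `hap_indices` so they can be held out of the panel at
#' imputation time (leave-one-out).
#'
#' @param panel A `haplotype_panel`.
#' @param recomb_rate Per-interval switch probability in \[0, 1).
#' @param mutation_rate Per-site allele-flip probability in \[0, 1).
#' @param seed Optional integer seed.
#' @return An object of class `truth_individual`: list with `hap_indices`
#'   (the two held-out panel rows), `mosaic_paths` (2 x n_sites matrix of
#'   source-haplotype indices), `haplotypes` (2 x n_sites 0/1 matrix) and
#'   `genotypes` (per-site alternate-allele count in 0:2).
#' @examples
#' p <- generate_panel(8, 50, seed = 2)
#' ind <- simulate_individual(p, recomb_rate = 0.01, seed = 3)
#' table(ind$genotypes)
#' @export
simulate_individual <- function(panel, recomb_rate = 0.001,
                                mutation_rate = 0, seed = NULL) {
  validate_panel(panel)
  if (recomb_rate < 0 || recomb_rate >= 1) stop("`recomb_rate` must be in [0, 1)")
  if (mutation_rate < 0 || mutation_rate >= 1) stop("`mutation_rate` must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n_hap <- nrow(panel$alleles)
  m <- ncol(panel$alleles)

  hap_indices <- sample.int(n_hap, 2L)
  paths <- matrix(NA_integer_, nrow = 2L, ncol = m)
  haps <- matrix(0L, nrow = 2L, ncol = m)
  for (h in 1:2) {
    src <- hap_indices[h]
    path <- integer(m)
    path[1L] <- src
    if (m > 1L) {
      switch_at <- stats::runif(m - 1L) < recomb_rate
      for (j in 2:m) {
        if (switch_at[j - 1L]) src <- sample.int(n_hap, 1L)
        path[j] <- src
      }
    }
    paths[h, ] <- path
    copied <- panel$alleles[cbind(path, seq_len(m))]
    flip <- stats::runif(m) < mutation_rate
    haps[h, ] <- ifelse(flip, 1L - copied, copied)
  }

  structure(
    list(
      hap_indices = hap_indices,
      mosaic_paths = paths,
      haplotypes = haps,
      genotypes = as.integer(colSums(haps))
    ),
    class = "truth_individual"
  )
}

#' @export
print.truth_individual <- function(x, ...) {
  cat("Truth individual over", ncol(x$haplotypes), "sites; held-out panel rows:",
      paste(x$hap_indices, collapse = ", "), "\n")
  g <- table(factor(x$genotypes, levels = 0:2))
  cat(sprintf("  genotypes: %d hom-ref, %d het, %d hom-alt\n", g[1], g[2], g[3]))
  invisible(x)
}

#' Configuration for pileup simulation
#'
#' @param nominal_coverage Mean raw reads per panel site (> 0).
#' @param dup_rate Probability that a raw read is a duplicate, in \[0, 1).
#' @param overdispersion Dispersion of per-site raw read counts: 0 gives
#'   Poisson counts; d > 0 gives negative-binomial counts with variance
#'   mu + d * mu^2.
#' @param base_error Per-base miscall probability in \[0, 0.5); a miscalled
#'   base reports the other panel allele.
#' @param bq_distribution Distribution over Phred base qualities: a named
#'   numeric vector of probabilities whose names are Phred scores, e.g.
#'   `c("30" = 0.9, "12" = 0.1)`. Default: all bases Q30.
#' @param seed Optional integer seed used by [simulate_pileup()].
#' @return An object of class `read_sim_config`.
#' @export
read_sim_config <- function(nominal_coverage, dup_rate = 0,
                            overdispersion = 0, base_error = 0.002,
                            bq_distribution = c("30" = 1), seed = NULL) {
  if (!is.numeric(nominal_coverage) || nominal_coverage <= 0) {
    stop("`nominal_coverage` must be > 0")
  }
  if (dup_rate < 0 || dup_rate >= 1) stop("`dup_rate` must be in [0, 1)")
  if (overdispersion < 0) stop("`overdispersion` must be >= 0")
  if (base_error < 0 || base_error >= 0.5) stop("`base_error` must be in [0, 0.5)")
  q <- suppressWarnings(as.numeric(names(bq_distribution)))
  if (length(bq_distribution) == 0L || any(is.na(q)) || any(q < 0) ||
      any(bq_distribution < 0) || sum(bq_distribution) <= 0) {
    stop("`bq_distribution` must be a named vector of probabilities over Phred scores")
  }
  structure(
    list(
      nominal_coverage = nominal_coverage,
      dup_rate = dup_rate,
      overdispersion = overdispersion,
      base_error = base_error,
      bq_phred = as.integer(q),
      bq_prob = unname(bq_distribution) / sum(bq_distribution),
      seed = seed
    ),
    class = "read_sim_config"
  )
}

#' Simulate panel-site pileups for a truth individual
#'
#' Draws a raw read count at every panel site with mean
#' `config$nominal_coverage` (Poisson when `overdispersion = 0`, otherwise
#' negative binomial), marks each raw read as a duplicate independently with
#' probability `config$dup_rate`, and generates the unique (non-duplicate)
#' reads: each samples one of the individual's two haplotypes with equal
#' probability, miscalls the allele with probability `config$base_error`, and
#' carries a Phred base quality drawn from `config$bq_distribution`. Duplicate
#' reads are redundant copies of unique reads; they are tallied but excluded
#' from the pileup counts, mirroring duplicate-filtered (`--ff DUP`) pileups.
#' Bases below `min_base_quality` are likewise excluded from `ref_count` /
#' `alt_count` (the coverage rule used throughout).
#'
#' @param individual A `truth_individual` from [simulate_individual()].
#' @param panel The `haplotype_panel` the individual was simulated from.
#' @param config A [read_sim_config()].
#' @param min_base_quality Minimum Phred base quality for a base to count
#'   (default 13).
#' @param keep_reads If `TRUE`, attach the unique read-level data (site index,
#'   base, quality) as attribute `"reads"` on the pileup data.frame, e.g. for
#'   writing mpileup text with [write_mpileup()].
#' @return A list with `pileups` (a `site_pileup` data.frame: `chrom`, `pos`,
#'   `ref`, `alt`, `ref_count`, `alt_count`, `other_count`, `raw_depth`,
#'   `dup_count`, post-filter unique-read counts) and `raw_tally` (class
#'   `raw_read_tally`: `total_reads`, `dup_reads`).
#' @examples
#' p <- generate_panel(8, 200, seed = 4)
#' ind <- simulate_individual(p, seed = 5)
#' sim <- simulate_pileup(ind, p, read_sim_config(0.8, seed = 6))
#' head(sim$pileups)
#' @export
simulate_pileup <- function(individual, panel, config,
                            min_base_quality = 13L, keep_reads = FALSE) {
  stopifnot(inherits(individual, "truth_individual"),
            inherits(config, "read_sim_config"))
  validate_panel(panel)
  m <- nrow(panel$sites)
  if (ncol(individual$haplotypes) != m) {
    stop("individual and panel site lists differ")
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  raw <- if (config$overdispersion == 0) {
    stats::rpois(m, config$nominal_coverage)
  } else {
    stats::rnbinom(m, size = 1 / config$overdispersion,
                   mu = config$nominal_coverage)
  }

  # Per-read simulation over all raw reads. Duplicate flags are independent
  # Bernoulli(dup_rate) thinning; content is drawn for every raw read so
  # that two configs differing only in dup_rate and run under the same seed
  # share raw counts and read content (common-random-numbers coupling for
  # paired arm comparisons) and the higher-duplication arm drops a superset
  # of reads.
  all_idx <- rep.int(seq_len(m), raw)
  n_raw <- length(all_idx)
  is_dup <- stats::runif(n_raw) < config$dup_rate
  hap_row <- sample(1:2, n_raw, replace = TRUE)
  true_allele <- individual$haplotypes[cbind(hap_row, all_idx)]
  err <- stats::runif(n_raw) < config$base_error
  obs_all <- ifelse(err, 1L - true_allele, true_allele)
  qual_all <- if (length(config$bq_phred) == 1L) {
    rep.int(config$bq_phred, n_raw)
  } else {
    config$bq_phred[sample.int(length(config$bq_phred), n_raw,
                               replace = TRUE, prob = config$bq_prob)]
  }
  dup <- tabulate(all_idx[is_dup], nbins = m)

  site_idx <- all_idx[!is_dup]
  obs_allele <- obs_all[!is_dup]
  qual <- qual_all[!is_dup]
  pass <- qual >= min_base_quality

  tab <- function(keep) tabulate(site_idx[keep], nbins = m)
  pileups <- data.frame(
    chrom = panel$sites$chrom,
    pos = panel$sites$pos,
    ref = panel$sites$ref,
    alt = panel$sites$alt,
    ref_count = tab(pass & obs_allele == 0L),
    alt_count = tab(pass & obs_allele == 1L),
    other_count = 0L,
    raw_depth = raw,
    dup_count = dup,
    stringsAsFactors = FALSE
  )
  class(pileups) <- c("site_pileup", "data.frame")
  if (keep_reads) {
    base_chr <- ifelse(obs_allele == 1L,
                       panel$sites$alt[site_idx], panel$sites$ref[site_idx])
    attr(pileups, "reads") <- data.frame(
      site = site_idx, base = base_chr, qual = qual,
      stringsAsFactors = FALSE
    )
  }
  list(
    pileups = pileups,
    raw_tally = structure(
      list(total_reads = sum(raw), dup_reads = sum(dup)),
      class = "raw_read_tally"
    )
  )
}

#' @export
print.raw_read_tally <- function(x, ...) {
  cat(sprintf("Raw read tally: %d reads, %d duplicates (%.3f%%)\n",
              x$total_reads, x$dup_reads,
              100 * x$dup_reads / max(1L, x$total_reads)))
  invisible(x)
}
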