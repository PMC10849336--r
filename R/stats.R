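# Group summaries, Welch's t-test comparison, and the two-arm synthetic
# experiment driver.

#' Summarize a numeric sample as n / mean / sd
#'
#' @param values Numeric vector, length >= 1 (sd requires length >= 2).
#' @return List with `n`, `mean`, `sd` (sample standard deviation, n - 1
#'   denominator; `NA` for n = 1).
#' @export
summarize <- function(values) {
  if (length(values) < 1L || !is.numeric(values)) {
    stop("`values` must be a non-empty numeric vector")
  }
  list(n = length(values), mean = mean(values),
       sd = if (length(values) >= 2L) stats::sd(values) else NA_real_)
}

#' Welch's unpaired two-sample t-test
#'
#' Unequal-variance comparison of two group means with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value (via [stats::t.test()]).
#' When both groups have zero variance the statistic is degenerate: equal
#' means give t = 0, p = 1; unequal means give an infinite t with p = 0.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param labels Character vector of two group labels.
#' @return An object of class `group_comparison`: per-group `n`, `mean`,
#'   `sd`, plus `t_statistic`, `dof`, `p_value`.
#' @examples
#' welch_t(rnorm(10), rnorm(10, 1))
#' @export
welch_t <- function(a, b, labels = c("a", "b")) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  sa <- summarize(a)
  sb <- summarize(b)
  if (sa$sd == 0 && sb$sd == 0) {
    if (sa$mean == sb$mean) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(sa$mean - sb$mean) * Inf; p <- 0
    }
    dof <- NA_real_
  } else {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    t_stat <- unname(ht$statistic)
    dof <- unname(ht$parameter)
    p <- ht$p.value
  }
  structure(
    list(labels = labels, summary_a = sa, summary_b = sb,
         t_statistic = t_stat, dof = dof, p_value = p),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Welch two-sample t-test\n")
  for (i in 1:2) {
    s <- if (i == 1) x$summary_a else x$summary_b
    cat(sprintf("  %-10s n = %d, mean = %.6g, sd = %.6g\n",
                x$labels[i], s$n, s$mean, s$sd))
  }
  cat(sprintf("  t = %.4g, df = %.2f, two-sided p = %.4g\n",
              x$t_statistic, x$dof, x$p_value))
  invisible(x)
}

#' Run the two-arm synthetic sequencing-chemistry comparison
#'
#' End-to-end synthetic replica of a two-chemistry low-pass study: a shared
#' haplotype panel is generated once; for each of `n_samples_per_arm`
#' sample slots a truth individual is simulated and sequenced under both arm
#' configurations (the arms differ only in their read-simulation settings,
#' by default in duplication rate). Each sample is then imputed in a
#' leave-one-out manner, confidence-filtered, and compared to its truth
#' genotypes. Per-sample coverage and concordance metrics are collected and
#' the arms are compared with Welch's t-tests on duplication rate,
#' effective-to-nominal coverage ratio, and NRC.
#'
#' Sample slots are paired across arms (same panel, same truth individual,
#' same per-slot base seed), so arm differences reflect the read-simulation
#' settings only.
#'
#' @param n_samples_per_arm Samples per arm (>= 2).
#' @param dup_rates Length-2 numeric: duplication rate of each arm.
#' @param nominal_coverage Mean raw reads per panel site (shared by arms).
#' @param overdispersion,base_error,bq_distribution Read-simulation settings
#'   shared by both arms (see [read_sim_config()]).
#' @param n_haplotypes,n_sites,sfs_shape,ld_strength Panel settings (see
#'   [generate_panel()]).
#' @param recomb_rate,mutation_rate Truth-individual settings (see
#'   [simulate_individual()]).
#' @param hmm An [hmm_params()] object for the imputation HMM.
#' @param gp_threshold Posterior-confidence filter threshold.
#' @param af_bin_edges Allele-frequency bin edges for stratified NRC.
#' @param arm_labels Character vector of two arm labels.
#' @param seed Master seed; per-slot seeds are derived deterministically.
#' @return An object of class `lp_experiment`: `samples` (one row per
#'   sample with coverage and NRC metrics), `arm_summaries`, `comparisons`
#'   (Welch tests for `dup_rate`, `eff_to_nominal_ratio`, `nrc`),
#'   `nrc_by_af` (pooled per-arm per-bin NRC), and the settings used.
#' @examples
#' \donttest{
#' ex <- run_experiment(n_samples_per_arm = 3, n_sites = 300, seed = 1)
#' ex$comparisons$dup_rate
#' }
#' @export
run_experiment <- function(n_samples_per_arm = 20,
                           dup_rates = c(0.0027, 0.055),
                           nominal_coverage = 1.0,
                           overdispersion = 0,
                           base_error = 0.002,
                           bq_distribution = c("30" = 1),
                           n_haplotypes = 40, n_sites = 2000,
                           sfs_shape = "neutral", ld_strength = 0.9,
                           recomb_rate = 0.001, mutation_rate = 0,
                           hmm = hmm_params(),
                           gp_threshold = 0.9,
                           af_bin_edges = default_af_bins(),
                           arm_labels = c("low_dup", "high_dup"),
                           seed = 1) {
  if (n_samples_per_arm < 2) stop("`n_samples_per_arm` must be >= 2")
  stopifnot(length(dup_rates) == 2L, length(arm_labels) == 2L)
  set.seed(seed)
  panel <- generate_panel(n_haplotypes, n_sites, sfs_shape = sfs_shape,
                          ld_strength = ld_strength)
  slot_seeds <- sample.int(.Machine$integer.max - 1L, n_samples_per_arm)

  rows <- list()
  bins <- list(list(), list())
  for (k in seq_len(n_samples_per_arm)) {
    ind <- simulate_individual(panel, recomb_rate = recomb_rate,
                               mutation_rate = mutation_rate,
                               seed = slot_seeds[k])
    for (arm in 1:2) {
      cfg <- read_sim_config(
        nominal_coverage = nominal_coverage, dup_rate = dup_rates[arm],
        overdispersion = overdispersion, base_error = base_error,
        bq_distribution = bq_distribution,
        # same read seed for both arms: common-random-numbers pairing
        seed = (slot_seeds[k] + 1L) %% (.Machine$integer.max - 1L)
      )
      sim <- simulate_pileup(ind, panel, cfg)
      cov <- summarize_coverage(sim$pileups, sim$raw_tally)
      gl <- genotype_likelihoods(sim$pileups$ref_count,
                                 sim$pileups$alt_count, base_error)
      gp <- impute_sample(gl, panel, held_out = ind$hap_indices, params = hmm)
      flt <- filter_posteriors(gp, threshold = gp_threshold)
      rep_af <- nrc_by_af_bin(flt$calls, ind$genotypes, panel$af,
                              bin_edges = af_bin_edges)
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm_labels[arm], sample = k,
        dup_rate = cov$dup_rate,
        nominal_coverage = cov$nominal_coverage,
        f_covered = cov$f_covered,
        lambda_eff = cov$lambda_eff,
        eff_to_nominal_ratio = cov$eff_to_nominal_ratio,
        nrc = rep_af$nrc,
        n_filtered = flt$n_removed,
        stringsAsFactors = FALSE
      )
      bins[[arm]][[k]] <- rep_af$per_bin
    }
  }
  samples <- do.call(rbind, rows)

  arm_summaries <- do.call(rbind, lapply(1:2, function(arm) {
    s <- samples[samples$arm == arm_labels[arm], ]
    data.frame(
      arm = arm_labels[arm], n = nrow(s),
      mean_dup_rate = mean(s$dup_rate), sd_dup_rate = stats::sd(s$dup_rate),
      mean_ratio = mean(s$eff_to_nominal_ratio),
      sd_ratio = stats::sd(s$eff_to_nominal_ratio),
      mean_nrc = mean(s$nrc), sd_nrc = stats::sd(s$nrc),
      stringsAsFactors = FALSE
    )
  }))

  metric_cmp <- function(col) {
    welch_t(samples[samples$arm == arm_labels[1L], col],
            samples[samples$arm == arm_labels[2L], col],
            labels = arm_labels)
  }
  comparisons <- list(
    dup_rate = metric_cmp("dup_rate"),
    eff_to_nominal_ratio = metric_cmp("eff_to_nominal_ratio"),
    nrc = metric_cmp("nrc")
  )

  # per-arm mean NRC per AF bin across samples
  nrc_by_af <- do.call(rbind, lapply(1:2, function(arm) {
    b <- bins[[arm]]
    template <- b[[1L]][, c("af_lo", "af_hi")]
    mat <- sapply(b, function(d) d$nrc)
    nmat <- sapply(b, function(d) d$n_sites)
    data.frame(
      arm = arm_labels[arm], template,
      n_sites = rowSums(nmat),
      mean_nrc = rowMeans(mat, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }))

  structure(
    list(samples = samples, arm_summaries = arm_summaries,
         comparisons = comparisons, nrc_by_af = nrc_by_af,
         settings = list(
           n_samples_per_arm = n_samples_per_arm, dup_rates = dup_rates,
           nominal_coverage = nominal_coverage,
           overdispersion = overdispersion, base_error = base_error,
           n_haplotypes = n_haplotypes, n_sites = n_sites,
           ld_strength = ld_strength, recomb_rate = recomb_rate,
           mutation_rate = mutation_rate, hmm = hmm,
           gp_threshold = gp_threshold, seed = seed
         )),
    class = "lp_experiment"
  )
}

#' @export
print.lp_experiment <- function(x, ...) {
  s <- x$arm_summaries
  cat("Two-arm synthetic low-pass sequencing experiment\n")
  cat(sprintf("  %d samples/arm, %d panel haplotypes x %d sites, %.2fx nominal coverage\n",
              x$settings$n_samples_per_arm, x$settings$n_haplotypes,
              x$settings$n_sites, x$settings$nominal_coverage))
  for (i in 1:2) {
    cat(sprintf("  arm %-9s dup rate %.3f%% (sd %.3f%%), eff/nominal %.3f, NRC %.4f (sd %.4f)\n",
                s$arm[i], 100 * s$mean_dup_rate[i], 100 * s$sd_dup_rate[i],
                s$mean_ratio[i], s$mean_nrc[i], s$sd_nrc[i]))
  }
  cat(sprintf("  Welch p (dup rate):     %.3g\n", x$comparisons$dup_rate$p_value))
  cat(sprintf("  Welch p (eff/nominal):  %.3g\n",
              x$comparisons$eff_to_nominal_ratio$p_value))
  cat(sprintf("  Welch p (NRC):          %.3g\n", x$comparisons$nrc$p_value))
  invisible(x)
}
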