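# Synthetic-data generator: panels, truth individuals, pileups.

test_that("panel generation is seeded-deterministic and always polymorphic", {
  p1 <- generate_panel(4, 10, seed = 7)
  p2 <- generate_panel(4, 10, seed = 7)
  expect_identical(p1$alleles, p2$alleles)
  expect_identical(p1$sites, p2$sites)

  for (s in 1:5) {
    p <- generate_panel(10, 200, ld_strength = runif(1), seed = s)
    ac <- colSums(p$alleles)
    expect_true(all(ac >= 1 & ac <= 9))
    expect_equal(p$af, colMeans(p$alleles), tolerance = 1e-12)
  }

  expect_error(generate_panel(3, 10), "even")
  expect_error(generate_panel(5, 10), "even")
  expect_error(generate_panel(4, 1), ">= 2")
})

test_that("neutral SFS mass at low frequency matches the 1/i spectrum", {
  n_hap <- 100
  n_sites <- 5000
  p <- generate_panel(n_hap, n_sites, sfs_shape = "neutral",
                      ld_strength = 0, seed = 11)
  expected <- oracle_neutral_sfs_mass_below(n_hap, k_max = 5) # AF < 0.05
  observed <- mean(p$af < 0.05)
  se <- sqrt(expected * (1 - expected) / n_sites)
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("higher ld_strength gives higher adjacent-site haplotype correlation", {
  adj_cor <- function(ld, seed) {
    p <- generate_panel(40, 800, ld_strength = ld, seed = seed)
    a <- p$alleles
    mean(vapply(seq_len(ncol(a) - 1L), function(j) {
      r <- suppressWarnings(cor(a[, j], a[, j + 1L]))
      if (is.na(r)) 0 else abs(r)
    }, numeric(1)))
  }
  means <- vapply(c(0.1, 0.5, 0.9), function(ld) {
    mean(vapply(1:3, function(s) adj_cor(ld, 100 + s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("truth individuals are faithful panel mosaics", {
  p <- generate_panel(8, 100, seed = 3)

  # no recombination, no mutation: exact copies of the held-out rows
  ind <- simulate_individual(p, recomb_rate = 0, mutation_rate = 0, seed = 4)
  for (h in 1:2) {
    expect_identical(ind$haplotypes[h, ], p$alleles[ind$hap_indices[h], ])
    expect_true(all(ind$mosaic_paths[h, ] == ind$hap_indices[h]))
  }
  expect_identical(ind$genotypes, as.integer(colSums(ind$haplotypes)))

  # copy fidelity: without mutation every allele equals its mosaic source
  ind2 <- simulate_individual(p, recomb_rate = 0.3, mutation_rate = 0, seed = 5)
  for (h in 1:2) {
    src <- p$alleles[cbind(ind2$mosaic_paths[h, ], seq_len(100))]
    expect_identical(ind2$haplotypes[h, ], src)
  }

  expect_error(simulate_individual(p, recomb_rate = 1), "recomb_rate")
  expect_error(simulate_individual(p, mutation_rate = -0.1), "mutation_rate")
})

test_that("recombination switch count matches its binomial distribution", {
  # a switch re-draws the source uniformly, so the path value changes with
  # probability recomb_rate * (1 - 1/n_hap) per interval
  n_hap <- 4
  m <- 10001
  p <- generate_panel(n_hap, m, ld_strength = 0, seed = 6)
  ind <- simulate_individual(p, recomb_rate = 0.5, seed = 7)
  pr <- 0.5 * (1 - 1 / n_hap)
  for (h in 1:2) {
    changes <- sum(diff(ind$mosaic_paths[h, ]) != 0)
    se <- sqrt((m - 1) * pr * (1 - pr))
    expect_lt(abs(changes - (m - 1) * pr), 3 * se)
  }
})

test_that("pileup simulation is deterministic and conserves reads", {
  p <- generate_panel(8, 500, seed = 8)
  ind <- simulate_individual(p, seed = 9)
  cfg <- read_sim_config(1.2, dup_rate = 0.1, base_error = 0.01, seed = 10)
  s1 <- simulate_pileup(ind, p, cfg, keep_reads = TRUE)
  s2 <- simulate_pileup(ind, p, cfg, keep_reads = TRUE)
  expect_identical(s1$pileups, s2$pileups)

  # conservation: raw reads = unique reads + duplicates at every site
  reads <- attr(s1$pileups, "reads")
  uniq_per_site <- tabulate(reads$site, nbins = nrow(s1$pileups))
  expect_identical(uniq_per_site + s1$pileups$dup_count, s1$pileups$raw_depth)
  expect_identical(s1$raw_tally$total_reads, sum(s1$pileups$raw_depth))
  expect_identical(s1$raw_tally$dup_reads, sum(s1$pileups$dup_count))

  # filtered counts never exceed unique reads
  with(s1$pileups, expect_true(all(ref_count + alt_count + other_count <=
                                     raw_depth - dup_count)))
})

test_that("dup_rate = 0 flags nothing and hom-ref sites stay alt-free without errors", {
  p <- generate_panel(6, 400, seed = 12)
  ind <- simulate_individual(p, seed = 13)
  sim <- simulate_pileup(ind, p, read_sim_config(2, dup_rate = 0,
                                                 base_error = 0, seed = 14))
  expect_true(all(sim$pileups$dup_count == 0L))
  expect_identical(sim$raw_tally$dup_reads, 0L)
  homref <- ind$genotypes == 0L
  expect_true(all(sim$pileups$alt_count[homref] == 0L))
  homalt <- ind$genotypes == 2L
  expect_true(all(sim$pileups$ref_count[homalt] == 0L))
})

test_that("unique reads are Poisson-thinned at rate (1 - dup_rate)", {
  p <- generate_panel(4, 100000, ld_strength = 0, seed = 15)
  ind <- simulate_individual(p, seed = 16)
  lam <- 1.0
  d <- 0.2
  sim <- simulate_pileup(ind, p, read_sim_config(lam, dup_rate = d, seed = 17))
  uniq <- sim$pileups$raw_depth - sim$pileups$dup_count
  target <- lam * (1 - d)
  expect_lt(abs(mean(uniq) - target), 3 * sqrt(target / length(uniq)))
  # variance should also match Poisson
  expect_lt(abs(var(uniq) - target), 0.02)

  # fraction of sites with >= 1 raw read vs the Poisson void probability
  covered <- mean(sim$pileups$raw_depth > 0)
  pcov <- 1 - exp(-lam)
  expect_lt(abs(covered - pcov), 3 * sqrt(pcov * (1 - pcov) / 100000))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(read_sim_config(0), "nominal_coverage")
  expect_error(read_sim_config(1, dup_rate = 1), "dup_rate")
  expect_error(read_sim_config(1, base_error = 0.5), "base_error")
  expect_error(read_sim_config(1, overdispersion = -1), "overdispersion")
  expect_error(read_sim_config(1, bq_distribution = c(a = 1)), "Phred")
})

test_that("overdispersion lowers the covered fraction at fixed mean coverage", {
  p <- generate_panel(4, 50000, ld_strength = 0, seed = 18)
  ind <- simulate_individual(p, seed = 19)
  f <- vapply(c(0, 1, 4), function(od) {
    sim <- simulate_pileup(ind, p, read_sim_config(1, overdispersion = od,
                                                   seed = 20))
    fraction_covered(sim$pileups)
  }, numeric(1))
  expect_true(all(diff(f) < 0))
})
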