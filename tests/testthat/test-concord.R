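# Non-reference concordance, overall and by allele-frequency bin.

test_that("NRC drops both-hom-ref sites from the denominator", {
  r <- nrc(c(1L, 2L, 0L), c(1L, 2L, 0L))
  expect_equal(r$n_intersect, 3L)
  expect_equal(r$n_both_homref, 1L)
  expect_equal(r$n_denom, 2L)
  expect_equal(r$nrc, 1.0)

  # truth hom-ref but imputed non-ref stays in the denominator
  r2 <- nrc(c(1L, 1L, 1L, 0L), c(0L, 1L, 2L, 0L))
  expect_equal(r2$n_denom, 3L)
  expect_equal(r2$nrc, 1 / 3)

  # all both-hom-ref: undefined, flagged, not zero
  r3 <- nrc(c(0L, 0L), c(0L, 0L))
  expect_true(r3$undefined)
  expect_true(is.na(r3$nrc))
  expect_equal(r3$n_both_homref, r3$n_intersect)

  # NA calls leave the intersection
  r4 <- nrc(c(1L, NA, 2L), c(1L, 1L, NA))
  expect_equal(r4$n_intersect, 1L)
  expect_equal(r4$nrc, 1.0)

  expect_error(nrc(c(1L, 3L), c(0L, 0L)), "\\{0, 1, 2\\}")
  expect_error(nrc(1L, c(0L, 1L)), "aligned")
})

test_that("optimized NRC equals the definition-level oracle", {
  set.seed(50)
  for (i in 1:60) {
    n <- sample(1:30, 1)
    imputed <- sample(c(0:2, NA), n, replace = TRUE)
    truth <- sample(c(0:2, NA), n, replace = TRUE)
    got <- nrc(imputed, truth)
    want <- oracle_nrc(imputed, truth)
    expect_equal(got$n_intersect, want$n_intersect)
    expect_equal(got$n_both_homref, want$n_both_homref)
    expect_equal(got$n_match_nonref, want$n_match_nonref)
    expect_equal(got$nrc, want$nrc)
  }
})

test_that("the NRC denominator rule is symmetric in the two call sets", {
  set.seed(51)
  for (i in 1:20) {
    a <- sample(c(0:2, NA), 40, replace = TRUE)
    b <- sample(c(0:2, NA), 40, replace = TRUE)
    ra <- nrc(a, b)
    rb <- nrc(b, a)
    expect_equal(ra$n_denom, rb$n_denom)
    expect_equal(ra$nrc, rb$nrc)
  }
})

test_that("NRC is 1 exactly when all denominator sites match", {
  mism <- c(1L, 2L, 0L, 1L)
  r <- nrc(mism, c(1L, 2L, 0L, 2L))
  expect_lt(r$nrc, 1)
  r2 <- nrc(mism, mism)
  expect_equal(r2$nrc, 1)
})

test_that("a single all-spanning bin reproduces the overall NRC", {
  set.seed(52)
  n <- 200
  imputed <- sample(0:2, n, replace = TRUE, prob = c(0.7, 0.2, 0.1))
  truth <- sample(0:2, n, replace = TRUE, prob = c(0.7, 0.2, 0.1))
  af <- runif(n, 0.01, 0.99)
  rep1 <- nrc_by_af_bin(imputed, truth, af, bin_edges = c(0, 0.5))
  expect_equal(rep1$per_bin$nrc, rep1$nrc)
  expect_equal(rep1$per_bin$n_sites, rep1$n_intersect)
})

test_that("per-bin NRC matches hand computation on a six-site example", {
  # folded MAFs: 0.01, 0.02 in bin [0, 0.05); 0.2, 0.3(=0.7), 0.4, 0.5 in
  # [0.05, 0.5]
  af <- c(0.01, 0.02, 0.2, 0.7, 0.4, 0.5)
  truth <- c(1L, 0L, 2L, 1L, 0L, 0L)
  imputed <- c(1L, 0L, 1L, 1L, 0L, 2L)
  r <- nrc_by_af_bin(imputed, truth, af, bin_edges = c(0, 0.05, 0.5))
  # bin 1: sites 1-2; site 2 both-hom-ref; 1 match / 1 -> 1
  expect_equal(r$per_bin$n_denom[1], 1L)
  expect_equal(r$per_bin$nrc[1], 1)
  # bin 2: sites 3-6; site 5 both-hom-ref; matches: site 4 only -> 1/3
  expect_equal(r$per_bin$n_denom[2], 3L)
  expect_equal(r$per_bin$nrc[2], 1 / 3)
  # pooling: per-bin matches sum to the overall numerator
  expect_equal(sum(r$per_bin$n_denom), r$n_denom)
  expect_equal(r$nrc, 2 / 4)
})

test_that("empty bins are reported with n = 0 and undefined NRC", {
  af <- c(0.01, 0.02)
  r <- nrc_by_af_bin(c(1L, 1L), c(1L, 0L), af, bin_edges = c(0, 0.05, 0.5))
  expect_equal(r$per_bin$n_sites[2], 0L)
  expect_true(is.na(r$per_bin$nrc[2]))

  expect_error(nrc_by_af_bin(c(1L, 1L), c(1L, 0L), af,
                             bin_edges = c(0.5, 0.05)), "increasing")
  expect_error(nrc_by_af_bin(c(1L, 1L), c(1L, 0L), af,
                             bin_edges = c(0.015, 0.5)), "outside")
})

test_that("unfolded binning uses the raw alternate frequency", {
  af <- c(0.7, 0.2)
  r <- nrc_by_af_bin(c(1L, 1L), c(1L, 1L), af, bin_edges = c(0, 0.5, 1),
                     fold_af = FALSE)
  expect_equal(r$per_bin$n_sites, c(1L, 1L))
  # folded, both sites land in the low bin
  rf <- nrc_by_af_bin(c(1L, 1L), c(1L, 1L), af, bin_edges = c(0, 0.5, 1))
  expect_equal(rf$per_bin$n_sites, c(2L, 0L))
})

test_that("panel diversity and LD shape accuracy across the frequency spectrum", {
  # high-diversity panels (weak LD, many rare variants) should help at rare
  # sites relative to high-LD panels, and vice versa at common sites
  run_regime <- function(ld, seed) {
    p <- generate_panel(40, 1200, ld_strength = ld, seed = seed)
    ind <- simulate_individual(p, recomb_rate = 0.001, seed = seed + 1L)
    sim <- simulate_pileup(ind, p, read_sim_config(1.0, base_error = 0.002,
                                                   seed = seed + 2L))
    gl <- genotype_likelihoods(sim$pileups$ref_count, sim$pileups$alt_count,
                               0.002)
    gp <- impute_sample(gl, p, held_out = ind$hap_indices)
    flt <- filter_posteriors(gp)
    r <- nrc_by_af_bin(flt$calls, ind$genotypes, p$af,
                       bin_edges = c(0, 0.1, 0.5))
    r$per_bin$nrc
  }
  set.seed(53)
  seeds <- sample.int(1e6, 10)
  lo_ld <- t(vapply(seeds, function(s) run_regime(0.5, s), numeric(2)))
  hi_ld <- t(vapply(seeds + 1L, function(s) run_regime(0.97, s), numeric(2)))
  # rank test over replicates: common-variant bin favors the high-LD panel
  expect_gt(mean(hi_ld[, 2], na.rm = TRUE), mean(lo_ld[, 2], na.rm = TRUE))
})
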