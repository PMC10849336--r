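# lpimpute

Evaluation toolkit for **low-pass whole-genome sequencing plus genotype
imputation**. Low-pass designs sequence individuals at well under 1–2× mean
depth and recover genotypes by imputing against a phased haplotype
reference panel; their performance hinges on how much *usable* coverage a
library delivers and how accurate the imputed genotypes are. `lpimpute`
implements that evaluation end-to-end, for methodologists and
sequencing-platform evaluators:

* **Effective coverage.** With `f_covered` the fraction of panel sites
  covered by ≥ 1 deduplicated read of base quality ≥ 13,

  λ<sub>eff</sub> = −ln(1 − f<sub>covered</sub>),

  the Poisson rate that reproduces the observed uncovered fraction. The
  ratio λ<sub>eff</sub>/λ<sub>nominal</sub> measures coverage evenness;
  under iid duplication at rate *d* it equals 1 − *d*.
* **Imputation.** Binomial genotype likelihoods from ref/alt pileup counts,
  then exact genotype posteriors under a diploid **Li–Stephens
  haplotype-copying HMM** over the panel with the sample's own two
  haplotypes removed (leave-one-out), by forward–backward over ordered
  haplotype pairs. Calls with max posterior ≤ 0.9 are flagged `LOWCONF`
  and filtered.
* **Non-reference concordance (NRC).** Genotype concordance on the
  intersection of called sites, excluding sites where both call sets are
  homozygous reference; reported overall and stratified by (minor) allele
  frequency bin.
* **Group comparison.** Welch's unequal-variance t-test between two arms,
  plus a driver (`run_experiment()`) that runs a full paired two-arm
  synthetic study in which the arms differ only in duplication rate.
* **Synthetic data.** A haplotype-panel generator (neutral site-frequency
  spectrum, tunable LD), recombinant-mosaic truth individuals, and a pileup
  simulator with tunable coverage, overdispersion, duplication rate and
  base errors — so everything above is testable with no downloads.
* **Formats.** samtools-mpileup text (read), a lossless pileup TSV dialect
  (read/write), VCF 4.2 with GT/GP and `LOWCONF` filters (read via vcfR,
  write), BED-derived site lists.

## Worked example

Simulate one sample at 0.8× nominal coverage with a 5.5% duplication rate,
then impute it leave-one-out against its 40-haplotype panel:

```r
library(lpimpute)

panel <- generate_panel(n_haplotypes = 40, n_sites = 2000, seed = 7)
ind   <- simulate_individual(panel, recomb_rate = 0.001, seed = 8)
cfg   <- read_sim_config(nominal_coverage = 0.8, dup_rate = 0.055,
                         base_error = 0.002, seed = 9)
sim   <- simulate_pileup(ind, panel, cfg)

summarize_coverage(sim$pileups, sim$raw_tally)
#> Coverage summary (simulation mode):
#>   nominal coverage      0.7790
#>   fraction covered      0.5270
#>   effective coverage    0.7487
#>   effective/nominal     0.9611
#>   duplication rate      5.0064%
```

The realized duplication rate (5.0%) drags the effective/nominal ratio
below 1 (0.961 here; ≈ 1 − d up to site-sampling noise): duplicates are
redundant, so they buy no new covered sites. Imputing and scoring:

```r
gl  <- genotype_likelihoods(sim$pileups$ref_count, sim$pileups$alt_count, 0.002)
gp  <- impute_sample(gl, panel, held_out = ind$hap_indices)
flt <- filter_posteriors(gp)          # strict "> 0.9" confidence rule
nrc_by_af_bin(flt$calls, ind$genotypes, panel$af)
#> Non-reference concordance
#>   intersecting sites       1664
#>   both hom-ref (dropped)   1103
#>   NRC                      466 / 561 = 0.8307
#>   by allele-frequency bin:
#>  af_lo af_hi n_sites n_denom       nrc
#>  0.010 0.050     453      37 0.6486486
#>  0.050 0.100     414      91 0.8241758
#>  0.100 0.200     323     101 0.8415842
#>  0.200 0.500     474     332 0.8493976
```

336 of 2,000 sites were filtered as low confidence; on the rest, NRC is
0.83 overall and rises with allele frequency — rare variants are the hard
case for imputation, especially against a small panel.

The full two-arm study (20 paired samples per arm, duplication rates
0.27% vs 5.5% at 1× coverage) is one call:

```r
ex <- run_experiment(n_samples_per_arm = 20, dup_rates = c(0.0027, 0.055),
                     nominal_coverage = 1.0, seed = 1)
print(ex)
```

It reports per-arm duplication rate, effective/nominal ratio and NRC
summaries, Welch tests between arms, and an NRC-by-allele-frequency table.

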