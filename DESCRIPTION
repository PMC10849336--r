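Package: lpimpute
Title: Evaluation of Low-Pass Sequencing Plus Genotype Imputation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate low-pass whole-genome sequencing followed by
    genotype imputation against a haplotype reference panel. Implements
    effective-coverage computation from panel-site pileups (lambda_eff =
    -ln(1 - f_covered)), leave-one-out genotype imputation with a diploid
    Li-Stephens haplotype-copying hidden Markov model, non-reference
    concordance (overall and stratified by allele frequency), Welch's t-test
    group comparisons, and a synthetic-data generator (haplotype panels with
    a configurable site-frequency spectrum and linkage disequilibrium,
    recombinant truth individuals, and pileup simulation with tunable
    duplication rate, overdispersion and base errors) so that the whole
    pipeline can be exercised end-to-end without external data. Readers and
    writers are provided for samtools-mpileup text, a pileup TSV dialect and
    VCF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
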