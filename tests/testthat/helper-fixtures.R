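# Small in-code fixtures shared across test files.

make_pileup_df <- function(n, ref_count = 0L, alt_count = 0L,
                           other_count = 0L, raw_depth = NULL,
                           dup_count = 0L) {
  out <- data.frame(
    chrom = rep("1", n), pos = seq_len(n) * 10L,
    ref = rep("A", n), alt = rep("G", n),
    ref_count = rep_len(ref_count, n),
    alt_count = rep_len(alt_count, n),
    other_count = rep_len(other_count, n),
    dup_count = rep_len(dup_count, n),
    stringsAsFactors = FALSE
  )
  out$raw_depth <- if (is.null(raw_depth)) {
    out$ref_count + out$alt_count + out$other_count + out$dup_count
  } else {
    rep_len(raw_depth, n)
  }
  class(out) <- c("site_pileup", "data.frame")
  out
}

# fully simulated sample at given settings: panel, individual, pileups
simulate_sample <- function(coverage, n_hap = 40, n_sites = 2000,
                            dup_rate = 0, base_error = 0.002,
                            ld_strength = 0.9, recomb_rate = 0.001,
                            seed = 1, ...) {
  panel <- generate_panel(n_hap, n_sites, ld_strength = ld_strength,
                          seed = seed)
  ind <- simulate_individual(panel, recomb_rate = recomb_rate,
                             seed = seed + 1L)
  cfg <- read_sim_config(coverage, dup_rate = dup_rate,
                         base_error = base_error, seed = seed + 2L, ...)
  sim <- simulate_pileup(ind, panel, cfg)
  list(panel = panel, ind = ind, sim = sim)
}
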