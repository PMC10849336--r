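# Leave-one-out genotype imputation: binomial genotype likelihoods from
# pileup counts and an exact diploid Li-Stephens haplotype-copying HMM.

#' Genotype likelihoods from ref/alt read counts
#'
#' Standard low-pass read-data likelihoods at a biallelic site with symmetric
#' per-base miscall probability `base_error` = e: for r reference and a
#' alternate reads,
#' `L(hom-ref) = (1-e)^r * e^a`, `L(het) = 0.5^(r+a)`,
#' `L(hom-alt) = e^r * (1-e)^a`
#' (the shared binomial coefficient cancels on normalization and is omitted).
#' At zero depth all three likelihoods are 1 (uninformative).
#'
#' @param ref_count,alt_count Non-negative integer vectors (recycled to a
#'   common length), filtered unique-read counts per site.
#' @param base_error Miscall probability in \[0, 0.5).
#' @return A numeric matrix with one row per site and columns
#'   `hom_ref`, `het`, `hom_alt`.
#' @examples
#' genotype_likelihoods(2, 0, 0.01)
#' @export
genotype_likelihoods <- function(ref_count, alt_count, base_error = 0.002) {
  if (any(ref_count < 0) || any(alt_count < 0)) stop("read counts must be >= 0")
  if (base_error < 0 || base_error >= 0.5) stop("`base_error` must be in [0, 0.5)")
  n <- max(length(ref_count), length(alt_count))
  r <- rep_len(as.numeric(ref_count), n)
  a <- rep_len(as.numeric(alt_count), n)
  gl <- cbind(
    hom_ref = (1 - base_error)^r * base_error^a,
    het = 0.5^(r + a),
    hom_alt = base_error^r * (1 - base_error)^a
  )
  gl
}

#' Li-Stephens HMM parameters
#'
#' @param recomb_scale Expected per-unit-genetic-distance switch probability
#'   of each haplotype-copying process, in (0, 1). The per-interval switch
#'   probability is `recomb_scale * genetic_dist` for that interval.
#' @param copy_error Probability that the copied panel allele mismatches the
#'   emitted haplotype allele, in (0, 1).
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(recomb_scale = 0.001, copy_error = 0.001) {
  if (recomb_scale <= 0 || recomb_scale >= 1) stop("`recomb_scale` must be in (0, 1)")
  if (copy_error <= 0 || copy_error >= 1) stop("`copy_error` must be in (0, 1)")
  structure(list(recomb_scale = recomb_scale, copy_error = copy_error),
            class = "hmm_params")
}

# Emission weights P(g | copied alt-allele count s, copy_error) for
# s in {0, 1, 2}, g in {0, 1, 2}: two independent allele-flip channels.
# Returns a 3 x 3 matrix [s + 1, g + 1].
emission_by_pair_sum <- function(copy_error) {
  th <- copy_error
  out <- matrix(0, 3, 3)
  for (s in 0:2) {
    # P(emitted allele = 1) for each copying process given copied alleles
    p1 <- if (s == 0) th else 1 - th     # s >= 1: first process copied 1
    p2 <- if (s == 2) 1 - th else th     # s == 2: second process copied 1
    out[s + 1, ] <- c((1 - p1) * (1 - p2),
                      p1 * (1 - p2) + (1 - p1) * p2,
                      p1 * p2)
  }
  out
}

# One step of the factorized pair transition: each copying process
# independently switches with probability rho to a uniform haplotype.
# For an H x H mass matrix F this is A F A^T with A = (1-rho) I + (rho/H) J,
# computed in O(H^2) via row/column sums.
pair_transition <- function(f, rho) {
  h <- nrow(f)
  q <- rho / h
  g <- (1 - rho) * f + matrix(q * colSums(f), h, h, byrow = TRUE)
  (1 - rho) * g + q * rowSums(g)
}

#' Impute genotype posteriors with a diploid Li-Stephens HMM
#'
#' Computes, by forward-backward, the exact per-site genotype posteriors
#' under the diploid Li-Stephens haplotype-copying model over the reference
#' panel with the sample's own two haplotypes removed (leave-one-out). The
#' hidden state is an ordered pair of panel haplotypes; per interval each of
#' the two copying processes independently switches, with probability
#' `recomb_scale * genetic_dist`, to a haplotype chosen uniformly from the
#' reduced panel. At a site the copied allele pair emits a true genotype
#' through two independent allele-flip channels with rate `copy_error`, and
#' the genotype emits the read data through the supplied likelihoods. The
#' recursion is numerically stabilized by per-site scaling.
#'
#' @param likelihoods Numeric matrix of per-site genotype likelihoods
#'   (columns hom-ref, het, hom-alt), e.g. from [genotype_likelihoods()].
#'   Rows may be arbitrarily rescaled; posteriors are invariant.
#' @param panel A `haplotype_panel`.
#' @param held_out `NULL`, or the two panel haplotype row indices to exclude
#'   (the sample's own haplotypes, `truth_individual$hap_indices`).
#' @param params An [hmm_params()] object.
#' @return An object of class `genotype_posteriors`: list with `posterior`
#'   (n_sites x 3 matrix, rows summing to 1), `call` (argmax genotype in
#'   0:2; ties broken toward the smaller genotype), `max_posterior`, and
#'   `low_confidence` (`TRUE` where the maximum posterior is <= 0.9).
#' @examples
#' p <- generate_panel(8, 30, seed = 1)
#' ind <- simulate_individual(p, seed = 2)
#' sim <- simulate_pileup(ind, p, read_sim_config(1.0, seed = 3))
#' gl <- genotype_likelihoods(sim$pileups$ref_count, sim$pileups$alt_count)
#' gp <- impute_sample(gl, p, held_out = ind$hap_indices)
#' mean(gp$call == ind$genotypes)
#' @export
impute_sample <- function(likelihoods, panel, held_out = NULL,
                          params = hmm_params()) {
  stopifnot(inherits(params, "hmm_params"),
            is.matrix(panel$alleles), all(panel$alleles %in% c(0L, 1L)))
  m <- nrow(likelihoods)
  if (m != ncol(panel$alleles)) stop("likelihoods / panel site lists misaligned")
  if (!is.null(held_out)) {
    if (length(held_out) != 2L || any(held_out < 1) ||
        any(held_out > nrow(panel$alleles))) {
      stop("`held_out` must be two valid haplotype row indices")
    }
    alleles <- panel$alleles[-held_out, , drop = FALSE]
  } else {
    alleles <- panel$alleles
  }
  h <- nrow(alleles)
  if (h < 2L) stop("reduced panel must retain at least 2 haplotypes")

  # guard against underflow at high depth: posteriors are scale-invariant
  gl <- likelihoods / pmax(apply(likelihoods, 1, max), .Machine$double.xmin)
  rho <- pmin(params$recomb_scale * panel$genetic_dist, 1)
  eg <- emission_by_pair_sum(params$copy_error)    # [s+1, g+1]
  # per-site emission value for pair-sum s: e[j, s+1] = sum_g eg[s+1, g+1] gl[j, g+1]
  esite <- gl %*% t(eg)                            # m x 3

  pair_sum <- function(j) outer(alleles[, j], alleles[, j], "+") + 1L

  # forward with per-site scaling; keep scaled forward matrices
  fwd <- vector("list", m)
  f <- matrix(1 / (h * h), h, h) * matrix(esite[1L, pair_sum(1L)], h, h)
  s1 <- sum(f)
  if (!is.finite(s1) || s1 <= 0) stop("non-finite forward mass at site 1")
  fwd[[1L]] <- f / s1
  if (m > 1L) {
    for (t in 2:m) {
      f <- pair_transition(fwd[[t - 1L]], rho[t - 1L]) *
        matrix(esite[t, pair_sum(t)], h, h)
      st <- sum(f)
      if (!is.finite(st) || st <= 0) {
        stop("non-finite forward mass at site ", t,
             " (check likelihoods and panel)")
      }
      fwd[[t]] <- f / st
    }
  }

  # backward pass, accumulating genotype posteriors site by site
  post <- matrix(NA_real_, m, 3L,
                 dimnames = list(NULL, c("hom_ref", "het", "hom_alt")))
  b <- matrix(1, h, h)
  for (t in m:1) {
    ps <- pair_sum(t)
    w_state <- fwd[[t]] * b
    w_state <- w_state / sum(w_state)
    # mass on each copied pair-sum class s
    w_s <- vapply(1:3, function(s) sum(w_state[ps == s]), numeric(1))
    # split each class's mass over genotypes: P(g | s, data_t)
    gsplit <- eg * rep(gl[t, ], each = 3L)         # [s+1, g+1]
    gsplit <- gsplit / rowSums(gsplit)
    post[t, ] <- as.vector(w_s %*% gsplit)
    if (t > 1L) {
      b <- pair_transition(b * matrix(esite[t, ps], h, h), rho[t - 1L])
      b <- b / sum(b)
    }
  }

  calls <- max.col(post, ties.method = "first") - 1L  # prefers smaller genotype
  maxp <- post[cbind(seq_len(m), calls + 1L)]
  structure(
    list(
      posterior = post,
      call = calls,
      max_posterior = maxp,
      low_confidence = maxp <= 0.9,
      n_haplotypes_used = h,
      params = params
    ),
    class = "genotype_posteriors"
  )
}

#' @export
print.genotype_posteriors <- function(x, ...) {
  cat("Genotype posteriors over", length(x$call), "sites (panel of",
      x$n_haplotypes_used, "haplotypes)\n")
  cat(sprintf("  low-confidence (max GP <= 0.9): %d sites (%.1f%%)\n",
              sum(x$low_confidence), 100 * mean(x$low_confidence)))
  invisible(x)
}

#' Apply the posterior-confidence filter to imputed calls
#'
#' Sites where none of the three genotype posteriors exceeds the threshold
#' (strictly: max posterior `<= threshold`) are marked low confidence and
#' removed from the call set before concordance comparisons.
#'
#' @param posteriors A `genotype_posteriors` object from [impute_sample()].
#' @param threshold Confidence threshold (default 0.9).
#' @return A list with `calls` (integer vector in 0:2 with `NA` at removed
#'   sites), `retained` (logical), and `n_removed`.
#' @examples
#' p <- matrix(c(0.95, 0.04, 0.01, 0.3, 0.4, 0.3), 2, 3, byrow = TRUE)
#' gp <- structure(list(posterior = p, call = c(0L, 1L),
#'                      max_posterior = c(0.95, 0.4)),
#'                 class = "genotype_posteriors")
#' filter_posteriors(gp)$n_removed
#' @export
filter_posteriors <- function(posteriors, threshold = 0.9) {
  stopifnot(inherits(posteriors, "genotype_posteriors"))
  maxp <- apply(posteriors$posterior, 1, max)
  retained <- maxp > threshold
  calls <- posteriors$call
  calls[!retained] <- NA_integer_
  list(calls = calls, retained = retained, n_removed = sum(!retained))
}
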