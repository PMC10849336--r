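# Independent oracles used by the test suite. These deliberately avoid the
# package's forward-backward / vectorized code paths: the HMM oracle sums
# over every hidden state path explicitly, the NRC oracle walks sites one by
# one, and the Welch oracle evaluates the closed formulas directly.

# Exhaustive diploid Li-Stephens genotype posteriors by full path
# enumeration. alleles: H x M 0/1 matrix (already reduced); gl: M x 3
# likelihoods; rho: per-interval switch probability; theta: copy error.
# Returns an M x 3 genotype posterior matrix.
oracle_hmm_posteriors <- function(alleles, gl, rho, theta) {
  h <- nrow(alleles)
  m <- ncol(alleles)
  n_state <- h * h                       # ordered pair (i, j) = (k-1)%%h+1, (k-1)%/%h+1
  i_of <- (seq_len(n_state) - 1L) %% h + 1L
  j_of <- (seq_len(n_state) - 1L) %/% h + 1L

  # single-process transition matrix from the model definition
  trans_one <- function(r) {
    tm <- matrix(r / h, h, h)
    diag(tm) <- diag(tm) + (1 - r)
    tm
  }

  # genotype emission P(g | state) and data emission e(state) per site
  p_alt <- function(a) a * (1 - theta) + (1 - a) * theta
  pg_site <- function(t) {
    p1 <- p_alt(alleles[i_of, t])
    p2 <- p_alt(alleles[j_of, t])
    cbind((1 - p1) * (1 - p2), p1 * (1 - p2) + (1 - p1) * p2, p1 * p2)
  }

  # enumerate all state paths
  paths <- as.matrix(expand.grid(rep(list(seq_len(n_state)), m)))
  w <- rep(1 / n_state, nrow(paths))
  e_site <- vector("list", m)
  for (t in seq_len(m)) {
    pg <- pg_site(t)
    e_site[[t]] <- as.vector(pg %*% gl[t, ])
    w <- w * e_site[[t]][paths[, t]]
    if (t < m) {
      tm <- trans_one(rho[t])
      s_from <- paths[, t]
      s_to <- paths[, t + 1L]
      w <- w * tm[cbind(i_of[s_from], i_of[s_to])] *
        tm[cbind(j_of[s_from], j_of[s_to])]
    }
  }
  w <- w / sum(w)

  post <- matrix(0, m, 3L)
  for (t in seq_len(m)) {
    pg <- pg_site(t)
    # joint over (path, g): reweight each path's site-t emission by genotype
    gterm <- pg * rep(gl[t, ], each = n_state)      # n_state x 3
    frac <- gterm / rowSums(gterm)
    for (g in 1:3) post[t, g] <- sum(w * frac[paths[, t], g])
  }
  post
}

# Definition-level NRC: walk the two call sets site by site.
oracle_nrc <- function(imputed, truth) {
  n_int <- 0L; n_bhr <- 0L; n_match <- 0L
  for (k in seq_along(imputed)) {
    if (is.na(imputed[k]) || is.na(truth[k])) next
    n_int <- n_int + 1L
    if (imputed[k] == 0L && truth[k] == 0L) {
      n_bhr <- n_bhr + 1L
    } else if (imputed[k] == truth[k]) {
      n_match <- n_match + 1L
    }
  }
  denom <- n_int - n_bhr
  list(n_intersect = n_int, n_both_homref = n_bhr, n_match_nonref = n_match,
       nrc = if (denom > 0) n_match / denom else NA_real_)
}

# Closed-form Welch statistic, Welch-Satterthwaite dof, two-sided p.
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  dof <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t_stat), df = dof)
  list(t = t_stat, dof = dof, p = p)
}

# Normalized neutral-SFS mass of sites with derived count below `k_max`
# out of n haplotypes (P(count = i) proportional to 1/i, i in 1..n-1).
oracle_neutral_sfs_mass_below <- function(n_haplotypes, k_max) {
  i <- seq_len(n_haplotypes - 1L)
  sum(1 / i[i < k_max]) / sum(1 / i)
}

# Small random pileup/panel instance helpers -------------------------------

random_hmm_instance <- function(seed) {
  set.seed(seed)
  h <- sample(2:5, 1)
  m <- sample(2:4, 1)
  alleles <- matrix(sample(0:1, h * m, replace = TRUE), h, m)
  # guard against an all-constant column set being degenerate is fine;
  # the model handles any 0/1 matrix
  gl <- matrix(stats::runif(m * 3, min = 0.05, max = 1), m, 3)
  rho <- stats::runif(m - 1, 0.01, 0.5)
  theta <- stats::runif(1, 0.001, 0.2)
  list(alleles = alleles, gl = gl, rho = rho, theta = theta)
}

# wrap an allele matrix as a haplotype_panel for impute_sample(); pass
# genetic_dist so that recomb_scale * genetic_dist gives the wanted
# per-interval switch probability.
panel_from_alleles <- function(alleles, genetic_dist = NULL) {
  m <- ncol(alleles)
  sites <- data.frame(
    chrom = "1", pos = seq_len(m) * 100L,
    ref = rep("A", m), alt = rep("G", m), stringsAsFactors = FALSE
  )
  structure(
    list(sites = sites, alleles = alleles, af = colMeans(alleles),
         genetic_dist = if (is.null(genetic_dist)) rep(1, m - 1) else genetic_dist),
    class = "haplotype_panel"
  )
}
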