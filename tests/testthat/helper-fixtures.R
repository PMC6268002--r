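# Shared fixtures built in code at test time.

# summary_stats from a plain z-vector under the standardized convention
stats_from_z <- function(z, n = 1e5, ids = sprintf("snp%03d", seq_along(z)),
                         freq = 0.3) {
  summary_stats(id = ids, effect_allele = "A", other_allele = "G",
                freq = freq, beta = z / sqrt(n),
                se = rep(1 / sqrt(n), length(z)), n = n)
}

# one simulated locus with a single planted causal SNP
planted_locus <- function(m = 12, causal = 6, lambda = 6, rho = 0.9,
                          n_hap = 400, seed = 1L, n = 1e5) {
  panel <- sim_haplotypes(n_hap, m, rho = rho, maf_range = c(0.1, 0.5),
                          seed = seed)
  ld <- ld_from_haplotypes(panel)
  z <- sim_gwas_z(ld, causal_config(m, causal, lambda), seed = seed + 5000L)
  list(locus = locus(stats_from_z(z, n = n, ids = panel$variant_ids,
                                  freq = panel$allele_freqs), ld),
       panel = panel, ld = ld, z = z, causal = causal)
}

# brute-force MVN log-density oracle, independent of the Cholesky path
logdmvn_oracle <- function(x, mu, S) {
  m <- length(x)
  Si <- solve(S)
  d <- x - mu
  -0.5 * (m * log(2 * pi) +
            as.numeric(determinant(S, logarithm = TRUE)$modulus) +
            drop(t(d) %*% Si %*% d))
}

# a small asymmetric test PWM (L = 4) with no zero counts
toy_pwm <- function(pseudocount = 0.8, background = rep(0.25, 4)) {
  counts <- matrix(c(8, 1, 1, 2,
                     1, 7, 2, 1,
                     2, 2, 6, 1,
                     1, 2, 3, 8),
                   nrow = 4, byrow = TRUE,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm(counts, background = background, pseudocount = pseudocount)
}

# enumerate all 4^L sequences of length L
all_kmers <- function(L) {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(rep(list(bases), L), stringsAsFactors = FALSE)
  apply(grid[, rev(seq_len(L)), drop = FALSE], 1, paste, collapse = "")
}
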