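# Synthetic-data generators: haplotype panels with tunable LD decay,
# multivariate-normal association z-scores, paired GWAS/eQTL scenarios,
# annotation matrices, qPCR mixing series and per-SNP marginal regression.
# Every generator takes an explicit integer seed; identical seed and
# parameters give bit-identical output.

#' Simulate a phased haplotype panel with Markov LD decay
#'
#' Haplotypes are generated by a first-order Markov copy process along the
#' chromosome: the first SNP is drawn at its target alternate-allele
#' frequency, and each subsequent SNP either copies the allele carried at
#' the previous SNP (with probability `rho`) or is redrawn independently at
#' its own target frequency. Adjacent-SNP allele correlation is therefore
#' approximately `rho` (exactly `rho` when target frequencies are equal),
#' and LD decays geometrically with SNP distance, emulating the haplotype
#' block structure of a phased reference panel at desk scale.
#'
#' @param n_hap number of haplotypes (rows), at least 2.
#' @param m_snp number of SNPs (columns), at least 1.
#' @param rho adjacent-site copy probability in `[0, 1)`; controls LD decay.
#' @param maf_range length-2 interval within `(0, 0.5]` from which target
#'   minor-allele frequencies are drawn uniformly.
#' @param seed integer seed; same seed and parameters give an identical panel.
#' @return an object of class `haplotype_panel`: a list with `alleles`
#'   (`n_hap x m_snp` 0/1 matrix), `variant_ids`, `positions` (strictly
#'   increasing 1-based bp) and `allele_freqs` (empirical column means).
#' @examples
#' panel <- sim_haplotypes(200, 10, rho = 0.9, seed = 1)
#' dim(panel$alleles)
#' @export
sim_haplotypes <- function(n_hap, m_snp, rho = 0.7,
                           maf_range = c(0.05, 0.5), seed = 1L) {
  stopifnot_scalar(n_hap, "n_hap", lo = 2)
  stopifnot_scalar(m_snp, "m_snp", lo = 1)
  stopifnot_scalar(rho, "rho", lo = 0, hi = 1 - 1e-12)
  if (!is.numeric(maf_range) || length(maf_range) != 2L ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("`maf_range` must be an interval within (0, 0.5]")
  }
  withr::with_seed(as.integer(seed), {
    target <- stats::runif(m_snp, maf_range[1], maf_range[2])
    positions <- cumsum(sample.int(2000L, m_snp, replace = TRUE))
    alleles <- matrix(0L, nrow = n_hap, ncol = m_snp)
    alleles[, 1] <- stats::rbinom(n_hap, 1L, target[1])
    if (m_snp > 1L) {
      for (j in 2:m_snp) {
        copy <- stats::runif(n_hap) < rho
        fresh <- stats::rbinom(n_hap, 1L, target[j])
        alleles[, j] <- ifelse(copy, alleles[, j - 1], fresh)
      }
    }
    ids <- sprintf("snp%03d", seq_len(m_snp))
    colnames(alleles) <- ids
    structure(
      list(alleles = alleles,
           variant_ids = ids,
           positions = as.integer(positions),
           allele_freqs = colMeans(alleles)),
      class = "haplotype_panel"
    )
  })
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d SNPs (alt freq %.3f-%.3f)\n",
              nrow(x$alleles), ncol(x$alleles),
              min(x$allele_freqs), max(x$allele_freqs)))
  invisible(x)
}

#' Causal configuration for a locus
#'
#' A binary causal-status vector with per-SNP non-centrality parameters:
#' the hypothesis object consumed by every fine-mapping engine. Under the
#' summary-statistic model, observed z-scores are distributed
#' `Z ~ N(Sigma (lambda * C), Sigma)` where `Sigma` is the LD matrix,
#' `C` the causal indicator and `lambda` the non-centrality at causal SNPs.
#'
#' @param m number of SNPs in the locus.
#' @param causal_idx indices of causal SNPs (possibly empty).
#' @param lambda non-centrality values, recycled across `causal_idx`.
#' @return object of class `causal_config` with fields `c` (0/1 vector),
#'   `k` (number of causal SNPs) and `lambda` (0 at non-causal SNPs).
#' @examples
#' causal_config(5, causal_idx = 2, lambda = 6)
#' @export
causal_config <- function(m, causal_idx = integer(0), lambda = numeric(0)) {
  stopifnot_scalar(m, "m", lo = 0)
  causal_idx <- as.integer(causal_idx)
  if (any(causal_idx < 1L | causal_idx > m)) {
    stop("`causal_idx` out of range 1..m")
  }
  if (anyDuplicated(causal_idx)) stop("duplicate causal indices")
  cvec <- integer(m)
  cvec[causal_idx] <- 1L
  lam <- numeric(m)
  if (length(causal_idx)) {
    lambda <- if (length(lambda)) as.numeric(lambda) else 0
    lam[causal_idx] <- rep_len(lambda, length(causal_idx))
  }
  structure(list(c = cvec, k = length(causal_idx), lambda = lam),
            class = "causal_config")
}

#' @export
print.causal_config <- function(x, ...) {
  cat(sprintf("causal_config: m=%d, k=%d, causal at {%s}\n",
              length(x$c), x$k, paste(which(x$c == 1L), collapse = ",")))
  invisible(x)
}

#' Draw association z-scores under the multivariate-normal locus model
#'
#' Samples one vector `Z ~ N(Sigma (lambda * C), Sigma)`: LD propagates the
#' non-centrality of causal SNPs to their neighbours through the matrix
#' product `Sigma (lambda * C)`.
#'
#' @param ld m x m LD correlation matrix.
#' @param config a [causal_config()].
#' @param seed integer seed.
#' @param n number of replicate draws; the default 1 returns a vector,
#'   larger values an `n x m` matrix.
#' @return numeric z-score vector of length m (or `n x m` matrix).
#' @examples
#' ld <- diag(3)
#' z <- sim_gwas_z(ld, causal_config(3, 1, 5), seed = 7)
#' @export
sim_gwas_z <- function(ld, config, seed = 1L, n = 1L) {
  ld <- as.matrix(ld)
  if (!inherits(config, "causal_config")) stop("`config` must be a causal_config")
  m <- nrow(ld)
  if (ncol(ld) != m || length(config$c) != m) {
    stop("dimension mismatch between `ld` and `config`")
  }
  mu <- as.numeric(ld %*% (config$lambda * config$c))
  R <- chol_safe(ld)
  out <- withr::with_seed(as.integer(seed), rmvn_chol(as.integer(n), mu, R))
  if (n == 1L) drop(out) else out
}

#' Simulation scenario linking a GWAS and an eQTL signal
#'
#' Encodes the pleiotropy-versus-linkage dichotomy that colocalization
#' tests must distinguish: under pleiotropy the same variant drives both
#' the trait and expression; under linkage two distinct (LD-linked)
#' variants do; under the null the GWAS carries no signal.
#'
#' @param scenario_kind one of `"pleiotropy"`, `"linkage"`, `"null"`.
#' @param causal_gwas,causal_eqtl causal SNP indices for each trait.
#' @param lambda_gwas,lambda_eqtl non-centrality magnitudes.
#' @param n_gwas,n_eqtl nominal sample sizes used to convert z to beta/se.
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(scenario_kind = c("pleiotropy", "linkage", "null"),
                         causal_gwas = integer(0), causal_eqtl = integer(0),
                         lambda_gwas = 0, lambda_eqtl = 0,
                         n_gwas = 1e5, n_eqtl = 500) {
  scenario_kind <- match.arg(scenario_kind)
  causal_gwas <- as.integer(causal_gwas)
  causal_eqtl <- as.integer(causal_eqtl)
  if (scenario_kind == "pleiotropy" &&
      !identical(sort(causal_gwas), sort(causal_eqtl))) {
    stop("pleiotropy scenario requires causal_gwas == causal_eqtl")
  }
  if (scenario_kind == "linkage" &&
      identical(sort(causal_gwas), sort(causal_eqtl))) {
    stop("linkage scenario requires causal_gwas != causal_eqtl")
  }
  if (scenario_kind == "null" && any(lambda_gwas != 0)) {
    stop("null scenario requires lambda_gwas == 0")
  }
  structure(list(scenario_kind = scenario_kind,
                 causal_gwas = causal_gwas, causal_eqtl = causal_eqtl,
                 lambda_gwas = lambda_gwas, lambda_eqtl = lambda_eqtl,
                 n_gwas = n_gwas, n_eqtl = n_eqtl),
            class = "sim_scenario")
}

#' Simulate paired GWAS and eQTL summary statistics for one scenario
#'
#' Both tables share variant identities and alleles; z-vectors are drawn
#' with [sim_gwas_z()] under the panel's LD, and effect sizes follow the
#' standardized-trait convention `beta = z / sqrt(n)`, `se = 1 / sqrt(n)`.
#'
#' @param panel a [sim_haplotypes()] panel.
#' @param scen a [sim_scenario()].
#' @param seed integer seed.
#' @return list with `gwas` and `eqtl` summary-statistic data frames
#'   (see [summary_stats()]) and the LD matrix used.
#' @examples
#' panel <- sim_haplotypes(400, 8, rho = 0.8, seed = 2)
#' sc <- sim_scenario("pleiotropy", 4, 4, lambda_gwas = 6, lambda_eqtl = 8)
#' pair <- sim_pair_scenario(panel, sc, seed = 3)
#' @export
sim_pair_scenario <- function(panel, scen, seed = 1L) {
  if (!inherits(panel, "haplotype_panel")) stop("`panel` must be a haplotype_panel")
  if (!inherits(scen, "sim_scenario")) stop("`scen` must be a sim_scenario")
  m <- ncol(panel$alleles)
  if (any(c(scen$causal_gwas, scen$causal_eqtl) > m)) {
    stop("causal index exceeds number of SNPs in panel")
  }
  ld <- ld_from_haplotypes(panel)
  cfg_g <- causal_config(m, scen$causal_gwas,
                         rep_len(scen$lambda_gwas, length(scen$causal_gwas)))
  cfg_e <- causal_config(m, scen$causal_eqtl,
                         rep_len(scen$lambda_eqtl, length(scen$causal_eqtl)))
  seed <- as.integer(seed)
  z_g <- sim_gwas_z(ld, cfg_g, seed = seed)
  z_e <- sim_gwas_z(ld, cfg_e, seed = seed + 1L)
  mk <- function(z, n) {
    summary_stats(
      id = panel$variant_ids, chrom = "1", pos = panel$positions,
      effect_allele = "A", other_allele = "G",
      freq = panel$allele_freqs,
      beta = z / sqrt(n), se = rep(1 / sqrt(n), m), n = n
    )
  }
  list(gwas = mk(z_g, scen$n_gwas), eqtl = mk(z_e, scen$n_eqtl), ld = ld)
}

#' Simulate binary functional annotations enriched at causal SNPs
#'
#' Each SNP is annotated with probability `plogis(gamma0 + gamma1 * c)`,
#' so `gamma1` is the annotation log-odds enrichment at causal SNPs — the
#' quantity the empirical-Bayes enrichment fit ([em_fit()]) estimates.
#'
#' @param config a [causal_config()].
#' @param gamma0 log-odds intercept (baseline annotation rate).
#' @param gamma1 log-odds enrichment at causal SNPs; a vector gives one
#'   annotation column per element.
#' @param seed integer seed.
#' @param names optional annotation column names.
#' @return m x a binary matrix with annotation names as columns.
#' @examples
#' cfg <- causal_config(100, 10, 6)
#' A <- sim_annotations(cfg, gamma0 = -2, gamma1 = 2, seed = 5)
#' @export
sim_annotations <- function(config, gamma0 = -2, gamma1 = 2, seed = 1L,
                            names = NULL) {
  if (!inherits(config, "causal_config")) stop("`config` must be a causal_config")
  if (!all(is.finite(c(gamma0, gamma1)))) stop("gamma values must be finite")
  m <- length(config$c)
  a <- length(gamma1)
  gamma0 <- rep_len(gamma0, a)
  withr::with_seed(as.integer(seed), {
    A <- vapply(seq_len(a), function(j) {
      p <- stats::plogis(gamma0[j] + gamma1[j] * config$c)
      stats::rbinom(m, 1L, p)
    }, integer(m))
    A <- matrix(A, nrow = m, ncol = a)
    colnames(A) <- names %||% sprintf("annot%d", seq_len(a))
    A
  })
}

#' Simulate a TaqMan-style qPCR calibration mixing series
#'
#' Emulates mixing gDNA (or cDNA) homozygous for each allele at ratios
#' 4:1, 2:1, 1:1, 1:2, 1:4 and reading the log2 fluorescence ratio of the
#' two allele-specific dyes: `measured = intercept + slope * true + noise`.
#'
#' @param true_log2_ratios planted log2 allele ratios; the default is the
#'   standard five-point series `log2(c(4, 2, 1, 1/2, 1/4))`.
#' @param slope,intercept linear response of measured log2 fluorescence
#'   ratio to true log2 allele ratio.
#' @param noise_sd Gaussian measurement noise SD (log2 scale), `>= 0`.
#' @param seed integer seed.
#' @return data frame with columns `true_log2_ratio`, `measured_log2_ratio`.
#' @examples
#' sim_qpcr_series(noise_sd = 0, slope = 0.9, intercept = 0.1, seed = 1)
#' @export
sim_qpcr_series <- function(true_log2_ratios = c(2, 1, 0, -1, -2),
                            slope = 1, intercept = 0, noise_sd = 0.05,
                            seed = 1L) {
  stopifnot_scalar(noise_sd, "noise_sd", lo = 0)
  withr::with_seed(as.integer(seed), {
    eps <- if (noise_sd > 0) stats::rnorm(length(true_log2_ratios), 0, noise_sd) else 0
    data.frame(
      true_log2_ratio = true_log2_ratios,
      measured_log2_ratio = intercept + slope * true_log2_ratios + eps
    )
  })
}

#' Per-SNP marginal association statistics by simple linear regression
#'
#' Regresses the phenotype on each SNP dosage separately and reports
#' slope, standard error, z and two-sided p per SNP — the basic operation
#' that turns individual-level fixtures into summary statistics.
#'
#' @param genotypes n x m dosage matrix (no missing values).
#' @param phenotype length-n numeric vector with positive variance.
#' @return summary-statistics data frame (one row per SNP). Monomorphic
#'   SNPs get `z = 0`, `se = Inf`, `p = 1`.
#' @examples
#' g <- matrix(rbinom(120, 2, 0.3), ncol = 2)
#' y <- g[, 1] * 0.5 + rnorm(60)
#' marginal_stats(g, y)
#' @export
marginal_stats <- function(genotypes, phenotype) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  if (length(phenotype) != n) stop("phenotype length must match genotype rows")
  if (anyNA(genotypes) || anyNA(phenotype)) stop("missing values not allowed")
  if (stats::var(phenotype) <= 0) stop("phenotype has zero variance")
  m <- ncol(genotypes)
  yc <- phenotype - mean(phenotype)
  out <- lapply(seq_len(m), function(j) {
    x <- genotypes[, j]
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) {
      return(c(beta = 0, se = Inf, z = 0, p = 1))
    }
    b <- sum((x - mean(x)) * yc) / sxx
    resid <- yc - b * (x - mean(x))
    df <- n - 2L
    se <- sqrt(sum(resid^2) / df / sxx)
    # perfect fit: se underflows to 0; report the smallest positive se so
    # z is huge and p underflows, rather than an invalid record
    se <- max(se, .Machine$double.xmin)
    z <- b / se
    p <- 2 * stats::pt(-abs(z), df)
    c(beta = b, se = se, z = z, p = max(p, .Machine$double.xmin))
  })
  out <- do.call(rbind, out)
  ids <- colnames(genotypes) %||% sprintf("snp%03d", seq_len(m))
  summary_stats(
    id = ids, effect_allele = "A", other_allele = "G",
    freq = colMeans(genotypes) / 2,
    beta = out[, "beta"], se = out[, "se"], p = out[, "p"], n = n,
    z = out[, "z"]
  )
}
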