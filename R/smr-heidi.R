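# Summary-based Mendelian randomization (SMR) and the HEIDI heterogeneity
# test: does the GWAS trait and gene expression share one causal variant
# (pleiotropy) or two LD-linked ones (linkage)?

#' SMR test at a single instrument SNP
#'
#' Ratio estimate `b_xy = beta_gwas / beta_eqtl` (trait units per unit of
#' expression) with the chi-square statistic
#' `T_smr = z_g^2 z_e^2 / (z_g^2 + z_e^2)` on 1 df. `T_smr` is symmetric
#' in the two z-scores and bounded by `min(z_g^2, z_e^2)`.
#'
#' @param z_gwas,z_eqtl z-scores at the instrument SNP (`z_eqtl != 0`).
#' @param beta_gwas,beta_eqtl effect sizes at the instrument.
#' @return list with `b_xy`, `T_smr`, `p_smr`.
#' @examples
#' smr_test(4, 6, 0.04, 0.3)
#' @export
smr_test <- function(z_gwas, z_eqtl, beta_gwas, beta_eqtl) {
  if (z_eqtl == 0) stop("undefined instrument: z_eqtl must be non-zero")
  T_smr <- (z_gwas^2 * z_eqtl^2) / (z_gwas^2 + z_eqtl^2)
  list(
    b_xy = beta_gwas / beta_eqtl,
    T_smr = T_smr,
    p_smr = stats::pchisq(T_smr, df = 1, lower.tail = FALSE)
  )
}

#' HEIDI test for heterogeneity in dependent instruments
#'
#' Under a single shared causal variant, the ratio estimate
#' `b_xy(i) = beta_gwas(i) / beta_eqtl(i)` is the same at every cis-SNP;
#' under linkage it varies. For each secondary SNP the difference
#' `d_i = b_xy(i) - b_xy(top)` is standardized using delta-method
#' variances with LD-induced covariance between SNPs (GWAS and eQTL
#' samples treated as independent), and the statistic `sum z_d^2` is
#' referred to a two-moment (Satterthwaite) scaled chi-square that
#' accounts for the correlation among the `d_i`. An eigenvalue
#' mixture-of-chi-squares mode is available for cross-checking.
#'
#' Secondary SNPs are selected by eQTL significance (`p < p_secondary`),
#' LD pruning to `r2_range` with the instrument, and capped at `max_snps`
#' (most significant eQTL first).
#'
#' @param gwas,eqtl `summary_stats` tables over the same variants (same
#'   order, harmonized alleles).
#' @param ld LD matrix aligned with the tables.
#' @param instrument_idx index of the instrument SNP; defaults to the top
#'   cis-eQTL (smallest eQTL p).
#' @param p_secondary eQTL p-value threshold for secondary SNPs
#'   (default 1.57e-3, i.e. |z| > 3.16).
#' @param r2_range allowed `r^2` with the instrument (default
#'   `c(0.05, 0.9)`).
#' @param max_snps cap on secondary SNPs (default 20).
#' @param method `"satterthwaite"` (default) or `"eigen"` (Monte-Carlo
#'   mixture of chi-squares; for cross-checks).
#' @param mc_reps Monte-Carlo replicates for the eigen mode.
#' @return list with `p_heidi`, `n_snps_used`, `statistic`, and `reason`
#'   (`NA` p with a reason code when fewer than 3 secondary SNPs survive).
#' @export
heidi_test <- function(gwas, eqtl, ld, instrument_idx = NULL,
                       p_secondary = 1.57e-3, r2_range = c(0.05, 0.9),
                       max_snps = 20L,
                       method = c("satterthwaite", "eigen"),
                       mc_reps = 1e5L) {
  method <- match.arg(method)
  m <- nrow(gwas)
  if (nrow(eqtl) != m || nrow(ld) != m) stop("dimension mismatch")
  if (is.null(instrument_idx)) instrument_idx <- which.min(eqtl$p)
  t <- instrument_idx
  r2 <- ld[, t]^2
  sec <- which(eqtl$p < p_secondary &
                 r2 >= r2_range[1] & r2 <= r2_range[2] &
                 seq_len(m) != t)
  if (length(sec) > max_snps) {
    sec <- sec[order(eqtl$p[sec])][seq_len(max_snps)]
  }
  if (length(sec) < 3L) {
    return(list(p_heidi = NA_real_, n_snps_used = length(sec),
                statistic = NA_real_,
                reason = "fewer than 3 usable secondary SNPs"))
  }
  snps <- c(t, sec)          # instrument first
  bg <- gwas$beta[snps]; sg <- gwas$se[snps]
  be <- eqtl$beta[snps]; se_ <- eqtl$se[snps]
  R <- ld[snps, snps, drop = FALSE]
  q <- length(sec)
  # d_i = bg_i/be_i - bg_1/be_1 for i = 2..q+1; delta method around the
  # observed estimates with Cov(bg)_jk = R_jk sg_j sg_k (and same for be),
  # GWAS and eQTL blocks independent
  d <- bg[-1] / be[-1] - bg[1] / be[1]
  Jg <- matrix(0, q, q + 1L)          # d wrt bg
  Je <- matrix(0, q, q + 1L)          # d wrt be
  for (i in seq_len(q)) {
    Jg[i, i + 1L] <- 1 / be[i + 1L]
    Jg[i, 1L] <- -1 / be[1L]
    Je[i, i + 1L] <- -bg[i + 1L] / be[i + 1L]^2
    Je[i, 1L] <- bg[1L] / be[1L]^2
  }
  Cg <- R * tcrossprod(sg)
  Ce <- R * tcrossprod(se_)
  Vd <- Jg %*% Cg %*% t(Jg) + Je %*% Ce %*% t(Je)
  sd_d <- sqrt(pmax(diag(Vd), .Machine$double.eps))
  z_d <- d / sd_d
  Rd <- Vd / tcrossprod(sd_d)
  Q <- sum(z_d^2)
  if (Q == 0) {
    return(list(p_heidi = 1, n_snps_used = q, statistic = 0, reason = NA_character_))
  }
  if (method == "satterthwaite") {
    # match first two moments of Q = sum z_d^2 with z_d ~ N(0, Rd):
    # E[Q] = q, Var[Q] = 2 ||Rd||_F^2
    eQ <- q
    vQ <- 2 * sum(Rd^2)
    scale <- vQ / (2 * eQ)
    df <- 2 * eQ^2 / vQ
    p <- stats::pchisq(Q / scale, df = df, lower.tail = FALSE)
  } else {
    ev <- eigen(Rd, symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    draws <- matrix(stats::rchisq(mc_reps * length(ev), df = 1),
                    ncol = length(ev))
    sim <- drop(draws %*% ev)
    p <- (sum(sim >= Q) + 1) / (mc_reps + 1)
  }
  list(p_heidi = p, n_snps_used = q, statistic = Q, reason = NA_character_)
}

#' SMR/HEIDI colocalization pipeline over genes
#'
#' For each gene: pick the top cis-eQTL SNP, require it to pass the eQTL
#' p-value filter and the GWAS p-value filter at the same SNP, then run
#' [smr_test()] and [heidi_test()]. A gene is flagged colocalized when
#' `p_smr < alpha_smr` and `p_heidi > alpha_heidi`.
#'
#' @param gwas a `summary_stats` table (the reference allele orientation).
#' @param eqtl_list named list of `summary_stats` tables, one per gene.
#' @param ld LD matrix aligned with `gwas`.
#' @param p_eqtl_max top-eQTL significance filter (default 5e-5).
#' @param p_gwas_max GWAS significance filter at the instrument
#'   (default 0.05).
#' @param alpha_smr,alpha_heidi decision thresholds (defaults 0.05, 0.05).
#' @param ... passed to [heidi_test()].
#' @return data frame with one row per gene: `gene`, `instrument`, `b_xy`,
#'   `T_smr`, `p_smr`, `p_heidi`, `n_heidi`, `colocalized`, `reason`
#'   (genes skipped by a filter keep `NA` results and a reason code).
#' @export
smr_pipeline <- function(gwas, eqtl_list, ld,
                         p_eqtl_max = 5e-5, p_gwas_max = 0.05,
                         alpha_smr = 0.05, alpha_heidi = 0.05, ...) {
  genes <- names(eqtl_list) %||% sprintf("gene%d", seq_along(eqtl_list))
  rows <- lapply(seq_along(eqtl_list), function(gi) {
    eq <- harmonize_alleles(eqtl_list[[gi]], gwas)
    skip <- function(reason) {
      data.frame(gene = genes[gi], instrument = NA_character_,
                 b_xy = NA_real_, T_smr = NA_real_, p_smr = NA_real_,
                 p_heidi = NA_real_, n_heidi = NA_integer_,
                 colocalized = FALSE, reason = reason,
                 stringsAsFactors = FALSE)
    }
    if (nrow(eq) != nrow(gwas)) return(skip("variant sets differ"))
    t <- which.min(eq$p)
    if (eq$p[t] >= p_eqtl_max) return(skip("no eQTL passes filter"))
    if (gwas$p[t] >= p_gwas_max) return(skip("instrument fails GWAS filter"))
    sm <- smr_test(gwas$z[t], eq$z[t], gwas$beta[t], eq$beta[t])
    he <- heidi_test(gwas, eq, ld, instrument_idx = t, ...)
    coloc <- isTRUE(sm$p_smr < alpha_smr) &&
      isTRUE(!is.na(he$p_heidi) && he$p_heidi > alpha_heidi)
    data.frame(gene = genes[gi], instrument = gwas$id[t],
               b_xy = sm$b_xy, T_smr = sm$T_smr, p_smr = sm$p_smr,
               p_heidi = he$p_heidi, n_heidi = he$n_snps_used,
               colocalized = coloc, reason = he$reason %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
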