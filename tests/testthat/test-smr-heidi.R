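# SMR ratio test and HEIDI heterogeneity test.

test_that("smr_test matches its closed form and the chi-square oracle", {
  # symmetric case: T = z^2 / 2
  r <- smr_test(3, 3, 0.1, 0.2)
  expect_equal(r$T_smr, 9 / 2)
  expect_equal(r$b_xy, 0.5)

  # worked example: z_g = 4, z_e = 6
  r2 <- smr_test(4, 6, 0.04, 0.3)
  expect_equal(r2$T_smr, 16 * 36 / 52, tolerance = 1e-12)
  expect_equal(r2$T_smr, 11.0769, tolerance = 1e-4)
  expect_equal(r2$p_smr, pchisq(16 * 36 / 52, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r2$p_smr, 8.77e-4, tolerance = 1e-2)

  # limit: infinitely strong instrument recovers the GWAS chi-square
  r3 <- smr_test(4, 1e8, 0.04, 1)
  expect_equal(r3$T_smr, 16, tolerance = 1e-6)

  # symmetry and sign-flip invariance
  expect_equal(smr_test(4, 6, 1, 1)$T_smr, smr_test(6, 4, 1, 1)$T_smr)
  expect_equal(smr_test(-4, -6, -0.04, -0.3)$T_smr, r2$T_smr)
  expect_equal(smr_test(-4, -6, -0.04, -0.3)$b_xy, r2$b_xy)

  expect_error(smr_test(4, 0, 1, 1), "z_eqtl")
})

# shared fixture: LD panel and summary-stat generator for HEIDI scenarios
heidi_sim <- function(kind, seed, panel, ld, causal = 15, partner = NULL,
                      lam_g = 6, lam_e = 8, n_g = 1e5, n_e = 500) {
  m <- ncol(panel$alleles)
  cg <- if (kind == "pleiotropy") causal_config(m, causal, lam_g)
        else causal_config(m, partner, lam_g)
  ce <- causal_config(m, causal, lam_e)
  zg <- sim_gwas_z(ld, cg, seed = 2L * seed)
  ze <- sim_gwas_z(ld, ce, seed = 2L * seed + 1L)
  list(gwas = stats_from_z(zg, n = n_g, ids = panel$variant_ids),
       eqtl = stats_from_z(ze, n = n_e, ids = panel$variant_ids))
}

test_that("heidi_test handles exact pleiotropy and degenerate input", {
  panel <- sim_haplotypes(2000, 20, rho = 0.9, maf_range = c(0.2, 0.5),
                          seed = 3)
  ld <- ld_from_haplotypes(panel)
  # noise-free proportional signals: all b_xy identical, statistic 0
  mu_e <- as.numeric(ld %*% (causal_config(20, 10, 8)$lambda *
                               causal_config(20, 10, 8)$c))
  gw <- stats_from_z(0.75 * mu_e, n = 1e5, ids = panel$variant_ids)
  eq <- stats_from_z(mu_e, n = 500, ids = panel$variant_ids)
  he <- heidi_test(gw, eq, ld)
  expect_equal(he$statistic, 0, tolerance = 1e-12)
  expect_equal(he$p_heidi, 1)

  # too few usable secondary SNPs: NA with a reason, not a crash
  he2 <- heidi_test(gw[1:3, ], eq[1:3, ], ld[1:3, 1:3])
  expect_true(is.na(he2$p_heidi))
  expect_match(he2$reason, "fewer than 3")
})

test_that("heidi statistic is invariant to secondary-SNP ordering", {
  panel <- sim_haplotypes(2000, 20, rho = 0.9, maf_range = c(0.2, 0.5),
                          seed = 3)
  ld <- ld_from_haplotypes(panel)
  sim <- heidi_sim("pleiotropy", 11, panel, ld, causal = 10)
  he <- heidi_test(sim$gwas, sim$eqtl, ld)
  perm <- c(10, sample(setdiff(1:20, 10)))
  gw_p <- sim$gwas[perm, ]; class(gw_p) <- class(sim$gwas)
  eq_p <- sim$eqtl[perm, ]; class(eq_p) <- class(sim$eqtl)
  he_p <- heidi_test(gw_p, eq_p, ld[perm, perm], instrument_idx = 1)
  expect_equal(he_p$statistic, he$statistic, tolerance = 1e-9)
  expect_equal(he_p$p_heidi, he$p_heidi, tolerance = 1e-9)
})

test_that("satterthwaite and eigen modes agree", {
  panel <- sim_haplotypes(2000, 20, rho = 0.9, maf_range = c(0.2, 0.5),
                          seed = 3)
  ld <- ld_from_haplotypes(panel)
  sim <- heidi_sim("pleiotropy", 21, panel, ld, causal = 10)
  ps <- heidi_test(sim$gwas, sim$eqtl, ld)$p_heidi
  pe <- withr::with_seed(1,
    heidi_test(sim$gwas, sim$eqtl, ld, method = "eigen",
               mc_reps = 2e5)$p_heidi)
  expect_lt(abs(ps - pe), 0.05)
})

test_that("heidi separates pleiotropy from linkage", {
  panel <- sim_haplotypes(3000, 25, rho = 0.9, maf_range = c(0.2, 0.5),
                          seed = 5)
  ld <- ld_from_haplotypes(panel)
  causal <- 13
  partner <- which.min(abs(ld[, causal] - 0.7))
  rate <- function(kind, reps, seed0) {
    p <- vapply(seq_len(reps), function(i) {
      sim <- heidi_sim(kind, seed0 + i, panel, ld, causal = causal,
                       partner = partner)
      heidi_test(sim$gwas, sim$eqtl, ld)$p_heidi
    }, numeric(1))
    mean(p[!is.na(p)] < 0.05)
  }
  r_pleio <- rate("pleiotropy", 300, 1000)
  r_link <- rate("linkage", 300, 5000)
  expect_lt(abs(r_pleio - 0.05), 0.04)
  expect_gt(r_link, r_pleio)
})

test_that("smr_pipeline applies the printed filters and decision rule", {
  panel <- sim_haplotypes(2000, 20, rho = 0.9, maf_range = c(0.2, 0.5),
                          seed = 7)
  ld <- ld_from_haplotypes(panel)

  # pleiotropy gene: expect colocalized most of the time
  coloc <- vapply(1:25, function(i) {
    sim <- heidi_sim("pleiotropy", 100 + i, panel, ld, causal = 10)
    res <- smr_pipeline(sim$gwas, list(gene = sim$eqtl), ld)
    res$colocalized
  }, logical(1))
  expect_gt(mean(coloc), 0.8)

  # weak eQTL gene is skipped by the eQTL filter: best p around 1e-4
  z_weak <- c(rep(0.1, 9), 3.89, rep(0.1, 10))
  eq_weak <- stats_from_z(z_weak, n = 500, ids = panel$variant_ids)
  expect_gt(min(eq_weak$p), 5e-5)   # confirm it misses the 5e-5 cut
  sim <- heidi_sim("pleiotropy", 31, panel, ld, causal = 10)
  res_w <- smr_pipeline(sim$gwas, list(weak = eq_weak), ld)
  expect_false(res_w$colocalized)
  expect_match(res_w$reason, "eQTL")

  # null GWAS: rarely colocalized
  nulls <- vapply(1:40, function(i) {
    m <- 20
    ze <- sim_gwas_z(ld, causal_config(m, 10, 8), seed = 9000 + 2 * i)
    zg <- sim_gwas_z(ld, causal_config(m), seed = 9001 + 2 * i)
    res <- smr_pipeline(stats_from_z(zg, ids = panel$variant_ids),
                        list(g = stats_from_z(ze, n = 500,
                                              ids = panel$variant_ids)), ld)
    res$colocalized
  }, logical(1))
  expect_lt(mean(nulls), 0.2)
})
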