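# Generators: statistical structure and reproducibility.

test_that("sim_haplotypes controls adjacent-SNP correlation and is seeded", {
  # independence at rho = 0
  p0 <- sim_haplotypes(10000, 6, rho = 0, seed = 3)
  r <- ld_from_haplotypes(p0)
  adj_r2 <- diag(r[-nrow(r), -1])^2
  expect_lt(mean(adj_r2), 0.01)

  # strong copying: empirical r close to rho when target freqs are equal
  p95 <- sim_haplotypes(50000, 2, rho = 0.95, maf_range = c(0.3, 0.3),
                        seed = 4)
  r2snp <- ld_from_haplotypes(p95)
  expect_lt(abs(r2snp[1, 2] - 0.95), 0.02)

  # reproducibility and invariants
  a <- sim_haplotypes(50, 8, rho = 0.5, seed = 11)
  b <- sim_haplotypes(50, 8, rho = 0.5, seed = 11)
  expect_identical(a, b)
  expect_true(all(a$alleles %in% c(0L, 1L)))
  expect_equal(a$allele_freqs, colMeans(a$alleles))
  expect_true(all(diff(a$positions) > 0))
  expect_error(sim_haplotypes(10, 2, maf_range = c(0, 0.6)), "maf_range")
})

test_that("sim_gwas_z draws from N(Sigma (lambda*C), Sigma)", {
  # null: marginally standard normal
  z0 <- sim_gwas_z(diag(3), causal_config(3), seed = 1, n = 1e4)
  expect_lt(max(abs(colMeans(z0))), 0.05)

  # identity LD: mean equals lambda at the causal SNP
  z1 <- sim_gwas_z(diag(3), causal_config(3, 1, 5), seed = 2, n = 1e4)
  expect_equal(colMeans(z1), c(5, 0, 0), tolerance = 0.02)

  # LD propagates the non-centrality: r12 = 0.8 gives mean z2 = 4
  S <- diag(3); S[1, 2] <- S[2, 1] <- 0.8
  z2 <- sim_gwas_z(S, causal_config(3, 1, 5), seed = 3, n = 1e4)
  expect_equal(mean(z2[, 2]), 4.0, tolerance = 0.05)

  expect_error(sim_gwas_z(diag(3), causal_config(2, 1, 5)), "dimension")
})

test_that("sim_gwas_z sample covariance converges to Sigma", {
  S <- 0.8^abs(outer(1:5, 1:5, "-"))
  z <- sim_gwas_z(S, causal_config(5), seed = 9, n = 1e5)
  frob <- sqrt(sum((stats::cov(z) - S)^2))
  expect_lt(frob, 0.05)
})

test_that("sim_scenario enforces the pleiotropy/linkage/null invariants", {
  expect_error(sim_scenario("pleiotropy", 1, 2, 5, 5), "pleiotropy")
  expect_error(sim_scenario("linkage", 1, 1, 5, 5), "linkage")
  expect_error(sim_scenario("null", integer(0), 3,
                            lambda_gwas = 2, lambda_eqtl = 5), "null")
  expect_s3_class(sim_scenario("pleiotropy", 2, 2, 5, 8), "sim_scenario")
})

test_that("paired scenarios have the advertised statistical behaviour", {
  panel <- sim_haplotypes(1000, 10, rho = 0.8, seed = 21)

  # null: ~5% of GWAS z exceed 1.96 in absolute value
  zs <- unlist(lapply(1:200, function(i) {
    pr <- sim_pair_scenario(panel,
      sim_scenario("null", integer(0), 5, lambda_gwas = 0, lambda_eqtl = 0),
      seed = 100 + i)
    pr$gwas$z
  }))
  expect_lt(abs(mean(abs(zs) > 1.96) - 0.05), 0.02)

  # pleiotropy with a strong eQTL: top eQTL SNP is the causal one
  hits <- vapply(1:100, function(i) {
    pr <- sim_pair_scenario(panel,
      sim_scenario("pleiotropy", 5, 5, lambda_gwas = 6, lambda_eqtl = 8),
      seed = 300 + i)
    which.max(abs(pr$eqtl$z)) == 5
  }, logical(1))
  expect_gt(mean(hits), 0.9)

  # betas/se follow the standardized-trait convention
  pr <- sim_pair_scenario(panel,
    sim_scenario("pleiotropy", 5, 5, lambda_gwas = 6, lambda_eqtl = 8),
    seed = 1)
  expect_equal(pr$gwas$beta / pr$gwas$se, pr$gwas$z, tolerance = 1e-12)
  expect_equal(pr$gwas$se, rep(1 / sqrt(1e5), 10), tolerance = 1e-12)
  expect_identical(pr$gwas$id, pr$eqtl$id)
})

test_that("linkage scenario propagates the GWAS effect through LD", {
  # E[z_gwas at the eQTL-causal SNP] = r(causal_g, causal_e) * lambda_g
  panel <- sim_haplotypes(2000, 8, rho = 0.9, maf_range = c(0.2, 0.5),
                          seed = 31)
  ld <- ld_from_haplotypes(panel)
  r <- ld[3, 5]
  zg <- vapply(1:400, function(i) {
    pr <- sim_pair_scenario(panel,
      sim_scenario("linkage", 3, 5, lambda_gwas = 8, lambda_eqtl = 8),
      seed = 500 + i)
    pr$gwas$z[5]
  }, numeric(1))
  expect_equal(mean(zg), r * 8, tolerance = 0.15)
})

test_that("sim_annotations follows the logistic enrichment model", {
  cfg <- causal_config(10000, sample.int(10000, 500), 5)

  # no enrichment: annotation independent of causal status
  A0 <- sim_annotations(cfg, gamma0 = -1, gamma1 = 0, seed = 7)
  tab <- table(A0[, 1], cfg$c)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)

  # gamma0 + gamma1 = 0: half the causal SNPs annotated
  A1 <- sim_annotations(cfg, gamma0 = -3, gamma1 = 3, seed = 8)
  expect_equal(mean(A1[cfg$c == 1, 1]), 0.5, tolerance = 0.07)

  expect_identical(sim_annotations(cfg, -2, 2, seed = 9),
                   sim_annotations(cfg, -2, 2, seed = 9))

  # empirical enrichment log-odds recovers gamma1
  A2 <- sim_annotations(cfg, gamma0 = -2, gamma1 = 2, seed = 10)
  p1 <- mean(A2[cfg$c == 1, 1]); p0 <- mean(A2[cfg$c == 0, 1])
  lor <- log(p1 / (1 - p1)) - log(p0 / (1 - p0))
  expect_lt(abs(lor - 2), 0.3)
})

test_that("sim_qpcr_series is a seeded linear response", {
  exact <- sim_qpcr_series(noise_sd = 0, slope = 1, intercept = 0, seed = 1)
  expect_equal(exact$measured_log2_ratio, exact$true_log2_ratio)
  expect_equal(exact$true_log2_ratio, c(2, 1, 0, -1, -2))

  lin <- sim_qpcr_series(noise_sd = 0, slope = 0.9, intercept = 0.1, seed = 1)
  expect_equal(lin$measured_log2_ratio[1], 0.1 + 0.9 * 2)
})

test_that("marginal_stats matches closed-form OLS and is calibrated", {
  # hand-computed 6-sample toy
  x <- c(0, 1, 2, 0, 1, 2)
  y <- c(0.1, 0.9, 2.2, -0.3, 1.1, 1.8)
  sxx <- sum((x - mean(x))^2)
  b_hat <- sum((x - mean(x)) * (y - mean(y))) / sxx
  res <- y - mean(y) - b_hat * (x - mean(x))
  se_hat <- sqrt(sum(res^2) / 4 / sxx)
  st <- marginal_stats(matrix(x, ncol = 1), y)
  expect_equal(st$beta, b_hat, tolerance = 1e-12)
  expect_equal(st$se, se_hat, tolerance = 1e-12)

  # perfect predictor: p underflows toward 0
  g <- matrix(rep(c(0, 1, 2), 20), ncol = 1)
  st2 <- marginal_stats(g, as.numeric(g))
  expect_lt(st2$p, 1e-100)

  # monomorphic SNP flagged, not a crash
  g3 <- cbind(mono = rep(1, 30), poly = rep(c(0, 1, 2), 10))
  st3 <- marginal_stats(g3, rnorm(30))
  expect_equal(st3$z[1], 0)
  expect_equal(st3$se[1], Inf)

  # permuted phenotype: uniform p-values
  set.seed(42)
  G <- matrix(rbinom(50 * 2000, 2, 0.3), nrow = 50)
  pv <- marginal_stats(G, sample(rnorm(50)))$p
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})
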