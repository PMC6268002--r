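# PWM parsing, scoring, exact p-values, scanning, density profiles.

test_that("parse_jaspar round-trips and validates", {
  txt <- c(">MTOY toy_motif",
           "A [ 3 10 ]",
           "C [ 1  0 ]",
           "G [ 5  2 ]",
           "T [ 0  1 ]")
  x <- parse_jaspar(txt)
  expect_equal(unname(x$counts["A", ]), c(3, 10))
  expect_equal(unname(x$counts["T", ]), c(0, 1))
  expect_equal(x$id, "MTOY")

  back <- parse_jaspar(write_jaspar(x))
  expect_equal(back$counts, x$counts)

  # bracket-less rows also parse
  x2 <- parse_jaspar(c(">M2 m2", "A 3 10", "C 1 0", "G 5 2", "T 0 1"))
  expect_equal(x2$counts, x$counts)

  expect_error(parse_jaspar(c(">B b", "A [ 1 2 ]", "C [ 1 ]",
                              "G [ 1 2 ]", "T [ 1 2 ]")), "ragged|C")
  expect_error(parse_jaspar(c(">B b", "A [ 1 2 ]", "C [ 1 2 ]",
                              "G [ 1 2 ]", "X [ 1 2 ]")), "unknown base")
  expect_error(parse_jaspar(c(">B b", "A [ 1 -2 ]", "C [ 1 2 ]",
                              "G [ 1 2 ]", "T [ 1 2 ]")), "negative")
})

test_that("relative_score hits its closed-form anchors", {
  x <- toy_pwm()
  consensus <- paste(c("A", "C", "G", "T")[apply(x$log_odds, 2, which.max)],
                     collapse = "")
  anti <- paste(c("A", "C", "G", "T")[apply(x$log_odds, 2, which.min)],
                collapse = "")
  expect_equal(relative_score(x, consensus), 1)
  expect_equal(relative_score(x, anti), 0)

  # hand computation for a 2-column matrix
  counts <- matrix(c(3, 10, 1, 0, 5, 2, 0, 1), nrow = 4, byrow = TRUE,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  y <- pwm(counts, pseudocount = 0.8)
  p_A1 <- (3 + 0.8 * 0.25) / (9 + 0.8)
  p_G2 <- (2 + 0.8 * 0.25) / (13 + 0.8)
  s_AG <- log2(p_A1 / 0.25) + log2(p_G2 / 0.25)
  lo <- y$log_odds
  smin <- sum(apply(lo, 2, min)); smax <- sum(apply(lo, 2, max))
  expect_equal(relative_score(y, "AG"), (s_AG - smin) / (smax - smin),
               tolerance = 1e-12)

  # invariant to adding a constant to every column of the log-odds
  x_shift <- x
  x_shift$log_odds <- x$log_odds +
    matrix(rep(c(0.7, -0.3, 1.1, 0.2), each = 4), nrow = 4)
  expect_equal(relative_score(x_shift, "ACGT"), relative_score(x, "ACGT"),
               tolerance = 1e-12)

  expect_error(relative_score(x, "ACGN"), "position 4")
  expect_error(relative_score(x, "ACG"), "length")
})

test_that("the DP score distribution is exact", {
  for (bg in list(rep(0.25, 4), c(0.29, 0.21, 0.21, 0.29))) {
    x <- toy_pwm(background = bg)
    d <- score_distribution(x, granularity = 1e-3)
    expect_equal(sum(d$prob), 1, tolerance = 1e-9)

    # brute force over all 4^L sequences, discretizing per column exactly
    # as the score definition does
    kmers <- all_kmers(4)
    idx_all <- lapply(strsplit(kmers, ""), match, c("A", "C", "G", "T"))
    qcols <- round(x$log_odds / 1e-3)
    key <- vapply(idx_all, function(ii)
      sum(qcols[cbind(ii, 1:4)]), numeric(1))
    w <- vapply(idx_all, function(ii) prod(bg[ii]), numeric(1))
    brute <- tapply(w, key, sum)
    dp_key <- round(d$score / 1e-3)
    tv <- 0.5 * sum(abs(
      vapply(union(names(brute), as.character(dp_key)), function(k) {
        b <- if (k %in% names(brute)) brute[[k]] else 0
        p <- d$prob[match(as.integer(k), dp_key)]
        if (is.na(p)) p <- 0
        b - p
      }, numeric(1))))
    expect_lt(tv, 1e-12)

    # p-values of grid scores against the enumeration oracle
    for (i in c(1, 57, 130, 256)) {
      expect_equal(score_pvalue(x, key[i] * 1e-3), sum(w[key >= key[i]]),
                   tolerance = 1e-9)
    }
  }
})

test_that("score_pvalue boundary behaviour", {
  x <- toy_pwm()
  rng <- finecoloc:::.score_range(x)
  # minimal attainable score: p = 1
  expect_equal(score_pvalue(x, rng["min"]), 1, tolerance = 1e-9)
  # above the maximum: boundary mass = P(S = S_max)
  cons_idx <- apply(x$log_odds, 2, which.max)
  p_max <- prod(x$background[cons_idx])
  expect_equal(score_pvalue(x, rng["max"] + 5), p_max, tolerance = 1e-9)
  expect_equal(score_pvalue(x, rng["max"]), p_max, tolerance = 1e-9)
})

test_that("scan_sequences finds planted sites and respects defaults", {
  x <- toy_pwm()
  consensus <- paste(c("A", "C", "G", "T")[apply(x$log_odds, 2, which.max)],
                     collapse = "")
  bgseq <- paste(rep(c("A", "C", "G", "T")[apply(x$log_odds, 2, which.min)],
                     25), collapse = "")
  s <- paste0(substr(bgseq, 1, 40), consensus,
              substr(bgseq, 45, nchar(bgseq)))
  hits <- scan_sequences(c(test = s), x, p_cutoff = 0.004)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 40L)   # 0-based
  expect_equal(hits$rel_score, 1)

  # formals carry the documented defaults
  fm <- formals(scan_sequences)
  expect_equal(fm$p_cutoff, 1e-4)
  expect_true(fm$both_strands)
  expect_true(fm$non_overlapping)
})

test_that("scanning is reverse-complement symmetric", {
  x <- toy_pwm()
  set.seed(8)
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
             collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h1 <- scan_sequences(c(fw = s), x, p_cutoff = 0.05,
                       non_overlapping = FALSE)
  h2 <- scan_sequences(c(rc = rc), x, p_cutoff = 0.05,
                       non_overlapping = FALSE)
  expect_equal(nrow(h1), nrow(h2))
  # a + hit at start i maps to a - hit at n - L - i on the reverse
  mapped <- sort(500 - 4 - h2$start)
  expect_equal(sort(h1$start), mapped)
  expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-12)
})

test_that("background hit counts are Poisson-calibrated", {
  x <- parse_jaspar(c(">M8 m8", "A [ 9 1 2 3 4 5 6 7 ]",
                      "C [ 0 8 1 1 2 2 1 0 ]", "G [ 1 1 7 2 2 1 1 2 ]",
                      "T [ 0 0 0 4 2 2 2 1 ]"))
  set.seed(91)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
             collapse = "")
  cutoff <- 1e-3
  hits <- scan_sequences(c(bg = s), x, p_cutoff = cutoff,
                         non_overlapping = FALSE)
  # expectation uses the attained tail mass at the discrete threshold
  d <- score_distribution(x)
  tails <- rev(cumsum(rev(d$prob)))
  p_eff <- max(tails[tails <= cutoff])
  lambda <- 2 * (10000 - 8 + 1) * p_eff
  expect_gte(nrow(hits), qpois(0.005, lambda))
  expect_lte(nrow(hits), qpois(0.995, lambda))
})

test_that("allele_best_scores matches exhaustive window enumeration", {
  x <- toy_pwm()
  consensus <- paste(c("A", "C", "G", "T")[apply(x$log_odds, 2, which.max)],
                     collapse = "")
  # identical alleles: delta 0
  same <- allele_best_scores(x, "TTTT", "AC", "AC", "GGGG")
  expect_identical(same$delta_rel_score, 0)

  # planted perfect site destroyed by a 1-bp deletion
  ref_allele <- substr(consensus, 1, 2)
  alt_allele <- substr(consensus, 1, 1)
  flank5 <- "TTTT"
  flank3 <- paste0(substr(consensus, 3, 4), "TTT")
  res <- allele_best_scores(x, flank5, ref_allele, alt_allele, flank3)
  expect_equal(res$ref$rel_score, 1)
  expect_lt(res$alt$rel_score, 1)

  # oracle: enumerate every window of each haplotype on both strands
  brute_best <- function(hap) {
    wins <- vapply(1:(nchar(hap) - 3), function(i) substr(hap, i, i + 3),
                   character(1))
    best <- -Inf
    for (w in wins) {
      for (v in c(w, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(w))))) {
        best <- max(best, relative_score(x, v))
      }
    }
    best
  }
  expect_equal(res$ref$rel_score,
               brute_best(paste0(flank5, ref_allele, flank3)),
               tolerance = 1e-12)
  expect_equal(res$alt$rel_score,
               brute_best(paste0(flank5, alt_allele, flank3)),
               tolerance = 1e-12)

  expect_error(allele_best_scores(x, "TT", "A", "AC", "TTTT"), "flank")
})

test_that("shuffle_pwm permutes columns reproducibly", {
  txt <- c(">M8 m8", "A [ 9 1 2 3 4 5 6 7 ]", "C [ 0 8 1 1 2 2 1 0 ]",
           "G [ 1 1 7 2 2 1 1 2 ]", "T [ 0 0 0 4 2 2 2 1 ]")
  x <- parse_jaspar(txt)
  sh1 <- shuffle_pwm(x, seed = 1)
  sh2 <- shuffle_pwm(x, seed = 1)
  expect_identical(sh1$counts, sh2$counts)

  cols_sorted <- function(m) m[, do.call(order, as.data.frame(t(m))),
                               drop = FALSE]
  expect_equal(cols_sorted(sh1$counts), cols_sorted(x$counts),
               ignore_attr = TRUE)
  expect_equal(pwm_information(sh1), pwm_information(x), tolerance = 1e-12)
  expect_false(identical(shuffle_pwm(x, seed = 1)$counts,
                         shuffle_pwm(x, seed = 2)$counts))
})

test_that("density_profile is calibrated and centered", {
  set.seed(12)
  genome <- 1e6
  refs <- sort(sample.int(genome - 40000, 50)) + 20000
  targets <- sample.int(genome, 1e5, replace = TRUE)
  prof <- density_profile(refs, targets, range_bp = 10000, window_bp = 500,
                          genome_length = genome)
  expect_equal(nrow(prof), 40L)   # 2 * 10000 / 500
  expect_lt(max(abs(prof$fold_change - 1)), 0.1)

  # all targets at the reference centers: central bin dominates
  prof2 <- density_profile(refs, rep(refs, 3), range_bp = 10000,
                           window_bp = 500, genome_length = genome)
  central <- which(prof2$bin_center > 0 & prof2$bin_center < 500)
  expect_equal(which.max(prof2$fold_change), central)

  expect_warning(
    p0 <- density_profile(refs, numeric(0), genome_length = genome),
    "no target")
  expect_true(all(p0$fold_change == 0))
  expect_error(density_profile(refs, targets, range_bp = 10000,
                               window_bp = 333, genome_length = genome),
               "divide")
})
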