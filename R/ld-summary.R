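# LD computation from haplotypes, summary-statistic containers and I/O in
# the GCTA ".ma" dialect, allele harmonization, and single-SNP approximate
# conditional association.

#' Construct a summary-statistics table
#'
#' Canonical per-variant container: effect sizes with standard errors on a
#' consistent effect-allele orientation, plus z and two-sided p. `z` is
#' derived as `beta/se` when not supplied.
#'
#' @param id variant identifiers (unique).
#' @param effect_allele,other_allele allele strings; `beta` refers to
#'   `effect_allele` dosage.
#' @param freq effect-allele frequency in `[0, 1]`.
#' @param beta,se effect and standard error (`se > 0`).
#' @param n per-variant sample size.
#' @param chrom,pos optional chromosome and 1-based position.
#' @param p optional two-sided p; computed from z when missing.
#' @param z optional z-score; `beta/se` when missing.
#' @return data frame of class `summary_stats`.
#' @export
summary_stats <- function(id, effect_allele, other_allele, freq, beta, se, n,
                          chrom = NA_character_, pos = NA_integer_,
                          p = NULL, z = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("duplicate SNP id(s): ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(se <= 0, na.rm = TRUE)) stop("all `se` must be > 0")
  z <- if (is.null(z)) beta / se else z
  p <- if (is.null(p)) 2 * stats::pnorm(-abs(z)) else p
  p <- pmax(p, .Machine$double.xmin)
  if (any(p > 1)) stop("p-values must lie in (0, 1]")
  out <- data.frame(
    id = id, chrom = chrom, pos = pos,
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    freq = freq, beta = beta, se = se, z = z, p = p, n = n,
    stringsAsFactors = FALSE
  )
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' LD matrix from a phased haplotype panel
#'
#' Signed LD `r[j, k]` is the Pearson correlation of the phased 0/1 allele
#' indicator columns; `r^2` is its elementwise square. For unphased data
#' pass a dosage matrix: the composite Pearson correlation of dosages is
#' used the same way.
#'
#' @param panel a [sim_haplotypes()] panel, or a numeric haplotype/dosage
#'   matrix with variants in columns.
#' @return symmetric correlation matrix with unit diagonal and variant ids
#'   as dimnames.
#' @examples
#' panel <- sim_haplotypes(100, 5, seed = 1)
#' r <- ld_from_haplotypes(panel)
#' @export
ld_from_haplotypes <- function(panel) {
  X <- if (inherits(panel, "haplotype_panel")) panel$alleles else as.matrix(panel)
  ids <- colnames(X) %||% sprintf("snp%03d", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("monomorphic SNP(s): ", paste(ids[sds == 0], collapse = ", "))
  }
  r <- stats::cor(X)
  # clamp tiny numerical overshoot, keep exact unit diagonal
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(ids, ids)
  r
}

#' Approximate conditional z-scores given one conditioning SNP
#'
#' Standard single-SNP summary-statistic approximation
#' `z_{j|c} = (z_j - r_{jc} z_c) / sqrt(1 - r_{jc}^2)`: the residual
#' association of each SNP after removing the component explained by its
#' LD with the conditioning SNP. The conditioned SNP's own conditional z
#' is exactly 0; SNPs uncorrelated with it are unchanged. SNPs in perfect
#' LD with the conditioning SNP (|r| = 1, j != c) are non-estimable and
#' returned as `NA`.
#'
#' @param stats a `summary_stats` table or a plain z-score vector.
#' @param ld LD matrix aligned with `stats`.
#' @param cond_idx index (or variant id) of the conditioning SNP.
#' @return numeric vector of conditional z-scores (named when ids known).
#' @examples
#' ld <- matrix(c(1, .8, .8, 1), 2)
#' conditional_z(c(5, 4.5), ld, 1)
#' @export
conditional_z <- function(stats, ld, cond_idx) {
  z <- if (inherits(stats, "summary_stats")) stats$z else as.numeric(stats)
  ld <- as.matrix(ld)
  m <- length(z)
  if (nrow(ld) != m) stop("dimension mismatch between `stats` and `ld`")
  if (is.character(cond_idx)) {
    cond_idx <- match(cond_idx, rownames(ld))
    if (is.na(cond_idx)) stop("conditioning SNP id not found in LD matrix")
  }
  r <- ld[, cond_idx]
  zc <- z[cond_idx]
  out <- (z - r * zc) / sqrt(pmax(1 - r^2, 0))
  collinear <- abs(r) >= 1 - 1e-12
  collinear[cond_idx] <- FALSE
  out[collinear] <- NA_real_
  if (any(collinear)) {
    warning(sum(collinear), " SNP(s) collinear with conditioning SNP; NA returned")
  }
  out[cond_idx] <- 0
  names(out) <- rownames(ld)
  out
}

.ma_columns <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "N")

#' Read GCTA ".ma"-style summary statistics
#'
#' Whitespace-delimited text with header columns `SNP A1 A2 freq b se p N`
#' (`A1` is the effect allele). Validation errors name the offending
#' column or the 1-based data line.
#'
#' @param path file path.
#' @return a `summary_stats` table.
#' @export
read_summary <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  missing <- setdiff(.ma_columns, names(tab))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  num_cols <- c("freq", "b", "se", "p", "N")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    bad <- which(is.na(v) & !is.na(tab[[cc]]))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s' at line %d: '%s'",
                   cc, bad[1] + 1L, tab[[cc]][bad[1]]))
    }
    tab[[cc]] <- v
  }
  if (anyDuplicated(tab$SNP)) {
    dup <- tab$SNP[duplicated(tab$SNP)][1]
    stop(sprintf("duplicate SNP id '%s' at line %d",
                 dup, which(tab$SNP == dup)[2] + 1L))
  }
  summary_stats(
    id = tab$SNP, effect_allele = tab$A1, other_allele = tab$A2,
    freq = tab$freq, beta = tab$b, se = tab$se, p = tab$p, n = tab$N
  )
}

#' Write summary statistics as a GCTA ".ma"-style table
#'
#' @param stats a `summary_stats` table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_summary <- function(stats, path) {
  out <- data.frame(
    SNP = stats$id, A1 = stats$effect_allele, A2 = stats$other_allele,
    freq = stats$freq, b = stats$beta, se = stats$se, p = stats$p,
    N = stats$n
  )
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Harmonize summary statistics to a reference allele orientation
#'
#' Records whose effect/other alleles are swapped relative to the reference
#' orientation have `beta` and `z` sign-flipped and `freq` complemented.
#' Allele pairs that match neither orientation raise an error; no silent
#' frequency-based strand flipping is attempted (strand-ambiguous A/T and
#' C/G pairs are treated like any other pair, so a genuine strand mismatch
#' surfaces as an error rather than a silent flip).
#'
#' @param stats a `summary_stats` table.
#' @param ref data frame with columns `id`, `effect_allele`, `other_allele`
#'   giving the target orientation (e.g. another `summary_stats` table).
#' @return harmonized `summary_stats` table, rows restricted to shared ids
#'   and ordered as in `ref`.
#' @export
harmonize_alleles <- function(stats, ref) {
  idx <- match(ref$id, stats$id)
  keep <- !is.na(idx)
  ref <- ref[keep, , drop = FALSE]
  out <- stats[idx[keep], , drop = FALSE]
  same <- out$effect_allele == ref$effect_allele &
    out$other_allele == ref$other_allele
  swapped <- out$effect_allele == ref$other_allele &
    out$other_allele == ref$effect_allele
  bad <- !(same | swapped)
  if (any(bad)) {
    stop("allele mismatch (not a swap) for: ",
         paste(out$id[bad], collapse = ", "))
  }
  if (any(swapped)) {
    out$beta[swapped] <- -out$beta[swapped]
    out$z[swapped] <- -out$z[swapped]
    out$freq[swapped] <- 1 - out$freq[swapped]
    out$effect_allele[swapped] <- ref$effect_allele[swapped]
    out$other_allele[swapped] <- ref$other_allele[swapped]
  }
  rownames(out) <- NULL
  out
}

#' Write an LD matrix as TSV with a header row of variant ids
#' @param ld LD matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_ld <- function(ld, path) {
  utils::write.table(as.data.frame(ld), path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' Read an LD matrix written by [write_ld()]
#' @param path file path.
#' @return LD matrix with variant-id dimnames.
#' @export
read_ld <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  r <- as.matrix(tab)
  rownames(r) <- colnames(r)
  r
}

#' Write a haplotype panel as minimal phased VCF v4.2 (GT only)
#'
#' Variants use 1-based positions on the panel's (single) chromosome with
#' placeholder REF/ALT alleles; haplotype pairs are emitted as phased
#' diploid genotypes (an odd trailing haplotype is dropped with a warning).
#'
#' @param panel a [sim_haplotypes()] panel.
#' @param path output path.
#' @param chrom chromosome name.
#' @return the path, invisibly.
#' @export
write_panel_vcf <- function(panel, path, chrom = "1") {
  X <- panel$alleles
  n <- nrow(X)
  if (n %% 2L == 1L) {
    warning("odd number of haplotypes; dropping the last one")
    X <- X[-n, , drop = FALSE]
    n <- n - 1L
  }
  n_ind <- n %/% 2L
  gt <- vapply(seq_len(ncol(X)), function(j) {
    a <- X[, j]
    paste0(a[seq(1, n, by = 2)], "|", a[seq(2, n, by = 2)])
  }, character(n_ind))
  gt <- matrix(gt, nrow = n_ind)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", chrom),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("ind%03d", seq_len(n_ind))), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(X)), function(j) {
    paste(c(chrom, panel$positions[j], panel$variant_ids[j], "G", "A",
            ".", "PASS", ".", "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased GT-only VCF into a haplotype panel
#'
#' Uses `vcfR` to parse the VCF; each diploid genotype contributes two
#' haplotypes. Only biallelic phased sites are supported.
#'
#' @param path VCF path.
#' @return a `haplotype_panel`.
#' @export
read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(!grepl("^[01]\\|[01]$", gt))) {
    stop("only phased biallelic GT fields (0|0 .. 1|1) are supported")
  }
  m <- nrow(gt)
  hap1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = m)
  hap2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = m)
  n_ind <- ncol(gt)
  alleles <- matrix(0L, nrow = 2L * n_ind, ncol = m)
  alleles[seq(1, 2 * n_ind, by = 2), ] <- t(hap1)
  alleles[seq(2, 2 * n_ind, by = 2), ] <- t(hap2)
  ids <- vcfR::getID(v)
  colnames(alleles) <- ids
  structure(
    list(alleles = alleles, variant_ids = ids,
         positions = as.integer(vcfR::getPOS(v)),
         allele_freqs = colMeans(alleles)),
    class = "haplotype_panel"
  )
}
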