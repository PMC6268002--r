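# Sequence scanning with a PWM, allele-aware best scores across an indel,
# and peak-centered motif density profiles.

# score every window of one sequence on the forward strand; windows
# containing non-ACGT characters are skipped (NA score)
.window_scores <- function(x, seq) {
  v <- strsplit(toupper(seq), "")[[1]]
  idx <- match(v, .DNA)
  L <- x$length
  n <- length(idx) - L + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  ok <- rep(TRUE, n)
  for (p in seq_len(L)) {
    b <- idx[p:(p + n - 1L)]
    bad <- is.na(b)
    ok <- ok & !bad
    b[bad] <- 1L
    sc <- sc + x$log_odds[cbind(b, p)]
  }
  sc[!ok] <- NA_real_
  sc
}

#' Scan sequences for PWM matches above a p-value cutoff
#'
#' Scores every window of every sequence (both strands by default), keeps
#' windows whose exact background p-value is at or below `p_cutoff`, and
#' optionally reduces to non-overlapping matches by greedy selection in
#' descending score order (ties: leftmost first, then '+' strand).
#'
#' @param sequences a FASTA path, a `Biostrings::DNAStringSet`, or a named
#'   character vector of sequences.
#' @param x a [pwm()].
#' @param p_cutoff match p-value cutoff (default 1e-4).
#' @param both_strands scan the reverse strand too (default TRUE).
#' @param non_overlapping greedily enforce non-overlapping matches
#'   (default TRUE).
#' @param background optional background override for scoring/p-values
#'   (e.g. the genome composition `c(0.29, 0.21, 0.21, 0.29)` used for
#'   genome-wide scans).
#' @param granularity score-distribution discretization (default 1e-3).
#' @return data frame of hits: `seq_id`, `start` (0-based, forward-strand
#'   window start), `strand`, `score` (raw log2-odds), `rel_score`,
#'   `p_value`, sorted by sequence then position.
#' @export
scan_sequences <- function(sequences, x, p_cutoff = 1e-4,
                           both_strands = TRUE, non_overlapping = TRUE,
                           background = NULL, granularity = 1e-3) {
  if (!is.null(background)) {
    x <- pwm(x$counts, background = background, pseudocount = x$pseudocount,
             id = x$id, name = x$name)
  }
  seqs <- .as_named_seqs(sequences)
  dist <- score_distribution(x, granularity)
  rng <- .score_range(x)
  L <- x$length
  hits <- list()
  for (sid in names(seqs)) {
    s <- seqs[[sid]]
    fwd <- .window_scores(x, s)
    per_strand <- list(`+` = fwd)
    if (both_strands) {
      rev_scores <- rev(.window_scores(x, .revcomp(s)))
      per_strand$`-` <- rev_scores
    }
    for (strand in names(per_strand)) {
      sc <- per_strand[[strand]]
      if (!length(sc)) next
      keep <- which(!is.na(sc))
      if (!length(keep)) next
      pv <- score_pvalue(x, sc[keep], dist = dist)
      sel <- pv <= p_cutoff
      if (!any(sel)) next
      hits[[length(hits) + 1L]] <- data.frame(
        seq_id = sid, start = keep[sel] - 1L, strand = strand,
        score = sc[keep][sel],
        rel_score = (sc[keep][sel] - rng["min"]) / (rng["max"] - rng["min"]),
        p_value = pv[sel], stringsAsFactors = FALSE
      )
    }
  }
  if (!length(hits)) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      strand = character(0), score = numeric(0),
                      rel_score = numeric(0), p_value = numeric(0)))
  }
  out <- do.call(rbind, hits)
  if (non_overlapping) {
    pieces <- lapply(split(out, out$seq_id), function(d) {
      d <- d[order(-d$score, d$start, d$strand), , drop = FALSE]
      taken_start <- integer(0)
      keep <- logical(nrow(d))
      for (i in seq_len(nrow(d))) {
        s0 <- d$start[i]
        if (!any(abs(taken_start - s0) < L)) {
          keep[i] <- TRUE
          taken_start <- c(taken_start, s0)
        }
      }
      d[keep, , drop = FALSE]
    })
    out <- do.call(rbind, pieces)
  }
  out <- out[order(out$seq_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.as_named_seqs <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) {
    out <- as.character(sequences)
  } else if (is.character(sequences) && length(sequences) == 1L &&
             file.exists(sequences)) {
    out <- as.character(Biostrings::readDNAStringSet(sequences))
  } else {
    out <- sequences
  }
  if (is.null(names(out))) names(out) <- sprintf("seq%d", seq_along(out))
  as.list(out)
}

#' Best allele-specific PWM scores across a variant (indel-aware)
#'
#' Builds the two haplotype sequences `flank5 + allele + flank3`, scans
#' every window overlapping the allele (both strands), and reports the
#' maximal relative score per allele and their difference — the predicted
#' binding disruption. Alleles may differ in length, so a 1-bp deletion
#' (e.g. TA > T) is handled naturally.
#'
#' @param x a [pwm()].
#' @param flank5,flank3 flanking sequences, each at least `L - 1` bases.
#' @param ref_allele,alt_allele allele sequences (may be empty for a full
#'   deletion).
#' @return list with `ref` and `alt` (each: `start` 0-based in its
#'   haplotype, `strand`, `score`, `rel_score`, `window`) and
#'   `delta_rel_score` = ref - alt.
#' @examples
#' m <- parse_jaspar(c(">toy toy", "A [ 9 0 0 9 ]", "C [ 0 9 0 0 ]",
#'                     "G [ 0 0 9 0 ]", "T [ 0 0 0 0 ]"))
#' allele_best_scores(m, "TTTT", "ACGA", "ACA", "TTTT")
#' @export
allele_best_scores <- function(x, flank5, ref_allele, alt_allele, flank3) {
  L <- x$length
  if (nchar(flank5) < L - 1L || nchar(flank3) < L - 1L) {
    stop("flanks must each be at least L - 1 = ", L - 1L, " bases")
  }
  best_for <- function(allele) {
    hap <- paste0(flank5, allele, flank3)
    n5 <- nchar(flank5)
    na <- nchar(allele)
    total <- nchar(hap)
    # windows [i, i+L-1] (1-based) overlapping the allele span; for an
    # empty allele, windows spanning the deletion junction
    lo <- max(1L, n5 - L + 2L)
    hi <- min(if (na >= 1L) n5 + na else n5 + 1L, total - L + 1L)
    if (hi < lo) stop("no window overlaps the allele")
    starts <- lo:hi
    rng <- .score_range(x)
    best <- list(score = -Inf)
    for (i in starts) {
      win <- substr(hap, i, i + L - 1L)
      for (strand in c("+", "-")) {
        w <- if (strand == "+") win else .revcomp(win)
        sc <- .raw_score(x, .seq_to_idx(w))
        if (sc > best$score) {
          best <- list(start = i - 1L, strand = strand, score = sc,
                       rel_score = unname((sc - rng["min"]) /
                                            (rng["max"] - rng["min"])),
                       window = win)
        }
      }
    }
    best
  }
  ref <- best_for(ref_allele)
  alt <- best_for(alt_allele)
  list(ref = ref, alt = alt,
       delta_rel_score = ref$rel_score - alt$rel_score)
}

#' Motif density profile around reference feature centers
#'
#' Histograms target-site positions at signed offsets from each reference
#' center within `+/- range_bp`, in windows of `window_bp`, and normalizes
#' globally — by the product of reference count, target count and window
#' width over the genome length — so that a uniformly distributed target
#' set gives fold change 1 in every bin.
#'
#' @param reference_centers integer positions of reference features.
#' @param target_sites integer positions of target features (e.g. motif
#'   match centers).
#' @param range_bp half-width of the profile (default 10000).
#' @param window_bp bin width (default 500); must divide `2 * range_bp`.
#' @param genome_length total genome length used for the uniform
#'   expectation.
#' @return object of class `density_profile`: data frame with
#'   `bin_center` (bp offset) and `fold_change`.
#' @export
density_profile <- function(reference_centers, target_sites,
                            range_bp = 10000L, window_bp = 500L,
                            genome_length) {
  stopifnot_scalar(genome_length, "genome_length", lo = 1)
  if ((2L * range_bp) %% window_bp != 0L) {
    stop("`window_bp` must divide 2 * range_bp")
  }
  n_ref <- length(reference_centers)
  n_tgt <- length(target_sites)
  breaks <- seq(-range_bp, range_bp, by = window_bp)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  counts <- numeric(length(centers))
  if (n_tgt == 0L) {
    warning("no target sites; all-zero profile")
  } else {
    tgt <- sort(as.numeric(target_sites))
    for (rc in reference_centers) {
      i0 <- findInterval(rc - range_bp, tgt, left.open = TRUE) + 1L
      i1 <- findInterval(rc + range_bp, tgt)
      if (i1 < i0) next
      off <- tgt[i0:i1] - rc
      bin <- pmin(pmax(floor((off + range_bp) / window_bp) + 1L, 1L),
                  length(centers))
      tb <- tabulate(bin, nbins = length(centers))
      counts <- counts + tb
    }
  }
  expected_per_bin <- n_ref * n_tgt * window_bp / genome_length
  fold <- if (expected_per_bin > 0) counts / expected_per_bin else counts
  structure(data.frame(bin_center = centers, fold_change = fold),
            class = c("density_profile", "data.frame"),
            range_bp = range_bp, window_bp = window_bp,
            n_reference = n_ref, n_target = n_tgt)
}
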