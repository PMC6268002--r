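# Position weight matrices: JASPAR PFM parsing, log-odds scoring, exact
# score-distribution p-values by dynamic-programming convolution, and
# column-shuffling controls.

.DNA <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' Counts are converted to probabilities with a pseudocount distributed
#' proportionally to the background composition, then to log2-odds against
#' that background.
#'
#' @param counts 4 x L non-negative matrix, rows A, C, G, T.
#' @param background length-4 base composition summing to 1 (default
#'   uniform; genome scans conventionally use the scan tool's stated
#'   composition, see [scan_sequences()]).
#' @param pseudocount total pseudocount added per column (default 0.8),
#'   split across bases proportionally to `background`.
#' @param id,name optional identifiers.
#' @return object of class `pwm` with `counts`, `prob`, `log_odds`,
#'   `background`, `pseudocount`, `length`.
#' @examples
#' m <- pwm(matrix(c(8, 0, 0, 0, 0, 0, 0, 8), nrow = 4,
#'                 dimnames = list(c("A", "C", "G", "T"), NULL)))
#' @export
pwm <- function(counts, background = rep(0.25, 4), pseudocount = 0.8,
                id = "motif", name = id) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("`counts` must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) stop("negative counts")
  if (ncol(counts) < 1L) stop("motif length must be >= 1")
  if (abs(sum(background) - 1) > 1e-9 || any(background <= 0)) {
    stop("`background` must be positive and sum to 1")
  }
  stopifnot_scalar(pseudocount, "pseudocount", lo = 0)
  if (pseudocount == 0 && any(counts == 0)) {
    stop("zero counts require pseudocount > 0 for finite log-odds")
  }
  rownames(counts) <- .DNA
  prob <- sweep(counts + pseudocount * background,
                2, colSums(counts) + pseudocount, "/")
  log_odds <- log2(prob / background)
  structure(list(counts = counts, prob = prob, log_odds = log_odds,
                 background = background, pseudocount = pseudocount,
                 length = ncol(counts), id = id, name = name),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': length %d, consensus %s\n", x$id, x$length,
              paste(.DNA[apply(x$counts, 2, which.max)], collapse = "")))
  invisible(x)
}

#' Parse a JASPAR-format position frequency matrix
#'
#' Accepts the JASPAR PFM text layout: a `>ID NAME` header followed by
#' four rows `A [ 3 10 ... ]` (brackets optional). Counts are preserved
#' exactly; [write_jaspar()] round-trips.
#'
#' @param text character vector of lines, a single string with newlines,
#'   or a file path.
#' @param ... passed to [pwm()] (background, pseudocount).
#' @return a [pwm()].
#' @export
parse_jaspar <- function(text, ...) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text)
  } else if (length(text) == 1L) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  text <- trimws(text)
  text <- text[nzchar(text)]
  id <- "motif"; name <- "motif"
  if (length(text) && startsWith(text[1], ">")) {
    hdr <- strsplit(sub("^>", "", text[1]), "\\s+")[[1]]
    id <- hdr[1]
    name <- if (length(hdr) > 1L) hdr[2] else id
    text <- text[-1]
  }
  if (length(text) != 4L) {
    stop("expected 4 base rows, found ", length(text))
  }
  rows <- lapply(text, function(line) {
    base <- toupper(sub("^([ACGTacgt]).*$", "\\1", line))
    if (!base %in% .DNA) stop("unknown base label in row: ", line)
    nums <- gsub("[][]", " ", sub("^[ACGTacgt]", "", line))
    vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
    if (anyNA(vals)) stop("non-numeric count in row for base ", base)
    if (any(vals < 0)) stop("negative count in row for base ", base)
    list(base = base, vals = vals)
  })
  bases <- vapply(rows, `[[`, character(1), "base")
  if (!setequal(bases, .DNA)) stop("rows must cover A, C, G, T exactly once")
  lens <- vapply(rows, function(r) length(r$vals), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("ragged rows: base ", rows[[which(lens != lens[1])[1]]]$base,
         " has ", lens[which(lens != lens[1])[1]], " columns, expected ",
         lens[1])
  }
  counts <- do.call(rbind, lapply(rows, `[[`, "vals"))
  rownames(counts) <- bases
  counts <- counts[.DNA, , drop = FALSE]
  pwm(counts, id = id, name = name, ...)
}

#' Write a PWM in JASPAR PFM format
#' @param x a [pwm()].
#' @param path optional output file; when `NULL` the lines are returned.
#' @return the text lines, invisibly when written to file.
#' @export
write_jaspar <- function(x, path = NULL) {
  lines <- c(
    sprintf(">%s %s", x$id, x$name),
    vapply(.DNA, function(b) {
      sprintf("%s [ %s ]", b,
              paste(format(x$counts[b, ], trim = TRUE), collapse = " "))
    }, character(1))
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

.seq_to_idx <- function(s) {
  v <- strsplit(toupper(s), "")[[1]]
  idx <- match(v, .DNA)
  if (anyNA(idx)) {
    stop("non-ACGT character '", v[which(is.na(idx))[1]], "' at position ",
         which(is.na(idx))[1])
  }
  idx
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# raw log2-odds score of an L-length window given base indices
.raw_score <- function(x, idx) sum(x$log_odds[cbind(idx, seq_along(idx))])

.score_range <- function(x) {
  c(min = sum(apply(x$log_odds, 2, min)), max = sum(apply(x$log_odds, 2, max)))
}

#' Relative PWM score of a window
#'
#' `(S - S_min) / (S_max - S_min)` where S is the summed log-odds of the
#' window and S_min/S_max are the minimal and maximal attainable sums.
#' The consensus sequence scores exactly 1, the anti-consensus exactly 0,
#' and the value is invariant to adding a constant to every column.
#'
#' @param x a [pwm()].
#' @param window sequence of length `x$length` over A/C/G/T.
#' @return score in `[0, 1]`.
#' @examples
#' m <- parse_jaspar(c(">toy toy", "A [ 9 0 ]", "C [ 0 9 ]",
#'                     "G [ 0 0 ]", "T [ 1 1 ]"))
#' relative_score(m, "AC")
#' @export
relative_score <- function(x, window) {
  idx <- .seq_to_idx(window)
  if (length(idx) != x$length) {
    stop("window length ", length(idx), " != motif length ", x$length)
  }
  rng <- .score_range(x)
  unname((.raw_score(x, idx) - rng["min"]) / (rng["max"] - rng["min"]))
}

#' Exact score distribution of a PWM under its background
#'
#' Distribution of the summed log-odds of a random L-mer drawn from the
#' background composition, computed exactly on an integer-discretized
#' score grid by convolving the per-column score distributions.
#'
#' @param x a [pwm()].
#' @param granularity discretization step on the log-odds scale
#'   (default 1e-3).
#' @return list with `score` (grid values) and `prob` (masses, sum 1).
#' @export
score_distribution <- function(x, granularity = 1e-3) {
  stopifnot_scalar(granularity, "granularity", lo = 1e-9)
  qcols <- round(x$log_odds / granularity)
  cur <- c(1)                    # mass vector; support offset tracked in cur_lo
  cur_lo <- 0L
  for (j in seq_len(ncol(qcols))) {
    col <- qcols[, j]
    new_lo <- cur_lo + min(col)
    new_hi <- cur_lo + length(cur) - 1L + max(col)
    nxt <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      sh <- cur_lo + col[b] - new_lo
      rng <- (sh + 1L):(sh + length(cur))
      nxt[rng] <- nxt[rng] + x$background[b] * cur
    }
    cur <- nxt
    cur_lo <- new_lo
  }
  list(score = (cur_lo + seq_along(cur) - 1L) * granularity, prob = cur,
       granularity = granularity)
}

#' Exact p-value of a raw PWM score
#'
#' `P(S >= s)` for a background-random L-mer, from the discretized exact
#' score distribution. Scores above the maximal attainable score return
#' the boundary mass `P(S = S_max)`; the minimal attainable score returns
#' p = 1.
#'
#' @param x a [pwm()].
#' @param score raw log2-odds score(s).
#' @param granularity discretization step (default 1e-3).
#' @param dist optional precomputed [score_distribution()].
#' @return p-value(s) in `(0, 1]`.
#' @export
score_pvalue <- function(x, score, granularity = 1e-3, dist = NULL) {
  if (is.null(dist)) dist <- score_distribution(x, granularity)
  tail_from <- rev(cumsum(rev(dist$prob)))
  vapply(unname(as.numeric(score)), function(s) {
    # half-step tolerance so scores on the grid are counted inclusively
    i <- which(dist$score >= s - dist$granularity / 2)[1]
    if (is.na(i)) return(dist$prob[length(dist$prob)])
    max(tail_from[i], .Machine$double.xmin)
  }, numeric(1))
}

#' Shuffle PWM columns (randomized-matrix control)
#'
#' Permutes the column order with a seeded RNG; the column multiset and
#' total information content are unchanged, destroying positional
#' structure while preserving base composition.
#'
#' @param x a [pwm()].
#' @param seed integer seed.
#' @return a [pwm()] with permuted columns.
#' @export
shuffle_pwm <- function(x, seed = 1L) {
  if (x$length < 2L) stop("motif length must be >= 2 to shuffle")
  perm <- withr::with_seed(as.integer(seed), sample.int(x$length))
  pwm(x$counts[, perm, drop = FALSE], background = x$background,
      pseudocount = x$pseudocount, id = paste0(x$id, "_shuffled"),
      name = x$name)
}

#' Total information content of a PWM (bits)
#' @param x a [pwm()].
#' @return sum over columns of `2 + sum(p log2 p)`.
#' @export
pwm_information <- function(x) {
  sum(apply(x$prob, 2, function(p) 2 + sum(ifelse(p > 0, p * log2(p), 0))))
}
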