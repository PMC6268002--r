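# Locus container: the unit every fine-mapping engine consumes.

#' Bundle summary statistics, LD and annotations for one region
#'
#' @param stats a [summary_stats()] table.
#' @param ld LD matrix aligned with `stats` (same order).
#' @param annotations optional m x a binary annotation matrix.
#' @return object of class `locus`.
#' @examples
#' panel <- sim_haplotypes(200, 6, seed = 1)
#' pair <- sim_pair_scenario(panel,
#'   sim_scenario("pleiotropy", 3, 3, lambda_gwas = 5, lambda_eqtl = 5),
#'   seed = 2)
#' loc <- locus(pair$gwas, pair$ld)
#' @export
locus <- function(stats, ld, annotations = NULL) {
  if (!inherits(stats, "summary_stats")) stop("`stats` must be a summary_stats")
  ld <- as.matrix(ld)
  m <- nrow(stats)
  if (nrow(ld) != m || ncol(ld) != m) stop("`ld` must be m x m")
  if (!is.null(rownames(ld)) && !identical(rownames(ld), stats$id)) {
    stop("LD matrix variant ids do not match `stats$id` order")
  }
  if (max(abs(ld - t(ld))) > 1e-8) stop("`ld` must be symmetric")
  if (any(abs(diag(ld) - 1) > 1e-8)) stop("`ld` must have unit diagonal")
  if (!is.null(annotations)) {
    annotations <- as.matrix(annotations)
    if (nrow(annotations) != m) stop("`annotations` must have one row per SNP")
    if (!all(annotations %in% c(0, 1))) stop("`annotations` must be binary")
  }
  dimnames(ld) <- list(stats$id, stats$id)
  structure(list(stats = stats, ld = ld, annotations = annotations),
            class = "locus")
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("locus: %d SNPs, lead %s (p = %.3g)%s\n",
              nrow(x$stats), x$stats$id[which.min(x$stats$p)],
              min(x$stats$p),
              if (is.null(x$annotations)) "" else
                sprintf(", %d annotation(s)", ncol(x$annotations))))
  invisible(x)
}
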