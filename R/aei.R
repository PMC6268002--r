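# Allelic expression imbalance: calibration-curve fit from a TaqMan-style
# mixing series, correction and gDNA normalization of cDNA fluorescence
# ratios, and a cohort-level imbalance test. The same correction operation
# serves allele-specific ChIP ratios, with input DNA in the gDNA role.

#' Fit the allelic-ratio calibration curve
#'
#' Ordinary least-squares fit of measured log2 fluorescence ratio against
#' true log2 allele ratio from a mixing series (e.g. 4:1, 2:1, 1:1, 1:2,
#' 1:4, i.e. true log2 ratios 2, 1, 0, -1, -2).
#'
#' @param series data frame with columns `true_log2_ratio` and
#'   `measured_log2_ratio` (as produced by [sim_qpcr_series()]), with at
#'   least two distinct true ratios.
#' @return object of class `calibration_curve` with `slope`, `intercept`,
#'   `r_squared`, `n_points`.
#' @examples
#' fit_calibration(sim_qpcr_series(slope = 0.9, intercept = 0.1,
#'                                 noise_sd = 0, seed = 1))
#' @export
fit_calibration <- function(series) {
  need <- c("true_log2_ratio", "measured_log2_ratio")
  if (!all(need %in% names(series))) {
    stop("`series` needs columns: ", paste(need, collapse = ", "))
  }
  if (length(unique(series$true_log2_ratio)) < 2L) {
    stop("degenerate design: all true ratios identical")
  }
  fit <- stats::lm(measured_log2_ratio ~ true_log2_ratio, data = series)
  co <- stats::coef(fit)
  tss <- sum((series$measured_log2_ratio -
                mean(series$measured_log2_ratio))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 r_squared = r2, n_points = nrow(series)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve: slope %.4f, intercept %.4f, r2 %.4f (n=%d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Correct measured ratios by the calibration curve and normalize to gDNA
#'
#' Inverts the calibration (`corrected = (measured - intercept) / slope`)
#' for both the cDNA and the gDNA log2 fluorescence ratios, then forms
#' the normalized allelic ratio `2^(corrected_cdna - corrected_gdna)` on
#' the linear scale. A balanced heterozygote (cDNA ratio equal to gDNA
#' ratio) gives exactly 1.
#'
#' @param cdna_log2 measured cDNA log2 fluorescence ratio(s).
#' @param gdna_log2 measured gDNA log2 fluorescence ratio(s).
#' @param calib a [fit_calibration()] curve with non-zero slope.
#' @return normalized allelic ratio(s), linear scale, `> 0`.
#' @examples
#' cal <- list(slope = 1, intercept = 0)
#' correct_and_normalize(-1, 0, cal)  # 0.5
#' @export
correct_and_normalize <- function(cdna_log2, gdna_log2, calib) {
  if (calib$slope == 0) stop("calibration slope is zero")
  corr_c <- (cdna_log2 - calib$intercept) / calib$slope
  corr_g <- (gdna_log2 - calib$intercept) / calib$slope
  2^(corr_c - corr_g)
}

#' Cohort-level allelic imbalance test
#'
#' Tests whether the normalized allelic ratios of heterozygous samples
#' deviate from 1 (balance) via a one-sample test of the log2 ratios
#' against 0: Student's t by default, Wilcoxon signed-rank optionally.
#' Relabeling the alleles inverts every ratio and leaves the p-value
#' unchanged. Zero variance at ratio 1 is reported as "no evidence"
#' (p = 1).
#'
#' @param ratios normalized allelic ratios of heterozygous samples
#'   (length >= 2, all > 0).
#' @param genotype optional per-sample genotype codes; any value other
#'   than `"het"`/`"heterozygous"` raises an error (AEI is defined only
#'   for heterozygotes).
#' @param method `"t"` (default) or `"wilcoxon"`.
#' @return list with `mean_ratio` (geometric mean), `p_value`, `n`,
#'   `method`.
#' @export
cohort_imbalance_test <- function(ratios, genotype = NULL,
                                  method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  if (!is.null(genotype)) {
    ok <- tolower(genotype) %in% c("het", "heterozygous")
    if (!all(ok)) {
      stop("homozygous sample(s) present: ",
           paste(which(!ok), collapse = ", "),
           " (AEI is defined only for heterozygotes)")
    }
  }
  if (length(ratios) < 2L) stop("need >= 2 heterozygous samples")
  if (any(ratios <= 0)) stop("ratios must be positive")
  lr <- log2(ratios)
  if (stats::sd(lr) == 0) {
    p <- if (all(lr == 0)) 1 else 0  # identical non-unity ratios: degenerate
    return(list(mean_ratio = 2^mean(lr), p_value = p, n = length(ratios),
                method = method))
  }
  p <- if (method == "t") {
    stats::t.test(lr, mu = 0)$p.value
  } else {
    stats::wilcox.test(lr, mu = 0, exact = FALSE)$p.value
  }
  list(mean_ratio = 2^mean(lr), p_value = p, n = length(ratios),
       method = method)
}

#' Per-sample AEI quantification from a measurement table
#'
#' Applies [correct_and_normalize()] to each heterozygous sample's paired
#' gDNA/cDNA (or input/ChIP) log2 ratios and runs the cohort test.
#'
#' @param measurements data frame with columns `sample_id`, `genotype`,
#'   `assay` (two levels: the genomic baseline, e.g. `"gdna"` or
#'   `"input"`, and the expression/pulldown readout, e.g. `"cdna"` or
#'   `"chip"`), `log2_ratio`.
#' @param calib a calibration curve.
#' @param baseline,readout assay labels (defaults `"gdna"`, `"cdna"`).
#' @param method cohort test, see [cohort_imbalance_test()].
#' @return list with `samples` (data frame: sample_id, genotype,
#'   gdna_log2_ratio, cdna_log2_ratio, normalized_allelic_ratio) and
#'   `cohort` (test on heterozygous samples, `NULL` when fewer than 2).
#' @export
aei_quantify <- function(measurements, calib, baseline = "gdna",
                         readout = "cdna", method = "t") {
  need <- c("sample_id", "genotype", "assay", "log2_ratio")
  if (!all(need %in% names(measurements))) {
    stop("`measurements` needs columns: ", paste(need, collapse = ", "))
  }
  wide <- lapply(split(measurements, measurements$sample_id), function(d) {
    g <- d$log2_ratio[d$assay == baseline]
    c_ <- d$log2_ratio[d$assay == readout]
    if (length(g) != 1L || length(c_) != 1L) {
      stop("sample ", d$sample_id[1], " needs exactly one '", baseline,
           "' and one '", readout, "' measurement")
    }
    data.frame(sample_id = d$sample_id[1], genotype = d$genotype[1],
               gdna_log2_ratio = g, cdna_log2_ratio = c_,
               stringsAsFactors = FALSE)
  })
  wide <- do.call(rbind, wide)
  wide$normalized_allelic_ratio <- correct_and_normalize(
    wide$cdna_log2_ratio, wide$gdna_log2_ratio, calib)
  het <- tolower(wide$genotype) %in% c("het", "heterozygous")
  cohort <- if (sum(het) >= 2L) {
    cohort_imbalance_test(wide$normalized_allelic_ratio[het],
                          method = method)
  }
  rownames(wide) <- NULL
  list(samples = wide, cohort = cohort)
}
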