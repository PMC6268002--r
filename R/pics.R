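# Permutation-based probabilistic identification of causal SNPs: posterior
# probability that each LD partner of the lead SNP is the causal variant,
# with the lead association strength held fixed.

#' Empirical SD of -log10 p at an LD partner of a causal SNP
#'
#' Default dispersion model for the permutation draws:
#' `sd = sqrt(1 - |r|^6.4) * sqrt(S) / 2`, where `S` is the causal SNP's
#' association strength on the -log10 p scale. At |r| = 1 the partner's
#' association is fully determined (sd 0); as |r| drops the spread grows
#' toward `sqrt(S)/2`.
#'
#' @param r signed LD correlation with the causal SNP.
#' @param S association strength (-log10 p) at the causal SNP.
#' @return standard deviation on the -log10 p scale.
#' @export
pics_sd <- function(r, S) sqrt(pmax(1 - abs(r)^6.4, 0)) * sqrt(S) / 2

#' PICS-style posterior causal probabilities at one locus
#'
#' For each candidate causal SNP `j` (every SNP with `r^2 > r2_min` to the
#' lead, the lead itself included), `n_perm` association profiles are
#' simulated under the hypothesis "j is causal at the observed lead
#' strength S": SNP `i` draws its -log10 p from
#' `Normal(r2[i, j] * S, sd_model(r[i, j], S))`. The likelihood of the
#' observed profile under each hypothesis is estimated from these draws
#' (per-SNP Gaussian kernel density with Silverman bandwidth, independence
#' approximation across SNPs) and posteriors follow Bayes' rule with equal
#' priors over candidates. A closed-form variant (`method = "normal"`)
#' evaluates the Normal density directly instead of the kernel estimate;
#' the two must agree in ranking.
#'
#' @param loc a [locus()].
#' @param lead_idx index of the lead SNP; defaults to the SNP with the
#'   maximal -log10 p, which is also required.
#' @param n_perm number of permutation draws per hypothesis (default
#'   10000); at least 100.
#' @param r2_min candidate-set threshold: SNPs with `r^2 > r2_min` to the
#'   lead enter (default 0.5).
#' @param seed integer seed.
#' @param sd_model dispersion callable `function(r, S)`; default [pics_sd()].
#' @param sd_floor lower bound on the per-SNP dispersion (default 0.05 on
#'   the -log10 p scale). At `|r| = 1` the model's dispersion is exactly 0
#'   and any mismatch between the observed and hypothesized profile —
#'   including the slight non-quadratic mapping between z and -log10 p —
#'   would annihilate a hypothesis; the floor keeps likelihoods finite
#'   without materially affecting non-degenerate dispersions (~ sqrt(S)/2).
#' @param method `"kde"` (permutation kernel density, default) or
#'   `"normal"` (closed-form density, no permutations).
#' @return object of class `pics_result`: a data frame with `id`,
#'   `r2_to_lead`, `pics_probability` (0 outside the candidate set),
#'   ordered by probability then r2 then id, with attributes `lead`,
#'   `n_permutations`, `seed`.
#' @examples
#' panel <- sim_haplotypes(500, 5, rho = 0.9, seed = 1)
#' pair <- sim_pair_scenario(panel,
#'   sim_scenario("pleiotropy", 3, 3, lambda_gwas = 7, lambda_eqtl = 7),
#'   seed = 2)
#' pics_posterior(locus(pair$gwas, pair$ld), n_perm = 500, seed = 3)
#' @export
pics_posterior <- function(loc, lead_idx = NULL, n_perm = 10000L,
                           r2_min = 0.5, seed = 1L, sd_model = pics_sd,
                           sd_floor = 0.05, method = c("kde", "normal")) {
  method <- match.arg(method)
  if (n_perm < 100L) stop("`n_perm` must be >= 100")
  stopifnot_scalar(r2_min, "r2_min", lo = 0, hi = 1)
  stats_tab <- loc$stats
  mlp <- -log10(stats_tab$p)
  if (is.null(lead_idx)) lead_idx <- which.max(mlp)
  if (mlp[lead_idx] < max(mlp) - 1e-9) {
    stop("lead SNP must carry the maximal -log10 p in the locus")
  }
  m <- nrow(stats_tab)
  r_lead <- loc$ld[, lead_idx]
  candidates <- which(r_lead^2 > r2_min | seq_len(m) == lead_idx)
  prob <- numeric(m)
  if (length(candidates) == 1L) {
    prob[lead_idx] <- 1
  } else {
    S <- mlp[lead_idx]
    obs <- mlp[candidates]
    Rc <- loc$ld[candidates, candidates, drop = FALSE]
    loglik <- withr::with_seed(as.integer(seed), {
      vapply(seq_along(candidates), function(jj) {
        r_ij <- Rc[, jj]
        mu <- r_ij^2 * S
        sdv <- pmax(sd_model(r_ij, S), sd_floor)
        if (method == "normal") {
          sum(stats::dnorm(obs, mu, sdv, log = TRUE))
        } else {
          sum(vapply(seq_along(obs), function(ii) {
            draws <- stats::rnorm(n_perm, mu[ii], sdv[ii])
            bw <- .silverman_bw(draws)
            log(max(mean(stats::dnorm(obs[ii], draws, bw)),
                    .Machine$double.xmin))
          }, numeric(1)))
        }
      }, numeric(1))
    })
    prob[candidates] <- exp(loglik - logsumexp(loglik))
  }
  r2 <- r_lead^2
  out <- data.frame(id = stats_tab$id, r2_to_lead = r2,
                    pics_probability = prob, stringsAsFactors = FALSE)
  out <- out[order(-out$pics_probability, -out$r2_to_lead, out$id), ]
  rownames(out) <- NULL
  structure(out, class = c("pics_result", "data.frame"),
            lead = stats_tab$id[lead_idx],
            n_permutations = as.integer(n_perm), seed = as.integer(seed))
}

# Silverman's rule-of-thumb bandwidth with a floor so degenerate draw sets
# (perfect LD: all draws identical) still yield a proper density
.silverman_bw <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  iqr <- stats::IQR(x) / 1.349
  spread <- min(s, if (iqr > 0) iqr else s)
  max(0.9 * spread * n^(-1 / 5), 1e-8)
}

#' Write PICS probabilities as TSV (id, r2_to_lead, pics_probability)
#' @param result a `pics_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pics <- function(result, path) {
  utils::write.table(as.data.frame(result), path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
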