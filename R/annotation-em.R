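# Annotation-informed empirical-Bayes fine-mapping: multivariate-normal
# locus likelihood with plug-in non-centrality, logistic annotation prior
# per SNP, and an EM loop over loci that learns the annotation enrichment
# (log-odds) coefficients from the data.

#' Multivariate-normal locus log-likelihood of a causal configuration
#'
#' Density of the observed z-vector under mean `Sigma (lambda * C)` and
#' covariance `Sigma`. The non-centrality at causal SNPs is plugged in as
#' the observed z there (`lambda_j = z_j`), the standard plug-in practice;
#' a prior-integrated alternative is available through
#' [config_log_bf()]'s covariance form.
#'
#' @param z observed z-scores.
#' @param ld LD matrix.
#' @param config a [causal_config()]; if its `lambda` is all zero at causal
#'   SNPs, the plug-in `lambda_j = z_j` is used.
#' @return log density.
#' @export
locus_loglik <- function(z, ld, config) {
  ld <- as.matrix(ld)
  m <- length(z)
  if (!all(is.finite(z))) stop("non-finite z-scores")
  if (length(config$c) != m || nrow(ld) != m) stop("dimension mismatch")
  lam <- config$lambda
  causal <- config$c == 1L
  if (any(causal) && all(lam[causal] == 0)) lam[causal] <- z[causal]
  mu <- as.numeric(ld %*% (lam * config$c))
  R <- chol_safe(ld)
  logdmvn_chol(z, mu, R)
}

#' Logistic annotation enrichment model
#'
#' @param gamma numeric vector: intercept followed by one log-odds
#'   coefficient per annotation.
#' @param annotation_names optional names for the annotation coefficients.
#' @return object of class `enrichment_model`.
#' @export
enrichment_model <- function(gamma, annotation_names = NULL) {
  if (!all(is.finite(gamma))) stop("gamma must be finite")
  names(gamma) <- c("(Intercept)",
                    annotation_names %||% sprintf("annot%d", seq_len(length(gamma) - 1L)))
  structure(list(gamma = gamma), class = "enrichment_model")
}

# per-SNP prior causal probability under the logistic model
.snp_prior <- function(annots, model) {
  X <- cbind(1, as.matrix(annots))
  stats::plogis(drop(X %*% model$gamma))
}

#' Prior probability of a causal configuration under annotation enrichment
#'
#' Product over SNPs of `plogis(gamma . [1, A_j])` for causal SNPs and its
#' complement for non-causal SNPs.
#'
#' @param config a [causal_config()].
#' @param annots m x a binary annotation matrix.
#' @param model an [enrichment_model()].
#' @param log return the log prior.
#' @return prior probability (or log prior).
#' @export
prior_config <- function(config, annots, model, log = FALSE) {
  p <- .snp_prior(annots, model)
  lp <- sum(ifelse(config$c == 1L, log(p), log1p(-p)))
  if (log) lp else exp(lp)
}

# Plug-in log-likelihoods of a configuration list, relative computation:
# with lambda_c = z_c, the density simplifies to
#   loglik(null) + sum(z_c^2) - z_c' Sigma_cc z_c / 2,
# so only the null density needs the m x m factorization.
.config_logliks <- function(z, ld, idx_list) {
  m <- length(z)
  R <- chol_safe(ld)
  ll0 <- logdmvn_chol(z, rep(0, m), R)
  vapply(idx_list, function(idx) {
    if (!length(idx)) return(ll0)
    zc <- z[idx]
    ll0 + sum(zc^2) -
      0.5 * drop(crossprod(zc, ld[idx, idx, drop = FALSE] %*% zc))
  }, numeric(1))
}

# E-step for one locus: per-SNP posterior causal probabilities and the
# marginal log-likelihood, enumerating configurations with k <= k_max
.locus_estep <- function(z, ld, annots, model, k_max, idx_list = NULL,
                         logliks = NULL) {
  m <- length(z)
  if (is.null(idx_list)) idx_list <- .enumerate_configs(m, k_max)
  if (is.null(logliks)) logliks <- .config_logliks(z, ld, idx_list)
  p <- .snp_prior(annots, model)
  lp_snp1 <- log(p); lp_snp0 <- log1p(-p)
  base <- sum(lp_snp0)
  logw <- vapply(seq_along(idx_list), function(i) {
    idx <- idx_list[[i]]
    base + sum(lp_snp1[idx] - lp_snp0[idx]) + logliks[i]
  }, numeric(1))
  lz <- logsumexp(logw)
  w <- exp(logw - lz)
  q <- numeric(m)
  for (i in seq_along(idx_list)) {
    if (length(idx_list[[i]])) q[idx_list[[i]]] <- q[idx_list[[i]]] + w[i]
  }
  list(q = q, logmarg = lz, post = w, idx_list = idx_list)
}

# weighted logistic M-step: maximize sum_j q_j log p_j + (1-q_j) log(1-p_j)
# by Newton-Raphson with step halving; coefficients clipped at +/- clip
.mstep_logistic <- function(q, X, gamma0, clip = 10, tol = 1e-6,
                            max_iter = 50L) {
  obj <- function(g) {
    eta <- drop(X %*% g)
    sum(q * eta - log1p(exp(eta)))
  }
  g <- gamma0
  f <- obj(g)
  for (it in seq_len(max_iter)) {
    mu <- stats::plogis(drop(X %*% g))
    grad <- drop(crossprod(X, q - mu))
    W <- mu * (1 - mu)
    H <- crossprod(X * W, X)
    step <- tryCatch(solve(H + diag(1e-8, ncol(X)), grad),
                     error = function(e) grad * 0.1)
    # step halving: accept only improving (or equal) moves
    lambda_step <- 1
    repeat {
      g_new <- pmin(pmax(g + lambda_step * step, -clip), clip)
      f_new <- obj(g_new)
      if (f_new >= f - 1e-12 || lambda_step < 1e-6) break
      lambda_step <- lambda_step / 2
    }
    moved <- max(abs(g_new - g))
    g <- g_new; f <- f_new
    if (moved < tol) break
  }
  clipped <- any(abs(g) >= clip - 1e-9)
  list(gamma = g, hessian = {
    mu <- stats::plogis(drop(X %*% g))
    crossprod(X * (mu * (1 - mu)), X)
  }, clipped = clipped)
}

#' Empirical-Bayes EM fit of annotation enrichment across loci
#'
#' Alternates an E-step — per-locus posterior over causal configurations
#' with `k <= k_max`, prior [prior_config()] times likelihood
#' `exp(locus_loglik)` — with an M-step that refits the logistic
#' enrichment coefficients by weighted logistic regression of the per-SNP
#' posterior causal probabilities on the annotations. The marginal
#' log-likelihood is non-decreasing across iterations; convergence is
#' declared when its change drops below `tol`.
#'
#' @param loci list of [locus()] objects, each carrying the same
#'   annotation columns; at least 2 for a stable enrichment estimate.
#' @param k_max maximum causal SNPs per configuration in the enumeration
#'   (default 2).
#' @param tol convergence tolerance on the marginal log-likelihood change
#'   (default 1e-4).
#' @param max_iter maximum EM iterations (default 50).
#' @return list with `model` (an `enrichment_model` plus `se` from the
#'   observed information, `iterations`, `loglik_trace`, `converged`,
#'   `clipped`) and `pips` (list of per-locus named PIP vectors).
#' @examples
#' loci <- lapply(1:3, function(s) {
#'   panel <- sim_haplotypes(200, 6, rho = 0.7, seed = s)
#'   cfg <- causal_config(6, (s %% 6) + 1, 6)
#'   pair <- sim_pair_scenario(panel,
#'     sim_scenario("pleiotropy", (s %% 6) + 1, (s %% 6) + 1,
#'                  lambda_gwas = 6, lambda_eqtl = 6), seed = s + 100)
#'   locus(pair$gwas, pair$ld, sim_annotations(cfg, -2, 2, seed = s))
#' })
#' fit <- em_fit(loci, k_max = 1, max_iter = 5)
#' @export
em_fit <- function(loci, k_max = 2L, tol = 1e-4, max_iter = 50L) {
  if (length(loci) < 2L) stop("need >= 2 loci for a stable enrichment fit")
  a_set <- vapply(loci, function(l) {
    if (is.null(l$annotations)) stop("every locus needs annotations")
    ncol(l$annotations)
  }, integer(1))
  if (length(unique(a_set)) != 1L) stop("loci must share the annotation set")
  a <- a_set[1]
  Xs <- lapply(loci, function(l) cbind(1, as.matrix(l$annotations)))
  Xall <- do.call(rbind, Xs)
  idx_lists <- lapply(loci, function(l)
    .enumerate_configs(nrow(l$stats), min(k_max, nrow(l$stats))))
  # likelihoods do not depend on gamma: compute once, reuse every iteration
  loglik_lists <- Map(function(l, il) .config_logliks(l$stats$z, l$ld, il),
                      loci, idx_lists)
  # initialize: baseline causal rate ~ 1 / average locus size, no enrichment
  m_bar <- mean(vapply(loci, function(l) nrow(l$stats), integer(1)))
  gamma <- c(stats::qlogis(1 / (m_bar + 1)), rep(0, a))
  model <- enrichment_model(gamma,
                            colnames(loci[[1]]$annotations))
  trace <- numeric(0)
  converged <- FALSE
  clipped <- FALSE
  mres <- NULL
  for (iter in seq_len(max_iter)) {
    es <- Map(function(l, il, ll) .locus_estep(l$stats$z, l$ld,
                                               l$annotations, model,
                                               k_max, il, ll),
              loci, idx_lists, loglik_lists)
    ll <- sum(vapply(es, `[[`, numeric(1), "logmarg"))
    trace <- c(trace, ll)
    if (iter > 1L && ll - trace[iter - 1L] < tol) {
      converged <- TRUE
      break
    }
    q_all <- unlist(lapply(es, `[[`, "q"))
    mres <- .mstep_logistic(q_all, Xall, model$gamma)
    clipped <- clipped || mres$clipped
    model <- enrichment_model(mres$gamma, colnames(loci[[1]]$annotations))
  }
  if (clipped) {
    warning("separation detected: enrichment coefficients clipped at +/-10")
  }
  if (!converged) warning("EM did not converge in ", max_iter, " iterations")
  # final E-step under the returned model (PIPs consistent with gamma)
  es <- Map(function(l, il) .locus_estep(l$stats$z, l$ld, l$annotations,
                                         model, k_max, il),
            loci, idx_lists)
  pips <- lapply(seq_along(loci), function(i) {
    q <- es[[i]]$q
    names(q) <- loci[[i]]$stats$id
    q
  })
  se <- tryCatch(sqrt(diag(solve(mres$hessian %||% diag(a + 1L)))),
                 error = function(e) rep(NA_real_, a + 1L))
  model$se <- se
  model$iterations <- length(trace)
  model$loglik_trace <- trace
  model$converged <- converged
  model$clipped <- clipped
  list(model = model, pips = pips)
}

#' @export
print.enrichment_model <- function(x, ...) {
  cat("enrichment_model (logistic causal prior):\n")
  print(x$gamma)
  invisible(x)
}

#' Write annotation-informed PIPs and the enrichment report as TSV
#' @param fit result of [em_fit()].
#' @param pip_path per-SNP TSV (locus, id, pip).
#' @param enrich_path enrichment TSV (annotation, gamma, se).
#' @return `pip_path`, invisibly.
#' @export
write_enrichment <- function(fit, pip_path, enrich_path = NULL) {
  tabs <- lapply(seq_along(fit$pips), function(i) {
    data.frame(locus = i, id = names(fit$pips[[i]]),
               pip = unname(fit$pips[[i]]))
  })
  utils::write.table(do.call(rbind, tabs), pip_path, quote = FALSE,
                     sep = "\t", row.names = FALSE)
  if (!is.null(enrich_path)) {
    g <- fit$model$gamma
    utils::write.table(
      data.frame(annotation = names(g), gamma = unname(g),
                 se = fit$model$se %||% NA_real_),
      enrich_path, quote = FALSE, sep = "\t", row.names = FALSE)
  }
  invisible(pip_path)
}
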