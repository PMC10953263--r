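#' Wakefield approximate Bayes factor
#'
#' Per-SNP evidence for association from an estimate and its standard
#' error under a normal prior on the true effect with scale `prior_sd`.
#' With \eqn{z = \beta/se} and shrinkage
#' \eqn{r = prior\_sd^2/(prior\_sd^2 + se^2)}:
#' \deqn{\log ABF = \tfrac12 \log(1 - r) + \tfrac12 z^2 r.}
#'
#' @param beta,se association estimate and standard error (`se > 0`).
#' @param prior_sd prior standard deviation of the true effect (> 0).
#' @return log approximate Bayes factor (vectorised).
#' @export
wakefield_log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop_mr("se must be positive")
  if (any(prior_sd <= 0)) stop_mr("prior_sd must be positive")
  z <- beta / se
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  0.5 * log1p(-r) + 0.5 * z^2 * r
}

#' Bayesian colocalization of two traits over one region
#'
#' Enumerates the five single-causal-variant hypotheses for a cis region —
#' H0 no association with either trait, H1/H2 association with one trait
#' only, H3 both traits with distinct causal variants, H4 a shared causal
#' variant — from per-SNP Wakefield log approximate Bayes factors, and
#' returns posterior probabilities PP0..PP4. All sums are computed in log
#' space with log-sum-exp, so z-scores of large magnitude do not overflow.
#'
#' The hypothesis sums are \eqn{L_1 = \sum_j ABF^{(1)}_j},
#' \eqn{L_2 = \sum_j ABF^{(2)}_j},
#' \eqn{L_4 = \sum_j ABF^{(1)}_j ABF^{(2)}_j}, and
#' \eqn{L_3 = L_1 L_2 - L_4} (the sum over distinct pairs); unnormalized
#' posteriors are \eqn{(1,\; p_1 L_1,\; p_2 L_2,\; p_1 p_2 L_3,\; p_{12} L_4)}.
#'
#' @param trait1,trait2 GWAS tables covering the identical SNP set in the
#'   identical order (harmonize first).
#' @param p1,p2 prior probability a SNP is causal for trait 1 (2) only.
#'   Defaults `1e-4`.
#' @param p12 prior probability a SNP is causal for both. Default `1e-5`.
#' @param prior_sd1,prior_sd2 prior effect scales per trait; 0.15 is the
#'   conventional quantitative-trait choice, 0.2 suits log-odds estimates.
#' @return object of class `coloc_result`: list with `pp` (named PP0..PP4,
#'   summing to 1), `n_snps`, `log_abf_trait1`, `log_abf_trait2`, `priors`.
#' @export
coloc_abf <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd1 = 0.15, prior_sd2 = 0.15) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, p12 > 0, p12 < 1)
  if (nrow(trait1) != nrow(trait2) || any(trait1$SNP != trait2$SNP))
    stop_mr("trait1 and trait2 must cover the identical SNP set in identical order")
  l1 <- wakefield_log_abf(trait1$BETA, trait1$SE, prior_sd1)
  l2 <- wakefield_log_abf(trait2$BETA, trait2$SE, prior_sd2)
  lH1 <- logsumexp(l1)
  lH2 <- logsumexp(l2)
  lH4 <- logsumexp(l1 + l2)
  # L3 = L1*L2 - L4, all positive; in log space via log1p of the ratio
  if (length(l1) == 1L) {
    lH3 <- -Inf
  } else {
    d <- lH4 - (lH1 + lH2)             # log(L4/(L1*L2)) in (-Inf, 0]
    lH3 <- if (d >= 0) -Inf else lH1 + lH2 + log1p(-exp(d))
  }
  lpost <- c(0,
             log(p1) + lH1,
             log(p2) + lH2,
             log(p1) + log(p2) + lH3,
             log(p12) + lH4)
  pp <- exp(lpost - logsumexp(lpost))
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP", 0:4)
  structure(list(pp = pp, n_snps = length(l1),
                 log_abf_trait1 = l1, log_abf_trait2 = l2,
                 priors = c(p1 = p1, p2 = p2, p12 = p12)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization over %d SNP(s)  (p1=%g, p2=%g, p12=%g)\n",
              x$n_snps, x$priors["p1"], x$priors["p2"], x$priors["p12"]))
  print(round(x$pp, 4))
  cat(sprintf("Shared-causal-variant posterior PP4 = %.3f\n", x$pp["PP4"]))
  invisible(x)
}

#' Colocalization decision rule
#'
#' TRUE iff the shared-causal-variant posterior PP4 strictly exceeds the
#' threshold (default 70%, the gate used to accept a drug-target locus).
#'
#' @param result a [coloc_abf()] result.
#' @param threshold posterior probability gate. Default `0.70`.
#' @return logical.
#' @export
coloc_decision <- function(result, threshold = 0.70) {
  stopifnot(inherits(result, "coloc_result"))
  unname(result$pp["PP4"] > threshold)
}
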