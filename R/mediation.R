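#' Product-of-coefficients indirect effect
#'
#' The indirect (mediated) effect of an exposure on an outcome through a
#' mediator is the product \eqn{\beta_1 \beta_2} of the
#' exposure-to-mediator and mediator-to-outcome path effects. The default
#' standard error is the first-order product delta approximation
#' \eqn{\sqrt{\beta_1^2 se_2^2 + \beta_2^2 se_1^2}}, assuming independence
#' of the two path estimates (distinct instrument sets, non-overlapping
#' samples); `second_order = TRUE` adds the \eqn{se_1^2 se_2^2} term.
#'
#' @param beta1,se1 exposure-to-mediator effect and standard error.
#' @param beta2,se2 mediator-to-outcome effect and standard error.
#' @param second_order include the second-order variance term.
#' @return list with `indirect` and `se`.
#' @export
indirect_effect <- function(beta1, se1, beta2, se2, second_order = FALSE) {
  stopifnot(is.finite(beta1), is.finite(beta2), se1 >= 0, se2 >= 0)
  v <- beta1^2 * se2^2 + beta2^2 * se1^2
  if (second_order) v <- v + se1^2 * se2^2
  list(indirect = beta1 * beta2, se = sqrt(v))
}

#' Proportion mediated with delta-method confidence interval
#'
#' The proportion of the total effect \eqn{\alpha} carried through the
#' mediator is \eqn{indirect/\alpha}. Its variance by the first-order
#' ratio delta method (independence assumed) is
#' \deqn{var \approx \frac{se_{ind}^2}{\alpha^2} +
#'   \frac{indirect^2\, se_\alpha^2}{\alpha^4},}
#' giving a symmetric 95% normal interval and a two-sided normal p-value
#' for proportion \eqn{\ne} 0. A proportion outside \[-1, 1\] flags
#' inconsistent mediation (warning, not an error).
#'
#' @param indirect,indirect_se indirect effect and standard error.
#' @param alpha,alpha_se total effect and standard error (`alpha != 0`).
#' @return list with `proportion`, `se`, `ci` (length-2), `pval`,
#'   `inconsistent` flag.
#' @export
proportion_mediated <- function(indirect, indirect_se, alpha, alpha_se) {
  if (alpha == 0) stop_mr("proportion mediated undefined for alpha = 0")
  prop <- indirect / alpha
  v <- indirect_se^2 / alpha^2 + indirect^2 * alpha_se^2 / alpha^4
  se <- sqrt(v)
  inconsistent <- abs(prop) > 1
  if (inconsistent)
    warn_mr("proportion mediated %.3g outside [-1,1]: inconsistent mediation", prop)
  list(proportion = prop, se = se,
       ci = c(prop - Z95 * se, prop + Z95 * se),
       pval = z_pval(prop / se), inconsistent = inconsistent)
}

#' Two-step MR mediation analysis
#'
#' Decomposes the total causal effect of the exposure on the outcome into
#' direct and indirect components through one mediator, using three
#' univariable IVW fits on summary statistics:
#' step 1 regresses the mediator on the exposure's instruments
#' (\eqn{\beta_1}); step 2 regresses the outcome on the *mediator's own*
#' instruments (\eqn{\beta_2}); the total effect \eqn{\alpha} comes from
#' the exposure's instruments against the outcome. The indirect effect is
#' \eqn{\beta_1\beta_2} and the proportion mediated
#' \eqn{\beta_1\beta_2/\alpha}, both with delta-method uncertainty.
#'
#' @param exposure_instruments an `instrument_set` (or GWAS table) of the
#'   exposure's instruments with their exposure associations.
#' @param mediator_stats GWAS table of mediator associations (must cover
#'   the exposure instruments).
#' @param mediator_instruments an `instrument_set` (or GWAS table) of the
#'   mediator's own instruments with their mediator associations.
#' @param outcome_stats GWAS table of outcome associations (must cover
#'   both instrument sets).
#' @param exposure_stats optional GWAS table of exposure associations; by
#'   default the exposure instruments' records are used.
#' @param invert_exposure negate exposure effects (inhibition-proxy
#'   orientation); applied to steps 1 and the total effect.
#' @return object of class `mediation_result`: list with `alpha`,
#'   `alpha_se`, `beta1`, `beta1_se`, `beta2`, `beta2_se`, `indirect`,
#'   `indirect_se`, `indirect_ci`, `proportion`, `proportion_se`,
#'   `proportion_ci`, `proportion_pval`, `direct`, `fits` (the three
#'   underlying `mr_result`s).
#' @export
two_step_mr <- function(exposure_instruments, mediator_stats,
                        mediator_instruments, outcome_stats,
                        exposure_stats = NULL, invert_exposure = FALSE) {
  exp_rec <- instrument_records(exposure_instruments)
  med_rec <- instrument_records(mediator_instruments)
  if (!is.null(exposure_stats))
    exp_rec <- exposure_stats[exposure_stats$SNP %in% exp_rec$SNP, , drop = FALSE]

  fit_step <- function(inst, stats_tab, label) {
    h <- tryCatch(harmonize(inst, stats_tab),
                  error = function(e) stop_mr("%s: %s", label, conditionMessage(e)))
    if (invert_exposure && label != "step2 (mediator->outcome)")
      h$beta_exp <- -h$beta_exp
    if (length(h$beta_exp) >= 2) mr_ivw(h)
    else wald_ratio(h$beta_exp, h$se_exp, h$beta_out, h$se_out)
  }
  f1 <- fit_step(exp_rec, mediator_stats, "step1 (exposure->mediator)")
  f2 <- fit_step(med_rec, outcome_stats, "step2 (mediator->outcome)")
  fa <- fit_step(exp_rec, outcome_stats, "total (exposure->outcome)")

  ind <- indirect_effect(f1$beta, f1$se, f2$beta, f2$se)
  pm <- proportion_mediated(ind$indirect, ind$se, fa$beta, fa$se)
  structure(list(
    alpha = fa$beta, alpha_se = fa$se,
    beta1 = f1$beta, beta1_se = f1$se,
    beta2 = f2$beta, beta2_se = f2$se,
    indirect = ind$indirect, indirect_se = ind$se,
    indirect_ci = c(ind$indirect - Z95 * ind$se, ind$indirect + Z95 * ind$se),
    proportion = pm$proportion, proportion_se = pm$se,
    proportion_ci = pm$ci, proportion_pval = pm$pval,
    inconsistent = pm$inconsistent,
    direct = fa$beta - ind$indirect,
    fits = list(step1 = f1, step2 = f2, total = fa)
  ), class = "mediation_result")
}

instrument_records <- function(x) {
  if (inherits(x, "instrument_set")) x$records
  else if (is.data.frame(x)) x
  else stop_mr("expected an instrument_set or a GWAS table")
}

#' @export
print.mediation_result <- function(x, digits = 4, ...) {
  cat("Two-step MR mediation\n")
  cat(sprintf("  total effect alpha      = %.*g (se %.3g)\n", digits, x$alpha, x$alpha_se))
  cat(sprintf("  exposure->mediator b1   = %.*g (se %.3g)\n", digits, x$beta1, x$beta1_se))
  cat(sprintf("  mediator->outcome  b2   = %.*g (se %.3g)\n", digits, x$beta2, x$beta2_se))
  cat(sprintf("  indirect effect b1*b2   = %.*g [%.4g, %.4g]\n", digits,
              x$indirect, x$indirect_ci[1], x$indirect_ci[2]))
  cat(sprintf("  direct effect           = %.*g\n", digits, x$direct))
  cat(sprintf("  proportion mediated     = %.1f%% [%.1f%%, %.1f%%], p = %.3g\n",
              100 * x$proportion, 100 * x$proportion_ci[1],
              100 * x$proportion_ci[2], x$proportion_pval))
  if (isTRUE(x$inconsistent)) cat("  (flag: inconsistent mediation, |proportion| > 1)\n")
  invisible(x)
}
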