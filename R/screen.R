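#' Bonferroni-corrected significance threshold
#'
#' Returns `alpha/m` exactly (unrounded); display layers round for
#' printing, the gate itself never does. With 249 metabolites at
#' alpha = 0.05 the threshold is 2.008e-4; with 9 survivors it is
#' 5.556e-3.
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param m number of tests (>= 1).
#' @return numeric threshold.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1)
  if (!is.finite(m) || m < 1) stop_mr("m must be a positive count")
  alpha / m
}

#' Bonferroni-screened metabolite mediator scan
#'
#' The two-step screen for candidate mediators between an exposure and an
#' outcome. Step 1 fits IVW MR of the exposure on each of the M candidate
#' metabolites and keeps those with p below `alpha/M`. Step 2 fits IVW MR
#' of each survivor on the outcome using the metabolite's own instruments
#' and keeps those with p below `alpha/K`, K being the observed number of
#' step-1 survivors (never a constant). Metabolites passing both gates get
#' a full [two_step_mr()] mediation decomposition. Step-1 significance
#' gates on the IVW p-value, the primary estimator. The sign consistency
#' of the indirect path with the total effect is recorded
#' (`direction_consistent`) but does not gate inclusion.
#'
#' @param exposure_instruments `instrument_set` (or GWAS table) for the
#'   exposure.
#' @param metabolite_stats named list of GWAS tables, one per metabolite
#'   (associations at the exposure's instruments at minimum).
#' @param metabolite_instruments named list of `instrument_set`s (or GWAS
#'   tables), one per metabolite, used at step 2; a survivor without
#'   instruments is flagged, not fatal.
#' @param outcome_stats GWAS table of outcome associations.
#' @param exposure_stats optional exposure GWAS table (see [two_step_mr()]).
#' @param alpha family-wise error rate. Default 0.05.
#' @param invert_exposure inhibition-proxy orientation (see [mr_fit()]).
#' @return object of class `mr_screen`: a data frame with one row per
#'   metabolite (`metabolite_id`, `step1_beta`, `step1_se`, `step1_p`,
#'   `step1_pass`, `step2_beta`, `step2_se`, `step2_p`, `step2_pass`,
#'   `direction_consistent`, `proportion`, `proportion_lo`,
#'   `proportion_hi`, `note`) and attributes `M`, `K`,
#'   `step1_threshold`, `step2_threshold`, `mediation` (named list of
#'   `mediation_result`s for double-passers).
#' @export
run_screen <- function(exposure_instruments, metabolite_stats,
                       metabolite_instruments, outcome_stats,
                       exposure_stats = NULL, alpha = 0.05,
                       invert_exposure = FALSE) {
  ids <- names(metabolite_stats)
  if (is.null(ids) || any(ids == ""))
    stop_mr("metabolite_stats must be a named list")
  M <- length(ids)
  thr1 <- bonferroni_threshold(alpha, M)
  exp_rec <- instrument_records(exposure_instruments)
  if (!is.null(exposure_stats))
    exp_rec <- exposure_stats[exposure_stats$SNP %in% exp_rec$SNP, , drop = FALSE]

  step1 <- lapply(ids, function(id) {
    h <- harmonize(exp_rec, metabolite_stats[[id]])
    if (invert_exposure) h$beta_exp <- -h$beta_exp
    if (length(h$beta_exp) >= 2) mr_ivw(h)
    else wald_ratio(h$beta_exp, h$se_exp, h$beta_out, h$se_out)
  })
  names(step1) <- ids
  p1 <- vapply(step1, `[[`, numeric(1), "pval")
  pass1 <- p1 < thr1
  K <- sum(pass1)
  thr2 <- if (K > 0) bonferroni_threshold(alpha, K) else NA_real_

  rows <- lapply(ids, function(id) {
    f1 <- step1[[id]]
    row <- data.frame(metabolite_id = id, step1_beta = f1$beta,
                      step1_se = f1$se, step1_p = f1$pval,
                      step1_pass = pass1[[id]],
                      step2_beta = NA_real_, step2_se = NA_real_,
                      step2_p = NA_real_, step2_pass = NA,
                      direction_consistent = NA,
                      proportion = NA_real_, proportion_lo = NA_real_,
                      proportion_hi = NA_real_, note = "",
                      stringsAsFactors = FALSE)
    row
  })
  audit <- do.call(rbind, rows)
  mediation <- list()

  for (id in ids[pass1]) {
    i <- which(audit$metabolite_id == id)
    inst <- metabolite_instruments[[id]]
    if (is.null(inst)) {
      audit$note[i] <- "no instruments for step 2"
      next
    }
    f2 <- {
      h2 <- harmonize(instrument_records(inst), outcome_stats)
      if (length(h2$beta_exp) >= 2) mr_ivw(h2)
      else wald_ratio(h2$beta_exp, h2$se_exp, h2$beta_out, h2$se_out)
    }
    audit$step2_beta[i] <- f2$beta
    audit$step2_se[i] <- f2$se
    audit$step2_p[i] <- f2$pval
    audit$step2_pass[i] <- f2$pval < thr2
    if (isTRUE(audit$step2_pass[i])) {
      med <- two_step_mr(exposure_instruments, metabolite_stats[[id]],
                         inst, outcome_stats, exposure_stats,
                         invert_exposure = invert_exposure)
      mediation[[id]] <- med
      audit$proportion[i] <- med$proportion
      audit$proportion_lo[i] <- med$proportion_ci[1]
      audit$proportion_hi[i] <- med$proportion_ci[2]
      audit$direction_consistent[i] <- sign(med$indirect) == sign(med$alpha)
    }
  }
  structure(audit, class = c("mr_screen", "data.frame"),
            M = M, K = K, step1_threshold = thr1, step2_threshold = thr2,
            alpha = alpha, mediation = mediation)
}

#' @export
print.mr_screen <- function(x, ...) {
  M <- attr(x, "M"); K <- attr(x, "K")
  cat(sprintf("Mediator screen: %d metabolite(s), step-1 threshold %.3g, %d survivor(s)",
              M, attr(x, "step1_threshold"), K))
  if (K > 0) cat(sprintf(", step-2 threshold %.3g", attr(x, "step2_threshold")))
  cat("\n")
  med <- attr(x, "mediation")
  if (length(med))
    cat("Mediator(s) passing both gates:", paste(names(med), collapse = ", "), "\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Metabolites passing both screen gates
#'
#' @param screen an [run_screen()] result.
#' @return character vector of metabolite ids with a mediation result.
#' @export
screen_mediators <- function(screen) {
  names(attr(screen, "mediation"))
}
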