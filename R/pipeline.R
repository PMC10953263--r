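#' Run the four-stage drug-target MR pipeline
#'
#' Executes the full analysis in order: (1) cis-instrument selection for
#' the drug-target proxy (eQTL allowlist, biomarker association filter,
#' LD clumping); (2) the colocalization gate — the locus must show a
#' shared-causal-variant posterior PP4 above the threshold or the
#' pipeline halts; (3) MR of the proxied exposure on the outcome with all
#' applicable estimators and sensitivity statistics; (4) the
#' Bonferroni-screened metabolite mediator scan with two-step MR mediation
#' for double-survivors.
#'
#' @param config a named list, or path to a YAML file, with elements
#'   \describe{
#'     \item{preset}{`"paper"` to run on the shipped synthetic study
#'       conditions (default), or `"files"` to supply paths.}
#'     \item{seed}{integer seed for the synthetic preset. Default 1.}
#'     \item{m}{metabolite panel size for the preset. Default 20.}
#'     \item{true_mediator_index}{planted mediator for the preset.
#'       Default 7.}
#'     \item{p_biomarker}{drug-target association filter. Default `1e-4`.}
#'     \item{clump_r2_target}{cis clumping threshold. Default `0.8`.}
#'     \item{coloc_threshold}{PP4 gate. Default `0.70`.}
#'     \item{alpha}{screen family-wise error rate. Default `0.05`.}
#'     \item{outcome_binary}{outcome on log-odds scale. Default FALSE.}
#'     \item{out_dir}{optional directory for result tables
#'       (instruments.tsv, coloc.tsv, mr_results.tsv, screen.tsv,
#'       mediation.tsv, report.json).}
#'     \item{biomarker_file, outcome_file, ld_file, eqtl_file, region}{
#'       inputs for `preset = "files"`; metabolite inputs are then not
#'       screened.}
#'   }
#' @return object of class `run_report`: list with `config_echo`,
#'   `stage_outputs` (per-stage summary numbers), `objects` (the fitted
#'   objects), `software_version`, `seeds`, `warnings`.
#' @export
full_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(preset = "paper", seed = 1L, m = 20L,
                   true_mediator_index = 7L, p_biomarker = 1e-4,
                   clump_r2_target = 0.8, coloc_threshold = 0.70,
                   alpha = 0.05, outcome_binary = FALSE, out_dir = NULL,
                   coloc_preset = "coloc-shared")
  cfg <- utils::modifyList(defaults, config)
  warnings_seen <- character(0)
  wh <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  stage <- list(); objects <- list()

  if (identical(cfg$preset, "paper")) {
    seed <- as.integer(cfg$seed)
    # stage 1: cis instrument selection on a synthetic drug-target locus
    study <- simulate_mediation_study(truth_config(seed = seed))
    locus <- study$exposure_stats
    n_extra <- 10L
    extra <- gwas_table(sprintf("bg_%02d", seq_len(n_extra)), "16",
                        31494000 + 5000 * (nrow(locus) + seq_len(n_extra)),
                        rep(0.3, n_extra), rep(0.001, n_extra),
                        rep(0.01, n_extra), locus$N[1])
    locus_all <- rbind(locus, extra)
    ld <- ld_matrix(diag(1, nrow(locus_all)), locus_all$SNP)
    inst <- wh(select_drug_target_instruments(
      locus_all, eqtl_snps = locus$SNP,
      region = list("16", 31400000, 31700000),
      p_threshold = cfg$p_biomarker, ld = ld,
      clump_r2 = cfg$clump_r2_target))
  } else {
    biomarker <- read_gwas(cfg$biomarker_file)
    ld <- read_ld_matrix(cfg$ld_file)
    eqtl <- readLines(cfg$eqtl_file)
    inst <- wh(select_drug_target_instruments(
      biomarker, eqtl_snps = eqtl, region = cfg$region,
      p_threshold = cfg$p_biomarker, ld = ld,
      clump_r2 = cfg$clump_r2_target))
  }
  stage$instruments <- list(n_instruments = nrow(inst$records),
                            min_f = min(inst$per_snp_f),
                            r2_explained = inst$r2_explained)
  objects$instruments <- inst

  # stage 2: colocalization gate at the drug-target locus
  if (identical(cfg$preset, "paper")) {
    reg <- simulate_preset(cfg$coloc_preset, seed = cfg$seed)
    cres <- coloc_abf(reg$trait1, reg$trait2)
  } else {
    t1 <- read_gwas(cfg$coloc_trait1_file); t2 <- read_gwas(cfg$coloc_trait2_file)
    shared <- intersect(t1$SNP, t2$SNP)
    cres <- coloc_abf(t1[match(shared, t1$SNP), ], t2[match(shared, t2$SNP), ])
  }
  stage$coloc <- as.list(cres$pp)
  objects$coloc <- cres
  if (!coloc_decision(cres, cfg$coloc_threshold))
    stop_mr(paste0("colocalization gate failed: PP4 = %.3f <= %.2f; the locus ",
                   "does not support a shared causal variant, so the proxy ",
                   "is not carried forward"),
            cres$pp["PP4"], cfg$coloc_threshold)

  # stage 3: MR of the proxied exposure on the outcome
  if (identical(cfg$preset, "paper")) {
    outcome_stats <- study$outcome_stats
  } else {
    outcome_stats <- read_gwas(cfg$outcome_file)
  }
  h <- harmonize(inst$records, outcome_stats)
  fit <- wh(mr_fit(h, outcome_binary = isTRUE(cfg$outcome_binary),
                   seed = cfg$seed))
  stage$mr <- list(
    ivw_beta = fit$results$beta[fit$results$method == "ivw_re"],
    ivw_pval = fit$results$pval[fit$results$method == "ivw_re"],
    Q = fit$sensitivity$Q, egger_intercept = fit$sensitivity$egger_intercept)
  objects$mr <- fit

  # stage 4: mediator screen + mediation
  if (identical(cfg$preset, "paper")) {
    panel <- simulate_metabolite_panel(cfg$m, cfg$true_mediator_index,
                                       panel_truth_config(),
                                       seed = cfg$seed + 1L)
    screen <- wh(run_screen(panel$exposure_instruments, panel$metabolite_stats,
                            panel$metabolite_instruments, panel$outcome_stats,
                            alpha = cfg$alpha))
    stage$screen <- list(M = attr(screen, "M"), K = attr(screen, "K"),
                         step1_threshold = attr(screen, "step1_threshold"),
                         step2_threshold = attr(screen, "step2_threshold"),
                         mediators = screen_mediators(screen))
    med <- attr(screen, "mediation")
    if (length(med))
      stage$mediation <- list(
        mediator = names(med)[1],
        proportion = med[[1]]$proportion,
        proportion_ci = med[[1]]$proportion_ci)
    objects$screen <- screen
  }

  report <- structure(list(
    config_echo = cfg, stage_outputs = stage, objects = objects,
    software_version = as.character(utils::packageVersion("mrmediate")),
    seeds = list(pipeline = cfg$seed),
    warnings = warnings_seen), class = "run_report")

  if (!is.null(cfg$out_dir)) write_run_outputs(report, cfg$out_dir)
  report
}

write_run_outputs <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  o <- report$objects
  if (!is.null(o$instruments))
    write_results(o$instruments$records, file.path(out_dir, "instruments.tsv"))
  if (!is.null(o$coloc))
    write_results(as.data.frame(t(o$coloc$pp)), file.path(out_dir, "coloc.tsv"))
  if (!is.null(o$mr))
    write_results(o$mr$results, file.path(out_dir, "mr_results.tsv"))
  if (!is.null(o$screen))
    write_results(as.data.frame(o$screen), file.path(out_dir, "screen.tsv"))
  med <- if (!is.null(o$screen)) attr(o$screen, "mediation") else NULL
  if (length(med)) {
    tab <- do.call(rbind, lapply(names(med), function(id) {
      m <- med[[id]]
      data.frame(metabolite_id = id, alpha = m$alpha, alpha_se = m$alpha_se,
                 beta1 = m$beta1, beta1_se = m$beta1_se,
                 beta2 = m$beta2, beta2_se = m$beta2_se,
                 indirect = m$indirect, indirect_se = m$indirect_se,
                 proportion = m$proportion,
                 proportion_lo = m$proportion_ci[1],
                 proportion_hi = m$proportion_ci[2],
                 stringsAsFactors = FALSE)
    }))
    write_results(tab, file.path(out_dir, "mediation.tsv"))
  }
  slim <- report[c("config_echo", "stage_outputs", "software_version",
                   "seeds", "warnings")]
  slim$config_echo$out_dir <- NULL
  jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Drug-target MR pipeline run (version", x$software_version, ")\n")
  s <- x$stage_outputs
  cat(sprintf("  stage 1  instruments: %d selected, min F = %.1f\n",
              s$instruments$n_instruments, s$instruments$min_f))
  cat(sprintf("  stage 2  coloc: PP4 = %.3f (gate passed)\n", s$coloc$PP4))
  cat(sprintf("  stage 3  MR (IVW): beta = %.4g, p = %.3g\n",
              s$mr$ivw_beta, s$mr$ivw_pval))
  if (!is.null(s$screen))
    cat(sprintf("  stage 4  screen: M = %d, K = %d, mediator(s): %s\n",
                s$screen$M, s$screen$K,
                if (length(s$screen$mediators))
                  paste(s$screen$mediators, collapse = ", ") else "none"))
  if (!is.null(s$mediation))
    cat(sprintf("           proportion mediated via %s: %.1f%% [%.1f%%, %.1f%%]\n",
                s$mediation$mediator, 100 * s$mediation$proportion,
                100 * s$mediation$proportion_ci[1],
                100 * s$mediation$proportion_ci[2]))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
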