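#' Truth configuration for the mediation-study simulator
#'
#' Describes the structural model behind a simulated two-sample MR
#' mediation study: per-SNP instrument effects on the exposure
#' (`gamma`), the exposure-to-mediator path `beta1_true`, the
#' mediator-to-outcome path `beta2_true`, a direct exposure-to-outcome
#' path `theta_direct`, and the implied total effect
#' `alpha_true = theta_direct + beta1_true * beta2_true` (always derived,
#' never stored independently). Per-study standard-error scales and sample
#' sizes control the observed summary statistics.
#'
#' The defaults are the package's calibrated study conditions: six cis
#' instruments for an HbA1c-scaled inhibition proxy, `beta1 = 0.65`,
#' `beta2 = 0.01`, `theta_direct = 0.0435` (total effect 0.05, proportion
#' mediated 13%), with per-SNP standard errors chosen so the three IVW
#' path estimates have standard errors matching those back-computed from
#' the corresponding published interval widths (0.145, 0.0033 and 0.0128).
#'
#' @param n_instruments number of exposure instruments.
#' @param gamma vector of true SNP-exposure effects (length
#'   `n_instruments`).
#' @param beta1_true,beta2_true,theta_direct structural path effects.
#' @param pleiotropy_mode `"none"`, `"balanced"` (zero-mean) or
#'   `"directional"` per-SNP pleiotropic effects added to the mediator and
#'   outcome means of the exposure instruments.
#' @param pleiotropy_sd,pleiotropy_mean pleiotropy distribution
#'   parameters.
#' @param se_exp,se_med,se_out per-study per-SNP standard-error scales.
#' @param n_exp,n_med,n_out GWAS sample sizes.
#' @param n_mediator_instruments,gamma_med the mediator's own instrument
#'   count and true SNP-mediator effects.
#' @param maf_range effect-allele frequencies drawn uniformly here.
#' @param outcome_binary report the outcome on the log-odds scale.
#' @param seed RNG seed; outputs are a pure function of the config.
#' @return list of class `truth_config` with an `alpha_true` element
#'   recomputed from the paths.
#' @export
truth_config <- function(n_instruments = 6,
                         gamma = c(0.040, 0.036, 0.033, 0.030, 0.027, 0.024),
                         beta1_true = 0.65, beta2_true = 0.01,
                         theta_direct = 0.0435,
                         pleiotropy_mode = c("none", "balanced", "directional"),
                         pleiotropy_sd = 0, pleiotropy_mean = 0,
                         se_exp = 0.0026, se_med = 0.01144, se_out = 0.001,
                         n_exp = 344182, n_med = 121000, n_out = 567460,
                         n_mediator_instruments = 20,
                         gamma_med = seq(0.055, 0.080,
                                         length.out = n_mediator_instruments),
                         maf_range = c(0.1, 0.5),
                         outcome_binary = FALSE, seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(length(gamma) == n_instruments,
            length(gamma_med) == n_mediator_instruments,
            se_exp >= 0, se_med >= 0, se_out >= 0)
  cfg <- list(n_instruments = n_instruments, gamma = gamma,
              beta1_true = beta1_true, beta2_true = beta2_true,
              theta_direct = theta_direct,
              alpha_true = theta_direct + beta1_true * beta2_true,
              pleiotropy_mode = pleiotropy_mode,
              pleiotropy_sd = pleiotropy_sd, pleiotropy_mean = pleiotropy_mean,
              se_exp = se_exp, se_med = se_med, se_out = se_out,
              n_exp = n_exp, n_med = n_med, n_out = n_out,
              n_mediator_instruments = n_mediator_instruments,
              gamma_med = gamma_med, maf_range = maf_range,
              outcome_binary = outcome_binary, seed = seed)
  class(cfg) <- "truth_config"
  cfg
}

# assemble a canonical GWAS table
gwas_table <- function(snp, chr, pos, eaf, beta, se, n) {
  data.frame(SNP = snp, CHR = as.character(chr), POS = as.integer(pos),
             EA = "A", OA = "G", EAF = eaf, BETA = beta,
             SE = pmax(se, 1e-150),
             P = pmax(z_pval(beta / pmax(se, 1e-150)), 1e-300),
             N = n, stringsAsFactors = FALSE)
}

#' Simulate a two-sample MR mediation study
#'
#' Draws GWAS summary statistics under the structural model of a
#' [truth_config()]: for exposure instrument j,
#' observed exposure beta ~ N(gamma_j, se_exp^2),
#' mediator beta ~ N(gamma_j * beta1 + pleio_j, se_med^2),
#' outcome beta ~ N(gamma_j * alpha + pleio_j, se_out^2);
#' the mediator's own instruments get mediator beta ~ N(gamma_med, se_med^2)
#' and outcome beta ~ N(gamma_med * beta2, se_out^2). Pleiotropic effects
#' pleio_j are 0 (`none`), N(0, sd^2) (`balanced`) or N(mean, sd^2)
#' (`directional`). P-values are two-sided normal; allele frequencies are
#' uniform over `maf_range`; all alleles are non-palindromic A/G so
#' harmonization is exact. Outputs are byte-identical for identical
#' configs.
#'
#' @param cfg a [truth_config()].
#' @return list with `exposure_stats`, `mediator_stats` (covers both
#'   instrument sets), `outcome_stats` (ditto), `exposure_instruments`
#'   (`instrument_set` of the exposure instruments),
#'   `mediator_instruments` (`instrument_set` of the mediator's own
#'   instruments, records = their mediator associations), and `truth`
#'   (gamma, paths, `alpha_true`, per-SNP pleiotropy).
#' @export
simulate_mediation_study <- function(cfg) {
  stopifnot(inherits(cfg, "truth_config"))
  with_seed(cfg$seed, {
    k <- cfg$n_instruments; k2 <- cfg$n_mediator_instruments
    iv <- sprintf("iv_%02d", seq_len(k))
    miv <- sprintf("miv_%02d", seq_len(k2))
    eaf_iv <- stats::runif(k, cfg$maf_range[1], cfg$maf_range[2])
    eaf_miv <- stats::runif(k2, cfg$maf_range[1], cfg$maf_range[2])
    pleio <- switch(cfg$pleiotropy_mode,
                    none = rep(0, k),
                    balanced = stats::rnorm(k, 0, cfg$pleiotropy_sd),
                    directional = stats::rnorm(k, cfg$pleiotropy_mean,
                                               cfg$pleiotropy_sd))
    bx <- stats::rnorm(k, cfg$gamma, cfg$se_exp)
    bm_iv <- stats::rnorm(k, cfg$gamma * cfg$beta1_true + pleio, cfg$se_med)
    by_iv <- stats::rnorm(k, cfg$gamma * cfg$alpha_true + pleio, cfg$se_out)
    bm_miv <- stats::rnorm(k2, cfg$gamma_med, cfg$se_med)
    by_miv <- stats::rnorm(k2, cfg$gamma_med * cfg$beta2_true, cfg$se_out)

    exposure_stats <- gwas_table(iv, "16", 31494000 + 5000 * seq_len(k),
                                 eaf_iv, bx, cfg$se_exp, cfg$n_exp)
    mediator_stats <- rbind(
      gwas_table(iv, "16", 31494000 + 5000 * seq_len(k), eaf_iv,
                 bm_iv, cfg$se_med, cfg$n_med),
      gwas_table(miv, as.character((seq_len(k2) - 1) %% 22 + 1),
                 1e6 * seq_len(k2), eaf_miv, bm_miv, cfg$se_med, cfg$n_med))
    outcome_stats <- rbind(
      gwas_table(iv, "16", 31494000 + 5000 * seq_len(k), eaf_iv,
                 by_iv, cfg$se_out, cfg$n_out),
      gwas_table(miv, as.character((seq_len(k2) - 1) %% 22 + 1),
                 1e6 * seq_len(k2), eaf_miv, by_miv, cfg$se_out, cfg$n_out))
    list(exposure_stats = exposure_stats,
         mediator_stats = mediator_stats,
         outcome_stats = outcome_stats,
         exposure_instruments = instrument_set(exposure_stats),
         mediator_instruments = instrument_set(
           mediator_stats[mediator_stats$SNP %in% miv, , drop = FALSE]),
         truth = list(gamma = cfg$gamma, beta1 = cfg$beta1_true,
                      beta2 = cfg$beta2_true, theta_direct = cfg$theta_direct,
                      alpha = cfg$alpha_true,
                      proportion = cfg$beta1_true * cfg$beta2_true / cfg$alpha_true,
                      pleiotropy = pleio))
  })
}

#' Region configuration for the colocalization simulator
#'
#' @param n_snps SNPs in the cis region.
#' @param rho AR(1) LD correlation parameter in \[0, 1); the correlation
#'   between SNPs i and j is `rho^|i-j|`, which is always positive
#'   definite.
#' @param causal_config `"shared"` (one causal variant for both traits),
#'   `"distinct"` (different causal variants), `"trait1_only"`, or
#'   `"null"`.
#' @param causal_z target marginal z-score magnitude at the causal
#'   variant(s).
#' @param maf_range allele-frequency range.
#' @param n1,n2 GWAS sample sizes used to convert z-scores to effect
#'   sizes via `se = 1/sqrt(2 f (1-f) n)`.
#' @param seed RNG seed.
#' @return list of class `region_config`.
#' @export
region_config <- function(n_snps = 50, rho = 0.5,
                          causal_config = c("shared", "distinct",
                                            "trait1_only", "null"),
                          causal_z = 12, maf_range = c(0.1, 0.5),
                          n1 = 31684, n2 = 344182, seed = 1) {
  causal_config <- match.arg(causal_config)
  stopifnot(n_snps >= 1, rho >= 0, rho < 1, causal_z >= 0)
  structure(list(n_snps = n_snps, rho = rho, causal_config = causal_config,
                 causal_z = causal_z, maf_range = maf_range,
                 n1 = n1, n2 = n2, seed = seed),
            class = "region_config")
}

ar1_correlation <- function(n, rho) {
  rho^abs(outer(seq_len(n), seq_len(n), "-"))
}

#' Simulate an LD-structured cis region for colocalization
#'
#' Marginal z-scores follow the standard summary-statistic model for a
#' single causal variant: `z = R[, c] * causal_z + e` with
#' `e ~ N(0, R)`, R the AR(1) correlation matrix of the region. Under
#' `"shared"` both traits use the same causal index (region centre);
#' `"distinct"` uses indices at the first and third quartiles of the
#' region; `"trait1_only"` and `"null"` zero the respective signals.
#' Betas are `z * se` with `se = 1/sqrt(2 f (1-f) n)`.
#'
#' @param cfg a [region_config()].
#' @return list with GWAS tables `trait1`, `trait2`, an [ld_matrix()]
#'   `ld` (`r2 = R * R`), and `causal_index` (named vector).
#' @export
simulate_coloc_region <- function(cfg) {
  stopifnot(inherits(cfg, "region_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_snps
    R <- ar1_correlation(n, cfg$rho)
    L <- chol(R)
    c1 <- max(1L, ceiling(n / 2))
    c2 <- if (n >= 4) max(1L, ceiling(n / 4)) else 1L
    c2b <- if (n >= 4) min(n, ceiling(3 * n / 4)) else n
    idx <- switch(cfg$causal_config,
                  shared = c(t1 = c1, t2 = c1),
                  distinct = c(t1 = c2, t2 = c2b),
                  trait1_only = c(t1 = c1, t2 = NA),
                  null = c(t1 = NA, t2 = NA))
    draw_z <- function(ci) {
      mu <- if (is.na(ci)) rep(0, n) else R[, ci] * cfg$causal_z
      mu + drop(crossprod(L, stats::rnorm(n)))
    }
    z1 <- draw_z(idx["t1"]); z2 <- draw_z(idx["t2"])
    eaf <- stats::runif(n, cfg$maf_range[1], cfg$maf_range[2])
    se1 <- 1 / sqrt(2 * eaf * (1 - eaf) * cfg$n1)
    se2 <- 1 / sqrt(2 * eaf * (1 - eaf) * cfg$n2)
    snp <- sprintf("cis_%03d", seq_len(n))
    pos <- 31490000 + 2000 * seq_len(n)
    list(trait1 = gwas_table(snp, "16", pos, eaf, z1 * se1, se1, cfg$n1),
         trait2 = gwas_table(snp, "16", pos, eaf, z2 * se2, se2, cfg$n2),
         ld = ld_matrix(R * R, snp),
         causal_index = idx)
  })
}

#' Simulate a metabolite panel for the mediator screen
#'
#' M metabolite GWAS sharing one exposure instrument set; only the planted
#' mediator (if any) carries nonzero exposure-to-metabolite and
#' metabolite-to-outcome paths. Every metabolite also gets its own
#' instrument set for the screen's second step.
#'
#' @param m panel size.
#' @param true_mediator_index 1-based index of the planted mediator, or
#'   `NULL` for an all-null panel.
#' @param base_cfg a [truth_config()] supplying effects, ses and sizes.
#' @param seed RNG seed (overrides `base_cfg$seed`).
#' @return list with `exposure_instruments`, `exposure_stats`,
#'   `metabolite_stats` (named list), `metabolite_instruments` (named
#'   list), `outcome_stats`, `truth`.
#' @export
simulate_metabolite_panel <- function(m, true_mediator_index = NULL,
                                      base_cfg = truth_config(), seed = 1) {
  stopifnot(m >= 1)
  if (!is.null(true_mediator_index))
    stopifnot(true_mediator_index >= 1, true_mediator_index <= m)
  ids <- sprintf("met_%03d", seq_len(m))
  with_seed(seed, {
    cfg <- base_cfg
    k <- cfg$n_instruments; k2 <- cfg$n_mediator_instruments
    iv <- sprintf("iv_%02d", seq_len(k))
    eaf_iv <- stats::runif(k, cfg$maf_range[1], cfg$maf_range[2])
    bx <- stats::rnorm(k, cfg$gamma, cfg$se_exp)
    exposure_stats <- gwas_table(iv, "16", 31494000 + 5000 * seq_len(k),
                                 eaf_iv, bx, cfg$se_exp, cfg$n_exp)
    has_med <- !is.null(true_mediator_index)
    alpha_true <- cfg$theta_direct +
      if (has_med) cfg$beta1_true * cfg$beta2_true else 0
    by_iv <- stats::rnorm(k, cfg$gamma * alpha_true, cfg$se_out)
    outcome_stats <- gwas_table(iv, "16", 31494000 + 5000 * seq_len(k),
                                eaf_iv, by_iv, cfg$se_out, cfg$n_out)
    metabolite_stats <- list(); metabolite_instruments <- list()
    for (i in seq_len(m)) {
      b1_i <- if (has_med && i == true_mediator_index) cfg$beta1_true else 0
      b2_i <- if (has_med && i == true_mediator_index) cfg$beta2_true else 0
      bm_iv <- stats::rnorm(k, cfg$gamma * b1_i, cfg$se_med)
      miv <- sprintf("%s_iv%02d", ids[i], seq_len(k2))
      eaf_miv <- stats::runif(k2, cfg$maf_range[1], cfg$maf_range[2])
      bm_miv <- stats::rnorm(k2, cfg$gamma_med, cfg$se_med)
      by_miv <- stats::rnorm(k2, cfg$gamma_med * b2_i, cfg$se_out)
      met_tab <- rbind(
        gwas_table(iv, "16", 31494000 + 5000 * seq_len(k), eaf_iv,
                   bm_iv, cfg$se_med, cfg$n_med),
        gwas_table(miv, as.character((seq_len(k2) - 1) %% 22 + 1),
                   1e6 * seq_len(k2) + 1000 * i, eaf_miv, bm_miv,
                   cfg$se_med, cfg$n_med))
      metabolite_stats[[ids[i]]] <- met_tab
      metabolite_instruments[[ids[i]]] <- instrument_set(
        met_tab[met_tab$SNP %in% miv, , drop = FALSE])
      outcome_stats <- rbind(outcome_stats,
        gwas_table(miv, as.character((seq_len(k2) - 1) %% 22 + 1),
                   1e6 * seq_len(k2) + 1000 * i, eaf_miv, by_miv,
                   cfg$se_out, cfg$n_out))
    }
    list(exposure_instruments = instrument_set(exposure_stats),
         exposure_stats = exposure_stats,
         metabolite_stats = metabolite_stats,
         metabolite_instruments = metabolite_instruments,
         outcome_stats = outcome_stats,
         truth = list(mediator = if (has_med) ids[true_mediator_index] else NA,
                      alpha = alpha_true,
                      proportion = if (has_med)
                        cfg$beta1_true * cfg$beta2_true / alpha_true else 0))
  })
}

# study conditions for the screen presets: the planted mediator carries
# strong, well-powered paths so both Bonferroni gates are all-but
# deterministic, while null metabolites keep standard-normal z-scores
panel_truth_config <- function() {
  truth_config(se_med = 0.006,
               gamma_med = seq(0.12, 0.16, length.out = 20))
}

#' Named simulation presets
#'
#' Shipped study conditions: `"mediation-paper"` (the calibrated six-SNP
#' mediation study), `"coloc-shared"` and `"coloc-distinct"` (cis regions
#' with a shared / distinct causal variant at marginal z = 12),
#' `"panel-one-mediator"` and `"panel-null"` (20-metabolite screens with
#' and without a planted mediator at index 7).
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @return the simulated data set for the preset (see the generator that
#'   backs each one).
#' @export
simulate_preset <- function(name = c("mediation-paper", "coloc-shared",
                                     "coloc-distinct", "panel-one-mediator",
                                     "panel-null"), seed = 1) {
  name <- match.arg(name)
  switch(name,
    "mediation-paper" = simulate_mediation_study(truth_config(seed = seed)),
    "coloc-shared" = simulate_coloc_region(
      region_config(causal_config = "shared", causal_z = 12, rho = 0.5,
                    seed = seed)),
    "coloc-distinct" = simulate_coloc_region(
      region_config(causal_config = "distinct", causal_z = 12, rho = 0.1,
                    seed = seed)),
    "panel-one-mediator" = simulate_metabolite_panel(
      20, true_mediator_index = 7, base_cfg = panel_truth_config(),
      seed = seed),
    "panel-null" = simulate_metabolite_panel(
      20, true_mediator_index = NULL, base_cfg = panel_truth_config(),
      seed = seed))
}
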