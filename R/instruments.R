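#' LD matrices
#'
#' An LD matrix holds pairwise squared correlations (r\eqn{^2}) between
#' variants: a symmetric numeric matrix with unit diagonal, entries in
#' \[0, 1\] and SNP ids as dimnames. `ld_matrix()` validates and classes a
#' matrix; `read_ld_matrix()` reads either a square tab-delimited matrix
#' (SNP ids as header and first column) or a long-format three-column file
#' (`snp_a`, `snp_b`, `r2`).
#'
#' @param r2 square numeric matrix of squared correlations.
#' @param snp_ids optional SNP ids (defaults to existing dimnames).
#' @return a matrix of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, snp_ids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(snp_ids)) stop_mr("LD matrix needs SNP ids")
  dimnames(r2) <- list(snp_ids, snp_ids)
  if (nrow(r2) != ncol(r2)) stop_mr("LD matrix must be square")
  if (max(abs(r2 - t(r2))) > 1e-8) stop_mr("LD matrix must be symmetric")
  if (any(abs(diag(r2) - 1) > 1e-8)) stop_mr("LD matrix diagonal must be 1")
  if (any(r2 < -1e-12 | r2 > 1 + 1e-12)) stop_mr("LD r2 entries must lie in [0,1]")
  r2[r2 < 0] <- 0; r2[r2 > 1] <- 1
  diag(r2) <- 1
  class(r2) <- c("ld_matrix", class(r2))
  r2
}

#' @rdname ld_matrix
#' @param path path to a square or long-format LD file.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stop_mr("LD file not found: %s", path)
  head1 <- strsplit(readLines(path, n = 1), "\t| +")[[1]]
  if (length(head1) == 3 && any(is.na(suppressWarnings(as.numeric(head1))))) {
    long <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
    ids <- unique(c(long[[1]], long[[2]]))
    m <- diag(1, length(ids)); dimnames(m) <- list(ids, ids)
    m[cbind(match(long[[1]], ids), match(long[[2]], ids))] <- long[[3]]
    m[cbind(match(long[[2]], ids), match(long[[1]], ids))] <- long[[3]]
    return(ld_matrix(m))
  }
  sq <- utils::read.table(path, header = TRUE, row.names = 1,
                          check.names = FALSE)
  ld_matrix(as.matrix(sq))
}

#' Greedy LD clumping of summary statistics
#'
#' Plink-style greedy selection: records are ranked by ascending p-value
#' (ties broken by chromosome then position); the best remaining SNP is
#' accepted and every unaccepted SNP on the same chromosome within
#' `window_kb` kilobases with r\eqn{^2 \ge} `r2_threshold` against it is
#' removed. Deterministic and invariant to input row order.
#'
#' @param records GWAS table of candidate instruments (canonical columns;
#'   `CHR` and `POS` required).
#' @param ld an [ld_matrix()] covering every record.
#' @param r2_threshold clumping threshold in (0, 1\].
#' @param window_kb clumping window in kilobases.
#' @return an `instrument_set`: list with `records` (retained rows),
#'   `per_snp_f`, `r2_explained`, `f_overall`, `strength_fallback` and
#'   `selection_log` (data frame of snp/action/reason).
#' @export
clump <- function(records, ld, r2_threshold, window_kb) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1, window_kb > 0)
  absent <- setdiff(records$SNP, rownames(ld))
  if (length(absent))
    stop_mr("SNP(s) missing from LD matrix: %s", paste(absent, collapse = ", "))
  ord <- order(records$P, records$CHR, records$POS)
  rec <- records[ord, , drop = FALSE]
  status <- rep("pending", nrow(rec))          # pending / kept / removed
  log_snp <- character(0); log_action <- character(0); log_reason <- character(0)
  for (i in seq_len(nrow(rec))) {
    if (status[i] != "pending") next
    status[i] <- "kept"
    log_snp <- c(log_snp, rec$SNP[i]); log_action <- c(log_action, "keep")
    log_reason <- c(log_reason, sprintf("index SNP, p=%.3g", rec$P[i]))
    pending <- which(status == "pending")
    if (!length(pending)) next
    same_chr <- rec$CHR[pending] == rec$CHR[i]
    near <- abs(rec$POS[pending] - rec$POS[i]) <= window_kb * 1000
    r2v <- ld[rec$SNP[i], rec$SNP[pending]]
    hit <- pending[same_chr & near & r2v >= r2_threshold]
    if (length(hit)) {
      status[hit] <- "removed"
      log_snp <- c(log_snp, rec$SNP[hit])
      log_action <- c(log_action, rep("remove", length(hit)))
      log_reason <- c(log_reason,
                      sprintf("r2 %.3f with index %s", ld[rec$SNP[i], rec$SNP[hit]],
                              rec$SNP[i]))
    }
  }
  kept <- rec[status == "kept", , drop = FALSE]
  kept <- kept[order(match(kept$SNP, records$SNP)), , drop = FALSE]
  instrument_set(kept, selection_log = data.frame(
    snp = log_snp, action = log_action, reason = log_reason,
    stringsAsFactors = FALSE))
}

# construct an instrument_set with strength diagnostics attached
instrument_set <- function(records, selection_log = NULL) {
  rownames(records) <- NULL
  s <- instrument_strength(records)
  structure(list(records = records,
                 per_snp_f = s$per_snp_f,
                 r2_explained = s$r2_explained,
                 f_overall = s$f_overall,
                 strength_fallback = s$fallback,
                 selection_log = selection_log %||%
                   data.frame(snp = character(0), action = character(0),
                              reason = character(0))),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: %d SNP(s)\n", nrow(x$records)))
  cat(sprintf("  R2 explained: %.4g   overall F: %.4g   min per-SNP F: %.4g\n",
              x$r2_explained, x$f_overall, min(x$per_snp_f)))
  if (x$strength_fallback)
    cat("  (per-SNP F from (beta/se)^2 fallback: eaf or n missing)\n")
  invisible(x)
}

#' Instrument strength diagnostics
#'
#' Per-SNP variance explained uses the allele-frequency approximation
#' \deqn{R^2_j = \frac{2f_j(1-f_j)\beta_j^2}{2f_j(1-f_j)\beta_j^2 +
#'   2f_j(1-f_j) n_j se_j^2},}
#' per-SNP \eqn{F_j = (n_j-2) R^2_j/(1-R^2_j)}, total
#' \eqn{R^2 = \sum_j R^2_j}, and overall
#' \eqn{F = \frac{n-k-1}{k}\frac{R^2}{1-R^2}} with \eqn{n} the minimum
#' sample size and \eqn{k} the SNP count. When `EAF` or `N` is missing the
#' per-SNP fallback \eqn{F_j = (\beta_j/se_j)^2} is used and flagged.
#' F above 10 is the conventional bar against weak-instrument bias.
#'
#' @param records GWAS table of instrument-exposure associations.
#' @return list with `per_snp_f`, `r2_explained`, `f_overall`, `fallback`.
#' @export
instrument_strength <- function(records) {
  if (!nrow(records)) stop_mr("no records for instrument_strength()")
  k <- nrow(records)
  fallback <- any(is.na(records$EAF)) || any(is.na(records$N))
  if (fallback) {
    f <- (records$BETA / records$SE)^2
    return(list(per_snp_f = f, r2_explained = NA_real_,
                f_overall = NA_real_, fallback = TRUE))
  }
  v <- 2 * records$EAF * (1 - records$EAF)
  r2j <- v * records$BETA^2 / (v * records$BETA^2 + v * records$N * records$SE^2)
  fj <- (records$N - 2) * r2j / (1 - r2j)
  r2 <- sum(r2j)
  nmin <- min(records$N)
  f_all <- (nmin - k - 1) / k * r2 / (1 - r2)
  list(per_snp_f = fj, r2_explained = r2, f_overall = f_all, fallback = FALSE)
}

#' Select cis instruments for a drug target
#'
#' The four-step drug-target procedure: restrict a biomarker GWAS to SNPs
#' that (i) are expression QTLs for the target gene (`eqtl_snps`
#' allowlist), (ii) lie within the cis region, and (iii) pass the biomarker
#' association threshold (default P < 1e-4); then greedily clump the
#' survivors, by default at the permissive r\eqn{^2} < 0.8 used for
#' correlated cis instruments.
#'
#' @param biomarker GWAS table for the downstream biomarker (e.g. HbA1c for
#'   an SGLT2-inhibition proxy).
#' @param eqtl_snps character vector of SNP ids with eQTL evidence.
#' @param region list or vector `(chrom, start, end)` of the cis region.
#' @param p_threshold biomarker association threshold. Default `1e-4`.
#' @param ld [ld_matrix()] over the candidates.
#' @param clump_r2 clumping threshold. Default `0.8`.
#' @param window_kb clumping window. Default 1000 kb (the cis region is
#'   small; the window only needs to span it).
#' @return an `instrument_set`.
#' @export
select_drug_target_instruments <- function(biomarker, eqtl_snps, region,
                                           p_threshold = 1e-4, ld,
                                           clump_r2 = 0.8, window_kb = 1000) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  region <- as.list(region)
  chrom <- as.character(region[[1]])
  start <- as.numeric(region[[2]]); end <- as.numeric(region[[3]])
  if (!(is.finite(start) && is.finite(end) && start <= end))
    stop_mr("malformed region")
  n0 <- nrow(biomarker)
  in_eqtl <- biomarker[biomarker$SNP %in% eqtl_snps, , drop = FALSE]
  in_reg <- in_eqtl[in_eqtl$CHR == chrom & in_eqtl$POS >= start &
                      in_eqtl$POS <= end, , drop = FALSE]
  sig <- in_reg[in_reg$P < p_threshold, , drop = FALSE]
  if (!nrow(sig))
    stop_mr(paste0("no instruments survive drug-target selection ",
                   "(input %d -> eQTL %d -> region %d -> p<%g %d)"),
            n0, nrow(in_eqtl), nrow(in_reg), p_threshold, 0L)
  clump(sig, ld, r2_threshold = clump_r2, window_kb = window_kb)
}

#' Select genome-wide instruments for a metabolite exposure
#'
#' Keeps genome-wide-significant associations (default P < 5e-8) and clumps
#' them to independence (default r\eqn{^2} < 0.01 within a 10,000 kb
#' window).
#'
#' @param metabolite GWAS table for the metabolite.
#' @param ld [ld_matrix()] over the candidates.
#' @param p_threshold significance threshold. Default `5e-8`.
#' @param clump_r2 independence threshold. Default `0.01`.
#' @param window_kb clumping window. Default `10000`.
#' @return an `instrument_set`.
#' @export
select_metabolite_instruments <- function(metabolite, ld, p_threshold = 5e-8,
                                          clump_r2 = 0.01, window_kb = 10000) {
  sig <- metabolite[metabolite$P < p_threshold, , drop = FALSE]
  if (!nrow(sig)) stop_mr("no genome-wide significant SNPs at p<%g", p_threshold)
  clump(sig, ld, r2_threshold = clump_r2, window_kb = window_kb)
}
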