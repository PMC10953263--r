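#' GWAS summary-statistic tables
#'
#' A GWAS summary-statistic table is a base data frame with the canonical
#' columns `SNP` (variant id), `CHR` (chromosome, character), `POS`
#' (1-based base-pair position), `EA` (effect allele), `OA` (other allele),
#' `EAF` (effect-allele frequency, may be `NA`), `BETA` (effect per copy of
#' the effect allele, trait units or log-odds), `SE` (standard error,
#' positive), `P` (p-value in (0, 1]) and `N` (sample size). `read_gwas()`
#' builds such a table from a delimited text file, validating every row;
#' rows that violate the per-record invariants are removed and collected in
#' the `"rejected"` attribute together with the reason.
#'
#' @param path path to a whitespace- or tab-delimited text file with header.
#' @param column_map named character vector mapping canonical field names to
#'   the column names used in the file, e.g. `c(SNP = "rsid", EA = "a1")`.
#'   Unmapped canonical names are looked up verbatim. `SNP`, `EA`, `OA`,
#'   `BETA`, `SE` and `P` are required; `CHR`, `POS`, `EAF` and `N` are
#'   optional and filled with `NA` when absent.
#' @return a validated data frame of associations, in file order, with
#'   attributes `rejected` (data frame of dropped rows with a `reason`
#'   column) and `n_duplicates_dropped`.
#' @details Duplicated `SNP` ids keep the record with the smallest p-value.
#'   A p-value inconsistent with `|BETA/SE|` under a two-sided normal by
#'   more than a factor of 10 raises a warning but the row is kept, since
#'   meta-analysis p-values legitimately differ from Wald p-values.
#' @export
read_gwas <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop_mr("GWAS file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "")
  canon <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
  map <- stats::setNames(canon, canon)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), canon)
    if (length(bad)) stop_mr("unknown canonical field(s) in column_map: %s",
                             paste(bad, collapse = ", "))
    map[names(column_map)] <- unname(column_map)
  }
  required <- c("SNP", "EA", "OA", "BETA", "SE", "P")
  missing_req <- required[!map[required] %in% names(raw)]
  if (length(missing_req))
    stop_mr("mapped column(s) absent from header of %s: %s", path,
            paste(map[missing_req], collapse = ", "))
  get_col <- function(f, coerce = identity) {
    if (map[[f]] %in% names(raw)) coerce(raw[[map[[f]]]]) else rep(NA, nrow(raw))
  }
  df <- data.frame(
    SNP  = as.character(get_col("SNP")),
    CHR  = as.character(get_col("CHR")),
    POS  = suppressWarnings(as.integer(get_col("POS"))),
    EA   = toupper(as.character(get_col("EA"))),
    OA   = toupper(as.character(get_col("OA"))),
    EAF  = suppressWarnings(as.numeric(get_col("EAF"))),
    BETA = suppressWarnings(as.numeric(get_col("BETA"))),
    SE   = suppressWarnings(as.numeric(get_col("SE"))),
    P    = suppressWarnings(as.numeric(get_col("P"))),
    N    = suppressWarnings(as.numeric(get_col("N"))),
    stringsAsFactors = FALSE
  )
  validate_gwas(df, source = path)
}

#' Validate a GWAS summary-statistic table
#'
#' Enforces the per-record invariants (alleles in A/C/G/T and distinct,
#' `SE > 0`, `EAF` in \[0, 1\] when present, `P` in (0, 1\]) and resolves
#' duplicated `SNP` ids by keeping the smallest p-value. Invalid rows are
#' moved to the `rejected` attribute with a reason.
#'
#' @param df data frame with the canonical columns (see [read_gwas()]).
#' @param source label used in messages.
#' @return the validated data frame (see [read_gwas()] for attributes).
#' @export
validate_gwas <- function(df, source = "gwas") {
  df$EA <- toupper(df$EA); df$OA <- toupper(df$OA)
  ok_allele <- df$EA %in% c("A", "C", "G", "T") & df$OA %in% c("A", "C", "G", "T")
  reason <- rep(NA_character_, nrow(df))
  reason[!ok_allele] <- "invalid allele"
  reason[is.na(reason) & df$EA == df$OA] <- "effect allele equals other allele"
  reason[is.na(reason) & (!is.finite(df$BETA))] <- "non-numeric beta"
  reason[is.na(reason) & (!is.finite(df$SE) | df$SE <= 0)] <- "se not positive"
  reason[is.na(reason) & (!is.finite(df$P) | df$P <= 0 | df$P > 1)] <- "p out of (0,1]"
  reason[is.na(reason) & !is.na(df$EAF) & (df$EAF < 0 | df$EAF > 1)] <- "eaf out of [0,1]"
  reason[is.na(reason) & is.na(df$SNP)] <- "missing snp id"
  rejected <- df[!is.na(reason), , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!is.na(reason)]
  else rejected$reason <- character(0)
  keep <- df[is.na(reason), , drop = FALSE]
  if (!nrow(keep)) stop_mr("no valid rows in %s", source)

  # p-value vs Wald consistency: warn only. Compared on the log scale so
  # that extreme z-scores (where the p underflows) are still caught.
  log10_wald <- (stats::pnorm(-abs(keep$BETA / keep$SE), log.p = TRUE) +
                   log(2)) / log(10)
  inconsistent <- is.finite(log10_wald) &
    abs(log10(keep$P) - log10_wald) > 1
  if (any(inconsistent))
    warn_mr("%d record(s) in %s have p-values differing from the Wald p by >10x",
            sum(inconsistent), source)

  # duplicates: keep smallest p
  n_dup <- 0L
  if (anyDuplicated(keep$SNP)) {
    ord <- order(keep$P, seq_len(nrow(keep)))
    keep <- keep[ord, , drop = FALSE]
    dup <- duplicated(keep$SNP)
    n_dup <- sum(dup)
    keep <- keep[!dup, , drop = FALSE]
    keep <- keep[order(match(keep$SNP, df$SNP)), , drop = FALSE]
  }
  rownames(keep) <- NULL
  attr(keep, "rejected") <- rejected
  attr(keep, "n_duplicates_dropped") <- n_dup
  keep
}

#' Write a GWAS summary-statistic table
#'
#' Tab-delimited with header; numeric fields keep full precision so that
#' [read_gwas()] round-trips all fields.
#'
#' @param df GWAS table (canonical columns).
#' @param path output path.
#' @export
write_gwas <- function(df, path) {
  if (!nrow(df)) stop_mr("refusing to write an empty GWAS table")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result table as tab-delimited text
#'
#' Floats are rendered with at least 6 significant digits so a re-read
#' reproduces the values to output precision. Writing an empty result set is
#' an error and creates no file.
#'
#' @param results nonempty data frame.
#' @param path output path.
#' @export
write_results <- function(results, path) {
  results <- as.data.frame(results)
  if (!nrow(results)) stop_mr("refusing to write an empty result table")
  out <- results
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 8, format = "g"))
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_mr("could not write results to %s", path)
  invisible(path)
}

#' Harmonize exposure and outcome associations
#'
#' Aligns two GWAS tables onto the exposure's effect-allele orientation for
#' the SNPs they share. Outcome records whose alleles are swapped relative
#' to the exposure have their beta negated and EAF complemented; strand
#' flips (complementary alleles) are resolved for non-palindromic SNPs.
#' Palindromic SNPs (A/T or C/G) are dropped when the effect-allele
#' frequency is missing on either side or lies within
#' `palindromic_eaf_window` of 0.5 on either side; otherwise EAF concordance
#' decides the orientation. SNPs with irreconcilable allele sets are
#' dropped.
#'
#' @param exposure,outcome GWAS tables (canonical columns).
#' @param palindromic_eaf_window half-width of the ambiguous EAF zone around
#'   0.5 for palindromic SNPs. Default 0.08.
#' @return an object of class `harmonized_set`: a list with `snp`,
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf_exp`, `n_exp`, `n_out`,
#'   `n_dropped_palindromic`, `n_dropped_incompatible`, `n_flipped`.
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_window = 0.08) {
  if (!nrow(exposure) || !nrow(outcome)) stop_mr("empty input to harmonize()")
  shared <- intersect(exposure$SNP, outcome$SNP)
  if (!length(shared)) stop_mr("no SNPs shared between exposure and outcome")
  e <- exposure[match(shared, exposure$SNP), , drop = FALSE]
  o <- outcome[match(shared, outcome$SNP), , drop = FALSE]

  n <- length(shared)
  keep <- rep(TRUE, n); flip <- rep(FALSE, n)
  dropped_pal <- 0L; dropped_bad <- 0L

  pal <- is_palindromic(e$EA, e$OA)
  for (i in seq_len(n)) {
    if (pal[i]) {
      same <- (o$EA[i] == e$EA[i] && o$OA[i] == e$OA[i])
      swapped <- (o$EA[i] == e$OA[i] && o$OA[i] == e$EA[i])
      if (!same && !swapped) { keep[i] <- FALSE; dropped_bad <- dropped_bad + 1L; next }
      fe <- e$EAF[i]; fo <- o$EAF[i]
      w <- palindromic_eaf_window
      if (is.na(fe) || is.na(fo) ||
          abs(fe - 0.5) <= w || abs(fo - 0.5) <= w) {
        keep[i] <- FALSE; dropped_pal <- dropped_pal + 1L; next
      }
      # for a palindrome the allele labels cannot distinguish strands;
      # orient by frequency concordance alone
      flip[i] <- (fe - 0.5) * (fo - 0.5) < 0
    } else {
      ce <- allele_complement(o$EA[i]); co <- allele_complement(o$OA[i])
      if (o$EA[i] == e$EA[i] && o$OA[i] == e$OA[i]) {
        flip[i] <- FALSE
      } else if (o$EA[i] == e$OA[i] && o$OA[i] == e$EA[i]) {
        flip[i] <- TRUE
      } else if (ce == e$EA[i] && co == e$OA[i]) {
        flip[i] <- FALSE               # opposite strand, same orientation
      } else if (ce == e$OA[i] && co == e$EA[i]) {
        flip[i] <- TRUE                # opposite strand, swapped
      } else {
        keep[i] <- FALSE; dropped_bad <- dropped_bad + 1L
      }
    }
  }

  if (!any(keep)) stop_mr("no SNPs retained after harmonization")
  beta_out <- ifelse(flip, -o$BETA, o$BETA)[keep]
  structure(list(
    snp = shared[keep],
    beta_exp = e$BETA[keep], se_exp = e$SE[keep],
    beta_out = beta_out, se_out = o$SE[keep],
    eaf_exp = e$EAF[keep], n_exp = e$N[keep], n_out = o$N[keep],
    n_dropped_palindromic = dropped_pal,
    n_dropped_incompatible = dropped_bad,
    n_flipped = sum(flip[keep])
  ), class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized instrument set: %d SNP(s)\n", length(x$snp)))
  cat(sprintf("  flipped to exposure orientation: %d\n", x$n_flipped))
  cat(sprintf("  dropped ambiguous palindromic:   %d\n", x$n_dropped_palindromic))
  cat(sprintf("  dropped incompatible alleles:    %d\n", x$n_dropped_incompatible))
  invisible(x)
}

# build a harmonized_set directly from aligned vectors (internal)
harmonized_set <- function(snp, beta_exp, se_exp, beta_out, se_out,
                           eaf_exp = rep(NA_real_, length(snp)),
                           n_exp = rep(NA_real_, length(snp)),
                           n_out = rep(NA_real_, length(snp))) {
  stopifnot(length(beta_exp) == length(snp), length(beta_out) == length(snp))
  structure(list(snp = snp, beta_exp = beta_exp, se_exp = se_exp,
                 beta_out = beta_out, se_out = se_out, eaf_exp = eaf_exp,
                 n_exp = n_exp, n_out = n_out,
                 n_dropped_palindromic = 0L, n_dropped_incompatible = 0L,
                 n_flipped = 0L),
            class = "harmonized_set")
}
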