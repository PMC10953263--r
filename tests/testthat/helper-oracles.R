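# fixtures and independent oracles used across the suite

make_gwas <- function(snp, beta, se, ea = "A", oa = "G", chr = "1",
                      pos = seq_along(snp) * 1000, eaf = 0.3,
                      p = NULL, n = 1e5) {
  data.frame(SNP = snp, CHR = chr, POS = as.integer(pos),
             EA = ea, OA = oa, EAF = eaf, BETA = beta, SE = se,
             P = if (is.null(p)) 2 * pnorm(-abs(beta / se)) else p,
             N = n, stringsAsFactors = FALSE)
}

make_hset <- function(beta_exp, se_exp, beta_out, se_out) {
  n <- length(beta_exp)
  h <- list(snp = sprintf("s%d", seq_len(n)),
            beta_exp = beta_exp, se_exp = se_exp,
            beta_out = beta_out, se_out = se_out,
            eaf_exp = rep(0.3, n), n_exp = rep(1e5, n), n_out = rep(1e5, n),
            n_dropped_palindromic = 0L, n_dropped_incompatible = 0L,
            n_flipped = 0L)
  class(h) <- "harmonized_set"
  h
}

# weighted least squares through base lm(): independent of the closed forms
ivw_oracle <- function(h) {
  f <- lm(beta_out ~ 0 + beta_exp, data = h[c("beta_exp", "beta_out")],
          weights = 1 / h$se_out^2)
  unname(coef(f)[1])
}

egger_oracle <- function(h) {
  s <- sign(h$beta_exp); s[s == 0] <- 1
  d <- data.frame(x = h$beta_exp * s, y = h$beta_out * s)
  f <- lm(y ~ x, data = d, weights = 1 / h$se_out^2)
  unname(coef(f))                       # (intercept, slope)
}

# weighted median oracle: build the half-shifted piecewise-linear
# cumulative-weight curve explicitly, then invert it by scanning a dense
# grid for the first crossing of 0.5 (resolution = grid step)
weighted_median_oracle <- function(theta, w, n_grid = 400001) {
  w <- w / sum(w)
  ord <- order(theta)
  th <- theta[ord]; ww <- w[ord]
  p <- cumsum(ww) - ww / 2
  if (0.5 <= p[1]) return(th[1])
  if (0.5 >= p[length(p)]) return(th[length(th)])
  grid <- seq(th[1], th[length(th)], length.out = n_grid)
  cdf <- approx(th, p, xout = grid, method = "linear", ties = "ordered")$y
  grid[which(cdf >= 0.5)[1]]
}

# dense-grid argmax of the weighted kernel density
mode_oracle <- function(theta, w, bandwidth) {
  grid <- seq(min(theta) - 3 * bandwidth, max(theta) + 3 * bandwidth,
              length.out = 20001)
  dens <- vapply(grid, function(x)
    sum(w * dnorm((x - theta) / bandwidth)), numeric(1))
  grid[which.max(dens)]
}

# direct enumeration of the five colocalization hypotheses in plain
# probability space (adequate for small |z|), with explicit double loops
coloc_enumeration_oracle <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4,
                                     p12 = 1e-5, prior_sd1 = 0.15,
                                     prior_sd2 = 0.15) {
  abf <- function(b, s, w) {
    r <- w^2 / (w^2 + s^2)
    sqrt(1 - r) * exp(0.5 * (b / s)^2 * r)
  }
  a1 <- abf(trait1$BETA, trait1$SE, prior_sd1)
  a2 <- abf(trait2$BETA, trait2$SE, prior_sd2)
  n <- length(a1)
  L1 <- sum(a1); L2 <- sum(a2)
  L4 <- sum(a1 * a2)
  L3 <- 0
  for (j in seq_len(n)) for (k in seq_len(n)) if (j != k)
    L3 <- L3 + a1[j] * a2[k]
  u <- c(1, p1 * L1, p2 * L2, p1 * p2 * L3, p12 * L4)
  setNames(u / sum(u), paste0("PP", 0:4))
}

# brute-force validity check of a clumped set: every retained pair within
# the window satisfies r2 < threshold, and every removed SNP conflicts
# with a retained SNP of smaller (or tied-earlier) p-value
clump_is_valid <- function(records, kept_ids, ld, r2_threshold, window_kb) {
  kept <- records[records$SNP %in% kept_ids, , drop = FALSE]
  for (i in seq_len(nrow(kept))) for (j in seq_len(nrow(kept))) {
    if (i >= j) next
    if (kept$CHR[i] == kept$CHR[j] &&
        abs(kept$POS[i] - kept$POS[j]) <= window_kb * 1000 &&
        ld[kept$SNP[i], kept$SNP[j]] >= r2_threshold) return(FALSE)
  }
  removed <- records[!records$SNP %in% kept_ids, , drop = FALSE]
  for (i in seq_len(nrow(removed))) {
    conflict <- FALSE
    for (j in seq_len(nrow(kept))) {
      if (removed$CHR[i] == kept$CHR[j] &&
          abs(removed$POS[i] - kept$POS[j]) <= window_kb * 1000 &&
          ld[removed$SNP[i], kept$SNP[j]] >= r2_threshold &&
          kept$P[j] <= removed$P[i]) { conflict <- TRUE; break }
    }
    if (!conflict) return(FALSE)
  }
  TRUE
}
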