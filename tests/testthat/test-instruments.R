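test_that("clump keeps the strongest SNP and drops its correlates", {
  rec <- make_gwas(c("s1", "s2", "s3"), beta = c(0.1, 0.08, 0.05), se = 0.01,
                   p = c(1e-10, 1e-8, 1e-6), pos = c(1000, 3000, 5000))
  r2 <- diag(1, 3); r2[1, 2] <- r2[2, 1] <- 0.9
  r2[1, 3] <- r2[3, 1] <- 0.1; r2[2, 3] <- r2[3, 2] <- 0.1
  ld <- ld_matrix(r2, rec$SNP)
  out <- clump(rec, ld, r2_threshold = 0.8, window_kb = 10)
  expect_setequal(out$records$SNP, c("s1", "s3"))
  expect_true("remove" %in% out$selection_log$action)

  # independence: zero off-diagonal keeps everything
  out2 <- clump(rec, ld_matrix(diag(1, 3), rec$SNP), 0.01, 10)
  expect_equal(nrow(out2$records), 3)

  expect_error(clump(make_gwas("sX", 0.1, 0.01), ld, 0.8, 10), "sX")
})

test_that("clump matches the brute-force pair-validity oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20
    rec <- make_gwas(sprintf("v%02d", 1:n), beta = rnorm(n, 0, 0.05),
                     se = 0.01, p = runif(n, 1e-12, 1e-4),
                     pos = sort(sample.int(5e5, n)))
    A <- matrix(runif(n * n), n)
    r2 <- (A + t(A)) / 2 * 0.4
    diag(r2) <- 1
    ld <- ld_matrix(r2, rec$SNP)
    for (thr in c(0.01, 0.2, 0.5)) {
      out <- clump(rec, ld, thr, window_kb = 10000)
      expect_true(clump_is_valid(rec, out$records$SNP, ld, thr, 10000))
    }
  }
})

test_that("clump is order-invariant and monotone in the threshold", {
  set.seed(11)
  n <- 15
  rec <- make_gwas(sprintf("v%02d", 1:n), beta = rnorm(n, 0, 0.05),
                   se = 0.01, p = runif(n), pos = sort(sample.int(1e5, n)))
  A <- matrix(runif(n * n), n); r2 <- (A + t(A)) / 2 * 0.9; diag(r2) <- 1
  ld <- ld_matrix(r2, rec$SNP)
  base <- clump(rec, ld, 0.3, 1000)$records$SNP
  shuf <- clump(rec[sample.int(n), ], ld, 0.3, 1000)$records$SNP
  expect_setequal(base, shuf)
  counts <- vapply(c(0.05, 0.2, 0.5, 0.9),
                   function(t) nrow(clump(rec, ld, t, 1000)$records),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("drug-target selection applies eQTL, region and p filters", {
  # 10 region SNPs: 6 pass every filter, mirrors a six-SNP cis instrument
  rec <- make_gwas(sprintf("rs%02d", 1:12),
                   beta = c(rep(0.05, 6), rep(0.002, 4), 0.05, 0.05),
                   se = 0.01, chr = "16",
                   pos = c(seq(31500000, by = 5000, length.out = 10),
                           31500000, 40000000),
                   p = c(rep(1e-6, 6), rep(0.5, 4), 1e-6, 1e-6))
  eqtl <- rec$SNP[c(1:10, 12)]          # rs11 lacks eQTL evidence, rs12 off-region
  ld <- ld_matrix(diag(1, 12), rec$SNP)
  out <- select_drug_target_instruments(rec, eqtl,
                                        region = list("16", 31490000, 31600000),
                                        p_threshold = 1e-4, ld = ld,
                                        clump_r2 = 0.8)
  expect_equal(nrow(out$records), 6)
  expect_setequal(out$records$SNP, sprintf("rs%02d", 1:6))

  # p_threshold ~ 1 with independent LD keeps all eQTL-overlapping region SNPs
  all10 <- select_drug_target_instruments(rec, eqtl,
                                          region = list("16", 31490000, 31600000),
                                          p_threshold = 0.999, ld = ld,
                                          clump_r2 = 0.8)
  expect_equal(nrow(all10$records), 10)
  expect_error(select_drug_target_instruments(rec, character(0),
                                              region = list("16", 1, 2),
                                              ld = ld), "no instruments")
})

test_that("metabolite selection enforces the genome-wide boundary", {
  rec <- make_gwas(c("a", "b", "c"), beta = c(0.1, 0.1, 0.05), se = 0.01,
                   p = c(6e-8, 4e-8, 1e-9),
                   chr = c("1", "2", "3"), pos = c(1e6, 1e6, 1e6))
  ld <- ld_matrix(diag(1, 3), rec$SNP)
  out <- select_metabolite_instruments(rec, ld)
  expect_setequal(out$records$SNP, c("b", "c"))   # p = 6e-8 excluded
})

test_that("metabolite selection recovers planted independent loci", {
  set.seed(3)
  k <- 5; n_null <- 40
  rec <- rbind(
    make_gwas(sprintf("hit%d", 1:k), beta = 0.1, se = 0.01,
              p = rep(1e-12, k), chr = as.character(1:k), pos = 1e6),
    make_gwas(sprintf("null%02d", 1:n_null), beta = 0.001, se = 0.01,
              p = runif(n_null, 0.01, 1), chr = "9",
              pos = seq(1e6, by = 1e4, length.out = n_null)))
  ld <- ld_matrix(diag(1, nrow(rec)), rec$SNP)
  out <- select_metabolite_instruments(rec, ld)
  expect_setequal(out$records$SNP, sprintf("hit%d", 1:k))
})

test_that("instrument strength follows the variance-explained formulas", {
  # missing eaf triggers the (beta/se)^2 fallback
  rec <- make_gwas("rs1", beta = 0.03, se = 0.003)
  rec$EAF <- NA
  s <- instrument_strength(rec)
  expect_equal(s$per_snp_f, 100)
  expect_true(s$fallback)

  # zero effect gives zero R2 and F
  rec0 <- make_gwas("rs1", beta = 0, se = 0.003, n = 1000)
  s0 <- instrument_strength(rec0)
  expect_equal(s0$per_snp_f, 0)
  expect_equal(s0$r2_explained, 0)
})

test_that("estimated R2 recovers the generative value within 20%", {
  eaf <- 0.25; n <- 3e5
  v <- 2 * eaf * (1 - eaf)
  r2_true <- 0.001
  beta0 <- sqrt(r2_true / (1 - r2_true) / v)
  se <- 1 / sqrt(v * n)
  set.seed(99)
  est <- replicate(500, {
    b <- rnorm(1, beta0, se)
    instrument_strength(make_gwas("rs1", beta = b, se = se, eaf = eaf,
                                  n = n))$r2_explained
  })
  expect_lt(abs(mean(est) - r2_true) / r2_true, 0.2)
})
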