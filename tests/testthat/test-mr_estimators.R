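test_that("wald ratio arithmetic and delta variants", {
  w <- wald_ratio(0.1, 0.01, 0.05, 0.01)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.1)

  w0 <- wald_ratio(0.1, 0.01, 0, 0.01)
  expect_equal(w0$beta, 0)
  expect_equal(w0$se, 0.1)

  first <- wald_ratio(0.1, 0.05, 0.05, 0.01)
  second <- wald_ratio(0.1, 0.05, 0.05, 0.01, second_order = TRUE)
  expect_gt(second$se, first$se)
  expect_equal(second$se,
               sqrt(0.01^2 / 0.1^2 + 0.05^2 * 0.05^2 / 0.1^4), tolerance = 1e-12)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.01), "beta_exp")
})

test_that("IVW closed forms: collinear data, hand-computed case, weight algebra", {
  h <- make_hset(c(0.1, 0.2), c(0.01, 0.01), c(0.05, 0.10), c(0.01, 0.01))
  f <- mr_ivw(h)
  expect_equal(f$beta, 0.5, tolerance = 1e-12)
  expect_equal(f$Q, 0, tolerance = 1e-20)
  expect_equal(f$se, f$se_fixed)

  h2 <- make_hset(c(0.1, 0.1), c(0.01, 0.01), c(0.05, 0.08), c(0.01, 0.01))
  f2 <- mr_ivw(h2)
  expect_equal(f2$beta, 0.65, tolerance = 1e-12)   # (0.005 + 0.008) / 0.02

  # duplicating every SNP: same estimate, fixed-effect se shrinks by sqrt(2)
  hdup <- make_hset(rep(h2$beta_exp, 2), rep(h2$se_exp, 2),
                    rep(h2$beta_out, 2), rep(h2$se_out, 2))
  fdup <- mr_ivw(hdup)
  expect_equal(fdup$beta, f2$beta, tolerance = 1e-12)
  expect_equal(fdup$se_fixed, f2$se_fixed / sqrt(2), tolerance = 1e-12)
})

test_that("IVW and Egger agree with the weighted least squares oracle", {
  set.seed(4)
  for (i in 1:100) {
    n <- sample(3:30, 1)
    h <- make_hset(runif(n, 0.02, 0.2), rep(0.01, n),
                   rnorm(n, 0.05, 0.05), runif(n, 0.005, 0.05))
    expect_equal(mr_ivw(h)$beta, ivw_oracle(h), tolerance = 1e-10)
    eg <- mr_egger(h)
    ora <- egger_oracle(h)
    expect_equal(eg$intercept, ora[1], tolerance = 1e-10)
    expect_equal(eg$beta, ora[2], tolerance = 1e-10)
  }
})

test_that("Egger recovers an exact affine relationship with zero Q", {
  x <- c(0.05, 0.1, 0.15, 0.2)
  h <- make_hset(x, rep(0.01, 4), 0.02 + 0.5 * x, rep(0.01, 4))
  f <- mr_egger(h)
  expect_equal(f$beta, 0.5, tolerance = 1e-10)
  expect_equal(f$intercept, 0.02, tolerance = 1e-10)
  expect_equal(f$Q, 0, tolerance = 1e-16)
  expect_error(mr_egger(make_hset(c(0.1, 0.2), 0.01, c(0.1, 0.2), 0.01)), "3")
})

test_that("weighted median: symmetry, breakdown robustness, degenerate weights", {
  h <- make_hset(c(1, 1, 1), rep(1e-6, 3), c(0.4, 0.5, 0.6), rep(0.01, 3))
  expect_equal(mr_weighted_median(h, n_boot = 50)$beta, 0.5, tolerance = 1e-9)

  # one grossly invalid instrument carrying < 50% of the weight
  h2 <- make_hset(c(1, 1, 1), rep(1e-6, 3), c(0.5, 0.5, 5.0), rep(0.01, 3))
  expect_equal(mr_weighted_median(h2, n_boot = 50)$beta, 0.5, tolerance = 1e-9)

  # nearly all weight on the last SNP pulls the median to its ratio
  h3 <- make_hset(c(0.01, 0.01, 1), rep(1e-6, 3), c(0.004, 0.005, 1.2),
                  c(0.01, 0.01, 0.0001))
  expect_equal(mr_weighted_median(h3, n_boot = 50)$beta, 1.2, tolerance = 1e-6)
})

test_that("weighted median equals the replication-quantile oracle", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(4:25, 1)
    h <- make_hset(runif(n, 0.05, 0.3), rep(0.01, n),
                   rnorm(n, 0.05, 0.1), runif(n, 0.01, 0.05))
    theta <- h$beta_out / h$beta_exp
    w <- (h$beta_exp / h$se_out)^2
    est <- mr_weighted_median(h, n_boot = 2)$beta
    expect_equal(est, weighted_median_oracle(theta, w), tolerance = 2e-3)
  }
})

test_that("mode estimators find the dominant ratio cluster", {
  h <- make_hset(rep(1, 4), rep(1e-6, 4), rep(0.3, 4), rep(0.01, 4))
  expect_equal(mr_mode(h, n_boot = 20)$beta, 0.3, tolerance = 1e-9)

  h2 <- make_hset(rep(1, 4), rep(1e-6, 4), c(0.5, 0.5, 0.5, 2.0), rep(0.01, 4))
  f2 <- mr_mode(h2, weighted = FALSE, n_boot = 20)
  expect_lt(abs(f2$beta - 0.5), f2$bandwidth)

  # weighted mode follows the weight, not the count
  h3 <- make_hset(rep(1, 5), rep(1e-6, 5), c(0.5, 0.5, 0.5, 1.2, 1.2),
                  c(0.5, 0.5, 0.5, 0.001, 0.001))
  f3 <- mr_mode(h3, weighted = TRUE, n_boot = 20)
  expect_lt(abs(f3$beta - 1.2), f3$bandwidth)
})

test_that("mode estimates agree with a dense-grid density oracle", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    h <- make_hset(runif(n, 0.05, 0.3), rep(0.01, n),
                   rnorm(n, 0.05, 0.1), runif(n, 0.01, 0.05))
    f <- mr_mode(h, weighted = (i %% 2 == 0), n_boot = 2)
    theta <- h$beta_out / h$beta_exp
    w <- if (i %% 2 == 0) {
      ww <- (h$beta_exp / h$se_out)^2; ww / sum(ww)
    } else rep(1 / n, n)
    expect_lt(abs(f$beta - mode_oracle(theta, w, f$bandwidth)), f$bandwidth)
  }
})

test_that("estimators are sign- and scale-equivariant", {
  set.seed(31)
  n <- 12
  h <- make_hset(runif(n, 0.05, 0.3), rep(0.005, n),
                 rnorm(n, 0.06, 0.03), runif(n, 0.01, 0.03))
  neg <- h; neg$beta_out <- -neg$beta_out
  expect_equal(mr_ivw(neg)$beta, -mr_ivw(h)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(neg)$beta, -mr_egger(h)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(neg, n_boot = 2)$beta,
               -mr_weighted_median(h, n_boot = 2)$beta, tolerance = 1e-9)
  expect_equal(mr_mode(neg, n_boot = 2)$beta, -mr_mode(h, n_boot = 2)$beta,
               tolerance = 1e-6)
  # odds-ratio scale maps to the reciprocal
  fb <- mr_fit(h, outcome_binary = TRUE, n_boot = 5)
  fbn <- mr_fit(neg, outcome_binary = TRUE, n_boot = 5)
  expect_equal(fbn$results$or[1], 1 / fb$results$or[1], tolerance = 1e-10)

  cc <- 2.5
  sc <- h; sc$beta_exp <- sc$beta_exp * cc; sc$se_exp <- sc$se_exp * cc
  expect_equal(mr_ivw(sc)$beta, mr_ivw(h)$beta / cc, tolerance = 1e-12)
  expect_equal(mr_egger(sc)$beta, mr_egger(h)$beta / cc, tolerance = 1e-12)
  expect_equal(mr_weighted_median(sc, n_boot = 2)$beta,
               mr_weighted_median(h, n_boot = 2)$beta / cc, tolerance = 1e-9)
})

test_that("Q is zero iff all ratios agree, and its p-value is null-uniform", {
  h <- make_hset(c(0.1, 0.2, 0.4), rep(0.01, 3), c(0.05, 0.10, 0.20),
                 rep(0.01, 3))
  expect_equal(mr_ivw(h)$Q, 0, tolerance = 1e-20)

  set.seed(17)
  n <- 10
  bx <- runif(n, 0.05, 0.2)
  qp <- replicate(2000, {
    by <- 0.1 * bx + rnorm(n, 0, 0.01)
    mr_ivw(make_hset(bx, rep(0.001, n), by, rep(0.01, n)))$Q_pval
  })
  expect_gt(ks.test(qp, "punif")$p.value, 0.01)
})

test_that("all five estimators agree under homogeneous valid instruments", {
  set.seed(23)
  n <- 50
  bx <- runif(n, 0.05, 0.2)
  h <- make_hset(rnorm(n, bx, 0.001), rep(0.001, n),
                 rnorm(n, 0.05 * bx, 0.002), rep(0.002, n))
  f <- mr_fit(h, n_boot = 200)
  for (i in seq_len(nrow(f$results)))
    expect_lt(abs(f$results$beta[i] - 0.05), 2 * f$results$se[i] + 0.01)
})

test_that("IVW point estimate is unbiased for the true effect", {
  set.seed(29)
  n <- 50
  bx0 <- runif(n, 0.05, 0.2)
  est <- replicate(500, {
    bx <- rnorm(n, bx0, 0.001)
    by <- rnorm(n, 0.05 * bx0, 0.002)
    mr_ivw(make_hset(bx, rep(0.001, n), by, rep(0.002, n)))$beta
  })
  expect_lt(abs(mean(est) - 0.05), 0.005)
})

test_that("mr_fit dispatches on SNP count and reports the OR scale", {
  h1 <- make_hset(0.1, 0.01, 0.05, 0.01)
  f1 <- mr_fit(h1)
  expect_equal(f1$results$method, "wald")
  expect_true(all(c("egger", "weighted_median") %in% names(f1$skipped)))

  set.seed(41)
  n <- 6
  h6 <- make_hset(runif(n, 0.05, 0.2), rep(0.005, n),
                  rnorm(n, -0.6 * 0.1, 0.01), rep(0.01, n))
  h6$beta_out <- -0.6 * h6$beta_exp          # exact log-odds relationship
  f6 <- mr_fit(h6, outcome_binary = TRUE, n_boot = 20)
  expect_setequal(f6$results$method,
                  c("ivw_re", "egger", "weighted_median", "simple_mode",
                    "weighted_mode"))
  expect_equal(f6$results$or[f6$results$method == "ivw_re"], exp(-0.6),
               tolerance = 1e-9)
  expect_true(is.finite(f6$sensitivity$egger_intercept))
  # invariants of the result table
  expect_true(all(f6$results$ci_low <= f6$results$beta + 1e-12))
  expect_true(all(f6$results$beta <= f6$results$ci_high + 1e-12))
})
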