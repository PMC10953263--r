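#' Wald ratio estimate for a single SNP
#'
#' The per-SNP causal-effect building block: outcome effect divided by
#' exposure effect. The default standard error is the first-order delta
#' approximation `se_out/|beta_exp|` (exposure uncertainty ignored, the
#' usual no-measurement-error assumption); `second_order = TRUE` adds the
#' exposure-uncertainty term
#' \eqn{\sqrt{se_{out}^2/\beta_{exp}^2 + \beta_{out}^2 se_{exp}^2/\beta_{exp}^4}}.
#'
#' @param beta_exp,se_exp exposure association and standard error.
#' @param beta_out,se_out outcome association and standard error.
#' @param second_order include the exposure-uncertainty variance term.
#' @return an `mr_result` list: method, beta, se, ci_low, ci_high, pval,
#'   n_snp.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out,
                       second_order = FALSE) {
  if (beta_exp == 0) stop_mr("wald_ratio undefined for beta_exp = 0")
  beta <- beta_out / beta_exp
  se <- if (second_order)
    sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)
  else abs(se_out / beta_exp)
  mr_result("wald", beta, se, 1L)
}

mr_result <- function(method, beta, se, n_snp, extra = list()) {
  out <- c(list(method = method, beta = beta, se = se,
                ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
                pval = z_pval(beta / se), n_snp = as.integer(n_snp)),
           extra)
  class(out) <- "mr_result"
  out
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (se %.3g), 95%% CI [%.4g, %.4g], p = %.3g, nSNP = %d\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pval, x$n_snp))
  invisible(x)
}

#' Random-effects inverse-variance-weighted estimator
#'
#' Zero-intercept weighted regression of outcome on exposure effects with
#' weights \eqn{w_j = 1/se_{out,j}^2}:
#' \deqn{\hat\beta = \frac{\sum_j w_j \beta_{x,j}\beta_{y,j}}
#'   {\sum_j w_j \beta_{x,j}^2}, \qquad
#'   se_{FE} = \Big(\sum_j w_j \beta_{x,j}^2\Big)^{-1/2}.}
#' Cochran's Q about the fitted slope (df = nSNP - 1) drives the
#' multiplicative random-effects inflation
#' \eqn{se_{RE} = se_{FE}\sqrt{\max(1, Q/df)}}; p-values are two-sided
#' normal. With a single SNP the estimate falls back to the Wald ratio
#' with a message.
#'
#' @param h a `harmonized_set`.
#' @return an `mr_result` with method `"ivw_re"` and extra fields `Q`,
#'   `Q_df`, `Q_pval`, `se_fixed`.
#' @export
mr_ivw <- function(h) {
  n <- length(h$beta_exp)
  if (n == 0L) stop_mr("no SNPs for IVW")
  if (n < 2L) {
    message("IVW with a single SNP: returning the Wald ratio")
    return(wald_ratio(h$beta_exp, h$se_exp, h$beta_out, h$se_out))
  }
  w <- 1 / h$se_out^2
  denom <- sum(w * h$beta_exp^2)
  beta <- sum(w * h$beta_exp * h$beta_out) / denom
  se_fe <- 1 / sqrt(denom)
  Q <- sum(w * (h$beta_out - beta * h$beta_exp)^2)
  df <- n - 1L
  se <- se_fe * sqrt(max(1, Q / df))
  mr_result("ivw_re", beta, se, n,
            extra = list(Q = Q, Q_df = df,
                         Q_pval = stats::pchisq(Q, df, lower.tail = FALSE),
                         se_fixed = se_fe))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects *with* an intercept,
#' after orienting every SNP to a positive exposure effect (both betas
#' negated where needed, so exposure-decreasing alleles are recoded rather
#' than dropped). The slope is the pleiotropy-adjusted causal estimate;
#' the intercept estimates the average directional pleiotropic effect and
#' its test is the standard probe of the exclusion-restriction assumption.
#' Residual heterogeneity about the fitted line (df = nSNP - 2) is handled
#' with the same multiplicative random-effects inflation as IVW, applied
#' to both slope and intercept standard errors.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @return an `mr_result` with method `"egger"` and extra fields
#'   `intercept`, `intercept_se`, `intercept_pval`, `Q`, `Q_df`, `Q_pval`.
#' @export
mr_egger <- function(h) {
  n <- length(h$beta_exp)
  if (n < 3L) stop_mr("MR-Egger needs at least 3 SNPs (have %d)", n)
  s <- sign(h$beta_exp); s[s == 0] <- 1
  x <- h$beta_exp * s
  y <- h$beta_out * s
  w <- 1 / h$se_out^2
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  delta <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / delta
  intercept <- (swxx * swy - swx * swxy) / delta
  Q <- sum(w * (y - intercept - slope * x)^2)
  df <- n - 2L
  phi <- max(1, Q / df)
  se_slope <- sqrt(sw / delta * phi)
  se_int <- sqrt(swxx / delta * phi)
  mr_result("egger", slope, se_slope, n,
            extra = list(intercept = intercept, intercept_se = se_int,
                         intercept_pval = z_pval(intercept / se_int),
                         Q = Q, Q_df = df,
                         Q_pval = stats::pchisq(Q, df, lower.tail = FALSE)))
}

# interpolated weighted median of ratio estimates; weights must sum to 1
weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]; w <- w[ord]
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(theta[1])
  if (0.5 >= p[length(p)]) return(theta[length(theta)])
  stats::approx(p, theta, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' Per-SNP ratio estimates \eqn{\theta_j = \beta_{y,j}/\beta_{x,j}} with
#' inverse-variance weights \eqn{w_j = (\beta_{x,j}/se_{out,j})^2}
#' normalized to sum one. The estimate is the value at which the
#' half-weight-shifted cumulative weight crosses 0.5, interpolating
#' linearly between bracketing order statistics; it is consistent when at
#' least half the weight comes from valid instruments. The standard error
#' comes from a parametric bootstrap: exposure and outcome effects are
#' redrawn from normals centred at the observed values with their standard
#' errors and the median recomputed.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @param n_boot bootstrap replicates. Default 1000.
#' @param seed RNG seed for the bootstrap. Default 1.
#' @return an `mr_result` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1) {
  n <- length(h$beta_exp)
  if (n < 3L) stop_mr("weighted median needs at least 3 SNPs (have %d)", n)
  theta <- h$beta_out / h$beta_exp
  w <- (h$beta_exp / h$se_out)^2
  w <- w / sum(w)
  est <- weighted_median_point(theta, w)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(n, h$beta_exp, h$se_exp)
    by <- stats::rnorm(n, h$beta_out, h$se_out)
    wb <- (bx / h$se_out)^2
    weighted_median_point(by / bx, wb / sum(wb))
  }, numeric(1)))
  mr_result("weighted_median", est, stats::sd(boots), n)
}

# weighted gaussian-kernel density argmax over theta
mode_point <- function(theta, w, bandwidth_factor) {
  s <- stats::mad(theta)
  if (s == 0) s <- stats::sd(theta)
  if (!is.finite(s) || s == 0) return(list(est = theta[1], bandwidth = 0))
  h_bw <- bandwidth_factor * 0.9 * s * length(theta)^(-1 / 5)
  dens <- function(x)
    vapply(x, function(xi) sum(w * stats::dnorm((xi - theta) / h_bw)) / h_bw,
           numeric(1))
  grid <- seq(min(theta) - 3 * h_bw, max(theta) + 3 * h_bw, length.out = 512)
  fg <- dens(grid)
  i <- which.max(fg)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(512, i + 1)]
  opt <- stats::optimize(dens, interval = c(lo, hi), maximum = TRUE)
  list(est = opt$maximum, bandwidth = h_bw)
}

#' Mode-based estimators (simple and weighted)
#'
#' The causal estimate is the mode of the per-SNP ratio estimates: the
#' argmax of a gaussian-kernel-smoothed density over
#' \eqn{\theta_j = \beta_{y,j}/\beta_{x,j}}, with uniform weights (simple
#' mode) or inverse-variance weights \eqn{(\beta_{x,j}/se_{out,j})^2}
#' (weighted mode). The bandwidth is `bandwidth_factor` times the
#' median-absolute-deviation normal-reference rule
#' \eqn{0.9\,\mathrm{mad}(\theta)\,n^{-1/5}}; the density is evaluated on a
#' 512-point grid spanning the ratio range plus three bandwidths and the
#' argmax refined by golden-section search. When all ratios coincide the
#' common value is returned. Standard errors by parametric bootstrap as for
#' the weighted median.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @param weighted use inverse-variance weights. Default `FALSE`.
#' @param bandwidth_factor multiplier on the reference bandwidth. Default 1.
#' @param n_boot bootstrap replicates. Default 1000.
#' @param seed RNG seed. Default 1.
#' @return an `mr_result` with method `"simple_mode"` or
#'   `"weighted_mode"` and extra field `bandwidth`.
#' @export
mr_mode <- function(h, weighted = FALSE, bandwidth_factor = 1,
                    n_boot = 1000, seed = 1) {
  n <- length(h$beta_exp)
  if (n < 3L) stop_mr("mode estimator needs at least 3 SNPs (have %d)", n)
  theta <- h$beta_out / h$beta_exp
  weight_fn <- function(bx, so) {
    if (weighted) { w <- (bx / so)^2; w / sum(w) } else rep(1 / length(bx), length(bx))
  }
  w <- weight_fn(h$beta_exp, h$se_out)
  mp <- mode_point(theta, w, bandwidth_factor)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(n, h$beta_exp, h$se_exp)
    by <- stats::rnorm(n, h$beta_out, h$se_out)
    mode_point(by / bx, weight_fn(bx, h$se_out), bandwidth_factor)$est
  }, numeric(1)))
  mr_result(if (weighted) "weighted_mode" else "simple_mode",
            mp$est, stats::sd(boots), n,
            extra = list(bandwidth = mp$bandwidth))
}

# evaluate expr under a local RNG seed without disturbing the global stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fit all applicable MR estimators
#'
#' Runs the five two-sample MR estimators on a harmonized instrument set —
#' random-effects inverse-variance weighted (the primary method), MR-Egger,
#' weighted median, simple mode and weighted mode — plus the sensitivity
#' statistics (Cochran's Q from IVW, the Egger intercept test). Methods
#' whose minimum SNP count is not met are skipped with a message; with one
#' SNP only the Wald ratio is reported. For binary outcomes (log-odds
#' effects) estimates are also given on the odds-ratio scale.
#'
#' @param h a `harmonized_set`.
#' @param outcome_binary outcome betas are log-odds; report odds ratios.
#' @param invert_exposure negate exposure effects before fitting, so the
#'   estimand is per unit *lowering* of the exposure biomarker — the
#'   orientation used for an inhibition-proxy exposure such as genetically
#'   proxied SGLT2 inhibition scaled in SD HbA1c lowering.
#' @param n_boot,seed bootstrap settings for median/mode estimators.
#' @return object of class `mr_fit`: list with `results` (one row per
#'   method: method, n_snp, beta, se, ci_low, ci_high, pval, and or /
#'   or_ci_low / or_ci_high for binary outcomes), `sensitivity`
#'   (Q, Q_df, Q_pval, egger_intercept, egger_intercept_se,
#'   egger_intercept_pval), `skipped`, `harmonized`, `outcome_binary`.
#' @seealso [mr_ivw()], [mr_egger()], [mr_weighted_median()], [mr_mode()]
#' @export
mr_fit <- function(h, outcome_binary = FALSE, invert_exposure = FALSE,
                   n_boot = 1000, seed = 1) {
  stopifnot(inherits(h, "harmonized_set"))
  if (invert_exposure) h$beta_exp <- -h$beta_exp
  n <- length(h$beta_exp)
  if (n < 1L) stop_mr("empty harmonized set")
  fits <- list(); skipped <- character(0)
  sens <- list(Q = NA_real_, Q_df = NA_integer_, Q_pval = NA_real_,
               egger_intercept = NA_real_, egger_intercept_se = NA_real_,
               egger_intercept_pval = NA_real_)
  if (n == 1L) {
    fits$wald <- wald_ratio(h$beta_exp, h$se_exp, h$beta_out, h$se_out)
    skipped <- c(ivw_re = "needs >=2 SNPs", egger = "needs >=3 SNPs",
                 weighted_median = "needs >=3 SNPs",
                 simple_mode = "needs >=3 SNPs", weighted_mode = "needs >=3 SNPs")
  } else {
    ivw <- mr_ivw(h)
    fits$ivw_re <- ivw
    sens$Q <- ivw$Q; sens$Q_df <- ivw$Q_df; sens$Q_pval <- ivw$Q_pval
    if (n >= 3L) {
      egger <- mr_egger(h)
      fits$egger <- egger
      sens$egger_intercept <- egger$intercept
      sens$egger_intercept_se <- egger$intercept_se
      sens$egger_intercept_pval <- egger$intercept_pval
      fits$weighted_median <- mr_weighted_median(h, n_boot = n_boot, seed = seed)
      fits$simple_mode <- mr_mode(h, weighted = FALSE, n_boot = n_boot,
                                  seed = seed + 1L)
      fits$weighted_mode <- mr_mode(h, weighted = TRUE, n_boot = n_boot,
                                    seed = seed + 2L)
    } else {
      skipped <- c(egger = "needs >=3 SNPs", weighted_median = "needs >=3 SNPs",
                   simple_mode = "needs >=3 SNPs", weighted_mode = "needs >=3 SNPs")
    }
  }
  res <- do.call(rbind, lapply(fits, function(f)
    data.frame(method = f$method, n_snp = f$n_snp, beta = f$beta, se = f$se,
               ci_low = f$ci_low, ci_high = f$ci_high, pval = f$pval,
               stringsAsFactors = FALSE)))
  rownames(res) <- NULL
  if (outcome_binary) {
    res$or <- exp(res$beta)
    res$or_ci_low <- exp(res$ci_low)
    res$or_ci_high <- exp(res$ci_high)
  }
  structure(list(results = res, sensitivity = sens, skipped = skipped,
                 harmonized = h, outcome_binary = outcome_binary,
                 fits = fits),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR fit: %d SNP(s), primary method ivw_re\n",
              length(x$harmonized$beta_exp)))
  print(format(x$results, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  s <- x$fit$sensitivity
  cat("\nSensitivity statistics:\n")
  cat(sprintf("  Cochran's Q = %.4g on %s df, p = %.3g\n",
              s$Q, format(s$Q_df), s$Q_pval))
  if (is.finite(s$egger_intercept))
    cat(sprintf("  Egger intercept = %.4g (se %.3g), p = %.3g\n",
                s$egger_intercept, s$egger_intercept_se, s$egger_intercept_pval))
  if (length(x$fit$skipped))
    cat("  skipped:", paste(names(x$fit$skipped), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$results$beta, object$results$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- cbind(object$results$beta - z * object$results$se,
             object$results$beta + z * object$results$se)
  dimnames(m) <- list(object$results$method,
                      sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100))
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' Scatter plot of a two-sample MR fit
#'
#' SNP-level exposure vs outcome effects with 95% error bars and the
#' fitted IVW (through the origin) and MR-Egger lines.
#'
#' @param x an `mr_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  h <- x$harmonized
  graphics::plot(h$beta_exp, h$beta_out,
                 xlab = "SNP effect on exposure", ylab = "SNP effect on outcome",
                 pch = 19, ...)
  graphics::segments(h$beta_exp, h$beta_out - Z95 * h$se_out,
                     h$beta_exp, h$beta_out + Z95 * h$se_out, col = "grey60")
  r <- x$results
  if ("ivw_re" %in% r$method)
    graphics::abline(0, r$beta[r$method == "ivw_re"], col = "firebrick", lwd = 2)
  if ("egger" %in% r$method)
    graphics::abline(x$sensitivity$egger_intercept,
                     r$beta[r$method == "egger"], col = "steelblue",
                     lwd = 2, lty = 2)
  invisible(x)
}
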