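# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# numerically stable log(sum(exp(x))); -Inf-safe
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# DNA complement for allele strings (vectorised)
allele_complement <- function(a) chartr("ACGT", "TGCA", a)

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

# two-sided normal p-value from a z statistic
z_pval <- function(z) 2 * stats::pnorm(-abs(z))

# 95% normal CI half-width multiplier used throughout
Z95 <- stats::qnorm(0.975)

stop_mr <- function(...) stop(sprintf(...), call. = FALSE)

warn_mr <- function(...) warning(sprintf(...), call. = FALSE)
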