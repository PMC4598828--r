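#' Upper-tail binomial probability for methylation calling
#'
#' Probability of observing at least `m` methylated read calls among `x`
#' reads covering a cytosine when the true methylation level is zero and
#' each read independently fails bisulphite conversion with probability
#' `error_rate`. This is the null P value of the methylcytosine caller:
#' `P(X >= m)` for `X ~ Binomial(x, error_rate)`, with the inclusive tail
#' convention so `m = 0` always gives 1.
#'
#' @param m Integer vector, number of methylated read calls (0 <= m <= x).
#' @param x Integer vector, read depth at the site.
#' @param error_rate Non-conversion probability in `[0, 1)`, typically
#'   estimated from an unmethylated control contig with
#'   [estimate_error_rate()].
#' @return Numeric vector of tail probabilities.
#' @examples
#' binomial_pvalue(0, 30, 5e-4)   # 1
#' binomial_pvalue(5, 5, 5e-4)    # (5e-4)^5
#' @export
binomial_pvalue <- function(m, x, error_rate) {
  if (!is_probability(error_rate) || any(error_rate >= 1)) {
    stop("error_rate must be in [0, 1)", call. = FALSE)
  }
  if (any(m < 0) || any(x < 0)) stop("m and x must be non-negative", call. = FALSE)
  if (any(m > x)) stop("m cannot exceed the depth x", call. = FALSE)
  pbinom(m - 1, x, error_rate, lower.tail = FALSE)
}

# Two-sided Fisher exact P for a 2x2 table [[a, b], [c, d]], computed from
# the conditional hypergeometric distribution with the standard
# minimum-likelihood two-sided rule (sum of all outcome probabilities not
# exceeding that of the observed table, within a small relative epsilon).
fisher_p2 <- function(a, b, c, d) {
  if (min(a, b, c, d) < 0) stop("Fisher table entries must be non-negative", call. = FALSE)
  m <- a + b
  n <- c + d
  k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- dhyper(support, m, n, k)
  obs <- dens[a - lo + 1L]
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Two-sided Fisher exact test on pooled bin counts
#'
#' Vectorised over parallel count vectors; each element is an independent
#' 2x2 table `[[meth_A, unmeth_A], [meth_B, unmeth_B]]`. A table in which
#' one sample has zero total depth is degenerate and returns P = 1 with a
#' warning.
#'
#' @param meth_a,unmeth_a,meth_b,unmeth_b Non-negative integer vectors of
#'   pooled methylated/unmethylated read counts.
#' @return Numeric vector of two-sided P values.
#' @export
fisher_test_counts <- function(meth_a, unmeth_a, meth_b, unmeth_b) {
  n <- length(meth_a)
  stopifnot(length(unmeth_a) == n, length(meth_b) == n, length(unmeth_b) == n)
  degenerate <- (meth_a + unmeth_a) == 0 | (meth_b + unmeth_b) == 0
  if (any(degenerate)) {
    warning(sprintf("%d table(s) with a zero-depth sample; returning P = 1 for those",
                    sum(degenerate)), call. = FALSE)
  }
  p <- rep(1, n)
  idx <- which(!degenerate)
  p[idx] <- vapply(idx, function(i) {
    fisher_p2(meth_a[i], unmeth_a[i], meth_b[i], unmeth_b[i])
  }, numeric(1))
  p
}

#' Multiple-testing correction for binned methylation tests
#'
#' Benjamini-Hochberg (default) or a SLIM-style pi0-rescaled variant.
#' The SLIM mode estimates the null proportion pi0 on a lambda grid with a
#' spline smoother (qvalue-style) and rescales the BH values; the published
#' sliding-linear-model fitting constants are not reproduced, so SLIM mode
#' documents itself as approximate.
#'
#' @param p Numeric vector of P values in `[0, 1]`.
#' @param correction `"BH"` or `"SLIM"`.
#' @return Numeric vector of q values (same length as `p`).
#' @export
adjust_pvalues <- function(p, correction = c("BH", "SLIM")) {
  correction <- match.arg(correction)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p values must be in [0, 1] and non-missing", call. = FALSE)
  }
  q <- p.adjust(p, method = "BH")
  if (correction == "SLIM") {
    q <- pmin(1, estimate_pi0(p) * q)
  }
  q
}

# Spline-smoothed pi0 estimate on a lambda grid; conservative fallbacks for
# tiny inputs.
estimate_pi0 <- function(p) {
  if (length(p) < 20) return(1)
  lambda <- seq(0.05, 0.9, by = 0.05)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- try(smooth.spline(lambda, pi0_l, df = 3), silent = TRUE)
  pi0 <- if (inherits(fit, "try-error")) min(pi0_l) else predict(fit, x = max(lambda))$y
  min(1, max(pi0, 1e-3))
}

# Two-sided rank-sum (Wilcoxon) test wrapper: exact when the combined
# sample size is small and tie-free, otherwise the normal approximation
# with continuity correction.
rank_sum_p <- function(x, y, exact_max = 20) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) return(NA_real_)
  exact <- (length(x) + length(y)) <= exact_max && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  ht$p.value
}
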