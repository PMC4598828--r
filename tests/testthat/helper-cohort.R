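# Shared fixtures, generated in code and cached for the test session.

# Small cohort for fast unit tests: 100-kb chromosome, 5-kb control contig.
small_config <- function(seed = 11, ...) {
  defaults <- list(chrom_length = 1e5, control_length = 5e3,
                   gene_count = 30, te_count = 20, n_planted_dmrs = 20,
                   seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, config) {
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(config)
  }
  .cohort_cache[[key]]
}

small_cohort <- function() cached_cohort("small", small_config())

# Reference benchmarking cohort at generator defaults (1 Mb, 200 planted
# DMRs); used by the recovery and integration acceptance checks.
default_cohort <- function() cached_cohort("default", simulation_config(seed = 2024))

# Calls for both samples with the error rate estimated from the control
# contig, control contig excluded from the analysable tables.
cohort_calls <- function(cohort) {
  key <- paste0("calls_", substr(digest_key(cohort), 1, 8))
  if (is.null(.cohort_cache[[key]])) {
    err <- estimate_error_rate(cohort$cx$A, cohort$bundle$control_chrom)
    cp <- call_params(error_rate = err)
    drop_ctrl <- function(x) x[x$chrom != cohort$bundle$control_chrom, ]
    .cohort_cache[[key]] <- list(
      a = call_methylcytosines(drop_ctrl(cohort$cx$A), cp),
      b = call_methylcytosines(drop_ctrl(cohort$cx$B), cp),
      params = cp)
  }
  .cohort_cache[[key]]
}

digest_key <- function(cohort) {
  paste0(cohort$config$seed, "_", cohort$config$chrom_length)
}

# Exhaustive-enumeration oracles, independent of the implementation paths.

# binomial upper tail by direct pmf summation
oracle_binom_tail <- function(m, x, e) {
  if (m == 0) return(1)
  sum(vapply(m:x, function(k) choose(x, k) * e^k * (1 - e)^(x - k), numeric(1)))
}

# two-sided Fisher p by enumerating all tables with the observed margins,
# probabilities from the closed-form hypergeometric expression
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  prob <- vapply(lo:hi, function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, numeric(1))
  obs <- prob[a - lo + 1]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# two-sided rank-sum p by full enumeration of group assignments
oracle_ranksum_p <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v); k <- length(x)
  obs <- sum(rank(all_v)[seq_len(k)])
  sums <- apply(utils::combn(n, k), 2, function(idx) sum(rank(all_v)[idx]))
  mu <- k * (n + 1) / 2
  min(1, mean(abs(sums - mu) >= abs(obs - mu) - 1e-9))
}
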