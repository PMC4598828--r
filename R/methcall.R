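#' Estimate the bisulphite non-conversion error rate from a control contig
#'
#' The pooled, read-weighted fraction of methylated calls over all sites of
#' a contig known to be unmethylated (in plants typically the chloroplast):
#' `sum(m) / sum(m + u)`. This is the binomial null parameter of the
#' methylcytosine caller.
#'
#' @param sites Cytosine site tibble (`chrom`, `count_meth`, `count_unmeth`,
#'   ...).
#' @param control_chrom Name of the control contig; if `NULL`, all rows of
#'   `sites` are assumed to be control sites.
#' @return The estimated error rate (a single probability).
#' @export
estimate_error_rate <- function(sites, control_chrom = NULL) {
  assert_columns(sites, c("count_meth", "count_unmeth"))
  if (!is.null(control_chrom)) {
    sites <- filter(sites, .data$chrom %in% control_chrom)
    if (nrow(sites) == 0) {
      stop(sprintf("no sites on control contig '%s'", control_chrom), call. = FALSE)
    }
  }
  total <- sum(sites$count_meth) + sum(sites$count_unmeth)
  if (total == 0) stop("cannot estimate error rate: zero total depth on control sites",
                       call. = FALSE)
  sum(sites$count_meth) / total
}

#' Call methylcytosines by binomial test
#'
#' For every input site computes the methylation level (percent of reads
#' supporting methylation) and the upper-tail binomial P value under the
#' non-conversion null ([binomial_pvalue()]). A site is called a
#' methylcytosine iff its depth is at least `min_depth` and its P value is
#' at most `alpha` (both thresholds inclusive).
#'
#' @param sites Cytosine site tibble with columns `chrom`, `pos`, `strand`,
#'   `context`, `count_meth`, `count_unmeth`.
#' @param params A [call_params()] (carries `alpha`, `min_depth`,
#'   `error_rate`).
#' @return The input tibble plus `depth`, `level` (percent; `NA` at zero
#'   depth), `p_value` and `is_mC`.
#' @examples
#' sites <- tibble::tibble(chrom = "chr1", pos = 1:2, strand = "+",
#'                         context = "CG", count_meth = c(9L, 0L),
#'                         count_unmeth = c(1L, 30L))
#' call_methylcytosines(sites, call_params(error_rate = 5e-4))
#' @export
call_methylcytosines <- function(sites, params = call_params()) {
  stopifnot(inherits(params, "call_params"))
  assert_columns(sites, c("chrom", "pos", "strand", "context",
                          "count_meth", "count_unmeth"))
  if (nrow(sites) == 0) {
    return(mutate(sites, depth = integer(), level = numeric(),
                  p_value = numeric(), is_mC = logical()))
  }
  depth <- sites$count_meth + sites$count_unmeth
  p <- binomial_pvalue(sites$count_meth, depth, params$error_rate)
  sites |>
    mutate(depth = as.integer(depth),
           level = ifelse(depth > 0, 100 * .data$count_meth / depth, NA_real_),
           p_value = p,
           is_mC = depth >= params$min_depth & p <= params$alpha)
}

#' Genome-wide methylation summary
#'
#' Summarises a methylcytosine call table: the fraction of mCs in each
#' sequence context, the mean methylation level of mCs per context, the
#' overall mC frequency (percentage of callable cytosines that are mCs)
#' and per-strand mC counts.
#'
#' @param calls Output of [call_methylcytosines()].
#' @param min_depth Depth threshold defining the "covered" denominator.
#' @param denominator `"covered"` divides mC counts by cytosines with depth
#'   at least `min_depth`; `"all"` divides by every input site.
#' @return An object of class `methylome_summary`; `tidy()` gives the
#'   per-context table, `glance()` the genome-wide one-row summary.
#' @export
summarize_methylome <- function(calls, min_depth = 5,
                                denominator = c("covered", "all")) {
  denominator <- match.arg(denominator)
  assert_columns(calls, c("context", "strand", "level", "is_mC", "depth"))
  if (nrow(calls) == 0) stop("call table is empty", call. = FALSE)
  mc <- filter(calls, .data$is_mC)
  n_mc <- nrow(mc)
  by_context <- purrr::map_dfr(CONTEXTS, function(cx) {
    sub <- filter(mc, .data$context == cx)
    tibble(context = cx, n_mC = nrow(sub),
           fraction_of_mCs = if (n_mc > 0) 100 * nrow(sub) / n_mc else 0,
           mean_level = if (nrow(sub) > 0) mean(sub$level) else NA_real_)
  })
  denom <- if (denominator == "covered") sum(calls$depth >= min_depth) else nrow(calls)
  per_strand <- calls |>
    filter(.data$is_mC) |>
    count(.data$strand, name = "n_mC")
  structure(list(by_context = by_context,
                 mc_frequency = if (denom > 0) 100 * n_mc / denom else NA_real_,
                 n_mC = n_mc, n_denominator = denom,
                 per_strand = per_strand, denominator = denominator),
            class = "methylome_summary")
}

#' @export
print.methylome_summary <- function(x, ...) {
  cat("<methylome_summary>\n")
  cat(sprintf("  mC frequency: %.2f%% (%s of %s %s cytosines)\n",
              x$mc_frequency, format(x$n_mC, big.mark = ","),
              format(x$n_denominator, big.mark = ","), x$denominator))
  print(x$by_context)
  invisible(x)
}

#' @rdname summarize_methylome
#' @param x A `methylome_summary`.
#' @param ... Unused.
#' @export
tidy.methylome_summary <- function(x, ...) x$by_context

#' @rdname summarize_methylome
#' @export
glance.methylome_summary <- function(x, ...) {
  tibble(n_mC = x$n_mC, n_denominator = x$n_denominator,
         mc_frequency = x$mc_frequency,
         n_mC_plus = sum(x$per_strand$n_mC[x$per_strand$strand == "+"]),
         n_mC_minus = sum(x$per_strand$n_mC[x$per_strand$strand == "-"]))
}
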