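#' Pool methylation calls of two samples into fixed genomic bins
#'
#' Tiles each chromosome with non-overlapping bins of `bin_size` bases
#' (`[k*bin_size + 1, (k+1)*bin_size]`) and pools read counts of the two
#' samples over qualifying sites. A site qualifies only if it is covered
#' by at least `min_site_depth` reads in *both* samples (and matches
#' `context_mode`); bins with no qualifying site are omitted.
#'
#' @param calls_a,calls_b Call tables from [call_methylcytosines()] for the
#'   test (A) and reference (B) samples, on the same genome build.
#' @param params A [dmr_params()].
#' @return Tibble of bins: `chrom`, `start`, `end`, `n_sites`, `n_mC`,
#'   `meth_A`, `unmeth_A`, `meth_B`, `unmeth_B`, `level_A`, `level_B`.
#' @export
bin_methylome <- function(calls_a, calls_b, params = dmr_params()) {
  stopifnot(inherits(params, "dmr_params"))
  for (x in list(calls_a, calls_b)) {
    assert_columns(x, c("chrom", "pos", "strand", "context",
                        "count_meth", "count_unmeth", "depth", "is_mC"))
  }
  only_a <- setdiff(unique(calls_a$chrom), unique(calls_b$chrom))
  only_b <- setdiff(unique(calls_b$chrom), unique(calls_a$chrom))
  if (length(only_a) + length(only_b) > 0) {
    stop(sprintf("chromosome sets differ between samples (only in A: %s; only in B: %s)",
                 paste(only_a, collapse = ",") %||% "-",
                 paste(only_b, collapse = ",") %||% "-"), call. = FALSE)
  }
  joined <- inner_join(
    select(calls_a, "chrom", "pos", "strand", "context",
           m_a = "count_meth", u_a = "count_unmeth", d_a = "depth", mc_a = "is_mC"),
    select(calls_b, "chrom", "pos", "strand",
           m_b = "count_meth", u_b = "count_unmeth", d_b = "depth", mc_b = "is_mC"),
    by = c("chrom", "pos", "strand"))
  joined <- filter(joined, .data$d_a >= params$min_site_depth,
                   .data$d_b >= params$min_site_depth)
  if (params$context_mode != "combined") {
    joined <- filter(joined, .data$context == params$context_mode)
  }
  bs <- params$bin_size
  joined |>
    mutate(start = as.integer(((.data$pos - 1L) %/% bs) * bs + 1L)) |>
    group_by(.data$chrom, .data$start) |>
    summarise(
      end = .data$start[1] + bs - 1L,
      n_sites = dplyr::n(),
      n_mC = if (params$mc_rule == "either") sum(.data$mc_a | .data$mc_b)
             else sum(.data$mc_a & .data$mc_b),
      meth_A = sum(.data$m_a), unmeth_A = sum(.data$u_a),
      meth_B = sum(.data$m_b), unmeth_B = sum(.data$u_b),
      level_A = if (params$level_mode == "pooled")
        100 * sum(.data$m_a) / sum(.data$m_a + .data$u_a)
        else mean(100 * .data$m_a / .data$d_a),
      level_B = if (params$level_mode == "pooled")
        100 * sum(.data$m_b) / sum(.data$m_b + .data$u_b)
        else mean(100 * .data$m_b / .data$d_b),
      .groups = "drop") |>
    arrange(.data$chrom, .data$start)
}

#' Call differentially methylated regions from binned counts
#'
#' Tests every bin with a two-sided Fisher exact test on the pooled 2x2
#' count table, corrects P values over *all* tested bins genome-wide, and
#' reports as DMRs the bins satisfying all three inclusive filters: at
#' least `min_mcs` methylcytosines, absolute level difference at least
#' `min_diff` percentage points, and q value at most `max_q`. `diff` is
#' `level_A - level_B`; positive differences are `hyper` (sample A
#' hypermethylated relative to the reference).
#'
#' @param bins Bin table from [bin_methylome()].
#' @param params The same [dmr_params()] used for binning.
#' @return An object of class `dmr_result` with elements `bins` (all
#'   tested bins with `p_value`, `q_value`, `diff`, `is_dmr`), `dmrs`
#'   (the passing bins with `direction`) and `params`. `tidy()` returns
#'   the DMR table, `glance()` one-row counts.
#' @export
call_dmrs <- function(bins, params = dmr_params()) {
  stopifnot(inherits(params, "dmr_params"))
  assert_columns(bins, c("chrom", "start", "end", "n_sites", "n_mC",
                         "meth_A", "unmeth_A", "meth_B", "unmeth_B",
                         "level_A", "level_B"))
  bins <- bins |>
    mutate(p_value = fisher_test_counts(.data$meth_A, .data$unmeth_A,
                                        .data$meth_B, .data$unmeth_B),
           q_value = adjust_pvalues(.data$p_value, params$correction),
           diff = .data$level_A - .data$level_B,
           is_dmr = .data$n_mC >= params$min_mcs &
                    abs(.data$diff) >= params$min_diff &
                    .data$q_value <= params$max_q)
  dmrs <- bins |>
    filter(.data$is_dmr) |>
    mutate(direction = ifelse(.data$diff > 0, "hyper", "hypo"))
  structure(list(bins = bins, dmrs = dmrs, params = params),
            class = "dmr_result")
}

#' @export
print.dmr_result <- function(x, ...) {
  cat("<dmr_result>\n")
  cat(sprintf("  %s bins tested; %s DMRs (%s hyper, %s hypo)\n",
              format(nrow(x$bins), big.mark = ","),
              format(nrow(x$dmrs), big.mark = ","),
              sum(x$dmrs$direction == "hyper"), sum(x$dmrs$direction == "hypo")))
  invisible(x)
}

#' @rdname call_dmrs
#' @param x A `dmr_result`.
#' @param ... Unused.
#' @export
tidy.dmr_result <- function(x, ...) {
  select(x$dmrs, "chrom", "start", "end", "n_sites", "n_mC",
         "level_A", "level_B", "diff", "p_value", "q_value", "direction")
}

#' @rdname call_dmrs
#' @export
glance.dmr_result <- function(x, ...) {
  tibble(n_bins_tested = nrow(x$bins), n_dmrs = nrow(x$dmrs),
         n_hyper = sum(x$dmrs$direction == "hyper"),
         n_hypo = sum(x$dmrs$direction == "hypo"),
         min_diff = x$params$min_diff, max_q = x$params$max_q,
         min_mcs = x$params$min_mcs)
}
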