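#' Associate DMRs with genes and transposable elements
#'
#' A DMR is placed relative to a feature solely by its midpoint
#' (`floor((start + end) / 2)`): `genic` if the midpoint lies within the
#' feature body, otherwise `flank_upstream` / `flank_downstream` if within
#' `flank` bases of the strand-appropriate feature end. A DMR may
#' associate with several features (one row each); DMRs matching no
#' feature are absent from the output. Unstranded features (`strand
#' "."`) are treated as plus-strand with a warning, so flank labels follow
#' genomic left/right.
#'
#' @param dmrs A `dmr_result` or a DMR tibble with `chrom`, `start`,
#'   `end`, `diff`, `direction`.
#' @param genes,tes Feature tibbles (`feature_id`, `chrom`, `start`,
#'   `end`, `strand`); either may be empty or `NULL`.
#' @param flank Flank width in bases (default 2000).
#' @return Tibble: `dmr_id`, `chrom`, `start`, `end`, `diff`, `direction`,
#'   `feature_id`, `feature_kind`, `placement`.
#' @export
associate_dmrs <- function(dmrs, genes, tes = NULL, flank = 2000) {
  dmr_tbl <- if (inherits(dmrs, "dmr_result")) tidy(dmrs) else dmrs
  assert_columns(dmr_tbl, c("chrom", "start", "end", "diff", "direction"))
  feats <- bind_rows(
    if (!is.null(genes) && nrow(genes) > 0) mutate(genes, feature_kind = "gene"),
    if (!is.null(tes) && nrow(tes) > 0) mutate(tes, feature_kind = "TE"))
  empty <- tibble(dmr_id = character(), chrom = character(), start = integer(),
                  end = integer(), diff = numeric(), direction = character(),
                  feature_id = character(), feature_kind = character(),
                  placement = character())
  if (is.null(feats) || nrow(feats) == 0 || nrow(dmr_tbl) == 0) return(empty)
  if (any(feats$strand == ".")) {
    warning("unstranded feature(s): flank placement uses genomic left/right",
            call. = FALSE)
    feats$strand[feats$strand == "."] <- "+"
  }
  flank <- as.integer(flank)
  mid <- as.integer(floor((dmr_tbl$start + dmr_tbl$end) / 2))
  q <- GenomicRanges::GRanges(dmr_tbl$chrom, IRanges::IRanges(mid, width = 1))
  ext <- GenomicRanges::GRanges(feats$chrom,
           IRanges::IRanges(pmax(1L, feats$start - flank), feats$end + flank))
  hits <- GenomicRanges::findOverlaps(q, ext)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  m <- mid[qi]
  fs <- feats$start[si]; fe <- feats$end[si]; fstr <- feats$strand[si]
  placement <- ifelse(m >= fs & m <= fe, "genic",
               ifelse(m < fs,
                      ifelse(fstr == "+", "flank_upstream", "flank_downstream"),
                      ifelse(fstr == "+", "flank_downstream", "flank_upstream")))
  tibble(dmr_id = sprintf("%s:%d-%d", dmr_tbl$chrom[qi], dmr_tbl$start[qi],
                          dmr_tbl$end[qi]),
         chrom = dmr_tbl$chrom[qi], start = dmr_tbl$start[qi],
         end = dmr_tbl$end[qi], diff = dmr_tbl$diff[qi],
         direction = dmr_tbl$direction[qi],
         feature_id = feats$feature_id[si],
         feature_kind = feats$feature_kind[si],
         placement = placement) |>
    distinct()
}

#' Compare DMR methylation-level differences between gene- and
#' TE-associated DMRs
#'
#' Groups the absolute level differences of DMRs by the kind of feature
#' they associate with (a DMR associated with both kinds contributes to
#' both groups) and compares the two distributions with a two-sided
#' rank-sum test.
#'
#' @param associations Output of [associate_dmrs()].
#' @return List with `summary` (per-group `n`, `median`, `q1`, `q3`) and
#'   `p_value` (two-sided rank-sum; `NA` if a group is empty).
#' @export
dmr_level_difference_by_feature <- function(associations) {
  assert_columns(associations, c("dmr_id", "feature_kind", "diff"))
  by_kind <- associations |>
    distinct(.data$dmr_id, .data$feature_kind, .data$diff) |>
    mutate(abs_diff = abs(.data$diff))
  summary <- by_kind |>
    group_by(.data$feature_kind) |>
    summarise(n = dplyr::n(), median = median(.data$abs_diff),
              q1 = unname(quantile(.data$abs_diff, 0.25)),
              q3 = unname(quantile(.data$abs_diff, 0.75)), .groups = "drop")
  g <- by_kind$abs_diff[by_kind$feature_kind == "gene"]
  t <- by_kind$abs_diff[by_kind$feature_kind == "TE"]
  p <- if (length(g) == 0 || length(t) == 0) NA_real_ else rank_sum_p(g, t)
  list(summary = summary, p_value = p)
}
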