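#' Overlap between methylcytosines and small-RNA loci
#'
#' Computes, per sequence context and overall, the fraction of called
#' methylcytosines whose position lies inside a small-RNA locus, and the
#' fraction of loci containing at least one methylcytosine.
#'
#' @param smrna Locus tibble (`chrom`, `start`, `end`; 1-based inclusive).
#' @param calls Call table from [call_methylcytosines()]; only rows with
#'   `is_mC` are used.
#' @return List with `by_context` (tibble: `context`, `n_mC`,
#'   `n_mC_in_loci`, `fraction_in_loci` as a percentage) and
#'   `fraction_loci_with_mc` (percentage of loci containing a mC).
#' @export
smrna_mc_overlap <- function(smrna, calls) {
  assert_columns(smrna, c("chrom", "start", "end"))
  assert_columns(calls, c("chrom", "pos", "context", "is_mC"))
  mc <- filter(calls, .data$is_mC)
  if (nrow(smrna) == 0 || nrow(mc) == 0) {
    by_context <- tibble(context = c(CONTEXTS, "all"),
                         n_mC = 0L, n_mC_in_loci = 0L, fraction_in_loci = 0)
    by_context$n_mC <- c(as.integer(table(factor(mc$context, CONTEXTS))), nrow(mc))
    return(list(by_context = by_context, fraction_loci_with_mc = 0))
  }
  q <- GenomicRanges::GRanges(mc$chrom, IRanges::IRanges(mc$pos, width = 1))
  s <- GenomicRanges::GRanges(smrna$chrom, IRanges::IRanges(smrna$start, smrna$end))
  inside <- IRanges::overlapsAny(q, s)
  by_context <- purrr::map_dfr(c(as.list(CONTEXTS), list("all")), function(cx) {
    sel <- if (identical(cx, "all")) rep(TRUE, nrow(mc)) else mc$context == cx
    n <- sum(sel)
    tibble(context = cx, n_mC = n, n_mC_in_loci = sum(inside & sel),
           fraction_in_loci = if (n > 0) 100 * sum(inside & sel) / n else 0)
  })
  loci_hit <- IRanges::overlapsAny(s, q)
  list(by_context = by_context,
       fraction_loci_with_mc = 100 * mean(loci_hit))
}

#' Small-RNA enrichment in DMR-associated gene classes
#'
#' For each methylation class of genes, the fold enrichment of small-RNA
#' locus density (loci per kb of class gene territory, counted by locus
#' midpoint) relative to the density over the territory of all genes,
#' with a two-sided Fisher exact test on locus counts versus territory
#' sizes discretised to whole kb.
#'
#' @param smrna Locus tibble (`chrom`, `start`, `end`).
#' @param gene_classes Tibble with `gene_id`, `meth_class` (e.g. from
#'   [classify_dmr_genes()]); every distinct class is reported.
#' @param genes Gene tibble (`feature_id`, `chrom`, `start`, `end`)
#'   defining the all-genes baseline territory.
#' @return Tibble: `class`, `n_genes`, `territory_kb`, `n_loci`,
#'   `density_per_kb`, `fold`, `p_value`.
#' @export
smrna_dmr_enrichment <- function(smrna, gene_classes, genes) {
  assert_columns(genes, c("feature_id", "chrom", "start", "end"))
  assert_columns(gene_classes, c("gene_id", "meth_class"))
  if (nrow(genes) == 0) stop("zero gene territory", call. = FALSE)
  mid <- floor((smrna$start + smrna$end) / 2)
  gene_len <- genes$end - genes$start + 1
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                IRanges::IRanges(genes$start, genes$end))
  q <- GenomicRanges::GRanges(smrna$chrom, IRanges::IRanges(mid, width = 1))
  hit_gene <- GenomicRanges::findOverlaps(q, gr_genes, select = "first")
  loci_gene <- genes$feature_id[hit_gene[!is.na(hit_gene)]]
  all_kb <- sum(gene_len) / 1000
  all_n <- length(loci_gene)
  all_density <- all_n / all_kb
  purrr::map_dfr(unique(gene_classes$meth_class), function(cl) {
    ids <- gene_classes$gene_id[gene_classes$meth_class == cl]
    sel <- genes$feature_id %in% ids
    kb <- sum(gene_len[sel]) / 1000
    if (kb == 0) stop(sprintf("zero territory for class '%s'", cl), call. = FALSE)
    n <- sum(loci_gene %in% genes$feature_id[sel])
    density <- n / kb
    fold <- if (all_density > 0) density / all_density else NA_real_
    kb_units <- max(1L, round(kb))
    kb_other <- max(1L, round(all_kb - kb))
    p <- if (setequal(ids, genes$feature_id)) 1 else
      fisher_p2(n, all_n - n, kb_units, kb_other)
    tibble(class = cl, n_genes = sum(sel), territory_kb = kb, n_loci = n,
           density_per_kb = density, fold = fold, p_value = p)
  })
}
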