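#' Call differentially expressed genes from replicated abundances
#'
#' A pragmatic replacement for an upstream differential-expression engine:
#' log2 fold change from replicate means (pseudocount 0.01), a two-sided
#' two-sample t-test on log2 abundances, and status thresholds `up` iff
#' `log2fc >= log2(min_fold_change)` and `p <= max_p` (symmetrically for
#' `down`). Precomputed DE tables can be supplied downstream instead.
#' With a single replicate per sample the P value is undefined and status
#' is decided on fold change alone, with a warning.
#'
#' @param expression Long tibble: `gene_id`, `sample` (`"A"`/`"B"`),
#'   `replicate`, `abundance`.
#' @param params A [deg_params()].
#' @param pseudocount Added to abundances before taking logs.
#' @return Tibble: `gene_id`, `abundance_A`, `abundance_B` (replicate
#'   means), `log2fc` (A over B), `p_value`, `de_status`.
#' @export
call_degs <- function(expression, params = deg_params(), pseudocount = 0.01) {
  stopifnot(inherits(params, "deg_params"))
  assert_columns(expression, c("gene_id", "sample", "replicate", "abundance"))
  n_rep <- expression |> count(.data$gene_id, .data$sample) |> pull(.data$n)
  single <- any(n_rep < 2)
  if (single) {
    warning("single replicate: P values undefined, DE status from fold change alone",
            call. = FALSE)
  }
  lfc_cut <- log2(params$min_fold_change)
  wide <- expression |>
    mutate(log2_ab = log2(.data$abundance + pseudocount)) |>
    group_by(.data$gene_id) |>
    summarise(
      abundance_A = mean(.data$abundance[.data$sample == "A"]),
      abundance_B = mean(.data$abundance[.data$sample == "B"]),
      log2fc = mean(.data$log2_ab[.data$sample == "A"]) -
               mean(.data$log2_ab[.data$sample == "B"]),
      p_value = if (sum(.data$sample == "A") < 2 || sum(.data$sample == "B") < 2)
        NA_real_
      else safe_t_p(.data$log2_ab[.data$sample == "A"],
                    .data$log2_ab[.data$sample == "B"]),
      .groups = "drop")
  wide |>
    mutate(de_status = dplyr::case_when(
      .data$log2fc >= lfc_cut & (is.na(.data$p_value) | .data$p_value <= params$max_p) ~ "up",
      .data$log2fc <= -lfc_cut & (is.na(.data$p_value) | .data$p_value <= params$max_p) ~ "down",
      TRUE ~ "not_de"))
}

# t-test p that tolerates zero-variance data (identical replicates).
safe_t_p <- function(x, y) {
  if (stats::sd(c(x, y)) == 0) return(1)
  out <- try(t.test(x, y)$p.value, silent = TRUE)
  if (inherits(out, "try-error")) 1 else out
}

#' Classify DMR-associated genes as hyper- or hypomethylated
#'
#' A gene associated with one or more DMRs takes the direction of its
#' largest-|diff| DMR; genes whose largest hyper and hypo DMRs tie in
#' |diff| are excluded.
#'
#' @param associations Output of [associate_dmrs()] (gene rows are used).
#' @return Tibble: `gene_id`, `meth_class` (`"hyper"` / `"hypo"`).
#' @export
classify_dmr_genes <- function(associations) {
  assert_columns(associations, c("feature_id", "feature_kind", "diff", "direction"))
  associations |>
    filter(.data$feature_kind == "gene") |>
    group_by(gene_id = .data$feature_id) |>
    summarise(meth_class = {
      top <- max(abs(.data$diff))
      dirs <- unique(.data$direction[abs(.data$diff) == top])
      if (length(dirs) == 1) dirs else NA_character_
    }, .groups = "drop") |>
    filter(!is.na(.data$meth_class))
}

#' Compare differential expression across methylation classes
#'
#' Contrasts the log2 fold-change distribution of genes associated with
#' hyper- or hypomethylated DMRs against all (expressed) genes, reporting
#' per-class summaries and two-sided rank-sum P values (exact for small
#' tie-free samples, normal approximation with continuity correction
#' otherwise).
#'
#' @param degs DE table from [call_degs()] (or equivalent, with `gene_id`
#'   and `log2fc`).
#' @param gene_classes Output of [classify_dmr_genes()].
#' @return Object of class `meth_expr_comparison`; `tidy()` gives per-class
#'   `n`, `median`, `q1`, `q3`, `p_value` (vs all genes), `glance()` a
#'   one-row overview, `autoplot()` the box plot.
#' @export
compare_expression_by_methylation <- function(degs, gene_classes) {
  assert_columns(degs, c("gene_id", "log2fc"))
  assert_columns(gene_classes, c("gene_id", "meth_class"))
  all_fc <- degs$log2fc
  class_fc <- lapply(c(hyper = "hyper", hypo = "hypo"), function(cl) {
    ids <- gene_classes$gene_id[gene_classes$meth_class == cl]
    degs$log2fc[degs$gene_id %in% ids]
  })
  groups <- c(class_fc, list(all_genes = all_fc))
  stats_tbl <- purrr::imap_dfr(groups, function(v, nm) {
    tibble(class = nm, n = length(v),
           median = if (length(v)) median(v) else NA_real_,
           q1 = if (length(v)) unname(quantile(v, 0.25)) else NA_real_,
           q3 = if (length(v)) unname(quantile(v, 0.75)) else NA_real_,
           p_value = if (nm == "all_genes") NA_real_
                     else if (length(v) == 0) NA_real_
                     else rank_sum_p(v, all_fc))
  })
  structure(list(stats = stats_tbl, groups = groups),
            class = "meth_expr_comparison")
}

#' @export
print.meth_expr_comparison <- function(x, ...) {
  cat("<meth_expr_comparison>\n")
  print(x$stats)
  invisible(x)
}

#' @rdname compare_expression_by_methylation
#' @param x A `meth_expr_comparison`.
#' @param ... Unused.
#' @export
tidy.meth_expr_comparison <- function(x, ...) x$stats

#' @rdname compare_expression_by_methylation
#' @export
glance.meth_expr_comparison <- function(x, ...) {
  s <- x$stats
  tibble(n_hyper = s$n[s$class == "hyper"], n_hypo = s$n[s$class == "hypo"],
         n_all = s$n[s$class == "all_genes"],
         median_hyper = s$median[s$class == "hyper"],
         median_hypo = s$median[s$class == "hypo"],
         p_hyper = s$p_value[s$class == "hyper"],
         p_hypo = s$p_value[s$class == "hypo"])
}

#' Directional enrichment of differential expression at DMR genes
#'
#' Tests whether genes associated with hypermethylated DMRs are enriched
#' for downregulation (and hypo-DMR genes for upregulation) with a
#' two-sided Fisher exact test on the 2x2 classification of all genes in
#' the DE table. The `placement` filter restricts which DMR-gene
#' associations count (`"genic"`, `"flanking"`, or `"any"`).
#'
#' @param associations Output of [associate_dmrs()].
#' @param degs DE table with `gene_id` and `de_status`.
#' @param placement Association placement filter.
#' @return Tibble with one row per contrast (`hyper_down`, `hypo_up`):
#'   counts `a` (class & direction), `b`, `c`, `d`, `odds_ratio`
#'   (cross-product; `NA` on a zero margin) and `p_value`.
#' @export
enrichment_direction <- function(associations, degs,
                                 placement = c("genic", "flanking", "any")) {
  placement <- match.arg(placement)
  assert_columns(degs, c("gene_id", "de_status"))
  assoc <- filter(associations, .data$feature_kind == "gene")
  assoc <- switch(placement,
    genic = filter(assoc, .data$placement == "genic"),
    flanking = filter(assoc, .data$placement != "genic"),
    any = assoc)
  classes <- classify_dmr_genes(assoc)
  one <- function(meth_dir, de_dir) {
    in_class <- degs$gene_id %in% classes$gene_id[classes$meth_class == meth_dir]
    in_de <- degs$de_status == de_dir
    a <- sum(in_class & in_de); b <- sum(in_class & !in_de)
    c_ <- sum(!in_class & in_de); d <- sum(!in_class & !in_de)
    degenerate <- (a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0
    tibble(contrast = paste0(meth_dir, "_", de_dir),
           a = a, b = b, c = c_, d = d,
           odds_ratio = if (degenerate) NA_real_ else (a * d) / (b * c_),
           p_value = if (degenerate) 1 else fisher_p2(a, b, c_, d))
  }
  bind_rows(one("hyper", "down"), one("hypo", "up"))
}

#' Classify on/off expression status of genes between two samples
#'
#' A gene is "on" in a sample if its replicate-mean abundance is at least
#' `on_threshold` and "off" if below `off_threshold`; genes in the dead
#' zone in either sample are labelled `excluded` and take no part in
#' on/off contrasts.
#'
#' @param degs DE table with `gene_id`, `abundance_A`, `abundance_B`.
#' @param params A [deg_params()].
#' @return Tibble: `gene_id`, `status` in
#'   `A_on_B_off` / `A_off_B_on` / `both_on` / `both_off` / `excluded`.
#' @export
classify_on_off <- function(degs, params = deg_params()) {
  assert_columns(degs, c("gene_id", "abundance_A", "abundance_B"))
  lab <- function(x) ifelse(x >= params$on_threshold, "on",
                     ifelse(x < params$off_threshold, "off", "dead"))
  a <- lab(degs$abundance_A); b <- lab(degs$abundance_B)
  tibble(gene_id = degs$gene_id,
         status = dplyr::case_when(
           a == "dead" | b == "dead" ~ "excluded",
           a == "on" & b == "off" ~ "A_on_B_off",
           a == "off" & b == "on" ~ "A_off_B_on",
           a == "on" & b == "on" ~ "both_on",
           TRUE ~ "both_off"))
}

#' Mean TE count per gene for gene classes, with permutation test
#'
#' Counts, for every gene, the TEs overlapping the gene extended by
#' `flank` bases on each side, then reports the class mean for each named
#' gene class and a two-sided permutation P value of the difference
#' between the class mean and the complement mean under label shuffling.
#'
#' @param genes Gene tibble (`feature_id`, `chrom`, `start`, `end`).
#' @param tes TE tibble (`chrom`, `start`, `end`).
#' @param classes Named list of character vectors of gene ids; each must
#'   be a subset of `genes$feature_id`.
#' @param flank Extension in bases (default 2000).
#' @param n_perm Number of label shuffles (default 10000).
#' @param seed Seed for the shuffles.
#' @return Tibble: `class`, `n_genes`, `mean_te`, `complement_mean`,
#'   `p_value`.
#' @export
te_density_by_gene_class <- function(genes, tes, classes, flank = 2000,
                                     n_perm = 10000, seed = 1) {
  assert_columns(genes, c("feature_id", "chrom", "start", "end"))
  stopifnot(is.list(classes), !is.null(names(classes)))
  bad <- purrr::imap_chr(classes, function(ids, nm) {
    if (all(ids %in% genes$feature_id)) NA_character_ else nm
  })
  bad <- bad[!is.na(bad)]
  if (length(bad) > 0) {
    stop(sprintf("class(es) not a subset of the gene universe: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  te_count <- count_overlapping_tes(genes, tes, flank)
  with_seed(seed, {
    purrr::imap_dfr(classes, function(ids, nm) {
      in_class <- genes$feature_id %in% ids
      k <- sum(in_class)
      obs <- mean(te_count[in_class]) - mean(te_count[!in_class])
      perm <- replicate(n_perm, {
        idx <- sample.int(length(te_count), k)
        mean(te_count[idx]) - mean(te_count[-idx])
      })
      tibble(class = nm, n_genes = k, mean_te = mean(te_count[in_class]),
             complement_mean = mean(te_count[!in_class]),
             p_value = (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm))
    })
  })
}

count_overlapping_tes <- function(genes, tes, flank) {
  if (is.null(tes) || nrow(tes) == 0) return(rep(0L, nrow(genes)))
  ext <- GenomicRanges::GRanges(genes$chrom,
           IRanges::IRanges(pmax(1L, genes$start - as.integer(flank)),
                            genes$end + as.integer(flank)))
  tg <- GenomicRanges::GRanges(tes$chrom, IRanges::IRanges(tes$start, tes$end))
  GenomicRanges::countOverlaps(ext, tg)
}
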