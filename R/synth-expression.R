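#' Simulate replicated gene expression coupled to planted DMRs
#'
#' Each gene receives a baseline log2 abundance shared by both samples
#' (`Normal(expression_log2_mean, expression_log2_sd)`). Genes whose body
#' or 2-kb flank contains the midpoint of a planted hyper DMR have their
#' sample-A log2 abundance shifted by `-c`; hypo DMRs shift by `+c`
#' (`c = expression_coupling_strength`); a gene carrying both directions
#' nets to zero. Lognormal replicate noise (`replicate_log2_sd` on the
#' log2 scale) is added independently per replicate.
#'
#' @param genes Gene tibble (`feature_id`, `chrom`, `start`, `end`, ...).
#' @param dmr_truth Planted DMR truth from [plant_dmrs()] (may have 0 rows).
#' @param config The [simulation_config()].
#' @param flank Flank width used to couple DMRs to genes (bases).
#' @return List with `expression` (long tibble: `gene_id`, `sample`,
#'   `replicate`, `abundance`) and `truth` (tibble: `gene_id`, `shift`,
#'   `coupling_class` in hyper/hypo/both/none).
#' @export
simulate_expression <- function(genes, dmr_truth, config, flank = 2000) {
  if (config$replicates_per_sample < 2) {
    stop("replicates_per_sample must be at least 2", call. = FALSE)
  }
  cls <- gene_dmr_truth_class(genes, dmr_truth, flank)
  c0 <- config$expression_coupling_strength
  shift <- ifelse(cls == "hyper", -c0, ifelse(cls == "hypo", c0, 0))
  with_seed(derive_seed(config$seed, 6), {
    base <- rnorm(nrow(genes), config$expression_log2_mean, config$expression_log2_sd)
    reps <- seq_len(config$replicates_per_sample)
    grid <- tidyr::expand_grid(gene_idx = seq_len(nrow(genes)),
                               sample = c("A", "B"), replicate = reps)
    mu <- base[grid$gene_idx] + ifelse(grid$sample == "A", shift[grid$gene_idx], 0)
    log2_ab <- mu + rnorm(nrow(grid), 0, config$replicate_log2_sd)
    expression <- tibble(gene_id = genes$feature_id[grid$gene_idx],
                         sample = grid$sample, replicate = grid$replicate,
                         abundance = 2^log2_ab)
    list(expression = expression,
         truth = tibble(gene_id = genes$feature_id, shift = shift,
                        coupling_class = cls))
  })
}

# Direction class of each gene from the planted truth: which planted DMR
# midpoints fall in body +/- flank.
gene_dmr_truth_class <- function(genes, dmr_truth, flank = 2000) {
  cls <- rep("none", nrow(genes))
  if (is.null(dmr_truth) || nrow(dmr_truth) == 0 || nrow(genes) == 0) return(cls)
  mid <- floor((dmr_truth$start + dmr_truth$end) / 2)
  q <- GenomicRanges::GRanges(dmr_truth$chrom, IRanges::IRanges(mid, width = 1))
  ext <- GenomicRanges::GRanges(genes$chrom,
           IRanges::IRanges(pmax(1L, genes$start - as.integer(flank)),
                            genes$end + as.integer(flank)))
  hits <- GenomicRanges::findOverlaps(q, ext)
  if (length(hits) == 0) return(cls)
  hit_tbl <- tibble(gene_idx = S4Vectors::subjectHits(hits),
                    direction = dmr_truth$direction[S4Vectors::queryHits(hits)]) |>
    distinct() |>
    group_by(.data$gene_idx) |>
    summarise(cls = if (dplyr::n_distinct(.data$direction) > 1) "both"
              else .data$direction[1], .groups = "drop")
  cls[hit_tbl$gene_idx] <- hit_tbl$cls
  cls
}

#' Simulate small-RNA loci with planted enrichment at hyper-DMR genes
#'
#' Loci of 21-24 nt are scattered with a base rate per kb across the
#' genome. In sample A the rate is multiplied by `smrna_hyper_fold` inside
#' genes carrying a planted hyper DMR and divided by it inside hypo-DMR
#' genes; sample B uses the base rate everywhere. Per-locus abundance is a
#' geometric-tailed integer >= 1.
#'
#' @param bundle The `synthetic_genome`.
#' @param dmr_truth Planted DMR truth (may have 0 rows).
#' @param config The [simulation_config()].
#' @return Named list of per-sample locus tibbles (`chrom`, `start`, `end`,
#'   `length`, `abundance`; 1-based inclusive coordinates).
#' @export
simulate_smrna <- function(bundle, dmr_truth, config) {
  stopifnot(config$smrna_hyper_fold > 0)
  genes <- bundle$genes
  cls <- gene_dmr_truth_class(genes, dmr_truth)
  chroms <- setdiff(names(bundle$genome), bundle$control_chrom)
  lens <- stats::setNames(Biostrings::width(bundle$genome)[match(chroms, names(bundle$genome))],
                          chroms)
  regions <- purrr::map_dfr(chroms, function(ch) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    gc <- cls[genes$chrom == ch]
    segs <- tibble(start = g$start, end = g$end, class = gc)
    # complement (intergenic) segments of this chromosome
    occ <- sort(unique(c(0L, g$start - 1L, g$end, lens[[ch]])))
    inter <- tibble(start = head(occ, -1) + 1L, end = tail(occ, -1)) |>
      filter(.data$start <= .data$end)
    inter <- dplyr::anti_join(inter, segs[c("start", "end")], by = c("start", "end"))
    bind_rows(mutate(segs, chrom = ch),
              mutate(inter, chrom = ch, class = "none"))
  })
  fold <- config$smrna_hyper_fold
  mult_a <- ifelse(regions$class == "hyper", fold,
                   ifelse(regions$class == "hypo", 1 / fold, 1))
  draw <- function(mult, stage) {
    with_seed(derive_seed(config$seed, stage), {
      lens_kb <- (regions$end - regions$start + 1) / 1000
      n_loci <- rpois(nrow(regions), config$smrna_base_rate_per_kb * lens_kb * mult)
      idx <- rep(seq_len(nrow(regions)), n_loci)
      if (length(idx) == 0) {
        return(tibble(chrom = character(), start = integer(), end = integer(),
                      length = integer(), abundance = integer()))
      }
      len <- sample(21:24, length(idx), replace = TRUE)
      span <- pmax(1L, regions$end[idx] - regions$start[idx] + 1L - len + 1L)
      start <- regions$start[idx] + floor(runif(length(idx)) * span)
      tibble(chrom = regions$chrom[idx], start = as.integer(start),
             end = as.integer(start + len - 1L), length = as.integer(len),
             abundance = 1L + rgeom(length(idx), 0.3)) |>
        arrange(.data$chrom, .data$start)
    })
  }
  list(A = draw(mult_a, 7), B = draw(rep(1, nrow(regions)), 8))
}
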