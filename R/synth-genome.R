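#' Generate a random genome with gene and TE annotation
#'
#' Draws i.i.d. nucleotide sequences at the configured GC fraction for each
#' chromosome plus an unmethylated control contig, then places
#' non-overlapping genes and transposable elements with random strands.
#' With `te_clustering = TRUE` TEs concentrate around the chromosome
#' midpoint and genes toward the arms, giving the pericentromeric
#' repeat-density structure that chromosome-scale methylation tracks
#' correlate against.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_genome` with elements `genome`
#'   (a `Biostrings::DNAStringSet` including the control contig), `genes`
#'   and `tes` (tibbles: `feature_id`, `chrom`, `start`, `end`, `strand`,
#'   `kind`) and `control_chrom` (its name).
#' @export
generate_genome <- function(config) {
  validate_simulation_config(config)
  with_seed(derive_seed(config$seed, 1), {
    chroms <- paste0("chr", seq_len(config$n_chroms))
    lens <- stats::setNames(rep(config$chrom_length, config$n_chroms), chroms)
    seqs <- vapply(lens, random_sequence, character(1), gc = config$gc_fraction)
    ctrl <- random_sequence(config$control_length, config$gc_fraction)
    genome <- Biostrings::DNAStringSet(c(seqs, stats::setNames(ctrl, config$control_chrom)))

    occupied <- lapply(lens, function(L) logical(L))
    genes <- place_features(occupied, lens, config$gene_count,
                            config$gene_length_range, "gene",
                            weight = if (config$te_clustering) "arm" else "uniform")
    occupied <- attr(genes, "occupied")
    tes <- place_features(occupied, lens, config$te_count,
                          config$te_length_range, "TE",
                          weight = if (config$te_clustering) "centre" else "uniform")
    structure(list(genome = genome,
                   genes = strip_occupied(genes),
                   tes = strip_occupied(tes),
                   control_chrom = config$control_chrom),
              class = "synthetic_genome")
  })
}

random_sequence <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

strip_occupied <- function(x) { attr(x, "occupied") <- NULL; x }

# Rejection-sampled non-overlapping placement. `weight` shapes the start
# position density along each chromosome: "centre" peaks at the midpoint,
# "arm" at the ends, "uniform" is flat.
place_features <- function(occupied, lens, n, len_range, kind, weight = "uniform") {
  chroms <- names(lens)
  rows <- vector("list", n)
  if (n > 0) {
    chrom_pick <- sample(chroms, n, replace = TRUE, prob = lens / sum(lens))
    for (i in seq_len(n)) {
      ch <- chrom_pick[i]
      L <- lens[[ch]]
      flen <- sample(seq(len_range[1], len_range[2]), 1)
      placed <- FALSE
      for (attempt in seq_len(500)) {
        start <- sample.int(L - flen + 1L, 1)
        centre_d <- abs((start + flen / 2) / L - 0.5)
        keep <- switch(weight,
          centre = 0.15 + 0.85 * exp(-(centre_d / 0.2)^2),
          arm = 1 - 0.85 * exp(-(centre_d / 0.2)^2),
          uniform = 1)
        if (runif(1) > keep) next
        span <- start:(start + flen - 1L)
        if (!any(occupied[[ch]][span])) {
          occupied[[ch]][span] <- TRUE
          rows[[i]] <- tibble(
            feature_id = sprintf("%s%04d", tolower(kind), i),
            chrom = ch, start = as.integer(start),
            end = as.integer(start + flen - 1L),
            strand = sample(c("+", "-"), 1), kind = kind)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf(paste0("infeasible packing: could not place %s %d of %d ",
                            "(length %d) without overlap on %s"),
                     kind, i, n, flen, ch), call. = FALSE)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(feature_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  kind = character())
  }
  attr(out, "occupied") <- occupied
  out
}
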