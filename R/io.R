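#' Read a Bismark-style CX cytosine report
#'
#' Seven tab-separated columns without header: chromosome, 1-based
#' position, strand (`+`/`-`), methylated read count, unmethylated read
#' count, context (`CG`/`CHG`/`CHH`), trinucleotide. Malformed rows abort
#' with the first offending line number.
#'
#' @param path File path.
#' @return Cytosine site tibble (`chrom`, `pos`, `strand`, `count_meth`,
#'   `count_unmeth`, `context`, `trinucleotide`).
#' @export
read_cx_report <- function(path) {
  raw <- readr::read_tsv(path,
    col_names = c("chrom", "pos", "strand", "count_meth", "count_unmeth",
                  "context", "trinucleotide"),
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_character(),
      strand = readr::col_character(), count_meth = readr::col_character(),
      count_unmeth = readr::col_character(), context = readr::col_character(),
      trinucleotide = readr::col_character()),
    comment = "#", progress = FALSE)
  if (nrow(raw) == 0) {
    warning(sprintf("empty CX report: %s", path), call. = FALSE)
    return(tibble(chrom = character(), pos = integer(), strand = character(),
                  count_meth = integer(), count_unmeth = integer(),
                  context = character(), trinucleotide = character()))
  }
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop(sprintf("malformed CX report %s at line %d: %s", path, prob$row[1],
                 prob$expected[1]), call. = FALSE)
  }
  check <- function(ok, what) {
    if (!all(ok)) {
      stop(sprintf("malformed CX report %s at line %d: %s", path,
                   which(!ok)[1], what), call. = FALSE)
    }
  }
  int_ok <- function(x) grepl("^[0-9]+$", x)
  check(int_ok(raw$pos), "non-integer position")
  check(int_ok(raw$count_meth) & int_ok(raw$count_unmeth), "non-integer count")
  check(raw$strand %in% c("+", "-"), "strand must be + or -")
  check(raw$context %in% CONTEXTS, "unknown context")
  mutate(raw, pos = as.integer(.data$pos),
         count_meth = as.integer(.data$count_meth),
         count_unmeth = as.integer(.data$count_unmeth))
}

#' Write a CX cytosine report
#'
#' @param sites Cytosine site tibble (see [read_cx_report()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cx_report <- function(sites, path) {
  assert_columns(sites, c("chrom", "pos", "strand", "count_meth",
                          "count_unmeth", "context", "trinucleotide"))
  readr::write_tsv(sites[, c("chrom", "pos", "strand", "count_meth",
                             "count_unmeth", "context", "trinucleotide")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Read gene/TE annotation from GFF3 or BED
#'
#' Unifies to internal 1-based inclusive coordinates (BED input, 0-based
#' half-open, is shifted by +1 on the start). Feature identifiers come
#' from the GFF3 `ID` attribute or BED name column, falling back to
#' `kind_chrom_start`.
#'
#' @param path File path.
#' @param kind `"gff3"` or `"bed"`; guessed from the extension by default.
#' @param feature_kind Label stored in the `kind` column (e.g. `"gene"`,
#'   `"TE"`).
#' @return Feature tibble: `feature_id`, `chrom`, `start`, `end`,
#'   `strand`, `kind`.
#' @export
read_annotation <- function(path, kind = c("auto", "gff3", "bed"),
                            feature_kind = "gene") {
  kind <- match.arg(kind)
  if (kind == "auto") {
    kind <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- if (kind == "bed") rtracklayer::import(path, format = "BED")
        else rtracklayer::import(path, format = "GFF3")
  ids <- if (!is.null(gr$ID)) as.character(gr$ID)
         else if (!is.null(gr$Name)) as.character(gr$Name)
         else if (!is.null(gr$name)) as.character(gr$name)
         else sprintf("%s_%s_%d", feature_kind,
                      as.character(GenomicRanges::seqnames(gr)),
                      GenomicRanges::start(gr))
  out <- tibble(feature_id = ids,
                chrom = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr),
                end = GenomicRanges::end(gr),
                strand = as.character(GenomicRanges::strand(gr)),
                kind = feature_kind)
  out$strand[out$strand == "*"] <- "."
  if (any(out$end < out$start)) {
    stop(sprintf("annotation %s: end < start after coordinate conversion", path),
         call. = FALSE)
  }
  out
}

# GFF3 writer for the feature tables the generator produces.
write_features_gff3 <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    features$chrom,
    IRanges::IRanges(features$start, features$end),
    strand = ifelse(features$strand %in% c("+", "-"), features$strand, "*"))
  gr$ID <- features$feature_id
  gr$type <- ifelse(features$kind == "TE", "transposable_element", "gene")
  gr$source <- "methdiv"
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read / write small-RNA loci as BED6+1
#'
#' Column 7 carries the locus abundance. BED is 0-based half-open on
#' disk; the returned tibble is 1-based inclusive.
#'
#' @param path File path.
#' @return Tibble: `chrom`, `start`, `end`, `length`, `abundance`.
#' @export
read_smrna_bed <- function(path) {
  raw <- readr::read_tsv(path,
    col_names = c("chrom", "bed_start", "bed_end", "name", "score", "strand",
                  "abundance"),
    col_types = "ciicdci", comment = "#", progress = FALSE)
  tibble(chrom = raw$chrom, start = as.integer(raw$bed_start + 1L),
         end = as.integer(raw$bed_end),
         length = as.integer(raw$bed_end - raw$bed_start),
         abundance = as.integer(raw$abundance))
}

#' @rdname read_smrna_bed
#' @param smrna Locus tibble (1-based inclusive `start`/`end`,
#'   `abundance`).
#' @export
write_smrna_bed <- function(smrna, path) {
  assert_columns(smrna, c("chrom", "start", "end", "abundance"))
  readr::write_tsv(
    tibble(chrom = smrna$chrom, bed_start = smrna$start - 1L,
           bed_end = smrna$end,
           name = sprintf("smrna%06d", seq_len(nrow(smrna))),
           score = 0L, strand = "+", abundance = smrna$abundance),
    path, col_names = FALSE)
  invisible(path)
}

#' Export DMRs as BED6
#'
#' 0-based half-open intervals; name is the direction, score is
#' `min(1000, -10 * log10(q))`.
#'
#' @param dmrs A `dmr_result` or tidy DMR tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dmr_bed <- function(dmrs, path) {
  d <- if (inherits(dmrs, "dmr_result")) tidy(dmrs) else dmrs
  readr::write_tsv(
    tibble(chrom = d$chrom, bed_start = d$start - 1L, bed_end = d$end,
           name = d$direction,
           score = as.integer(pmin(1000, -10 * log10(pmax(d$q_value, 1e-100)))),
           strand = "."),
    path, col_names = FALSE)
  invisible(path)
}
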