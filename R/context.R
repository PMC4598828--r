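#' Classify the sequence context of a cytosine
#'
#' Determines CG / CHG / CHH status of a cytosine from the reference
#' sequence, reading 5' to 3' on the strand carrying the cytosine
#' (H = A, C or T). On the minus strand the site appears as a G on the
#' reference and its downstream bases are the reverse complement of the
#' upstream reference bases.
#'
#' Sites within two bases of a chromosome end are classified on the bases
#' available (CHH when undecidable) and flagged via the `incomplete`
#' column of [enumerate_cytosines()].
#'
#' @param genome A `Biostrings::DNAStringSet` (or named character vector of
#'   sequences).
#' @param chrom,pos,strand Parallel vectors locating the cytosines
#'   (1-based positions; strand `"+"` or `"-"`).
#' @return Character vector of contexts (`"CG"`, `"CHG"`, `"CHH"`).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGTCCGG"))
#' classify_context(g, "chr1", 2, "+")  # CG
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  genome <- as_genome_charset(genome)
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n); strand <- rep_len(strand, n)
  out <- character(n)
  for (ch in unique(chrom)) {
    if (!ch %in% names(genome)) stop(sprintf("unknown chromosome '%s'", ch), call. = FALSE)
    v <- genome_chars(genome, ch)
    idx <- which(chrom == ch)
    p <- pos[idx]
    if (any(p < 1 | p > length(v))) {
      bad <- p[p < 1 | p > length(v)][1]
      stop(sprintf("position %d out of range for %s (length %d)", bad, ch, length(v)),
           call. = FALSE)
    }
    base_here <- ifelse(strand[idx] == "+", v[p], complement_base(v[p]))
    if (any(base_here != "C")) {
      i <- which(base_here != "C")[1]
      stop(sprintf("base at %s:%d(%s) is %s, not a cytosine on that strand",
                   ch, p[i], strand[idx][i], base_here[i]), call. = FALSE)
    }
    out[idx] <- context_from_chars(v, p, strand[idx])
  }
  out
}

# Vectorised context call given the character vector of one chromosome.
# Missing downstream bases (chromosome end) resolve to CHH unless the first
# downstream base already decides CG.
context_from_chars <- function(v, p, strand) {
  L <- length(v)
  plus <- strand == "+"
  n1 <- character(length(p))
  n2 <- character(length(p))
  n1[plus] <- ifelse(p[plus] + 1 <= L, v[pmin(p[plus] + 1, L)], "N")
  n2[plus] <- ifelse(p[plus] + 2 <= L, v[pmin(p[plus] + 2, L)], "N")
  mn <- !plus
  n1[mn] <- ifelse(p[mn] - 1 >= 1, complement_base(v[pmax(p[mn] - 1, 1)]), "N")
  n2[mn] <- ifelse(p[mn] - 2 >= 1, complement_base(v[pmax(p[mn] - 2, 1)]), "N")
  ifelse(n1 == "G", "CG", ifelse(n2 == "G", "CHG", "CHH"))
}

as_genome_charset <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome sequences must be named", call. = FALSE)
    toupper(genome)
  } else {
    stop("genome must be a DNAStringSet or named character vector", call. = FALSE)
  }
}

genome_chars <- function(genome, chrom) {
  strsplit(genome[[chrom]], "", fixed = TRUE)[[1]]
}

#' Enumerate every cytosine of a genome on both strands
#'
#' Walks the reference and emits one row per strand-specific cytosine with
#' its sequence context and trinucleotide (5' to 3' on the cytosine's
#' strand, padded with `N` at chromosome ends). This is the site universe
#' of the synthetic methylome and of context audits.
#'
#' @inheritParams classify_context
#' @return Tibble with columns `chrom`, `pos`, `strand`, `context`,
#'   `trinucleotide`, `incomplete` (TRUE where fewer than two downstream
#'   bases existed).
#' @export
enumerate_cytosines <- function(genome) {
  genome <- as_genome_charset(genome)
  purrr::map_dfr(names(genome), function(ch) {
    v <- genome_chars(genome, ch)
    L <- length(v)
    pp <- which(v == "C")
    pm <- which(v == "G")
    mk <- function(p, strand) {
      if (length(p) == 0) {
        return(tibble(chrom = character(), pos = integer(), strand = character(),
                      context = character(), trinucleotide = character(),
                      incomplete = logical()))
      }
      if (strand == "+") {
        b1 <- ifelse(p + 1 <= L, v[pmin(p + 1, L)], "N")
        b2 <- ifelse(p + 2 <= L, v[pmin(p + 2, L)], "N")
        tri <- paste0("C", b1, b2)
      } else {
        b1 <- ifelse(p - 1 >= 1, complement_base(v[pmax(p - 1, 1)]), "N")
        b2 <- ifelse(p - 2 >= 1, complement_base(v[pmax(p - 2, 1)]), "N")
        tri <- paste0("C", b1, b2)
      }
      tibble(chrom = ch, pos = as.integer(p), strand = strand,
             context = ifelse(b1 == "G", "CG", ifelse(b2 == "G", "CHG", "CHH")),
             trinucleotide = tri,
             incomplete = b1 == "N" | (b1 != "G" & b2 == "N"))
    }
    dplyr::bind_rows(mk(pp, "+"), mk(pm, "-")) |>
      dplyr::arrange(.data$pos, .data$strand)
  })
}
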