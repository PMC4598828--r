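#' Assign a true methylome to a synthetic genome
#'
#' Enumerates every cytosine on both strands, classifies its context and
#' draws its methylation state: a site is methylated with the context's
#' `methylated_site_fraction` (multiplied by `te_level_multiplier`, capped
#' at 1, for sites inside a TE) and, if methylated, carries the context's
#' `true_level_by_context` percentage; otherwise level 0. Control-contig
#' sites are always unmethylated. Both samples start identical; differences
#' are introduced only by [plant_dmrs()].
#'
#' @param bundle A `synthetic_genome` from [generate_genome()].
#' @param config The [simulation_config()] used to build it.
#' @return Tibble of true sites: `chrom`, `pos`, `strand`, `context`,
#'   `trinucleotide`, `in_te`, `true_level_A`, `true_level_B`.
#' @export
assign_true_methylome <- function(bundle, config) {
  stopifnot(inherits(bundle, "synthetic_genome"))
  sites <- enumerate_cytosines(bundle$genome)
  with_seed(derive_seed(config$seed, 2), {
    frac <- config$methylated_site_fraction_by_context[sites$context]
    in_te <- sites_in_intervals(sites, bundle$tes)
    frac <- pmin(1, unname(frac) * ifelse(in_te, config$te_level_multiplier, 1))
    frac[sites$chrom == bundle$control_chrom] <- 0
    meth <- rbinom(nrow(sites), 1, frac) == 1
    level <- ifelse(meth, unname(config$true_level_by_context[sites$context]), 0)
    sites |>
      mutate(in_te = in_te, true_level_A = level, true_level_B = level) |>
      select(-"incomplete")
  })
}

# TRUE for site rows whose position falls inside any interval of `features`.
sites_in_intervals <- function(sites, features) {
  if (nrow(features) == 0) return(rep(FALSE, nrow(sites)))
  q <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, width = 1))
  s <- GenomicRanges::GRanges(features$chrom,
                              IRanges::IRanges(features$start, features$end))
  IRanges::overlapsAny(q, s)
}

#' Plant differentially methylated regions into a true methylome
#'
#' Selects `n_planted_dmrs` non-overlapping regions of `dmr_width_bins`
#' whole bins (optionally offset by `planted_offset` bases), assigns half
#' of them hyper and half hypo direction (odd remainder hyper), and shifts
#' sample-A true levels by +/- `planted_delta` percentage points inside
#' each region.
#'
#' With `clamp_baseline = TRUE` (default) the sample-B levels of planted
#' sites are first clamped into the feasible range (`[0, 100 - delta]` for
#' hyper, `[delta, 100]` for hypo) so the planted shift is exact at every
#' site and the recorded delta is recovered without clipping bias. With
#' `clamp_baseline = FALSE` sample B is left untouched and the shifted
#' sample-A level is clipped to `[0, 100]`.
#'
#' @param truth True methylome tibble from [assign_true_methylome()].
#' @param bundle The `synthetic_genome`.
#' @param config The [simulation_config()].
#' @param clamp_baseline See description.
#' @return List with `truth` (modified tibble) and `dmr_truth` (tibble:
#'   `chrom`, `start`, `end`, `direction`, `planted_delta`,
#'   `overlapped_gene_id`).
#' @export
plant_dmrs <- function(truth, bundle, config, clamp_baseline = TRUE) {
  n <- config$n_planted_dmrs
  delta <- config$planted_delta
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  direction = character(), planted_delta = numeric(),
                  overlapped_gene_id = character())
  if (n == 0) return(list(truth = truth, dmr_truth = empty))
  if (delta <= 0) stop("planted_delta must be positive", call. = FALSE)
  width <- config$bin_size * config$dmr_width_bins

  with_seed(derive_seed(config$seed, 3), {
    chroms <- setdiff(names(bundle$genome), bundle$control_chrom)
    lens <- stats::setNames(Biostrings::width(bundle$genome)[match(chroms, names(bundle$genome))],
                            chroms)
    cand <- purrr::map_dfr(chroms, function(ch) {
      starts <- seq(1L, lens[[ch]] - width + 1L, by = config$bin_size) +
        config$planted_offset
      starts <- starts[starts + width - 1L <= lens[[ch]]]
      tibble(chrom = ch, start = as.integer(starts))
    })
    # forbid overlap between planted regions by spacing in units of width
    picked <- list()
    taken <- lapply(chroms, function(ch) integer(0)); names(taken) <- chroms
    cand <- cand[sample.int(nrow(cand)), ]
    for (i in seq_len(nrow(cand))) {
      if (length(picked) == n) break
      ch <- cand$chrom[i]; s <- cand$start[i]; e <- s + width - 1L
      tk <- taken[[ch]]
      if (length(tk) > 0 && any(abs(tk - s) < width)) next
      taken[[ch]] <- c(tk, s)
      picked[[length(picked) + 1]] <- tibble(chrom = ch, start = s, end = e)
    }
    if (length(picked) < n) {
      stop(sprintf("cannot place %d non-overlapping planted DMRs of width %d",
                   n, width), call. = FALSE)
    }
    regions <- dplyr::bind_rows(picked)
    regions$planted_delta <- delta

    gene_id <- rep(NA_character_, n)
    if (nrow(bundle$genes) > 0) {
      mid <- floor((regions$start + regions$end) / 2)
      q <- GenomicRanges::GRanges(regions$chrom, IRanges::IRanges(mid, width = 1))
      ext <- GenomicRanges::GRanges(bundle$genes$chrom,
               IRanges::IRanges(pmax(1L, bundle$genes$start - 2000L),
                                bundle$genes$end + 2000L))
      hits <- GenomicRanges::findOverlaps(q, ext, select = "first")
      gene_id <- bundle$genes$feature_id[hits]
    }
    regions$overlapped_gene_id <- gene_id

    # Exactly half the regions are hyper (odd remainder hyper); directions
    # are assigned per gene neighbourhood so one gene does not receive
    # opposing planted directions (at most one mixed group when the quota
    # forces a split).
    grp_key <- ifelse(is.na(gene_id), paste0(".solo", seq_len(n)), gene_id)
    groups <- split(seq_len(n), grp_key)
    groups <- groups[sample.int(length(groups))]
    direction <- character(n)
    remaining <- ceiling(n / 2)
    for (g in groups) {
      take <- min(length(g), remaining)
      if (take == length(g)) {
        direction[g] <- "hyper"
      } else if (take > 0) {
        direction[g[seq_len(take)]] <- "hyper"
        direction[g[-seq_len(take)]] <- "hypo"
      } else {
        direction[g] <- "hypo"
      }
      remaining <- remaining - take
    }
    regions$direction <- direction

    for (i in seq_len(n)) {
      idx <- which(truth$chrom == regions$chrom[i] &
                     truth$pos >= regions$start[i] & truth$pos <= regions$end[i])
      if (length(idx) == 0) next
      b <- truth$true_level_B[idx]
      if (regions$direction[i] == "hyper") {
        if (clamp_baseline) b <- pmin(b, 100 - delta)
        a <- pmin(100, b + delta)
      } else {
        if (clamp_baseline) b <- pmax(b, delta)
        a <- pmax(0, b - delta)
      }
      truth$true_level_B[idx] <- b
      truth$true_level_A[idx] <- a
    }
    list(truth = truth, dmr_truth = regions)
  })
}
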