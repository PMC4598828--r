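#' Metagene / meta-feature profile
#'
#' Aggregates positional items (methylcytosine calls, or small-RNA loci by
#' midpoint) over a set of features into a strand-aware profile: fixed
#' `flank_bin`-width bins over the upstream and downstream flanks and
#' `body_bins` equal *relative* segments over the feature body. Minus-
#' strand features are mirrored so bin 1 is always the 5'-most upstream
#' bin. Features shorter than `body_bins` bases are skipped (their count
#' is reported in the result's attributes).
#'
#' Tracks: if the item table has a `context` column, one track per
#' context; otherwise a single track `"items"`. In the fraction modes
#' each track is normalised to sum to 1; `mean_level` averages the items'
#' `level` column per bin.
#'
#' @param items Tibble with `chrom` and either `pos` (site items) or
#'   `start`/`end` (interval items, assigned by midpoint); `level`
#'   required for `value_mode = "mean_level"`.
#' @param features Feature tibble (`chrom`, `start`, `end`, `strand`).
#' @param params A [profile_params()].
#' @return A tibble of class `meth_profile`: `bin_index` (1-based, 5' to
#'   3'), `segment` (`upstream` / `body` / `downstream`), `track`,
#'   `value`, with attributes `n_features_used` and `n_features_skipped`.
#' @export
metagene_profile <- function(items, features, params = profile_params()) {
  stopifnot(inherits(params, "profile_params"))
  assert_columns(features, c("chrom", "start", "end", "strand"))
  if (!"pos" %in% names(items)) {
    assert_columns(items, c("chrom", "start", "end"))
    items <- mutate(items, pos = floor((.data$start + .data$end) / 2))
  }
  flank <- params$flank; fb <- params$flank_bin; nb <- params$body_bins
  n_flank_bins <- flank %/% fb
  n_bins <- 2L * n_flank_bins + nb
  usable <- features$end - features$start + 1 >= nb
  n_skipped <- sum(!usable)
  features <- features[usable, , drop = FALSE]
  if (nrow(features) == 0) stop("no usable features (all shorter than body_bins bases)",
                                call. = FALSE)

  ext <- GenomicRanges::GRanges(features$chrom,
           IRanges::IRanges(pmax(1L, features$start - flank), features$end + flank))
  q <- GenomicRanges::GRanges(items$chrom, IRanges::IRanges(items$pos, width = 1))
  hits <- GenomicRanges::findOverlaps(q, ext)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (length(qi) == 0) stop("no items fall within any feature or flank", call. = FALSE)

  fs <- features$start[si]; fe <- features$end[si]
  minus <- features$strand[si] == "-"
  pos <- items$pos[qi]
  # strand-relative coordinate: 0 at feature 5' end, negative upstream
  r <- ifelse(minus, fe - pos, pos - fs)
  L <- fe - fs + 1
  bin <- integer(length(r))
  up <- r < 0
  dn <- r >= L
  body <- !up & !dn
  bin[up] <- (r[up] + flank) %/% fb + 1L
  bin[body] <- n_flank_bins + pmin(nb, floor(r[body] / L[body] * nb) + 1L)
  bin[dn] <- n_flank_bins + nb + pmin(n_flank_bins, (r[dn] - L[dn]) %/% fb + 1L)
  keep <- bin >= 1 & bin <= n_bins
  bin <- bin[keep]; qi <- qi[keep]

  track <- if ("context" %in% names(items)) items$context[qi] else rep("items", length(qi))
  df <- tibble(bin_index = bin, track = track)
  if (params$value_mode == "mean_level") {
    assert_columns(items, "level")
    df$level <- items$level[qi]
    prof <- df |>
      group_by(.data$track, .data$bin_index) |>
      summarise(value = mean(.data$level), .groups = "drop")
  } else {
    prof <- df |>
      count(.data$track, .data$bin_index, name = "n") |>
      group_by(.data$track) |>
      mutate(value = .data$n / sum(.data$n)) |>
      ungroup() |>
      select(-"n")
  }
  grid <- tidyr::expand_grid(track = unique(track), bin_index = seq_len(n_bins))
  out <- grid |>
    left_join(prof, by = c("track", "bin_index")) |>
    mutate(value = ifelse(is.na(.data$value) & params$value_mode != "mean_level",
                          0, .data$value),
           segment = ifelse(.data$bin_index <= n_flank_bins, "upstream",
                     ifelse(.data$bin_index <= n_flank_bins + nb, "body",
                            "downstream"))) |>
    select("bin_index", "segment", "track", "value") |>
    arrange(.data$track, .data$bin_index)
  structure(tibble::new_tibble(out, class = "meth_profile"),
            n_features_used = nrow(features), n_features_skipped = n_skipped,
            params = params)
}

#' Mean methylation of gene versus TE bodies
#'
#' Per feature class (gene body, TE body) and context: number of
#' methylcytosines, mean per-site level over covered sites and the
#' read-weighted methylation (`sum(m) / sum(m + u)`, as a percentage).
#' Sites inside both a TE and a gene count as TE by default (set
#' `te_precedence = FALSE` to invert).
#'
#' @param calls Call table from [call_methylcytosines()].
#' @param genes,tes Feature tibbles.
#' @param te_precedence See description.
#' @param min_depth Depth for a site to count as covered.
#' @return Tibble: `class`, `context`, `n_sites`, `n_mC`, `mean_level`,
#'   `weighted_level`. Classes with no covered sites are absent.
#' @export
feature_body_levels <- function(calls, genes, tes, te_precedence = TRUE,
                                min_depth = 5) {
  assert_columns(calls, c("chrom", "pos", "context", "count_meth",
                          "count_unmeth", "depth", "level", "is_mC"))
  covered <- filter(calls, .data$depth >= min_depth)
  in_gene <- sites_in_intervals(covered, genes)
  in_te <- sites_in_intervals(covered, tes)
  cls <- ifelse(in_te & in_gene, if (te_precedence) "TE" else "gene",
         ifelse(in_te, "TE", ifelse(in_gene, "gene", NA_character_)))
  covered |>
    mutate(class = cls) |>
    filter(!is.na(.data$class)) |>
    group_by(.data$class, .data$context) |>
    summarise(n_sites = dplyr::n(), n_mC = sum(.data$is_mC),
              mean_level = mean(.data$level),
              weighted_level = 100 * sum(.data$count_meth) /
                sum(.data$count_meth + .data$count_unmeth),
              .groups = "drop")
}
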