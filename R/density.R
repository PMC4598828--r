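#' Chromosome density tracks in fixed windows
#'
#' Counts items per non-overlapping window along each chromosome (last
#' window truncated at the chromosome end). Site items are counted by
#' position, interval items by midpoint.
#'
#' @param item_tables Named list of tibbles; each needs `chrom` and either
#'   `pos` or `start`/`end`. Names become track names. A table with a
#'   `context` column is split into one track per context
#'   (`name_CG`, ...).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param window Window size in bases (default 100000).
#' @return Tibble: `track`, `chrom`, `window_start`, `window_end`,
#'   `count`.
#' @export
chromosome_density <- function(item_tables, chrom_lengths, window = 1e5) {
  stopifnot(is.list(item_tables), !is.null(names(item_tables)),
            !is.null(names(chrom_lengths)), window >= 1)
  window <- as.integer(window)
  grid <- purrr::map_dfr(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(1L, L, by = window)
    tibble(chrom = ch, window_start = as.integer(starts),
           window_end = as.integer(pmin(starts + window - 1L, L)))
  })
  purrr::imap_dfr(item_tables, function(tbl, nm) {
    if (nrow(tbl) == 0) {
      return(mutate(grid, track = nm, count = 0L) |>
               select("track", "chrom", "window_start", "window_end", "count"))
    }
    pos <- if ("pos" %in% names(tbl)) tbl$pos else floor((tbl$start + tbl$end) / 2)
    track <- if ("context" %in% names(tbl)) paste0(nm, "_", tbl$context) else nm
    counts <- tibble(chrom = tbl$chrom,
                     window_start = as.integer(((pos - 1L) %/% window) * window + 1L),
                     track = track) |>
      count(.data$track, .data$chrom, .data$window_start, name = "count")
    tidyr::expand_grid(track = unique(track), grid) |>
      left_join(counts, by = c("track", "chrom", "window_start")) |>
      mutate(count = dplyr::coalesce(.data$count, 0L)) |>
      select("track", "chrom", "window_start", "window_end", "count")
  })
}

#' Rank correlation between density tracks
#'
#' Spearman rank correlation (two-sided) for every pair of tracks in a
#' density table, matched on identical windows. In repeat-driven
#' methylomes the methylcytosine track correlates positively with TE
#' density and negatively with gene density.
#'
#' @param density Output of [chromosome_density()].
#' @return Tibble: `track_1`, `track_2`, `n_windows`, `rho`, `p_value`.
#' @export
density_correlation <- function(density) {
  assert_columns(density, c("track", "chrom", "window_start", "count"))
  wide <- density |>
    tidyr::pivot_wider(id_cols = c("chrom", "window_start"),
                       names_from = "track", values_from = "count")
  tracks <- setdiff(names(wide), c("chrom", "window_start"))
  if (nrow(wide) < 3) stop("need at least 3 windows for a rank correlation",
                           call. = FALSE)
  pairs <- utils::combn(tracks, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    x <- wide[[pr[1]]]; y <- wide[[pr[2]]]
    ok <- complete.cases(x, y)
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
    tibble(track_1 = pr[1], track_2 = pr[2], n_windows = sum(ok),
           rho = unname(ct$estimate), p_value = ct$p.value)
  })
}
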