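#' Plot a DMR result as a difference-significance scatter
#'
#' Methylation-level difference (test minus reference, percentage points)
#' against -log10 q for every tested bin, with the DMR filters overlaid.
#'
#' @param object A `dmr_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dmr_result <- function(object, ...) {
  bins <- mutate(object$bins,
                 status = ifelse(!.data$is_dmr, "not DMR",
                                 ifelse(.data$diff > 0, "hyper", "hypo")))
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$diff,
                                     y = -log10(pmax(.data$q_value, 1e-300)),
                                     colour = .data$status)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$params$min_diff,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(object$params$max_q),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(hyper = "#c0392b", hypo = "#2980b9",
                                            `not DMR` = "grey70")) +
    ggplot2::labs(x = "methylation difference (points)",
                  y = expression(-log[10] ~ q), colour = NULL)
}

#' Plot a metagene profile
#'
#' One line per track across upstream flank, length-normalised body and
#' downstream flank; vertical guides mark the TSS and TTS.
#'
#' @param object A `meth_profile` from [metagene_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meth_profile <- function(object, ...) {
  params <- attr(object, "params")
  nf <- params$flank %/% params$flank_bin
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$bin_index, y = .data$value,
                               colour = .data$track)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(nf + 0.5, nf + params$body_bins + 0.5),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "bin (5' flank | body | 3' flank)",
                  y = params$value_mode, colour = NULL)
}

#' Plot expression distributions by methylation class
#'
#' @param object A `meth_expr_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meth_expr_comparison <- function(object, ...) {
  df <- purrr::imap_dfr(object$groups,
                        function(v, nm) tibble(class = nm, log2fc = v))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$log2fc,
                                   fill = .data$class)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = NULL, y = expression(log[2] ~ "fold change (A/B)"))
}

#' Plot chromosome density tracks
#'
#' @param density Output of [chromosome_density()].
#' @return A ggplot object (tracks faceted per chromosome).
#' @export
plot_density_tracks <- function(density) {
  ggplot2::ggplot(density,
                  ggplot2::aes(x = (.data$window_start + .data$window_end) / 2,
                               y = .data$count, colour = .data$track)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "items per window", colour = NULL)
}
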