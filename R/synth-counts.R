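#' Simulate bisulphite read counts for one sample
#'
#' Draws per-site depth `x ~ Poisson(depth_mean)` and methylated read count
#' `m ~ Binomial(x, p_eff)` with
#' `p_eff = level/100 + (1 - level/100) * error_rate`, so that at a truly
#' unmethylated site the methylcytosine caller's binomial null (reads
#' methylated only through non-conversion failure) is exactly realised.
#'
#' @param truth True methylome tibble (from [assign_true_methylome()] /
#'   [plant_dmrs()]).
#' @param config The [simulation_config()].
#' @param sample `"A"` or `"B"`: which sample's true levels to use.
#' @return A cytosine site tibble in CX-report column order: `chrom`,
#'   `pos`, `strand`, `count_meth`, `count_unmeth`, `context`,
#'   `trinucleotide`.
#' @export
simulate_counts <- function(truth, config, sample = c("A", "B")) {
  sample <- match.arg(sample)
  level <- truth[[paste0("true_level_", sample)]] / 100
  with_seed(derive_seed(config$seed, if (sample == "A") 4 else 5), {
    x <- rpois(nrow(truth), config$depth_mean)
    p_eff <- level + (1 - level) * config$error_rate
    m <- rbinom(nrow(truth), x, p_eff)
    tibble(chrom = truth$chrom, pos = truth$pos, strand = truth$strand,
           count_meth = as.integer(m), count_unmeth = as.integer(x - m),
           context = truth$context, trinucleotide = truth$trinucleotide)
  })
}
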