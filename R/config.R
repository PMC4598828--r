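#' Synthetic cohort configuration
#'
#' Parameters of the two-sample synthetic methylome cohort. Defaults define
#' the package's reference benchmarking cohort: one 1-Mb chromosome plus a
#' 20-kb fully unmethylated control contig (the stand-in for the chloroplast
#' used to estimate bisulphite non-conversion), 200 genes and 150 TEs,
#' context methylation levels CG 87.5 / CHG 67.5 / CHH 42 percent at
#' methylated sites, 200 planted whole-bin DMRs of 40 percentage points,
#' negative methylation-expression coupling and small-RNA excess at
#' hypermethylated genes.
#'
#' @param n_chroms Number of chromosomes (control contig is extra).
#' @param chrom_length Length of each chromosome in bases.
#' @param control_length Length of the unmethylated control contig.
#' @param gene_count,te_count Number of genes / transposable elements placed.
#' @param gene_length_range,te_length_range Length ranges (bases, inclusive).
#' @param gc_fraction G+C fraction of the random genome.
#' @param true_level_by_context Named percentages (`CG`,`CHG`,`CHH`): the true
#'   methylation level assigned to methylated sites in each context.
#' @param methylated_site_fraction_by_context Named probabilities: fraction of
#'   cytosines in each context that are methylated at all.
#' @param te_level_multiplier Multiplier (>= 1) applied to the methylated-site
#'   fraction inside TEs (capped at probability 1).
#' @param te_clustering If `TRUE`, TEs are placed preferentially around the
#'   chromosome midpoint and genes toward the arms, emulating pericentromeric
#'   repeat density.
#' @param depth_mean Mean Poisson sequencing depth per cytosine.
#' @param error_rate Bisulphite non-conversion probability (default 5e-4,
#'   i.e. 0.05 percent).
#' @param n_planted_dmrs Number of planted differentially methylated bins.
#' @param planted_delta Planted methylation difference in percentage points.
#' @param dmr_width_bins Width of each planted DMR in whole bins.
#' @param planted_offset Offset (bases) of planted regions from bin
#'   boundaries; 0 keeps them whole-bin aligned.
#' @param bin_size Bin width in bases used for DMR planting/recovery.
#' @param expression_coupling_strength Log2 expression shift `c` applied to
#'   sample A for genes carrying a planted hyper (-c) or hypo (+c) DMR in
#'   their body or 2-kb flanks.
#' @param expression_log2_mean,expression_log2_sd Baseline log2 abundance
#'   distribution shared by the two samples.
#' @param replicate_log2_sd Lognormal replicate noise (log2 scale).
#' @param smrna_base_rate_per_kb Baseline small-RNA locus rate per kb.
#' @param smrna_hyper_fold Locus-rate multiplier in hyper-DMR genes (divided
#'   by it in hypo-DMR genes) for sample A.
#' @param replicates_per_sample Expression replicates per sample (>= 2).
#' @param seed Integer seed; every random draw in the generator derives from
#'   it, so identical configs give byte-identical outputs.
#' @return A validated `simulation_config` object (a named list).
#' @export
simulation_config <- function(n_chroms = 1,
                              chrom_length = 1e6,
                              control_length = 2e4,
                              gene_count = 200,
                              te_count = 150,
                              gene_length_range = c(1000, 3000),
                              te_length_range = c(200, 1000),
                              gc_fraction = 0.43,
                              true_level_by_context = c(CG = 87.5, CHG = 67.5, CHH = 42),
                              methylated_site_fraction_by_context = c(CG = 0.80, CHG = 0.60, CHH = 0.13),
                              te_level_multiplier = 1.5,
                              te_clustering = TRUE,
                              depth_mean = 30,
                              error_rate = 5e-4,
                              n_planted_dmrs = 200,
                              planted_delta = 40,
                              dmr_width_bins = 1,
                              planted_offset = 0,
                              bin_size = 100,
                              expression_coupling_strength = 2,
                              expression_log2_mean = 3,
                              expression_log2_sd = 2,
                              replicate_log2_sd = 0.25,
                              smrna_base_rate_per_kb = 3,
                              smrna_hyper_fold = 1.7,
                              replicates_per_sample = 3,
                              seed = 1) {
  cfg <- list(
    n_chroms = as.integer(n_chroms), chrom_length = as.integer(chrom_length),
    control_length = as.integer(control_length),
    gene_count = as.integer(gene_count), te_count = as.integer(te_count),
    gene_length_range = as.integer(gene_length_range),
    te_length_range = as.integer(te_length_range),
    gc_fraction = gc_fraction,
    true_level_by_context = true_level_by_context,
    methylated_site_fraction_by_context = methylated_site_fraction_by_context,
    te_level_multiplier = te_level_multiplier,
    te_clustering = isTRUE(te_clustering),
    depth_mean = depth_mean, error_rate = error_rate,
    n_planted_dmrs = as.integer(n_planted_dmrs),
    planted_delta = planted_delta,
    dmr_width_bins = as.integer(dmr_width_bins),
    planted_offset = as.integer(planted_offset),
    bin_size = as.integer(bin_size),
    expression_coupling_strength = expression_coupling_strength,
    expression_log2_mean = expression_log2_mean,
    expression_log2_sd = expression_log2_sd,
    replicate_log2_sd = replicate_log2_sd,
    smrna_base_rate_per_kb = smrna_base_rate_per_kb,
    smrna_hyper_fold = smrna_hyper_fold,
    replicates_per_sample = as.integer(replicates_per_sample),
    seed = as.integer(seed),
    control_chrom = "chrC"
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stopifnot(
    cfg$n_chroms >= 1, cfg$chrom_length >= 1, cfg$control_length >= 1,
    cfg$gene_count >= 0, cfg$te_count >= 0,
    length(cfg$gene_length_range) == 2, length(cfg$te_length_range) == 2,
    cfg$gene_length_range[1] <= cfg$gene_length_range[2],
    cfg$te_length_range[1] <= cfg$te_length_range[2],
    cfg$depth_mean > 0, cfg$replicates_per_sample >= 1,
    cfg$bin_size >= 1, cfg$dmr_width_bins >= 1,
    cfg$smrna_hyper_fold > 0, cfg$smrna_base_rate_per_kb >= 0,
    cfg$te_level_multiplier >= 1
  )
  if (!is_probability(cfg$gc_fraction) || !is_probability(cfg$error_rate) ||
      cfg$error_rate >= 1) {
    stop("gc_fraction must be in [0,1] and error_rate in [0,1)", call. = FALSE)
  }
  lv <- cfg$true_level_by_context
  fr <- cfg$methylated_site_fraction_by_context
  if (!all(CONTEXTS %in% names(lv)) || any(lv < 0 | lv > 100)) {
    stop("true_level_by_context must name CG, CHG, CHH with percentages in [0,100]",
         call. = FALSE)
  }
  if (!all(CONTEXTS %in% names(fr)) || !is_probability(unname(fr))) {
    stop("methylated_site_fraction_by_context must name CG, CHG, CHH with probabilities",
         call. = FALSE)
  }
  max_feat <- max(cfg$gene_length_range[2], cfg$te_length_range[2])
  if (cfg$chrom_length < max_feat) {
    stop("chrom_length must be at least the maximum feature length", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  genome: %d x %s bp (+ control %s bp), GC %.2f\n",
              x$n_chroms, format(x$chrom_length, big.mark = ","),
              format(x$control_length, big.mark = ","), x$gc_fraction))
  cat(sprintf("  features: %d genes, %d TEs (TE multiplier %.2g)\n",
              x$gene_count, x$te_count, x$te_level_multiplier))
  cat(sprintf("  planted DMRs: %d x %d bin(s), delta %.1f points\n",
              x$n_planted_dmrs, x$dmr_width_bins, x$planted_delta))
  cat(sprintf("  depth ~ Poisson(%.1f), non-conversion %.2g, seed %d\n",
              x$depth_mean, x$error_rate, x$seed))
  invisible(x)
}

#' Methylcytosine calling parameters
#'
#' @param alpha Binomial P value cut-off (inclusive; default 0.001).
#' @param min_depth Minimum read depth for a site to be callable
#'   (inclusive; default 5).
#' @param error_rate Bisulphite non-conversion probability used as the
#'   binomial null parameter.
#' @return A `call_params` list.
#' @export
call_params <- function(alpha = 0.001, min_depth = 5, error_rate = 5e-4) {
  stopifnot(alpha > 0, alpha < 1, min_depth >= 1,
            error_rate >= 0, error_rate < 1)
  structure(list(alpha = alpha, min_depth = as.integer(min_depth),
                 error_rate = error_rate),
            class = "call_params")
}

#' DMR detection parameters
#'
#' Defaults reproduce the standard binned screen: 100-bp bins, sites covered
#' by at least five reads in each sample, at least three methylcytosines per
#' bin, a minimum methylation-level difference of 20 percentage points and a
#' q-value of at most 0.01. All thresholds are inclusive.
#'
#' @param bin_size Bin width in bases.
#' @param min_site_depth Per-sample minimum depth for a site to contribute.
#' @param min_mcs Minimum number of methylcytosines in the bin.
#' @param min_diff Minimum absolute level difference (percentage points).
#' @param max_q Maximum q value.
#' @param correction Multiple-testing correction, `"BH"` or `"SLIM"`.
#' @param context_mode `"combined"` or one of `"CG"`, `"CHG"`, `"CHH"` to
#'   restrict contributing sites.
#' @param mc_rule `"either"` counts a site as a methylcytosine if it is
#'   called in either sample (default); `"each"` requires both.
#' @param level_mode `"pooled"` computes bin levels from pooled read counts
#'   (consistent with the Fisher table); `"mean"` averages per-site levels.
#' @return A `dmr_params` list.
#' @export
dmr_params <- function(bin_size = 100, min_site_depth = 5, min_mcs = 3,
                       min_diff = 20, max_q = 0.01,
                       correction = c("BH", "SLIM"),
                       context_mode = c("combined", "CG", "CHG", "CHH"),
                       mc_rule = c("either", "each"),
                       level_mode = c("pooled", "mean")) {
  correction <- match.arg(correction)
  context_mode <- match.arg(context_mode)
  mc_rule <- match.arg(mc_rule)
  level_mode <- match.arg(level_mode)
  stopifnot(bin_size >= 1, min_site_depth >= 0, min_mcs >= 0,
            min_diff > 0, min_diff <= 100, max_q > 0, max_q < 1)
  structure(list(bin_size = as.integer(bin_size),
                 min_site_depth = as.integer(min_site_depth),
                 min_mcs = as.integer(min_mcs), min_diff = min_diff,
                 max_q = max_q, correction = correction,
                 context_mode = context_mode, mc_rule = mc_rule,
                 level_mode = level_mode),
            class = "dmr_params")
}

#' Differential-expression calling parameters
#'
#' @param min_fold_change Minimum fold change (default 2, i.e. |log2fc| >= 1).
#' @param max_p Maximum P value (inclusive; default 0.05).
#' @param on_threshold Abundance at or above which a gene is "on".
#' @param off_threshold Abundance below which a gene is "off"; genes between
#'   the two thresholds fall in a dead zone and are excluded from on/off
#'   contrasts.
#' @return A `deg_params` list.
#' @export
deg_params <- function(min_fold_change = 2, max_p = 0.05,
                       on_threshold = 1.0, off_threshold = 0.1) {
  stopifnot(min_fold_change > 1, max_p > 0, max_p < 1,
            off_threshold < on_threshold, off_threshold >= 0)
  structure(list(min_fold_change = min_fold_change, max_p = max_p,
                 on_threshold = on_threshold, off_threshold = off_threshold),
            class = "deg_params")
}

#' Metagene profile parameters
#'
#' @param flank Flank length in bases on each side (default 1000).
#' @param flank_bin Fixed flank bin width (default 50; must divide `flank`).
#' @param body_bins Number of length-normalised body bins (default 40).
#' @param value_mode `"mc_fraction"` (relative item fraction per bin, sums
#'   to 1 per track), `"mean_level"` (mean methylation level per bin) or
#'   `"smrna_fraction"` (as mc_fraction, for interval items by midpoint).
#' @return A `profile_params` list.
#' @export
profile_params <- function(flank = 1000, flank_bin = 50, body_bins = 40,
                           value_mode = c("mc_fraction", "mean_level", "smrna_fraction")) {
  value_mode <- match.arg(value_mode)
  stopifnot(flank >= flank_bin, flank %% flank_bin == 0, body_bins >= 1)
  structure(list(flank = as.integer(flank), flank_bin = as.integer(flank_bin),
                 body_bins = as.integer(body_bins), value_mode = value_mode),
            class = "profile_params")
}
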