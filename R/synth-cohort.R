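#' Simulate a complete two-sample methylome cohort
#'
#' Runs the whole generator: genome + annotation, true methylome, planted
#' DMRs, per-sample bisulphite counts, replicated expression and small-RNA
#' loci, all driven by the single config seed.
#'
#' @param config A [simulation_config()].
#' @param clamp_baseline Passed to [plant_dmrs()].
#' @return A list of class `meth_cohort` with elements `config`, `bundle`
#'   (synthetic genome), `truth_sites`, `dmr_truth`, `cx` (list `A`/`B` of
#'   cytosine count tibbles), `expression`, `expression_truth`, `smrna`
#'   (list `A`/`B`).
#' @export
simulate_cohort <- function(config = simulation_config(), clamp_baseline = TRUE) {
  bundle <- generate_genome(config)
  truth <- assign_true_methylome(bundle, config)
  planted <- plant_dmrs(truth, bundle, config, clamp_baseline = clamp_baseline)
  cx <- list(A = simulate_counts(planted$truth, config, "A"),
             B = simulate_counts(planted$truth, config, "B"))
  expr <- simulate_expression(bundle$genes, planted$dmr_truth, config)
  smrna <- simulate_smrna(bundle, planted$dmr_truth, config)
  structure(list(config = config, bundle = bundle,
                 truth_sites = planted$truth, dmr_truth = planted$dmr_truth,
                 cx = cx, expression = expr$expression,
                 expression_truth = expr$truth, smrna = smrna),
            class = "meth_cohort")
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat("<meth_cohort>\n")
  cat(sprintf("  %d chromosome(s) + control '%s'; %d genes, %d TEs\n",
              x$config$n_chroms, x$bundle$control_chrom,
              nrow(x$bundle$genes), nrow(x$bundle$tes)))
  cat(sprintf("  %s cytosine sites per sample; %d planted DMRs (delta %.1f)\n",
              format(nrow(x$truth_sites), big.mark = ","),
              nrow(x$dmr_truth), x$config$planted_delta))
  invisible(x)
}

#' Write a simulated cohort to standard on-disk formats
#'
#' Emits FASTA (genome), GFF3 (genes and TEs), Bismark-style CX reports per
#' sample, an expression TSV, small-RNA BED6+1 per sample and the truth
#' tables as TSV. All coordinate conversions happen at the file boundary:
#' internal tables are 1-based inclusive, BED output is 0-based half-open.
#'
#' @param cohort A `meth_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "meth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- c(genome = file.path(dir, "genome.fa"),
         genes = file.path(dir, "genes.gff3"),
         tes = file.path(dir, "tes.gff3"),
         cx_A = file.path(dir, "sampleA.cx.tsv"),
         cx_B = file.path(dir, "sampleB.cx.tsv"),
         expression = file.path(dir, "expression.tsv"),
         smrna_A = file.path(dir, "sampleA.smrna.bed"),
         smrna_B = file.path(dir, "sampleB.smrna.bed"),
         truth_sites = file.path(dir, "truth_sites.tsv"),
         dmr_truth = file.path(dir, "truth_dmrs.tsv"),
         expression_truth = file.path(dir, "truth_expression.tsv"))
  Biostrings::writeXStringSet(cohort$bundle$genome, f[["genome"]])
  write_features_gff3(cohort$bundle$genes, f[["genes"]])
  write_features_gff3(cohort$bundle$tes, f[["tes"]])
  write_cx_report(cohort$cx$A, f[["cx_A"]])
  write_cx_report(cohort$cx$B, f[["cx_B"]])
  readr::write_tsv(cohort$expression, f[["expression"]])
  write_smrna_bed(cohort$smrna$A, f[["smrna_A"]])
  write_smrna_bed(cohort$smrna$B, f[["smrna_B"]])
  readr::write_tsv(cohort$truth_sites, f[["truth_sites"]])
  readr::write_tsv(cohort$dmr_truth, f[["dmr_truth"]])
  readr::write_tsv(cohort$expression_truth, f[["expression_truth"]])
  invisible(f)
}
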