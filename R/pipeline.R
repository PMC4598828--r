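#' Pipeline configuration
#'
#' Bundles the stage parameters and input paths of a full two-sample run.
#' Either `simulate` holds a [simulation_config()] (the cohort is
#' generated into the output directory) or `paths` must name existing
#' files: `fasta`, `cx_a`, `cx_b`, `genes`, `tes`, `expression`,
#' `smrna`.
#'
#' @param simulate A [simulation_config()], or `NULL` to run on files.
#' @param paths Named list of input files (ignored when simulating).
#' @param control_chrom Control contig used for error-rate estimation.
#' @param call,dmr,deg,profile Stage parameter objects.
#' @param flank Gene flank width in bases used for association and
#'   coupling.
#' @param window Density window in bases.
#' @param seed Seed governing all randomness in the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = simulation_config(),
                            paths = list(), control_chrom = "chrC",
                            call = call_params(), dmr = dmr_params(),
                            deg = deg_params(), profile = profile_params(),
                            flank = 2000, window = 1e5, seed = 1) {
  structure(list(simulate = simulate, paths = paths,
                 control_chrom = control_chrom, call = call, dmr = dmr,
                 deg = deg, profile = profile, flank = flank,
                 window = window, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialise / restore a pipeline configuration
#'
#' Flat YAML key-value text; parameter objects are stored under their
#' stage names and re-validated on read.
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- lapply(unclass(config), function(v) {
    if (inherits(v, "simulation_config") || inherits(v, "call_params") ||
        inherits(v, "dmr_params") || inherits(v, "deg_params") ||
        inherits(v, "profile_params")) {
      lapply(unclass(v), function(e) {
        if (!is.null(names(e))) as.list(e)
        else if (is.numeric(e) || is.character(e) || is.logical(e)) e
        else as.character(e)
      })
    } else v
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  rebuild <- function(fields, ctor) do.call(ctor, fields)
  sim <- if (!is.null(x$simulate)) {
    f <- x$simulate
    simulation_config(
      n_chroms = f$n_chroms, chrom_length = f$chrom_length,
      control_length = f$control_length, gene_count = f$gene_count,
      te_count = f$te_count, gene_length_range = unlist(f$gene_length_range),
      te_length_range = unlist(f$te_length_range), gc_fraction = f$gc_fraction,
      true_level_by_context = unlist(f$true_level_by_context),
      methylated_site_fraction_by_context = unlist(f$methylated_site_fraction_by_context),
      te_level_multiplier = f$te_level_multiplier, te_clustering = f$te_clustering,
      depth_mean = f$depth_mean, error_rate = f$error_rate,
      n_planted_dmrs = f$n_planted_dmrs, planted_delta = f$planted_delta,
      dmr_width_bins = f$dmr_width_bins, planted_offset = f$planted_offset,
      bin_size = f$bin_size,
      expression_coupling_strength = f$expression_coupling_strength,
      expression_log2_mean = f$expression_log2_mean,
      expression_log2_sd = f$expression_log2_sd,
      replicate_log2_sd = f$replicate_log2_sd,
      smrna_base_rate_per_kb = f$smrna_base_rate_per_kb,
      smrna_hyper_fold = f$smrna_hyper_fold,
      replicates_per_sample = f$replicates_per_sample, seed = f$seed)
  } else NULL
  pipeline_config(
    simulate = sim, paths = x$paths %||% list(),
    control_chrom = x$control_chrom,
    call = rebuild(x$call, call_params), dmr = rebuild(x$dmr, dmr_params),
    deg = rebuild(x$deg, deg_params),
    profile = rebuild(x$profile, profile_params),
    flank = x$flank, window = x$window, seed = x$seed)
}

#' Run the full two-sample methylome pipeline
#'
#' Executes, in order: simulate (optional), methylcytosine calling per
#' sample, DMR calling, DMR-feature association, expression integration,
#' small-RNA integration, and profiles/density tracks. Every stage writes
#' plain TSV/JSON outputs into `out_dir` and is recorded in the run
#' manifest (`manifest.json`) with input/output row counts and file
#' hashes; a stage whose outputs already exist is skipped when
#' `resume = TRUE`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param resume Reuse existing stage outputs if present.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  log_stage <- function(name, rows_in, rows_out, files) {
    stages[[name]] <<- list(stage = name, rows_in = rows_in, rows_out = rows_out,
                            files = as.list(files))
    if (!quiet) message(sprintf("[%s] rows in: %s, out: %s", name,
                                format(rows_in, big.mark = ","),
                                format(rows_out, big.mark = ",")))
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # -- stage 1: inputs (simulate or load) ---------------------------------
  if (!is.null(config$simulate)) {
    cohort_dir <- file.path(out_dir, "cohort")
    run_stage("simulate", function() {
      cohort <- simulate_cohort(config$simulate)
      write_cohort(cohort, cohort_dir)
    })
    paths <- list(fasta = file.path(cohort_dir, "genome.fa"),
                  cx_a = file.path(cohort_dir, "sampleA.cx.tsv"),
                  cx_b = file.path(cohort_dir, "sampleB.cx.tsv"),
                  genes = file.path(cohort_dir, "genes.gff3"),
                  tes = file.path(cohort_dir, "tes.gff3"),
                  expression = file.path(cohort_dir, "expression.tsv"),
                  smrna = file.path(cohort_dir, "sampleA.smrna.bed"))
  } else {
    paths <- config$paths
  }
  needed <- c("fasta", "cx_a", "cx_b", "genes", "tes", "expression", "smrna")
  for (nm in needed) {
    if (is.null(paths[[nm]]) || !file.exists(paths[[nm]])) {
      stop(sprintf("pipeline input '%s' missing: %s", nm,
                   paths[[nm]] %||% "<unset>"), call. = FALSE)
    }
  }
  genome <- Biostrings::readDNAStringSet(paths$fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genes <- read_annotation(paths$genes, feature_kind = "gene")
  tes <- read_annotation(paths$tes, feature_kind = "TE")
  cx_a <- read_cx_report(paths$cx_a)
  cx_b <- read_cx_report(paths$cx_b)
  log_stage("simulate",
            rows_in = NA_integer_,
            rows_out = nrow(cx_a) + nrow(cx_b),
            files = unlist(paths))

  # -- stage 2: methylcytosine calling ------------------------------------
  err <- estimate_error_rate(cx_a, config$control_chrom)
  cpar <- call_params(alpha = config$call$alpha,
                      min_depth = config$call$min_depth, error_rate = err)
  calls <- list()
  for (s in c("a", "b")) {
    f <- file.path(out_dir, sprintf("calls_%s.tsv", s))
    cx <- if (s == "a") cx_a else cx_b
    e_s <- estimate_error_rate(cx, config$control_chrom)
    p_s <- call_params(alpha = config$call$alpha,
                       min_depth = config$call$min_depth, error_rate = e_s)
    calls[[s]] <- run_stage("call-mc", function() {
      if (resume && file.exists(f)) {
        readr::read_tsv(f, show_col_types = FALSE)
      } else {
        out <- call_methylcytosines(cx, p_s)
        readr::write_tsv(out, f)
        out
      }
    })
  }
  summ <- summarize_methylome(
    filter(calls$a, .data$chrom != config$control_chrom),
    min_depth = config$call$min_depth)
  jsonlite::write_json(c(glance(summ), list(by_context = tidy(summ),
                                            error_rate_a = err)),
                       file.path(out_dir, "methylome_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("call-mc", rows_in = nrow(cx_a) + nrow(cx_b),
            rows_out = nrow(calls$a) + nrow(calls$b),
            files = file.path(out_dir, c("calls_a.tsv", "calls_b.tsv")))

  # -- stage 3: DMR calling -----------------------------------------------
  analysable <- function(x) filter(x, .data$chrom != config$control_chrom)
  bins <- bin_methylome(analysable(calls$a), analysable(calls$b), config$dmr)
  dmr_res <- run_stage("call-dmr", function() call_dmrs(bins, config$dmr))
  readr::write_tsv(tidy(dmr_res), file.path(out_dir, "dmrs.tsv"))
  write_dmr_bed(dmr_res, file.path(out_dir, "dmrs.bed"))
  log_stage("call-dmr", rows_in = nrow(bins), rows_out = nrow(dmr_res$dmrs),
            files = file.path(out_dir, c("dmrs.tsv", "dmrs.bed")))

  # -- stage 4: association -----------------------------------------------
  assoc <- run_stage("associate", function() {
    associate_dmrs(dmr_res, genes, tes, flank = config$flank)
  })
  readr::write_tsv(assoc, file.path(out_dir, "dmr_associations.tsv"))
  log_stage("associate", rows_in = nrow(dmr_res$dmrs), rows_out = nrow(assoc),
            files = file.path(out_dir, "dmr_associations.tsv"))

  # -- stage 5: expression integration ------------------------------------
  expr <- readr::read_tsv(paths$expression, show_col_types = FALSE)
  integ <- run_stage("integrate-expr", function() {
    degs <- call_degs(expr, config$deg)
    classes <- classify_dmr_genes(assoc)
    cmp <- compare_expression_by_methylation(degs, classes)
    enr <- enrichment_direction(assoc, degs, placement = "genic")
    onoff <- classify_on_off(degs, config$deg)
    list(degs = degs, classes = classes, cmp = cmp, enr = enr, onoff = onoff)
  })
  readr::write_tsv(integ$degs, file.path(out_dir, "degs.tsv"))
  jsonlite::write_json(list(comparison = tidy(integ$cmp),
                            enrichment = integ$enr,
                            on_off = count(integ$onoff, .data$status)),
                       file.path(out_dir, "expression_integration.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("integrate-expr", rows_in = nrow(expr), rows_out = nrow(integ$degs),
            files = file.path(out_dir, c("degs.tsv", "expression_integration.json")))

  # -- stage 6: small-RNA integration -------------------------------------
  smrna <- read_smrna_bed(paths$smrna)
  smr <- run_stage("integrate-smrna", function() {
    ov <- smrna_mc_overlap(smrna, analysable(calls$a))
    enr <- smrna_dmr_enrichment(smrna, classify_dmr_genes(assoc), genes)
    list(ov = ov, enr = enr)
  })
  jsonlite::write_json(list(overlap = smr$ov$by_context,
                            fraction_loci_with_mc = smr$ov$fraction_loci_with_mc,
                            enrichment = smr$enr),
                       file.path(out_dir, "smrna_integration.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("integrate-smrna", rows_in = nrow(smrna), rows_out = nrow(smr$enr),
            files = file.path(out_dir, "smrna_integration.json"))

  # -- stage 7: profiles and density --------------------------------------
  prof_files <- run_stage("profile", function() {
    mc_a <- filter(analysable(calls$a), .data$is_mC)
    pf_gene <- metagene_profile(mc_a, genes, config$profile)
    pf_te <- metagene_profile(mc_a, tes, config$profile)
    lens <- stats::setNames(Biostrings::width(genome), names(genome))
    lens <- lens[names(lens) != config$control_chrom]
    dens <- chromosome_density(list(mC = mc_a, gene = genes, te = tes),
                               lens, window = config$window)
    f <- file.path(out_dir, c("profile_genes.tsv", "profile_tes.tsv",
                              "density.tsv", "density_correlation.tsv"))
    readr::write_tsv(as_tibble(pf_gene), f[1])
    readr::write_tsv(as_tibble(pf_te), f[2])
    readr::write_tsv(dens, f[3])
    total_mc <- dens |>
      filter(grepl("^mC_", .data$track)) |>
      group_by(.data$chrom, .data$window_start, .data$window_end) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      mutate(track = "mC_all")
    corr <- density_correlation(bind_rows(
      total_mc, filter(dens, .data$track %in% c("gene", "te"))))
    readr::write_tsv(corr, f[4])
    f
  })
  log_stage("profile", rows_in = NA_integer_, rows_out = length(prof_files),
            files = prof_files)

  # -- manifest -----------------------------------------------------------
  cfg_file <- file.path(out_dir, "config.yml")
  write_pipeline_config(config, cfg_file)
  manifest <- list(
    tool = "methdiv",
    version = as.character(utils::packageVersion("methdiv")),
    config_hash = unname(tools::md5sum(cfg_file)),
    input_hashes = as.list(tools::md5sum(unlist(paths))),
    stages = unname(stages),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
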