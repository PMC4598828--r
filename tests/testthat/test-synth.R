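test_that("genome generation honours the config and is deterministic", {
  cfg <- small_config(seed = 5)
  g1 <- generate_genome(cfg)
  expect_length(g1$genome, cfg$n_chroms + 1)  # + control contig
  expect_equal(unname(Biostrings::width(g1$genome)[1]), cfg$chrom_length)
  expect_equal(nrow(g1$genes), cfg$gene_count)
  expect_equal(nrow(g1$tes), cfg$te_count)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$genes, g2$genes)

  # features never overlap
  feats <- dplyr::bind_rows(g1$genes, g1$tes)
  gr <- GenomicRanges::GRanges(feats$chrom, IRanges::IRanges(feats$start, feats$end))
  expect_true(all(GenomicRanges::countOverlaps(gr, gr) == 1))

  g0 <- generate_genome(small_config(seed = 5, gene_count = 0))
  expect_equal(nrow(g0$genes), 0)
  expect_length(g0$genome, 2)

  expect_error(generate_genome(simulation_config(chrom_length = 3000,
                                                 gene_count = 50,
                                                 gene_length_range = c(1000, 2000),
                                                 te_count = 0)),
               "infeasible packing")
})

test_that("true methylome assignment follows the per-context site fractions", {
  cfg <- small_config(seed = 6,
                      methylated_site_fraction_by_context = c(CG = 0.5, CHG = 0.5, CHH = 0.5),
                      te_level_multiplier = 1, te_count = 0)
  bundle <- generate_genome(cfg)
  truth <- assign_true_methylome(bundle, cfg)
  cg <- truth[truth$context == "CG" & truth$chrom != "chrC", ]
  n <- nrow(cg)
  k <- sum(cg$true_level_A > 0)
  # binomial 99% interval around n * 0.5
  expect_gt(k, qbinom(0.005, n, 0.5))
  expect_lt(k, qbinom(0.995, n, 0.5))
  expect_true(all(truth$true_level_A[truth$chrom == "chrC"] == 0))
  expect_identical(truth$true_level_A, truth$true_level_B)

  # all-zero fractions give an unmethylated methylome
  cfg0 <- small_config(seed = 6,
                       methylated_site_fraction_by_context = c(CG = 0, CHG = 0, CHH = 0))
  truth0 <- assign_true_methylome(generate_genome(cfg0), cfg0)
  expect_true(all(truth0$true_level_A == 0))
})

test_that("TE multiplier = 1 leaves TE and gene site levels indistinguishable", {
  cfg <- small_config(seed = 8, te_level_multiplier = 1)
  bundle <- generate_genome(cfg)
  truth <- assign_true_methylome(bundle, cfg)
  in_gene <- methdiv:::sites_in_intervals(truth, bundle$genes)
  te_lv <- truth$true_level_A[truth$in_te & truth$context == "CG"]
  gene_lv <- truth$true_level_A[in_gene & !truth$in_te & truth$context == "CG"]
  set.seed(1)
  p <- wilcox.test(sample(te_lv, min(2000, length(te_lv))),
                   sample(gene_lv, min(2000, length(gene_lv))))$p.value
  expect_gt(p, 0.01)
})

test_that("DMR planting splits directions, records exact deltas, and can clip", {
  co <- small_cohort()
  tr <- co$dmr_truth
  expect_equal(nrow(tr), 20)
  expect_equal(sum(tr$direction == "hyper"), 10)
  expect_equal(sum(tr$direction == "hypo"), 10)
  expect_true(all((tr$end - tr$start + 1) %% co$config$bin_size == 0))

  # truth consistency: recomputed mean level difference equals the planted delta
  for (i in seq_len(nrow(tr))) {
    s <- co$truth_sites[co$truth_sites$chrom == tr$chrom[i] &
                          co$truth_sites$pos >= tr$start[i] &
                          co$truth_sites$pos <= tr$end[i], ]
    d <- mean(s$true_level_A) - mean(s$true_level_B)
    expect_equal(abs(d), tr$planted_delta[i], tolerance = 1)
    expect_equal(sign(d), if (tr$direction[i] == "hyper") 1 else -1)
  }

  # literal clipping mode: baseline 90 shifted +40 clips at 100
  cfg <- small_config(seed = 31, true_level_by_context = c(CG = 90, CHG = 90, CHH = 90),
                      methylated_site_fraction_by_context = c(CG = 1, CHG = 1, CHH = 1),
                      n_planted_dmrs = 4)
  bundle <- generate_genome(cfg)
  truth <- assign_true_methylome(bundle, cfg)
  planted <- plant_dmrs(truth, bundle, cfg, clamp_baseline = FALSE)
  hyp <- planted$dmr_truth[planted$dmr_truth$direction == "hyper", ][1, ]
  s <- planted$truth[planted$truth$chrom == hyp$chrom &
                       planted$truth$pos >= hyp$start &
                       planted$truth$pos <= hyp$end, ]
  expect_true(all(s$true_level_B == 90))
  expect_true(all(s$true_level_A == 100))

  # zero planted DMRs leave the methylome untouched
  cfg0 <- small_config(seed = 9, n_planted_dmrs = 0)
  b0 <- generate_genome(cfg0)
  t0 <- assign_true_methylome(b0, cfg0)
  p0 <- plant_dmrs(t0, b0, cfg0)
  expect_identical(p0$truth, t0)
  expect_equal(nrow(p0$dmr_truth), 0)
  expect_error(plant_dmrs(t0, b0, small_config(planted_delta = 0)), "positive")
})

test_that("simulated counts follow the depth and error model and conserve reads", {
  co <- small_cohort()
  cx <- co$cx$A
  expect_equal(nrow(cx), nrow(co$truth_sites))
  # conservation is structural: counts were emitted as m and x - m
  expect_true(all(cx$count_meth >= 0 & cx$count_unmeth >= 0))
  depth <- cx$count_meth + cx$count_unmeth
  expect_gt(mean(depth), 29)
  expect_lt(mean(depth), 31)

  # null sites emit methylated reads at the non-conversion rate
  ctrl <- cx[cx$chrom == "chrC", ]
  tot <- sum(ctrl$count_meth) + sum(ctrl$count_unmeth)
  rate <- sum(ctrl$count_meth) / tot
  ci <- qbinom(c(0.005, 0.995), tot, 5e-4) / tot
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])

  # fully methylated sites give m = x
  cfg <- small_config(seed = 13, chrom_length = 2e4,
                      methylated_site_fraction_by_context = c(CG = 1, CHG = 1, CHH = 1),
                      true_level_by_context = c(CG = 100, CHG = 100, CHH = 100),
                      n_planted_dmrs = 0, te_count = 0, gene_count = 0)
  b <- generate_genome(cfg)
  tr <- assign_true_methylome(b, cfg)
  cx1 <- simulate_counts(tr, cfg, "A")
  main <- cx1[cx1$chrom != "chrC", ]
  expect_true(all(main$count_unmeth == 0))
})

test_that("emitted contexts re-derive exactly from the genome sequence", {
  co <- small_cohort()
  set.seed(99)
  rows <- co$cx$A[sample.int(nrow(co$cx$A), 1000), ]
  rederived <- classify_context(co$bundle$genome, rows$chrom, rows$pos, rows$strand)
  expect_identical(rederived, rows$context)
})

test_that("cohort generation is deterministic from config + seed", {
  c1 <- simulate_cohort(small_config(seed = 77))
  c2 <- simulate_cohort(small_config(seed = 77))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_cohort(c1, d1); f2 <- write_cohort(c2, d2)
  for (nm in names(f1)) {
    expect_identical(unname(tools::md5sum(f1[[nm]])), unname(tools::md5sum(f2[[nm]])),
                     label = paste("file", nm))
  }
})

test_that("expression simulation couples genes to planted DMRs as configured", {
  genes <- tibble::tibble(feature_id = sprintf("g%04d", 1:1000), chrom = "chr1",
                          start = seq(1, by = 5000, length.out = 1000),
                          end = seq(1, by = 5000, length.out = 1000) + 999,
                          strand = "+", kind = "gene")
  no_dmrs <- tibble::tibble(chrom = character(), start = integer(), end = integer(),
                            direction = character(), planted_delta = numeric(),
                            overlapped_gene_id = character())
  cfg0 <- simulation_config(expression_coupling_strength = 0, seed = 21)
  ex0 <- simulate_expression(genes, no_dmrs, cfg0)
  lfc <- ex0$expression |>
    dplyr::mutate(l = log2(abundance)) |>
    dplyr::group_by(gene_id, sample) |>
    dplyr::summarise(m = mean(l), .groups = "drop") |>
    tidyr::pivot_wider(names_from = sample, values_from = m) |>
    dplyr::mutate(d = A - B)
  expect_lt(abs(mean(lfc$d)), 0.05)

  # a planted hyper DMR inside a gene shifts A down by the coupling strength
  dmr1 <- tibble::tibble(chrom = "chr1", start = 101L, end = 200L,
                         direction = "hyper", planted_delta = 40,
                         overlapped_gene_id = "g0001")
  cfg2 <- simulation_config(expression_coupling_strength = 2, seed = 22,
                            replicate_log2_sd = 1e-9)
  ex2 <- simulate_expression(genes, dmr1, cfg2)
  w <- ex2$expression |>
    dplyr::group_by(gene_id, sample) |>
    dplyr::summarise(m = mean(log2(abundance)), .groups = "drop") |>
    tidyr::pivot_wider(names_from = sample, values_from = m)
  expect_equal(w$A[w$gene_id == "g0001"] - w$B[w$gene_id == "g0001"], -2,
               tolerance = 1e-6)
  expect_equal(w$A[w$gene_id == "g0500"] - w$B[w$gene_id == "g0500"], 0,
               tolerance = 1e-6)
  expect_equal(ex2$truth$coupling_class[ex2$truth$gene_id == "g0001"], "hyper")
})

test_that("small-RNA loci have legal lengths and a null fold near 1", {
  co <- small_cohort()
  for (s in c("A", "B")) {
    sm <- co$smrna[[s]]
    expect_true(all(sm$length %in% 21:24))
    expect_true(all(sm$end - sm$start + 1 == sm$length))
    expect_true(all(sm$abundance >= 1))
  }
  # with fold 1 the recovered hyper-gene density ratio stays near 1
  cfg <- simulation_config(seed = 14, smrna_hyper_fold = 1,
                           smrna_base_rate_per_kb = 5)
  co1 <- simulate_cohort(cfg)
  cls <- tibble::tibble(
    gene_id = co1$expression_truth$gene_id[co1$expression_truth$coupling_class == "hyper"],
    meth_class = "hyper")
  enr <- smrna_dmr_enrichment(co1$smrna$A, cls, co1$bundle$genes)
  expect_gt(enr$n_loci, 500)
  expect_gt(enr$fold, 0.8)
  expect_lt(enr$fold, 1.2)
})
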