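mk_expr <- function(ga, gb, reps = 3, noise = 0) {
  # ga/gb: named vectors of per-gene mean abundances for samples A and B
  tidyr::expand_grid(gene_id = names(ga), sample = c("A", "B"),
                     replicate = seq_len(reps)) |>
    dplyr::mutate(abundance = ifelse(sample == "A", ga[gene_id], gb[gene_id]) +
                    noise * (replicate - (reps + 1) / 2))
}

test_that("DEG calling applies the fold-change and P thresholds", {
  ex <- mk_expr(c(g1 = 8, g2 = 3, g3 = 2), c(g1 = 2, g2 = 2, g3 = 2),
                noise = 0.05)
  degs <- call_degs(ex)
  d1 <- degs[degs$gene_id == "g1", ]
  expect_equal(d1$log2fc, log2(8.01 / 2.01), tolerance = 1e-3)
  expect_lt(d1$p_value, 0.05)
  expect_equal(d1$de_status, "up")
  # 1.5-fold change is never a DEG however significant
  expect_equal(degs$de_status[degs$gene_id == "g2"], "not_de")
  # identical replicates: log2fc 0, not DE
  d3 <- degs[degs$gene_id == "g3", ]
  expect_equal(d3$log2fc, 0)
  expect_equal(d3$de_status, "not_de")
  # single replicate: fold change decides, with a warning
  ex1 <- mk_expr(c(g1 = 8), c(g1 = 2), reps = 1)
  expect_warning(degs1 <- call_degs(ex1), "single replicate")
  expect_equal(degs1$de_status, "up")
  expect_true(is.na(degs1$p_value))
})

test_that("gene methylation classes take the largest-|diff| DMR and drop ties", {
  assoc <- tibble::tibble(
    dmr_id = paste0("d", 1:5), chrom = "chr1", start = 1:5, end = 1:5,
    diff = c(30, -60, 25, -25, 50),
    direction = c("hyper", "hypo", "hyper", "hypo", "hyper"),
    feature_id = c("g1", "g1", "g2", "g2", "t1"),
    feature_kind = c("gene", "gene", "gene", "gene", "TE"),
    placement = "genic")
  cls <- classify_dmr_genes(assoc)
  expect_equal(cls$meth_class[cls$gene_id == "g1"], "hypo")  # |-60| beats 30
  expect_false("g2" %in% cls$gene_id)                        # tied |25|
})

test_that("expression comparison contrasts methylation classes against all genes", {
  set.seed(61)
  degs <- tibble::tibble(gene_id = paste0("g", 1:40),
                         log2fc = c(rnorm(10, -3, 0.1), rnorm(30, 0, 0.1)))
  cls <- tibble::tibble(gene_id = paste0("g", 1:10), meth_class = "hyper")
  td <- tidy(compare_expression_by_methylation(degs, cls))
  expect_lt(td$p_value[td$class == "hyper"], 0.01)
  expect_lt(td$median[td$class == "hyper"], -2)
  expect_equal(td$n[td$class == "all_genes"], 40)
  expect_equal(td$n[td$class == "hypo"], 0)
  expect_true(is.na(td$p_value[td$class == "hypo"]))
  # a class identical to the all-genes sample is not significant
  cls_all <- tibble::tibble(gene_id = paste0("g", 1:40), meth_class = "hyper")
  td2 <- tidy(compare_expression_by_methylation(degs, cls_all))
  expect_gt(td2$p_value[td2$class == "hyper"], 0.9)
})

test_that("directional enrichment computes the cross-product odds ratio", {
  # construct 300 genes: 100 hyper-associated (30 down), 200 others (10 down)
  degs <- tibble::tibble(
    gene_id = paste0("g", 1:300),
    de_status = c(rep("down", 30), rep("not_de", 70), rep("down", 10),
                  rep("not_de", 190)))
  assoc <- tibble::tibble(
    dmr_id = paste0("d", 1:100), chrom = "chr1", start = 1:100, end = 1:100,
    diff = 50, direction = "hyper", feature_id = paste0("g", 1:100),
    feature_kind = "gene", placement = "genic")
  enr <- enrichment_direction(assoc, degs, placement = "genic")
  hd <- enr[enr$contrast == "hyper_down", ]
  expect_equal(hd$odds_ratio, (30 * 190) / (70 * 10), tolerance = 1e-12)
  expect_equal(hd$p_value, oracle_fisher_p(30, 70, 10, 190), tolerance = 1e-9)
  # no hypo genes at all: zero margin, OR undefined, P = 1
  hu <- enr[enr$contrast == "hypo_up", ]
  expect_true(is.na(hu$odds_ratio))
  expect_equal(hu$p_value, 1)
})

test_that("on/off classification partitions genes outside the dead zone", {
  degs <- tibble::tibble(gene_id = paste0("g", 1:5),
                         abundance_A = c(5, 0.05, 0.5, 0, 2),
                         abundance_B = c(0.05, 5, 0.5, 0, 3))
  st <- classify_on_off(degs)
  expect_equal(st$status, c("A_on_B_off", "A_off_B_on", "excluded",
                            "both_off", "both_on"))
  kept <- st$status[st$status != "excluded"]
  expect_equal(length(kept) + sum(st$status == "excluded"), nrow(degs))
})

test_that("TE density counts overlaps with the 2-kb extended gene", {
  genes <- tibble::tibble(feature_id = c("g1", "g2"), chrom = "chr1",
                          start = c(1000L, 10000L), end = c(2000L, 11000L),
                          strand = "+", kind = "gene")
  tes <- tibble::tibble(chrom = "chr1", start = c(2500L, 4100L),
                        end = c(2600L, 4200L), kind = "TE")
  out <- te_density_by_gene_class(genes, tes, list(cl = "g1"),
                                  n_perm = 100, seed = 1)
  # TE at 2500-2600 is within 2 kb of g1; 4100-4200 is 2100 bp away
  expect_equal(out$mean_te, 1)
  expect_equal(out$complement_mean, 0)
  expect_error(te_density_by_gene_class(genes, tes, list(bad = "gX")),
               "not a subset")
})

test_that("TE-density permutation P is calibrated under a random class", {
  set.seed(202)
  genes <- tibble::tibble(feature_id = paste0("g", 1:60), chrom = "chr1",
                          start = seq(1000L, by = 10000L, length.out = 60),
                          end = seq(1000L, by = 10000L, length.out = 60) + 2000L,
                          strand = "+", kind = "gene")
  te_start <- sort(sample.int(600000L, 150))
  tes <- tibble::tibble(chrom = "chr1", start = te_start,
                        end = te_start + 300L, kind = "TE")
  pvals <- vapply(1:100, function(i) {
    cls <- list(r = sample(genes$feature_id, 20))
    te_density_by_gene_class(genes, tes, cls, n_perm = 400, seed = i)$p_value
  }, numeric(1))
  frac <- mean(pvals < 0.05)
  expect_gte(frac, 0.0)
  expect_lte(frac, 0.12)
})

test_that("smRNA-mC overlap counts positions inside loci", {
  smrna <- tibble::tibble(chrom = "chr1", start = 100L, end = 120L,
                          length = 21L, abundance = 3L)
  calls <- tibble::tibble(chrom = "chr1", pos = c(105L, 500L), strand = "+",
                          context = c("CG", "CHH"), count_meth = 10L,
                          count_unmeth = 0L, depth = 10L, level = 100,
                          p_value = 1e-12, is_mC = TRUE)
  ov <- smrna_mc_overlap(smrna, calls)
  all_row <- ov$by_context[ov$by_context$context == "all", ]
  expect_equal(all_row$fraction_in_loci, 50)
  expect_equal(ov$fraction_loci_with_mc, 100)
  # no loci: zero fractions
  ov0 <- smrna_mc_overlap(smrna[0, ], calls)
  expect_equal(ov0$by_context$fraction_in_loci, rep(0, 4))
  expect_equal(ov0$fraction_loci_with_mc, 0)
})

test_that("smRNA enrichment is a density ratio with identity at the full gene set", {
  genes <- tibble::tibble(feature_id = c("g1", "g2"), chrom = "chr1",
                          start = c(1L, 10001L), end = c(10000L, 20000L),
                          strand = "+", kind = "gene")
  # 20 loci in g1's 10 kb, 10 loci in g2's 10 kb
  smrna <- tibble::tibble(chrom = "chr1",
                          start = as.integer(c(seq(10, 9800, length.out = 20),
                                               seq(10010, 19800, length.out = 10))),
                          end = as.integer(c(seq(10, 9800, length.out = 20),
                                             seq(10010, 19800, length.out = 10))) + 21L,
                          length = 22L, abundance = 1L)
  cls <- tibble::tibble(gene_id = "g1", meth_class = "hyper")
  enr <- smrna_dmr_enrichment(smrna, cls, genes)
  expect_equal(enr$fold, (20 / 10) / (30 / 20), tolerance = 1e-9)
  cls_all <- tibble::tibble(gene_id = c("g1", "g2"), meth_class = "hyper")
  enr_all <- smrna_dmr_enrichment(smrna, cls_all, genes)
  expect_identical(enr_all$fold, 1)
  expect_equal(enr_all$p_value, 1)
})
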