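test_that("metagene profile bins positions correctly and mirrors strands", {
  feats <- tibble::tibble(feature_id = "g1", chrom = "chr1", start = 2001L,
                          end = 6000L, strand = "+", kind = "gene")
  items <- tibble::tibble(chrom = "chr1", pos = 1951L, context = "CG")
  pf <- metagene_profile(items, feats)
  hit <- tibble::as_tibble(pf)[tibble::as_tibble(pf)$value > 0, ]
  # 50 bp upstream of the TSS falls in the last upstream bin (index 20 of 20)
  expect_equal(hit$bin_index, 20)
  expect_equal(hit$segment, "upstream")

  # mirrored geometry on the minus strand: 50 bp beyond the 3' reference end
  feats_m <- dplyr::mutate(feats, strand = "-")
  items_m <- tibble::tibble(chrom = "chr1", pos = 6050L, context = "CG")
  pf_m <- metagene_profile(items_m, feats_m)
  hit_m <- tibble::as_tibble(pf_m)[tibble::as_tibble(pf_m)$value > 0, ]
  expect_equal(hit_m$bin_index, 20)
  expect_equal(hit_m$segment, "upstream")
})

test_that("fraction profiles sum to one per track and body bins are uniform", {
  set.seed(17)
  feats <- tibble::tibble(feature_id = "g1", chrom = "chr1", start = 2001L,
                          end = 6000L, strand = "+", kind = "gene")
  items <- tibble::tibble(chrom = "chr1",
                          pos = sample(1001:7000, 20000, replace = TRUE),
                          context = sample(c("CG", "CHG"), 20000, replace = TRUE))
  pf <- tibble::as_tibble(metagene_profile(items, feats))
  sums <- tapply(pf$value, pf$track, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # uniform items: body-bin counts fluctuate within 3 sqrt(expected)
  body <- pf[pf$segment == "body" & pf$track == "CG", ]
  n_body <- sum(items$context == "CG" & items$pos >= 2001 & items$pos <= 6000)
  expected <- n_body / 40
  counts <- body$value * sum(items$context == "CG")
  expect_true(all(abs(counts - expected) < 3 * sqrt(expected)))
})

test_that("profiles are invariant under strand reversal with reflected items", {
  set.seed(23)
  feats <- tibble::tibble(feature_id = c("a", "b"), chrom = "chr1",
                          start = c(3001L, 9001L), end = c(5000L, 12000L),
                          strand = c("+", "-"), kind = "gene")
  items <- tibble::tibble(chrom = "chr1",
                          pos = sample(2001:13000, 5000, replace = TRUE),
                          context = "CG")
  pf1 <- tibble::as_tibble(metagene_profile(items, feats))
  # reflect every item about the midline of each feature it serves; since
  # items may hit both features' windows, reflect globally per feature and
  # recompute with flipped strands
  flip <- dplyr::mutate(feats, strand = ifelse(strand == "+", "-", "+"))
  refl <- items
  for (i in seq_len(nrow(feats))) {
    mid2 <- feats$start[i] + feats$end[i]
    in_win <- refl$pos >= feats$start[i] - 1000 & refl$pos <= feats$end[i] + 1000
    refl$pos[in_win] <- mid2 - refl$pos[in_win]
  }
  pf2 <- tibble::as_tibble(metagene_profile(refl, flip))
  expect_equal(pf1$value, pf2$value, tolerance = 1e-12)
})

test_that("single-feature profile equals the direct per-feature computation", {
  feats <- tibble::tibble(feature_id = "g1", chrom = "chr1", start = 1001L,
                          end = 2000L, strand = "+", kind = "gene")
  items <- tibble::tibble(chrom = "chr1", pos = c(1001L, 1500L, 2000L, 500L),
                          context = "CG")
  pf <- tibble::as_tibble(metagene_profile(items, feats))
  body <- pf[pf$segment == "body", ]
  expect_equal(sum(body$value > 0), 3)
  expect_equal(body$value[body$value > 0], rep(1 / 4, 3))  # 4th item upstream
  up <- pf[pf$segment == "upstream", ]
  expect_equal(sum(up$value), 1 / 4)
  # short features are skipped with a usable-feature error when none remain
  short <- dplyr::mutate(feats, end = start + 10L)
  expect_error(metagene_profile(items, short), "no usable features")
})

test_that("mean-level profile mode averages item levels per bin", {
  feats <- tibble::tibble(feature_id = "g1", chrom = "chr1", start = 1001L,
                          end = 2000L, strand = "+", kind = "gene")
  items <- tibble::tibble(chrom = "chr1", pos = c(1001L, 1010L, 1900L),
                          context = "CG", level = c(100, 50, 30))
  pf <- tibble::as_tibble(metagene_profile(items, feats,
                                   profile_params(value_mode = "mean_level")))
  vals <- pf$value[!is.na(pf$value)]
  expect_setequal(vals, c(75, 30))
  expect_true(all(vals >= 0 & vals <= 100))
})

test_that("gene and TE body methylation separate when TEs are hypermethylated", {
  co <- small_cohort()
  calls <- cohort_calls(co)
  out <- feature_body_levels(calls$a, co$bundle$genes, co$bundle$tes)
  for (cx in unique(out$context)) {
    te_w <- out$weighted_level[out$class == "TE" & out$context == cx]
    gene_w <- out$weighted_level[out$class == "gene" & out$context == cx]
    if (length(te_w) == 1 && length(gene_w) == 1) {
      expect_gt(te_w, gene_w)
    }
  }
  # an empty TE class is reported absent, not as zero
  out2 <- feature_body_levels(calls$a, co$bundle$genes, co$bundle$tes[0, ])
  expect_false("TE" %in% out2$class)
})

test_that("density tracks tile chromosomes and conserve totals", {
  items <- tibble::tibble(chrom = "chr1", pos = as.integer(c(5, 50, 99999, 150000)))
  dens <- chromosome_density(list(x = items), c(chr1 = 250000L), window = 1e5)
  expect_equal(nrow(dens), 3)
  expect_equal(dens$window_end - dens$window_start + 1L, c(1e5, 1e5, 5e4))
  expect_equal(dens$count, c(3L, 1L, 0L))
  expect_equal(sum(dens$count), nrow(items))

  ten <- tibble::tibble(chrom = "chr1", pos = as.integer(seq(10, 9e4, length.out = 10)))
  d10 <- chromosome_density(list(x = ten), c(chr1 = 250000L), window = 1e5)
  expect_equal(d10$count, c(10L, 0L, 0L))
})

test_that("density correlations recover engineered monotone relations", {
  dens <- tibble::tibble(
    track = rep(c("mc", "te", "gene"), each = 10),
    chrom = "chr1",
    window_start = rep(as.integer(seq(1, by = 1e5, length.out = 10)), 3),
    window_end = window_start + 1e5 - 1L,
    count = c(1:10, 1:10, 10:1))
  corr <- density_correlation(dens)
  expect_equal(corr$rho[corr$track_1 == "mc" & corr$track_2 == "te"], 1)
  expect_equal(corr$rho[corr$track_1 == "mc" & corr$track_2 == "gene"], -1)
  expect_error(density_correlation(dens[dens$window_start == 1, ]), "3 windows")
})
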