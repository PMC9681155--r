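test_that("simulation is fully deterministic under (config, seed)", {
  cfg <- quick_config(seed = 7)
  a <- simulate_annotation(cfg)
  b <- simulate_annotation(cfg)
  expect_identical(a, b)
  ra <- simulate_rnaseq(a, cfg)
  rb <- simulate_rnaseq(b, cfg)
  expect_identical(ra$counts$counts, rb$counts$counts)
})

test_that("planted truth is consistent with the emitted annotation", {
  cfg <- quick_config(seed = 3)
  sim <- simulate_annotation(cfg)
  expect_true(all(sim$truth$repressed_locus_ids %in% sim$loci$locus_id))
  expect_true(all(sim$truth$enhancer_locus_ids %in%
                    sim$truth$repressed_locus_ids))
  expect_true(all(sim$truth$linked_pairs$gene_id %in% sim$genes$gene_id))
  # loci do not overlap within a chromosome
  for (ch in unique(sim$loci$chrom)) {
    l <- sim$loci[sim$loci$chrom == ch, ]
    l <- l[order(l$start), ]
    expect_true(all(l$start[-1] >= l$end[-nrow(l)]))
  }
})

test_that("frac_repressed = 0 plants nothing", {
  cfg <- quick_config(frac_repressed = 0, seed = 2)
  sim <- simulate_annotation(cfg)
  expect_length(sim$truth$repressed_locus_ids, 0)
  expect_true(all(sim$truth$te_log2_fold == 0))
})

test_that("linked gene TSSs lie within the linkage window of their locus", {
  cfg <- quick_config(linkage_window = 50000, seed = 11)
  sim <- simulate_annotation(cfg)
  pairs <- sim$truth$linked_pairs
  li <- match(pairs$locus_id, sim$loci$locus_id)
  gi <- match(pairs$gene_id, sim$genes$gene_id)
  d <- pmin(abs(sim$genes$tss[gi] - sim$loci$start[li]),
            abs(sim$genes$tss[gi] - sim$loci$end[li]))
  expect_true(all(d >= 5000 & d <= 50000))
  expect_true(all(sim$genes$chrom[gi] == sim$loci$chrom[li]))
})

test_that("null RNA simulation has symmetric group ratios", {
  cfg <- sim_config(n_te = 2000, frac_repressed = 0, n_genes = 10, seed = 5)
  sim <- simulate_annotation(cfg)
  rna <- simulate_rnaseq(sim, cfg)
  f <- rle_size_factors(rna$counts)
  cnt <- sweep(rna$counts$counts[sim$loci$locus_id, ], 2, f, "/")
  scnt <- rna$sheet$sample_id[rna$sheet$condition == "SCNT"]
  ivf <- rna$sheet$sample_id[rna$sheet$condition == "IVF"]
  ratio <- log2((rowMeans(cnt[, scnt]) + 0.5) / (rowMeans(cnt[, ivf]) + 0.5))
  expect_lt(abs(mean(ratio)), 0.05)
})

test_that("planted repression reproduces the generating fold", {
  cfg <- sim_config(seed = 13, repression_fold = 0.25, nb_dispersion = 0.05,
                    n_embryos_per_condition = 12)
  sim <- simulate_annotation(cfg)
  rna <- simulate_rnaseq(sim, cfg)
  cnt <- rna$counts$counts
  scnt <- rna$sheet$sample_id[rna$sheet$condition == "SCNT"]
  ivf <- rna$sheet$sample_id[rna$sheet$condition == "IVF"]
  planted <- sim$truth$repressed_locus_ids
  ratio <- log2((rowMeans(cnt[planted, scnt]) + 0.5) /
                  (rowMeans(cnt[planted, ivf]) + 0.5))
  expect_lt(abs(mean(ratio) - (-2)), 0.3)
})

test_that("ChIP simulation is null-centred without planted enrichment", {
  cfg <- quick_config(chip_enrichment_fold = 1, seed = 17)
  sim <- simulate_annotation(cfg)
  bins <- make_bins(c(chr1 = cfg$chrom_length))
  sc <- simulate_chip(sim, cfg, bins)
  merged <- tibble::tibble(
    locus_id = sc$locus_counts$locus_id,
    length = sc$locus_counts$length,
    chip = sc$locus_counts$chip_1 + sc$locus_counts$chip_2,
    input = sc$locus_counts$input_1 + sc$locus_counts$input_2
  )
  rec <- te_enrichment(
    merged,
    chip_bin_total = sum(sc$bin_counts$chip_1 + sc$bin_counts$chip_2),
    input_bin_total = sum(sc$bin_counts$input_1 + sc$bin_counts$input_2)
  )
  expect_lt(abs(mean(rec$log2_enrichment)), 0.1)
})

test_that("planted ChIP enrichment is recovered by the scorer", {
  cfg <- quick_config(chip_enrichment_fold = 8, seed = 19)
  sim <- simulate_annotation(cfg)
  bins <- make_bins(c(chr1 = cfg$chrom_length))
  sc <- simulate_chip(sim, cfg, bins)
  merged <- tibble::tibble(
    locus_id = sc$locus_counts$locus_id,
    length = sc$locus_counts$length,
    chip = sc$locus_counts$chip_1 + sc$locus_counts$chip_2,
    input = sc$locus_counts$input_1 + sc$locus_counts$input_2
  )
  rec <- te_enrichment(
    merged,
    chip_bin_total = sum(sc$bin_counts$chip_1 + sc$bin_counts$chip_2),
    input_bin_total = sum(sc$bin_counts$input_1 + sc$bin_counts$input_2)
  )
  planted <- rec$log2_enrichment[rec$locus_id %in%
                                   sim$truth$enhancer_locus_ids]
  expect_lt(abs(mean(planted) - 3), 0.4)
})

test_that("ChIP replicates are distinct draws", {
  cfg <- quick_config(seed = 23)
  sim <- simulate_annotation(cfg)
  bins <- make_bins(c(chr1 = cfg$chrom_length))
  chip <- simulate_chip(sim, cfg, bins)
  expect_false(identical(chip$bin_counts$chip_1, chip$bin_counts$chip_2))
  expect_false(identical(chip$locus_counts$input_1,
                         chip$locus_counts$input_2))
})

test_that("written simulation files are readable and faithful", {
  cfg <- quick_config(seed = 29)
  sim <- simulate_annotation(cfg)
  rna <- simulate_rnaseq(sim, cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, rna, dir)
  expect_identical(read_count_matrix(file.path(dir, "counts.tsv"))$counts,
                   rna$counts$counts)
  truth <- ervscan:::read_truth_table(file.path(dir, "truth.tsv"),
                                      slope = cfg$linkage_slope)
  expect_setequal(truth$enhancer_locus_ids, sim$truth$enhancer_locus_ids)
  expect_equal(truth$te_log2_fold[sim$loci$locus_id],
               sim$truth$te_log2_fold[sim$loci$locus_id])
})
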