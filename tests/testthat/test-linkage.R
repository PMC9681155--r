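make_locus <- function(id = "L1", chrom = "chr1", start = 100000,
                       end = 105000, subfamily = "RLTR45-int") {
  tibble::tibble(locus_id = id, chrom = chrom, start = start, end = end,
                 strand = "+", subfamily = subfamily, family = "ERVK",
                 class_label = "LTR")
}
make_gene <- function(id, tss, chrom = "chr1") {
  tibble::tibble(gene_id = id, chrom = chrom, tss = tss, strand = "+",
                 gene_start = tss, gene_end = tss + 1000)
}

test_that("TSS distances map to the printed windows", {
  loci <- make_locus()
  genes <- dplyr::bind_rows(
    make_gene("g35k", 140000),    # 35 kb downstream -> proximal
    make_gene("gin", 103000),     # inside -> distance 0, excluded
    make_gene("g205k", 310000),   # 205 kb -> excluded
    make_gene("g50k", 155000),    # exactly 50 kb -> proximal (tie rule)
    make_gene("g50k1", 155001),   # 50,001 -> distal
    make_gene("g200k", 305000),   # exactly 200 kb -> distal
    make_gene("gup", 60000),      # 40 kb upstream -> proximal
    make_gene("g4999", 109999),   # 4,999 below the floor -> excluded
    make_gene("gother", 140000, chrom = "chr2")  # different chromosome
  )
  pairs <- link_nearby_genes(loci, genes)
  expect_setequal(pairs$gene_id, c("g35k", "g50k", "g50k1", "g200k", "gup"))
  expect_equal(pairs$distance[pairs$gene_id == "g35k"], 35000)
  expect_equal(pairs$window[pairs$gene_id == "g35k"], "kb5_50")
  expect_equal(pairs$window[pairs$gene_id == "g50k"], "kb5_50")
  expect_equal(pairs$window[pairs$gene_id == "g50k1"], "kb50_200")
  expect_equal(pairs$window[pairs$gene_id == "g200k"], "kb50_200")
  expect_equal(pairs$window[pairs$gene_id == "gup"], "kb5_50")
  # every emitted distance respects its window bounds
  expect_true(all(pairs$distance[pairs$window == "kb5_50"] >= 5000 &
                    pairs$distance[pairs$window == "kb5_50"] <= 50000))
  expect_true(all(pairs$distance[pairs$window == "kb50_200"] > 50000 &
                    pairs$distance[pairs$window == "kb50_200"] <= 200000))
})

test_that("linkage is symmetric under reflecting chromosome coordinates", {
  set.seed(77)
  C <- 1e6
  loci <- dplyr::bind_rows(lapply(1:15, function(i) {
    s <- sample(seq(10000, C - 20000, by = 7), 1)
    make_locus(sprintf("L%02d", i), start = s, end = s + 3000)
  }))
  genes <- dplyr::bind_rows(lapply(1:60, function(i) {
    make_gene(sprintf("g%02d", i), sample(seq(1, C - 1, by = 13), 1))
  }))
  fwd <- link_nearby_genes(loci, genes)
  rloci <- loci
  rloci$start <- C - loci$end
  rloci$end <- C - loci$start
  rgenes <- genes
  rgenes$tss <- C - genes$tss
  rev <- link_nearby_genes(rloci, rgenes)
  key <- function(p) paste(p$locus_id, p$gene_id, p$distance, p$window)
  expect_setequal(key(fwd), key(rev))
})

test_that("condition log2 ratio evaluates on TPM group means", {
  sheet <- two_group_sheet(n = 2)
  expr <- rbind(eq = rep(4, 4), up = c(4.5, 4.5, 9.5, 9.5),
                zero = rep(0, 4))
  colnames(expr) <- sheet$sample_id
  r <- condition_log2_ratio(expr, sheet, c("eq", "up", "zero"))
  expect_equal(unname(r["eq"]), 0)
  expect_equal(unname(r["up"]), 1)      # log2(10/5)
  expect_equal(unname(r["zero"]), 0)    # pseudocount floor
  expect_error(condition_log2_ratio(expr, sheet, "missing"), "unknown")
})

test_that("Spearman rho matches the rank-then-Pearson oracle", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(spearman_cor(x, exp(x))$rho, 1)    # monotone transform
  expect_equal(spearman_cor(x, exp(x))$p, 0)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  set.seed(12)
  for (i in 1:10) {
    a <- rnorm(10)
    b <- rnorm(10) + 0.5 * a
    res <- spearman_cor(a, b)
    expect_equal(res$rho, spearman_oracle(a, b), tolerance = 1e-12)
    tstat <- res$rho * sqrt(8 / (1 - res$rho^2))
    expect_equal(res$p, 2 * pt(-abs(tstat), 8), tolerance = 1e-12)
  }
  expect_error(spearman_cor(rep(1, 5), rnorm(5)), "constant")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
  expect_error(spearman_cor(1:5, 1:4), "equal length")
})

test_that("planted linkage yields strong positive rho; null covers zero", {
  cfg <- sim_config(
    n_te = 800, n_chrom = 1, chrom_length = 8e6,
    subfamily_proportions = c("RLTR45-int" = 0.25, "L1Md_T" = 0.40,
                              "B2_Mm2" = 0.35),
    linkage_slope = 0.8, n_genes = 150, library_size_mean = 5e4,
    seed = 41)
  sim <- simulate_annotation(cfg)
  rna <- simulate_rnaseq(sim, cfg)
  tpm <- compute_tpm(rna$counts)
  pairs <- sim$truth$linked_pairs
  te_r <- condition_log2_ratio(tpm, rna$sheet, pairs$locus_id)
  g_r <- condition_log2_ratio(tpm, rna$sheet, pairs$gene_id)
  expect_gte(length(te_r), 40)
  res <- spearman_cor(unname(te_r), unname(g_r))
  expect_gt(res$rho, 0)
  expect_lt(res$p, 0.01)
})

test_that("linkage summary counts distinct genes per window", {
  pairs <- tibble::tibble(
    locus_id = c("L1", "L2", "L3", "L4", "L5"),
    subfamily = "RLTR45-int",
    gene_id = c("g1", "g1", "g1", "g1", "g2"),
    distance = c(10000L, 20000L, 30000L, 60000L, 70000L),
    window = c("kb5_50", "kb5_50", "kb5_50", "kb50_200", "kb50_200")
  )
  s <- linkage_summary(pairs)
  expect_equal(s$n_genes[s$window == "kb5_50"], 1)     # shared gene once
  expect_equal(s$n_genes[s$window == "kb50_200"], 2)   # g1 again + g2
  expect_equal(nrow(linkage_summary(pairs[0, ])), 0)
})
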