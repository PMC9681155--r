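test_that("TPM follows the length-normalized formula and sums to 1e6", {
  m1 <- count_matrix(matrix(42, 1, 1, dimnames = list("f", "s")),
                     c(f = 1234))
  expect_equal(unname(compute_tpm(m1)[1, 1]), 1e6)

  m2 <- count_matrix(matrix(c(10, 10), 2, 1,
                            dimnames = list(c("a", "b"), "s")),
                     c(a = 1000, b = 2000))
  tpm <- compute_tpm(m2)
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  m <- tiny_counts()
  expect_equal(unname(colSums(compute_tpm(m))), rep(1e6, 4),
               tolerance = 1e-6)
})

test_that("CPM follows the count-proportion formula and handles zeros", {
  cnt <- matrix(c(30, 2e6 - 30), 2, 1, dimnames = list(c("a", "b"), "s"))
  m <- count_matrix(cnt, c(a = 1000, b = 1000))
  expect_equal(unname(compute_cpm(m)["a", 1]), 15)

  single <- count_matrix(matrix(c(7, 0), 2, 1,
                                dimnames = list(c("a", "b"), "s")),
                         c(a = 100, b = 100))
  expect_equal(unname(compute_cpm(single)["a", 1]), 1e6)

  zero <- count_matrix(matrix(0, 2, 1, dimnames = list(c("a", "b"), "s")),
                       c(a = 100, b = 100))
  expect_warning(cpm <- compute_cpm(zero), "all-zero")
  expect_true(all(cpm == 0))
})

test_that("RLE factors match the median-of-ratios closed form", {
  cnt <- matrix(c(10, 20, 30, 10, 20, 30), 3, 2,
                dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  m <- count_matrix(cnt, c(a = 1, b = 1, c = 1))
  expect_equal(unname(rle_size_factors(m)), c(1, 1))

  cnt2 <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  rownames(cnt2) <- c("a", "b", "c")
  m2 <- count_matrix(cnt2, c(a = 1, b = 1, c = 1))
  f <- rle_size_factors(m2)
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(unname(f[2] / f[1]), 2, tolerance = 1e-12)
})

test_that("features with a zero anywhere do not affect RLE factors", {
  cnt <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  rownames(cnt) <- c("a", "b", "c")
  m <- count_matrix(cnt, c(a = 1, b = 1, c = 1))
  cnt_z <- rbind(cnt, z1 = c(0, 1e6), z2 = c(1e6, 0))
  mz <- count_matrix(cnt_z, setNames(rep(1, 5), rownames(cnt_z)))
  expect_equal(rle_size_factors(mz), rle_size_factors(m))

  allz <- count_matrix(cbind(s1 = c(0, 5), s2 = c(5, 0)) |>
                         `rownames<-`(c("a", "b")),
                       c(a = 1, b = 1))
  expect_error(rle_size_factors(allz), "no feature")
})

test_that("RLE factors agree with an established median-of-ratios oracle", {
  skip_if_not_installed("DESeq2")
  set.seed(42)
  cnt <- matrix(rnbinom(600, mu = 50, size = 10) + 1, 100, 6,
                dimnames = list(sprintf("f%03d", 1:100),
                                sprintf("s%d", 1:6)))
  cnt[, 4:6] <- cnt[, 4:6] * 3
  m <- count_matrix(cnt, setNames(rep(1000, 100), rownames(cnt)))
  ours <- rle_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(cnt)
  # same up to the geometric-mean-1 rescaling convention; tiny differences
  # remain because the reference takes the median on the log scale, which
  # interpolates even-length medians geometrically rather than arithmetically
  expect_equal(unname(ours / ref), rep(mean(ours / ref), 6),
               tolerance = 1e-3)
})

test_that("expressed filter uses the pooled one-read-per-embryo rule", {
  cnt <- rbind(kept = rep(1, 12), dropped = c(rep(1, 11), 0))
  colnames(cnt) <- sprintf("s%02d", 1:12)
  m <- count_matrix(cnt, c(kept = 100, dropped = 100))
  out <- filter_expressed(m)
  expect_equal(rownames(out$counts), "kept")        # mean exactly 1 kept
  expect_identical(filter_expressed(out)$counts, out$counts)  # idempotent
  empty <- filter_expressed(count_matrix(
    matrix(0, 1, 2, dimnames = list("f", c("a", "b"))), c(f = 10)))
  expect_equal(nrow(empty$counts), 0)
})

test_that("aggregation is additive and partitions families", {
  loci <- tibble::tibble(
    locus_id = c("l1", "l2", "l3"),
    subfamily = c("RLTR45-int", "RLTR45-int", "MMETn-int"),
    family = c("ERVK", "ERVK", "ERVK")
  )
  expr <- matrix(c(3, 4, 5), 3, 1, dimnames = list(loci$locus_id, "s1"))
  sub <- aggregate_by_label(expr, loci, "subfamily")
  expect_equal(unname(sub["RLTR45-int", 1]), 7)
  fam <- aggregate_by_label(expr, loci, "family")
  expect_equal(unname(fam["ERVK", 1]), sum(sub[, 1]))

  rownames(expr)[1] <- "unknown"
  expect_error(aggregate_by_label(expr, loci, "subfamily"), "not in")
})

test_that("labels without expressed members aggregate to zero", {
  loci <- tibble::tibble(locus_id = c("l1", "l2"),
                         subfamily = c("A", "B"), family = c("FA", "FB"))
  expr <- matrix(5, 1, 1, dimnames = list("l1", "s1"))
  agg <- aggregate_by_label(expr, loci, "subfamily")
  expect_equal(unname(agg["B", 1]), 0)
})

test_that("family ratio test matches direct evaluation and a Welch oracle", {
  sheet <- two_group_sheet(n = 3)
  agg <- rbind(
    null = rep(2, 6),
    shifted = c(1, 1, 1, 4, 4, 4)
  )
  colnames(agg) <- sheet$sample_id
  res <- family_ratio_test(agg, sheet)
  expect_equal(res$log2_ratio[res$label == "null"], 0)
  expect_equal(res$p[res$label == "null"], 1)
  # group means 4 (SCNT) vs 1 (IVF) with pseudocount 0.5
  expect_equal(res$log2_ratio[res$label == "shifted"], log2(4.5 / 1.5),
               tolerance = 1e-9)

  set.seed(99)
  for (i in 1:10) {
    x <- rnorm(6, 10, 2)
    agg2 <- matrix(x, 1, 6, dimnames = list("r", sheet$sample_id))
    res2 <- family_ratio_test(agg2, sheet)
    expect_equal(res2$p,
                 welch_oracle_p(x[4:6], x[1:3]), tolerance = 1e-10)
  }
  expect_error(family_ratio_test(agg, sheet[sheet$condition == "IVF", ]),
               ">= 2 samples")
})
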