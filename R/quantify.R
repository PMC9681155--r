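#' Transcripts per million
#'
#' Per sample: `rate_i = count_i / length_kb_i`, then
#' `TPM_i = 1e6 * rate_i / sum(rate)`. An all-zero sample yields an all-zero
#' column with a warning.
#'
#' @param m A [count_matrix()].
#' @return Numeric matrix of TPM values with attribute `unit = "TPM"`.
#' @export
compute_tpm <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  rate <- m$counts / (m$lengths / 1000)
  tot <- colSums(rate)
  if (any(tot == 0)) {
    warning("all-zero sample(s): ",
            paste(colnames(m$counts)[tot == 0], collapse = ", "))
  }
  tpm <- sweep(rate, 2, ifelse(tot == 0, 1, tot), "/") * 1e6
  attr(tpm, "unit") <- "TPM"
  tpm
}

#' Counts per million
#'
#' `CPM_i = 1e6 * count_i / column_total`; all-zero columns stay zero with a
#' warning.
#'
#' @param m A [count_matrix()].
#' @return Numeric matrix with attribute `unit = "CPM"`.
#' @export
compute_cpm <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  tot <- colSums(m$counts)
  if (any(tot == 0)) {
    warning("all-zero sample(s): ",
            paste(colnames(m$counts)[tot == 0], collapse = ", "))
  }
  cpm <- sweep(m$counts, 2, ifelse(tot == 0, 1, tot), "/") * 1e6
  attr(cpm, "unit") <- "CPM"
  cpm
}

#' Relative log expression (median-of-ratios) size factors
#'
#' The reference for each feature is its geometric mean across samples,
#' computed over features with no zero in any sample; the factor for a sample
#' is the median of its count/reference ratios. Factors are rescaled to
#' geometric mean 1.
#'
#' @param m A [count_matrix()].
#' @return Named positive numeric vector, one factor per sample.
#' @export
rle_size_factors <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  cnt <- m$counts
  pos <- rowSums(cnt == 0) == 0
  if (!any(pos)) {
    stop("no feature with positive counts in all samples; ",
         "RLE factors undefined")
  }
  ref <- exp(rowMeans(log(cnt[pos, , drop = FALSE])))
  f <- apply(cnt[pos, , drop = FALSE], 2, function(col) stats::median(col / ref))
  f / exp(mean(log(f)))
}

#' Filter to expressed features
#'
#' Keeps a feature iff its total count divided by the number of samples
#' (all embryos of both conditions pooled) is at least `min_mean` — the
#' "at least one read on average per embryo" rule. Idempotent.
#'
#' @param m A [count_matrix()].
#' @param min_mean Minimum mean count per sample (default 1).
#' @return A [count_matrix()] restricted to expressed features.
#' @export
filter_expressed <- function(m, min_mean = 1) {
  stopifnot(inherits(m, "count_matrix"))
  keep <- rowMeans(m$counts) >= min_mean
  count_matrix(m$counts[keep, , drop = FALSE], m$lengths[keep])
}

#' Aggregate locus-level expression to subfamily or family level
#'
#' Per sample, a label's value is the sum over its member loci. Labels
#' present in the annotation but with no expressed member get 0. Features in
#' `expr` that do not map to a locus raise an error.
#'
#' @param expr Numeric matrix (loci x samples), e.g. from [compute_tpm()].
#' @param loci TE annotation tibble.
#' @param level `"subfamily"` or `"family"`.
#' @return Numeric matrix (labels x samples).
#' @export
aggregate_by_label <- function(expr, loci, level = c("subfamily", "family")) {
  level <- match.arg(level)
  idx <- match(rownames(expr), loci$locus_id)
  if (anyNA(idx)) {
    stop("feature(s) not in the annotation: ",
         rownames(expr)[which(is.na(idx))[1]])
  }
  lab <- loci[[level]][idx]
  all_labels <- sort(unique(loci[[level]]))
  agg <- rowsum(expr, group = lab)
  out <- matrix(0, nrow = length(all_labels), ncol = ncol(expr),
                dimnames = list(all_labels, colnames(expr)))
  out[rownames(agg), ] <- agg
  attr(out, "unit") <- attr(expr, "unit")
  out
}

#' Per-label SCNT/IVF expression ratio with a two-tailed Welch t-test
#'
#' For each label (TE family or subfamily), computes
#' `log2((mean_SCNT + c) / (mean_IVF + c))` on the aggregated per-embryo
#' values and a two-tailed Welch (unequal-variance) t-test between the
#' per-embryo values of the two conditions.
#'
#' @param agg Aggregated expression matrix from [aggregate_by_label()].
#' @param sheet Sample sheet tibble.
#' @param condition_a,condition_b Conditions forming the ratio a/b
#'   (default SCNT over IVF).
#' @param pseudocount Added to both group means before the ratio.
#' @return Tibble with `label`, `mean_a`, `mean_b`, `log2_ratio`, `p`.
#' @export
family_ratio_test <- function(agg, sheet, condition_a = "SCNT",
                              condition_b = "IVF", pseudocount = 0.5) {
  a_cols <- sheet$sample_id[sheet$condition == condition_a]
  b_cols <- sheet$sample_id[sheet$condition == condition_b]
  if (length(a_cols) < 2 || length(b_cols) < 2) {
    stop("need >= 2 samples in each of '", condition_a, "' and '",
         condition_b, "'")
  }
  A <- agg[, a_cols, drop = FALSE]
  B <- agg[, b_cols, drop = FALSE]
  mean_a <- rowMeans(A)
  mean_b <- rowMeans(B)
  p <- vapply(seq_len(nrow(agg)), function(i) {
    welch_p(A[i, ], B[i, ])
  }, numeric(1))
  tibble::tibble(
    label = rownames(agg),
    mean_a = unname(mean_a), mean_b = unname(mean_b),
    log2_ratio = unname(log2((mean_a + pseudocount) /
                               (mean_b + pseudocount))),
    p = p
  )
}

# Two-tailed Welch t-test p; degenerate constant groups resolve by the mean
# difference (equal -> 1, different -> 0).
welch_p <- function(x, y) {
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}
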