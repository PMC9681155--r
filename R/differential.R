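#' Negative-binomial Wald test for condition differences
#'
#' A locus-level two-group test on size-factor-normalized counts. Per
#' feature: group means of normalized counts, a pooled method-of-moments
#' dispersion (`alpha = (s^2 - mu) / mu^2` within each group, pooled by
#' degrees of freedom, floored at 1e-8), fold change
#' `log2fc = log2((mu_a + c) / (mu_b + c))` with pseudocount `c`, and a Wald
#' statistic `log2fc / SE(log2fc)` whose standard error comes from the NB
#' delta method, `Var(mu_hat_g) = (mu_g + alpha * mu_g^2) / n_g`. The p-value
#' is two-sided normal. Features failing the expressed filter (mean raw count
#' per sample below `expressed_min_mean`) are reported untested with no p.
#'
#' This is an intentionally transparent re-implementation of the NB testing
#' idea behind shrinkage-based DE packages; numerical equivalence with any
#' such package is not claimed (no dispersion shrinkage, no outlier
#' handling).
#'
#' @param m A [count_matrix()].
#' @param sheet Sample sheet tibble with `sample_id` and `condition`.
#' @param size_factors Optional per-sample positive factors; computed with
#'   [rle_size_factors()] when `NULL`.
#' @param condition_a,condition_b Conditions compared as a over b
#'   (default SCNT over IVF, so repression gives negative `log2fc`).
#' @param pseudocount Added to both group means in the fold change.
#' @param expressed_min_mean Expressed-filter threshold (mean raw count).
#' @return Tibble with `feature_id`, `base_mean`, `log2fc`, `p`, `tested`.
#' @export
nb_wald_test <- function(m, sheet, size_factors = NULL,
                         condition_a = "SCNT", condition_b = "IVF",
                         pseudocount = 0.5, expressed_min_mean = 1) {
  stopifnot(inherits(m, "count_matrix"))
  a_cols <- sheet$sample_id[sheet$condition == condition_a]
  b_cols <- sheet$sample_id[sheet$condition == condition_b]
  if (length(a_cols) < 2 || length(b_cols) < 2) {
    stop("need >= 2 samples per condition")
  }
  if (is.null(size_factors)) size_factors <- rle_size_factors(m)
  if (any(size_factors <= 0)) stop("size factors must be positive")
  norm <- sweep(m$counts, 2, size_factors[colnames(m$counts)], "/")

  tested <- rowMeans(m$counts) >= expressed_min_mean
  A <- norm[, a_cols, drop = FALSE]
  B <- norm[, b_cols, drop = FALSE]
  nA <- ncol(A)
  nB <- ncol(B)
  muA <- rowMeans(A)
  muB <- rowMeans(B)
  vA <- rowSums((A - muA)^2) / (nA - 1)
  vB <- rowSums((B - muB)^2) / (nB - 1)
  aA <- ifelse(muA > 0, (vA - muA) / muA^2, 0)
  aB <- ifelse(muB > 0, (vB - muB) / muB^2, 0)
  alpha <- pmax(((nA - 1) * aA + (nB - 1) * aB) / (nA + nB - 2), 1e-8)
  varA <- (muA + alpha * muA^2) / nA
  varB <- (muB + alpha * muB^2) / nB
  log2fc <- log2((muA + pseudocount) / (muB + pseudocount))
  se <- sqrt(varA / (muA + pseudocount)^2 +
               varB / (muB + pseudocount)^2) / log(2)
  p <- ifelse(se > 0, 2 * stats::pnorm(-abs(log2fc / se)),
              ifelse(log2fc == 0, 1, 0))
  # zero counts and zero variance in both groups: nothing to test
  tested <- tested & !(muA == 0 & muB == 0)
  p[!tested] <- NA_real_
  tibble::tibble(
    feature_id = rownames(m$counts),
    base_mean = unname(rowMeans(norm)),
    log2fc = unname(log2fc),
    p = unname(p),
    tested = unname(tested)
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotone enforcement; output order matches
#' input. `NA` p-values (untested features) pass through as `NA` and do not
#' enter the adjustment.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Classify features as SCNT-low / SCNT-high / unchanged
#'
#' Applies the printed thresholds: SCNT-low iff `log2fc <= -log2fc_cut` and
#' `padj < padj_cut`; SCNT-high iff `log2fc >= log2fc_cut` and
#' `padj < padj_cut`; otherwise unchanged. Untested features stay
#' `untested`. The fold-change bound is inclusive, the adjusted-p bound
#' exclusive.
#'
#' @param diff Tibble from [nb_wald_test()] (columns `log2fc`, `p`,
#'   `tested`). If a `padj` column is absent it is added with
#'   [bh_adjust()] over the tested features.
#' @param log2fc_cut Absolute log2 ratio threshold (default 1).
#' @param padj_cut Adjusted-p threshold (default 0.1).
#' @return The input tibble with columns `padj` and `klass`
#'   (`"SCNT_low"`, `"SCNT_high"`, `"unchanged"`, `"untested"`).
#' @export
classify_differential <- function(diff, log2fc_cut = 1, padj_cut = 0.1) {
  if (!"padj" %in% names(diff)) diff$padj <- bh_adjust(diff$p)
  tested <- if ("tested" %in% names(diff)) diff$tested else !is.na(diff$padj)
  diff$klass <- ifelse(
    !tested, "untested",
    ifelse(diff$log2fc <= -log2fc_cut & diff$padj < padj_cut, "SCNT_low",
           ifelse(diff$log2fc >= log2fc_cut & diff$padj < padj_cut,
                  "SCNT_high", "unchanged"))
  )
  diff
}

# round-half-away-from-zero, the convention for reported integer percents
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Integer percentage, rounded half away from zero
#'
#' @param n Numerator count.
#' @param total Denominator count.
#' @return `round(100 * n / total)` (half away from zero); `NA` when
#'   `total` is 0.
#' @export
round_percent <- function(n, total) {
  ifelse(total > 0, round_half_away(100 * n / total), NA_real_)
}

#' Family/subfamily composition of the expressed and differential strata
#'
#' For each stratum (`expressed` = all tested loci, `SCNT_low`,
#' `SCNT_high`), counts the member loci per family or subfamily and reports
#' the count, the stratum total, and the integer-rounded percentage. An empty
#' stratum reports percent `NA` (printed as em dash).
#'
#' @param diff Classified tibble from [classify_differential()].
#' @param loci TE annotation tibble; only features present here (TE loci)
#'   enter the summary.
#' @param level `"family"` or `"subfamily"`.
#' @return Tibble with `stratum`, `label`, `n`, `total`, `percent`.
#' @export
composition_summary <- function(diff, loci, level = c("family", "subfamily")) {
  level <- match.arg(level)
  d <- diff[diff$feature_id %in% loci$locus_id, ]
  lab <- loci[[level]][match(d$feature_id, loci$locus_id)]
  strata <- list(
    expressed = d$klass != "untested",
    SCNT_low = d$klass == "SCNT_low",
    SCNT_high = d$klass == "SCNT_high"
  )
  labels <- sort(unique(loci[[level]]))
  out <- lapply(names(strata), function(s) {
    in_s <- strata[[s]]
    total <- sum(in_s)
    n <- vapply(labels, function(l) sum(in_s & lab == l), numeric(1),
                USE.NAMES = FALSE)
    tibble::tibble(stratum = s, label = labels, n = n, total = total,
                   percent = round_percent(n, total))
  })
  dplyr::bind_rows(out)
}
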