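#' Link TE loci to nearby genes by TSS distance
#'
#' Pairs every TE locus with every gene on the same chromosome whose TSS
#' falls within one of the distance windows. Distance is 0 when the TSS lies
#' inside the locus, otherwise the distance to the nearest locus boundary
#' (`min(|tss - start|, |tss - end|)` on half-open coordinates). Both
#' genomic sides count ("up/downstream"); TE strand is ignored. Distances
#' below 5 kb or above 200 kb produce no pair; the shared 50-kb boundary is
#' assigned to the proximal window. A gene may pair with several loci and
#' vice versa.
#'
#' @param loci TE annotation tibble (typically an SCNT-low subset).
#' @param genes Gene-model tibble.
#' @param proximal,distal Two-element numeric vectors giving the closed
#'   proximal window and half-open distal window in bp.
#' @return Tibble with `locus_id`, `subfamily`, `gene_id`, `distance`,
#'   `window` (`"kb5_50"` or `"kb50_200"` under the defaults).
#' @export
link_nearby_genes <- function(loci, genes,
                              proximal = c(5000, 50000),
                              distal = c(50000, 200000)) {
  l <- loci[, c("locus_id", "subfamily", "chrom", "start", "end")]
  g <- genes[, c("gene_id", "chrom", "tss")]
  pairs <- dplyr::inner_join(l, g, by = "chrom",
                             relationship = "many-to-many")
  inside <- pairs$tss >= pairs$start & pairs$tss < pairs$end
  d <- ifelse(inside, 0,
              pmin(abs(pairs$tss - pairs$start), abs(pairs$tss - pairs$end)))
  win_names <- c(
    sprintf("kb%g_%g", proximal[1] / 1000, proximal[2] / 1000),
    sprintf("kb%g_%g", distal[1] / 1000, distal[2] / 1000)
  )
  window <- ifelse(d >= proximal[1] & d <= proximal[2], win_names[1],
                   ifelse(d > distal[1] & d <= distal[2], win_names[2],
                          NA_character_))
  keep <- !is.na(window)
  tibble::tibble(
    locus_id = pairs$locus_id[keep],
    subfamily = pairs$subfamily[keep],
    gene_id = pairs$gene_id[keep],
    distance = as.integer(d[keep]),
    window = window[keep]
  )
}

#' Per-feature SCNT/IVF log2 expression ratio
#'
#' `log2((mean_SCNT + c) / (mean_IVF + c))` over the TPM (or other
#' expression) values of the two conditions.
#'
#' @param expr Expression matrix (features x samples), e.g. [compute_tpm()].
#' @param sheet Sample sheet tibble.
#' @param feature_ids Features to evaluate (must be rows of `expr`).
#' @param condition_a,condition_b Ratio a over b (default SCNT/IVF).
#' @param pseudocount Added to both means (default 0.5).
#' @return Named numeric vector of log2 ratios.
#' @export
condition_log2_ratio <- function(expr, sheet, feature_ids,
                                 condition_a = "SCNT", condition_b = "IVF",
                                 pseudocount = 0.5) {
  missing <- setdiff(feature_ids, rownames(expr))
  if (length(missing)) stop("unknown feature(s): ", missing[1])
  a_cols <- sheet$sample_id[sheet$condition == condition_a]
  b_cols <- sheet$sample_id[sheet$condition == condition_b]
  if (length(a_cols) == 0 || length(b_cols) == 0) {
    stop("both conditions must be present in the sample sheet")
  }
  ma <- rowMeans(expr[feature_ids, a_cols, drop = FALSE])
  mb <- rowMeans(expr[feature_ids, b_cols, drop = FALSE])
  stats::setNames(log2((ma + pseudocount) / (mb + pseudocount)), feature_ids)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rho is the Pearson correlation of mid-ranks (average ties); the p-value
#' uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`,
#' two-sided, with `p = 0` at `|rho| = 1`. A least-squares line on the raw
#' values is attached for display only.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, neither constant.
#' @return List with `rho`, `p`, `n`, `slope`, `intercept`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  rho <- stats::cor(x, y, method = "spearman")
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  list(rho = rho, p = p, n = n,
       slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]))
}

#' Count distinct linked genes per window (and per TE subset)
#'
#' A gene linked to several loci within one window counts once there; a gene
#' reached through different loci in both windows counts once per window.
#'
#' @param pairs Linkage tibble from [link_nearby_genes()].
#' @param by Optional extra grouping column in `pairs` (e.g. `"subfamily"`).
#' @return Tibble with the grouping columns, `window`, and `n_genes`.
#' @export
linkage_summary <- function(pairs, by = "subfamily") {
  if (nrow(pairs) == 0) {
    return(tibble::tibble(window = character(), n_genes = integer()))
  }
  grp <- c(by[by %in% names(pairs)], "window")
  dplyr::summarise(
    dplyr::group_by(pairs, dplyr::across(dplyr::all_of(grp))),
    n_genes = dplyr::n_distinct(.data$gene_id),
    .groups = "drop"
  )
}
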