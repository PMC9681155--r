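#' Call homozygous knockout embryos from expression
#'
#' An embryo is called homozygous knockout when both target loci show no or
#' negligible expression: TPM strictly below `tpm_cut` (default 5) at both.
#' All other embryos (wild type and heterozygous pooled) are `other`.
#'
#' @param tpm TPM matrix (features x embryos) from [compute_tpm()].
#' @param target_locus_ids Character vector of the two targeted locus ids.
#' @param tpm_cut Strict upper TPM bound for "no or negligible" (default 5).
#' @return Tibble with `embryo_id`, `locus1_tpm`, `locus2_tpm`, `genotype`
#'   (`"hom_ko"` or `"other"`).
#' @export
call_homozygous_ko <- function(tpm, target_locus_ids, tpm_cut = 5) {
  stopifnot(length(target_locus_ids) == 2)
  missing <- setdiff(target_locus_ids, rownames(tpm))
  if (length(missing)) stop("target locus not in expression table: ",
                            missing[1])
  l1 <- unname(tpm[target_locus_ids[1], ])
  l2 <- unname(tpm[target_locus_ids[2], ])
  tibble::tibble(
    embryo_id = colnames(tpm),
    locus1_tpm = unname(l1),
    locus2_tpm = unname(l2),
    genotype = ifelse(l1 < tpm_cut & l2 < tpm_cut, "hom_ko", "other")
  )
}

#' Compare adjacent-gene expression between knockout and other embryos
#'
#' Per gene: two-tailed Welch t-test on TPM between homozygous-knockout and
#' other embryos, and the log2 ratio of group means (hom_ko over other) with
#' a pseudocount.
#'
#' @param tpm TPM matrix (features x embryos).
#' @param calls Genotype tibble with `embryo_id` and `genotype` columns
#'   (from [call_homozygous_ko()] or ground truth).
#' @param gene_ids Genes to compare.
#' @param pseudocount Added to both group means (default 0.5).
#' @return Tibble with `gene_id`, `mean_hom_ko`, `mean_other`,
#'   `log2_ratio`, `p`.
#' @export
compare_adjacent_genes <- function(tpm, calls, gene_ids, pseudocount = 0.5) {
  hom <- calls$embryo_id[calls$genotype == "hom_ko"]
  oth <- calls$embryo_id[calls$genotype == "other"]
  for (grp in list(c("hom_ko", length(hom)), c("other", length(oth)))) {
    if (as.integer(grp[2]) < 2) {
      stop("fewer than 2 embryos in group '", grp[1], "'")
    }
  }
  missing <- setdiff(gene_ids, rownames(tpm))
  if (length(missing)) stop("gene not in expression table: ", missing[1])
  H <- tpm[gene_ids, hom, drop = FALSE]
  O <- tpm[gene_ids, oth, drop = FALSE]
  tibble::tibble(
    gene_id = gene_ids,
    mean_hom_ko = unname(rowMeans(H)),
    mean_other = unname(rowMeans(O)),
    log2_ratio = unname(log2((rowMeans(H) + pseudocount) /
                               (rowMeans(O) + pseudocount))),
    p = vapply(seq_along(gene_ids),
               function(i) welch_p(H[i, ], O[i, ]), numeric(1))
  )
}

#' Correlate knockout and SCNT fold changes of adjacent genes
#'
#' Spearman correlation between per-gene log2 ratios under knockout
#' (hom_ko/other) and under SCNT (SCNT/IVF), for matched gene lists. The
#' attached least-squares line is for display only.
#'
#' @param ko_ratios,scnt_ratios Numeric vectors of per-gene log2 ratios in
#'   the same gene order, `n >= 3`.
#' @return List as from [spearman_cor()].
#' @export
ko_scnt_ratio_correlation <- function(ko_ratios, scnt_ratios) {
  spearman_cor(ko_ratios, scnt_ratios)
}

#' Chi-square test against Mendelian 1:2:1 genotype ratios
#'
#' For offspring of a heterozygote-by-heterozygote cross, compares observed
#' (wt, het, hom) counts to expected proportions (1/4, 1/2, 1/4) with a
#' Pearson chi-square statistic on 2 degrees of freedom, upper-tail p.
#'
#' @param n_wt,n_het,n_hom Observed genotype counts (non-negative, total
#'   > 0).
#' @return List with `chi2`, `df`, `p`, `expected`.
#' @export
mendelian_chisq <- function(n_wt, n_het, n_hom) {
  obs <- c(n_wt, n_het, n_hom)
  if (any(obs < 0)) stop("counts must be non-negative")
  total <- sum(obs)
  if (total == 0) stop("zero total count")
  expected <- total * c(0.25, 0.5, 0.25)
  chi2 <- sum((obs - expected)^2 / expected)
  list(chi2 = chi2, df = 2,
       p = stats::pchisq(chi2, df = 2, lower.tail = FALSE),
       expected = expected)
}
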