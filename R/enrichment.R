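#' Sliding-window bin grid
#'
#' Divides each chromosome into 2-kb bins starting every 1 kb (so adjacent
#' bins overlap by half), with the final bins truncated at the chromosome
#' end: bins `[k*1000, min(k*1000 + 2000, L))` for every `k` with
#' `k*1000 < L`.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
make_bins <- function(chrom_sizes) {
  stopifnot(!is.null(names(chrom_sizes)), all(chrom_sizes > 0))
  out <- lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    start <- seq(0, L - 1, by = 1000)
    tibble::tibble(chrom = ch, start = as.integer(start),
                   end = as.integer(pmin(start + 2000, L)))
  })
  dplyr::bind_rows(out)
}

#' Down-sample replicate count vectors to a matched depth
#'
#' Each replicate is binomially thinned with keep probability
#' `min(total) / total_r` so all replicates contribute a similar read count,
#' then the thinned replicates are summed into a merged vector. Deterministic
#' under `seed`.
#'
#' @param replicates List of non-negative integer count vectors of equal
#'   length (one per replicate).
#' @param seed Integer seed for the thinning.
#' @return List with `thinned` (list of vectors), `merged` (their sum), and
#'   `keep_prob` (per-replicate thinning probabilities).
#' @export
downsample_to_match <- function(replicates, seed = 1) {
  stopifnot(length(replicates) >= 1)
  totals <- vapply(replicates, sum, numeric(1))
  if (any(totals == 0)) {
    stop("replicate ", which(totals == 0)[1], " has zero total reads")
  }
  p <- min(totals) / totals
  set.seed(seed)
  thinned <- lapply(seq_along(replicates), function(r) {
    v <- replicates[[r]]
    if (p[r] >= 1) v else stats::rbinom(length(v), v, p[r])
  })
  merged <- Reduce(`+`, thinned)
  list(thinned = thinned, merged = merged, keep_prob = p)
}

#' Bin-normalized RPKM for a TE locus
#'
#' `count / ((length/1000) * (bin_total/1e6))`, where `bin_total` is the
#' total read count over all sliding 2-kb bins. Because adjacent bins
#' overlap, reads are counted about twice in `bin_total`; the formula is
#' applied literally so scores stay comparable across marks and stages.
#'
#' @param count Read count(s) on the locus.
#' @param length_bp Locus length(s) in bp (> 0).
#' @param bin_total Total read count over the 2-kb bin windows (> 0).
#' @return RPKM value(s).
#' @export
te_rpkm <- function(count, length_bp, bin_total) {
  if (any(bin_total <= 0)) stop("bin_total must be > 0")
  if (any(length_bp <= 0)) stop("length_bp must be > 0")
  count / ((length_bp / 1000) * (bin_total / 1e6))
}

#' log2 ChIP/input enrichment
#'
#' `log2((chip_rpkm + c) / (input_rpkm + c))` with pseudocount `c` (default
#' 0.5) so empty loci score 0 rather than diverging.
#'
#' @param chip_rpkm,input_rpkm Non-negative RPKM values.
#' @param pseudocount Pseudocount added to both (default 0.5).
#' @return log2 enrichment value(s).
#' @export
log2_enrichment <- function(chip_rpkm, input_rpkm, pseudocount = 0.5) {
  log2((chip_rpkm + pseudocount) / (input_rpkm + pseudocount))
}

#' Score ChIP/input enrichment over TE loci
#'
#' Combines [te_rpkm()] and [log2_enrichment()] for a table of per-locus
#' merged ChIP and input counts, then flags enhancer-like loci with
#' [classify_enhancer_like()].
#'
#' @param locus_counts Tibble with `locus_id`, `length`, `chip`, `input`
#'   (merged counts).
#' @param chip_bin_total,input_bin_total Totals over the 2-kb bin windows of
#'   the merged ChIP and input tracks.
#' @param mark Histone mark label (e.g. `"H3K27ac"`).
#' @param stage Developmental-stage label.
#' @param threshold Enhancer-like threshold on the log2 scale.
#' @return Tibble of enrichment records: `locus_id`, `chip_rpkm`,
#'   `input_rpkm`, `log2_enrichment`, `enhancer_like`, `mark`, `stage`.
#' @export
te_enrichment <- function(locus_counts, chip_bin_total, input_bin_total,
                          mark = "H3K27ac", stage = NA_character_,
                          threshold = 1.5) {
  rec <- tibble::tibble(
    locus_id = locus_counts$locus_id,
    chip_rpkm = te_rpkm(locus_counts$chip, locus_counts$length,
                        chip_bin_total),
    input_rpkm = te_rpkm(locus_counts$input, locus_counts$length,
                         input_bin_total),
    mark = mark, stage = stage
  )
  rec$log2_enrichment <- log2_enrichment(rec$chip_rpkm, rec$input_rpkm)
  classify_enhancer_like(rec, threshold = threshold, mark = mark)
}

#' Flag enhancer-like loci
#'
#' `enhancer_like = (log2_enrichment >= threshold)`; the default threshold
#' 1.5 is interpreted on the log2 scale (about 2.8-fold linear), matching
#' the definition of enrichment as a log2 ChIP/input ratio. Intended for the
#' active-enhancer mark H3K27ac; the flag is computed for whatever records
#' are supplied.
#'
#' @param records Tibble with a `log2_enrichment` column.
#' @param threshold Log2 enrichment threshold (default 1.5, inclusive).
#' @param mark Mark the threshold refers to (metadata only).
#' @return `records` with a logical `enhancer_like` column.
#' @export
classify_enhancer_like <- function(records, threshold = 1.5,
                                   mark = "H3K27ac") {
  records$enhancer_like <- records$log2_enrichment >= threshold
  records
}

#' Promoter ChIP/input enrichment
#'
#' Promoters are the strand-aware windows −2,000 to +500 bp around the TSS
#' (`[tss-2000, tss+500)` on `+`, `[tss-500, tss+2000)` on `-`), clipped to
#' the chromosome with a warning. Each promoter takes its counts from the
#' single 2-kb sliding bin with maximal overlap (ties resolved to the
#' leftmost bin), then RPKM (length 2,000) and log2 enrichment as for TE
#' loci.
#'
#' @param genes Gene-model tibble (`gene_id`, `chrom`, `tss`, `strand`).
#' @param bins Bin grid from [make_bins()].
#' @param bin_chip,bin_input Per-bin merged ChIP and input counts aligned
#'   with `bins` rows.
#' @return Tibble with `gene_id`, `bin_start`, `bin_end`, `chip_rpkm`,
#'   `input_rpkm`, `log2_enrichment`.
#' @export
promoter_enrichment <- function(genes, bins, bin_chip, bin_input) {
  stopifnot(nrow(bins) == length(bin_chip), nrow(bins) == length(bin_input))
  chip_total <- sum(bin_chip)
  input_total <- sum(bin_input)
  chrom_max <- tapply(bins$end, bins$chrom, max)
  p_start <- ifelse(genes$strand == "+", genes$tss - 2000, genes$tss - 500)
  p_end <- ifelse(genes$strand == "+", genes$tss + 500, genes$tss + 2000)
  clip_lo <- p_start < 0
  clip_hi <- p_end > chrom_max[genes$chrom]
  if (any(clip_lo | clip_hi)) {
    warning("promoter window clipped to chromosome bounds for: ",
            paste(genes$gene_id[clip_lo | clip_hi], collapse = ", "))
  }
  p_start <- pmax(p_start, 0)
  p_end <- pmin(p_end, chrom_max[genes$chrom])

  out <- lapply(seq_len(nrow(genes)), function(i) {
    on <- which(bins$chrom == genes$chrom[i] &
                  bins$start < p_end[i] & bins$end > p_start[i])
    ov <- pmin(bins$end[on], p_end[i]) - pmax(bins$start[on], p_start[i])
    best <- on[which.max(ov)]  # which.max takes the first (leftmost) tie
    chip_rpkm <- te_rpkm(bin_chip[best], 2000, chip_total)
    input_rpkm <- te_rpkm(bin_input[best], 2000, input_total)
    tibble::tibble(
      gene_id = genes$gene_id[i],
      bin_start = bins$start[best], bin_end = bins$end[best],
      chip_rpkm = chip_rpkm, input_rpkm = input_rpkm,
      log2_enrichment = log2_enrichment(chip_rpkm, input_rpkm)
    )
  })
  dplyr::bind_rows(out)
}

#' Fisher's exact test for overlap of two feature sets
#'
#' Builds the 2x2 table of membership in `a` and `b` over `universe` and
#' returns the two-sided exact p-value together with the sample odds ratio
#' (Haldane 0.5 correction applied to all cells when any cell is zero).
#'
#' @param a,b Character vectors of feature ids, subsets of `universe`.
#' @param universe Character vector of all feature ids.
#' @return List with `odds_ratio`, `p`, and the 2x2 `table`.
#' @export
overlap_fisher <- function(a, b, universe) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(a %in% universe) || !all(b %in% universe)) {
    stop("a and b must be subsets of universe")
  }
  in_a <- universe %in% a
  in_b <- universe %in% b
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("in_a", "not_a"), c("in_b", "not_b")))
  p <- stats::fisher.test(tab)$p.value
  h <- if (any(tab == 0)) 0.5 else 0
  or <- ((tab[1, 1] + h) * (tab[2, 2] + h)) /
    ((tab[1, 2] + h) * (tab[2, 1] + h))
  list(odds_ratio = or, p = p, table = tab)
}
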