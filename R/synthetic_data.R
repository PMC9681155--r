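#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study design the analysis assumes: single-embryo RNA-seq of two conditions
#' (12 IVF vs 12 SCNT embryos), overdispersed negative-binomial counts over
#' a few thousand TE loci dominated by a handful of subfamilies, a planted
#' SCNT-repressed subset of one ERVK subfamily (4-fold median repression),
#' a planted enhancer-like subset of those loci with 8-fold ChIP enrichment,
#' and linked nearby genes whose SCNT/IVF ratio follows the TE ratio with
#' slope 0.8.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_te Number of TE loci.
#' @param subfamily_proportions Named fractions per subfamily (must sum to 1).
#' @param n_genes Number of genes.
#' @param n_embryos_per_condition Embryos per condition (IVF and SCNT).
#' @param library_size_mean Expected total reads per embryo over all features.
#' @param library_log_sd SD of the log-normal per-embryo library factor.
#' @param baseline_log_mean,baseline_log_sd Natural-log mean/SD of the
#'   log-normal baseline expression of features.
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param repressed_subfamily Subfamily carrying the planted repression.
#' @param frac_repressed Fraction of that subfamily planted as repressed.
#' @param repression_fold Median fold (in (0, 1]) applied to the SCNT
#'   condition at planted loci.
#' @param repression_log2_sd Per-locus spread (SD, log2 scale) of the planted
#'   repression around `log2(repression_fold)`; folds are capped at 1.
#' @param frac_enhancer Fraction of repressed loci planted as enhancers.
#' @param chip_enrichment_fold ChIP rate multiplier (>= 1) at planted
#'   enhancer loci.
#' @param chip_depth Expected ChIP/input reads per bp per replicate.
#' @param chip_rep_depth Relative depth of the ChIP/input replicates.
#' @param linkage_slope Transfer of TE log2 ratio into the linked gene's
#'   log2 ratio.
#' @param linkage_window Maximum TSS distance (bp) at which linked genes are
#'   planted.
#' @param te_length_range Range (bp) of simulated TE locus lengths.
#' @param seed Integer seed governing all stages via derived sub-seeds.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 2,
                       chrom_length = 2e7,
                       n_te = 2000,
                       subfamily_proportions = c(
                         "RLTR45-int" = 0.10, "MMETn-int" = 0.05,
                         "IAPEz-int" = 0.10, "MTA_Mm-int" = 0.15,
                         "L1Md_T" = 0.30, "B2_Mm2" = 0.30),
                       n_genes = 400,
                       n_embryos_per_condition = 12,
                       library_size_mean = 1.2e5,
                       library_log_sd = 0.2,
                       baseline_log_mean = 3,
                       baseline_log_sd = 1,
                       nb_dispersion = 0.05,
                       repressed_subfamily = "RLTR45-int",
                       frac_repressed = 0.6,
                       repression_fold = 0.25,
                       repression_log2_sd = 0.5,
                       frac_enhancer = 0.6,
                       chip_enrichment_fold = 8,
                       chip_depth = 0.02,
                       chip_rep_depth = c(1, 0.7),
                       linkage_slope = 0.8,
                       linkage_window = 2e5,
                       te_length_range = c(500, 6000),
                       seed = 1) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$subfamily_proportions) - 1) > 1e-8) {
    stop("subfamily_proportions must sum to 1")
  }
  stopifnot(
    cfg$n_chrom >= 1, cfg$chrom_length > 0, cfg$n_te >= 1, cfg$n_genes >= 1,
    cfg$n_embryos_per_condition >= 2,
    cfg$repression_fold > 0, cfg$repression_fold <= 1,
    cfg$chip_enrichment_fold >= 1, cfg$nb_dispersion > 0,
    cfg$frac_repressed >= 0, cfg$frac_repressed <= 1,
    cfg$frac_enhancer >= 0, cfg$frac_enhancer <= 1,
    cfg$linkage_window >= 5000,
    cfg$repressed_subfamily %in% names(cfg$subfamily_proportions)
  )
  structure(cfg, class = "sim_config")
}

# RepeatMasker-style family/class for the default subfamilies; unknown
# subfamilies fall back to their own name.
.subfamily_families <- c(
  "RLTR45-int" = "ERVK", "MMETn-int" = "ERVK", "IAPEz-int" = "ERVK",
  "MTA_Mm-int" = "ERVL", "L1Md_T" = "L1", "B2_Mm2" = "B2"
)
.subfamily_classes <- c(
  "RLTR45-int" = "LTR", "MMETn-int" = "LTR", "IAPEz-int" = "LTR",
  "MTA_Mm-int" = "LTR", "L1Md_T" = "LINE", "B2_Mm2" = "SINE"
)

subfamily_family <- function(subfamily) {
  f <- .subfamily_families[subfamily]
  ifelse(is.na(f), subfamily, f)
}
subfamily_class <- function(subfamily) {
  f <- .subfamily_classes[subfamily]
  ifelse(is.na(f), subfamily, f)
}

# Derive a stage-specific sub-seed from the master seed so that one integer
# reproduces a whole run while stages stay independent.
stage_seed <- function(seed, stage) {
  u <- utf8ToInt(stage)
  h <- sum(u * seq_along(u)) %% 65536
  as.integer((as.numeric(seed) %% 65536) * 32749 + h * 7919) %% 2147483647L
}

#' Simulate a TE and gene annotation with planted ground truth
#'
#' Places non-overlapping TE loci uniformly on the simulated chromosomes,
#' assigns subfamilies, plants a repressed subset of the designated subfamily
#' (per-locus log2 folds drawn around `log2(repression_fold)`), plants
#' enhancer loci among the repressed set, and places one linked gene per
#' enhancer locus with its TSS at a uniform distance in
#' `[5 kb, linkage_window]` on a random side; remaining genes are placed
#' uniformly.
#'
#' @param config A [sim_config()].
#' @return A list with elements `loci` (TE annotation tibble), `genes`
#'   (gene-model tibble), and `truth` (list with `repressed_locus_ids`,
#'   `enhancer_locus_ids`, `linked_pairs`, `te_log2_fold`, `gene_log2_fold`).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "annotation"))
  chroms <- sprintf("chr%d", seq_len(config$n_chrom))
  L <- config$chrom_length

  # exact subfamily counts, largest-remainder on the cumulative rounding
  props <- config$subfamily_proportions
  cum <- round(cumsum(props) * config$n_te)
  n_per <- diff(c(0, cum))
  subfam_pool <- sample(rep(names(props), n_per))

  # spread loci across chromosomes
  per_chrom <- diff(c(0, round(seq_len(config$n_chrom) / config$n_chrom *
                                 config$n_te)))
  loci_list <- vector("list", config$n_chrom)
  offset <- 0L
  for (ci in seq_len(config$n_chrom)) {
    n <- per_chrom[ci]
    if (n == 0) next
    len <- round(stats::runif(n, config$te_length_range[1],
                              config$te_length_range[2]))
    free <- L - sum(len)
    if (free <= n) {
      stop("cannot place ", n, " loci on a chromosome of length ", L,
           "; increase chrom_length")
    }
    gap <- sort(stats::runif(n, 0, free))
    start <- floor(gap) + c(0, cumsum(len))[seq_len(n)]
    loci_list[[ci]] <- tibble::tibble(
      chrom = chroms[ci],
      start = as.integer(start),
      end = as.integer(start + len),
      strand = sample(c("+", "-"), n, replace = TRUE),
      subfamily = subfam_pool[offset + seq_len(n)]
    )
    offset <- offset + n
  }
  loci <- dplyr::bind_rows(loci_list)
  loci$locus_id <- sprintf("te_%05d", seq_len(nrow(loci)))
  loci$family <- subfamily_family(loci$subfamily)
  loci$class_label <- subfamily_class(loci$subfamily)
  loci <- loci[, c("locus_id", "chrom", "start", "end", "strand",
                   "subfamily", "family", "class_label")]

  # planted repression within the designated subfamily
  sub_ids <- loci$locus_id[loci$subfamily == config$repressed_subfamily]
  n_rep <- round(config$frac_repressed * length(sub_ids))
  repressed <- sort(sample(sub_ids, n_rep))
  te_log2_fold <- stats::setNames(numeric(nrow(loci)), loci$locus_id)
  te_log2_fold[repressed] <- pmin(
    0, stats::rnorm(n_rep, log2(config$repression_fold),
                    config$repression_log2_sd))

  # planted enhancers among the repressed loci
  n_enh <- round(config$frac_enhancer * n_rep)
  enhancers <- sort(sample(repressed, n_enh))
  if (n_enh > config$n_genes) {
    stop("n_genes too small for the planted linked genes; increase n_genes")
  }

  # one linked gene per enhancer locus, TSS within [5 kb, linkage_window]
  enh <- loci[match(enhancers, loci$locus_id), ]
  d <- round(stats::runif(n_enh, 5000, config$linkage_window))
  side <- sample(c(-1, 1), n_enh, replace = TRUE)
  tss <- ifelse(side > 0, enh$end + d, enh$start - d)
  flip <- tss < 1000 | tss > L - 25000
  tss[flip] <- ifelse(side[flip] > 0, enh$start[flip] - d[flip],
                      enh$end[flip] + d[flip])
  n_free <- config$n_genes - n_enh
  free_chrom <- sample(chroms, n_free, replace = TRUE)
  free_tss <- round(stats::runif(n_free, 1000, L - 25000))
  genes <- tibble::tibble(
    gene_id = sprintf("gene_%04d", seq_len(config$n_genes)),
    chrom = c(enh$chrom, free_chrom),
    tss = as.integer(c(tss, free_tss)),
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE)
  )
  glen <- round(stats::runif(config$n_genes, 2000, 20000))
  genes$gene_start <- ifelse(genes$strand == "+", genes$tss,
                             genes$tss + 1L - glen)
  genes$gene_end <- ifelse(genes$strand == "+", genes$tss + glen,
                           genes$tss + 1L)
  genes$gene_start <- as.integer(pmax(0, genes$gene_start))
  genes$gene_end <- as.integer(pmin(L, genes$gene_end))

  linked_pairs <- tibble::tibble(
    locus_id = enhancers,
    gene_id = genes$gene_id[seq_len(n_enh)],
    slope = config$linkage_slope
  )
  gene_log2_fold <- stats::setNames(numeric(config$n_genes), genes$gene_id)
  gene_log2_fold[linked_pairs$gene_id] <-
    config$linkage_slope * te_log2_fold[linked_pairs$locus_id]

  list(
    loci = loci,
    genes = genes,
    truth = list(
      repressed_locus_ids = repressed,
      enhancer_locus_ids = enhancers,
      linked_pairs = linked_pairs,
      te_log2_fold = te_log2_fold,
      gene_log2_fold = gene_log2_fold
    )
  )
}

#' Simulate single-embryo RNA-seq counts
#'
#' Draws negative-binomial counts for every TE locus and gene in both
#' conditions. The mean for feature *i* in embryo *s* is
#' `baseline_i * libfactor_s * 2^(log2fold_i)` with the planted fold applied
#' only in SCNT embryos; `libfactor_s` is log-normal (sd
#' `library_log_sd`) so the RLE normalizer has something to estimate.
#'
#' @param sim Result of [simulate_annotation()].
#' @param config The same [sim_config()].
#' @return A list with `counts` (a [count_matrix()] over TE loci then genes)
#'   and `sheet` (sample-sheet tibble).
#' @export
simulate_rnaseq <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "rnaseq"))
  feats <- c(sim$loci$locus_id, sim$genes$gene_id)
  lens <- c(sim$loci$end - sim$loci$start,
            sim$genes$gene_end - sim$genes$gene_start)
  names(lens) <- feats
  nf <- length(feats)
  n <- config$n_embryos_per_condition
  baseline <- stats::rlnorm(nf, config$baseline_log_mean,
                            config$baseline_log_sd)
  baseline <- baseline * config$library_size_mean / sum(baseline)
  lib <- stats::rlnorm(2 * n, 0, config$library_log_sd)
  lfc <- c(sim$truth$te_log2_fold[sim$loci$locus_id],
           sim$truth$gene_log2_fold[sim$genes$gene_id])
  fold <- 2^lfc
  mu <- outer(baseline, lib)
  mu[, n + seq_len(n)] <- mu[, n + seq_len(n)] * fold
  cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                               size = 1 / config$nb_dispersion),
                nrow = nf)
  rownames(cnt) <- feats
  colnames(cnt) <- c(sprintf("IVF_%02d", seq_len(n)),
                     sprintf("SCNT_%02d", seq_len(n)))
  sheet <- tibble::tibble(
    sample_id = colnames(cnt),
    condition = rep(c("IVF", "SCNT"), each = n),
    replicate = rep(seq_len(n), 2)
  )
  list(counts = count_matrix(cnt, lens), sheet = sheet)
}

#' Simulate ChIP and input read counts over bins and TE loci
#'
#' Input counts are Poisson with a length-proportional rate
#' (`chip_depth` reads/bp per replicate); ChIP counts use the same rate
#' multiplied by `chip_enrichment_fold` at planted enhancer loci (and,
#' for bins, in proportion to their overlap with enhancer loci) and 1
#' elsewhere. Two replicates are drawn per track with distinct sub-seeds;
#' replicate depths follow `chip_rep_depth`.
#'
#' @param sim Result of [simulate_annotation()].
#' @param config The same [sim_config()].
#' @param bins Bin grid from [make_bins()] over the simulated chromosomes.
#' @return A list with `bin_counts` (tibble `chrom`, `start`, `end`,
#'   `chip_1`, `chip_2`, `input_1`, `input_2`) and `locus_counts` (tibble
#'   `locus_id`, `length`, same four count columns).
#' @export
simulate_chip <- function(sim, config, bins) {
  stopifnot(inherits(config, "sim_config"))
  width <- bins$end - bins$start
  base_rate <- config$chip_depth * width

  # ChIP rate boost for bins overlapping planted enhancer loci
  boost <- numeric(nrow(bins))
  enh <- sim$loci[sim$loci$locus_id %in% sim$truth$enhancer_locus_ids, ]
  for (i in seq_len(nrow(enh))) {
    on <- which(bins$chrom == enh$chrom[i] &
                  bins$start < enh$end[i] & bins$end > enh$start[i])
    ov <- pmin(bins$end[on], enh$end[i]) - pmax(bins$start[on], enh$start[i])
    boost[on] <- boost[on] + ov * config$chip_depth *
      (config$chip_enrichment_fold - 1)
  }

  len <- sim$loci$end - sim$loci$start
  locus_fold <- ifelse(sim$loci$locus_id %in% sim$truth$enhancer_locus_ids,
                       config$chip_enrichment_fold, 1)
  locus_rate_input <- config$chip_depth * len
  locus_rate_chip <- locus_rate_input * locus_fold

  bin_counts <- tibble::tibble(chrom = bins$chrom, start = bins$start,
                               end = bins$end)
  locus_counts <- tibble::tibble(locus_id = sim$loci$locus_id,
                                 length = as.integer(len))
  for (r in 1:2) {
    depth <- config$chip_rep_depth[r]
    set.seed(stage_seed(config$seed, paste0("chip-rep", r)))
    bin_counts[[paste0("chip_", r)]] <-
      stats::rpois(nrow(bins), depth * (base_rate + boost))
    bin_counts[[paste0("input_", r)]] <-
      stats::rpois(nrow(bins), depth * base_rate)
    locus_counts[[paste0("chip_", r)]] <-
      stats::rpois(nrow(sim$loci), depth * locus_rate_chip)
    locus_counts[[paste0("input_", r)]] <-
      stats::rpois(nrow(sim$loci), depth * locus_rate_input)
  }
  list(bin_counts = bin_counts, locus_counts = locus_counts)
}

#' Simulate RNA-seq counts for a knockout experiment
#'
#' Emulates CRISPR deletion of planted enhancer loci in otherwise wild-type
#' (IVF-derived) embryos. In homozygous-knockout embryos the target loci are
#' silenced (mean scaled by 1e-3) and each linked gene's mean is multiplied
#' by `2^(linkage_slope * te_log2_fold)` of its locus — the full loss of the
#' planted enhancer effect. "Other" embryos (wild-type and heterozygous
#' pooled) keep baseline means.
#'
#' @param sim Result of [simulate_annotation()].
#' @param config The same [sim_config()].
#' @param target_locus_ids Locus ids to delete (must be planted enhancers).
#' @param n_hom,n_other Embryos per genotype group.
#' @return A list with `counts` (a [count_matrix()]) and `sheet` (tibble with
#'   `sample_id`, `condition`, `genotype_true`).
#' @export
simulate_ko <- function(sim, config, target_locus_ids,
                        n_hom = 5, n_other = 5) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(target_locus_ids %in% sim$truth$enhancer_locus_ids)) {
    stop("target loci must be planted enhancer loci")
  }
  set.seed(stage_seed(config$seed, "ko"))
  feats <- c(sim$loci$locus_id, sim$genes$gene_id)
  lens <- c(sim$loci$end - sim$loci$start,
            sim$genes$gene_end - sim$genes$gene_start)
  names(lens) <- feats
  nf <- length(feats)
  baseline <- stats::rlnorm(nf, config$baseline_log_mean,
                            config$baseline_log_sd)
  baseline <- baseline * config$library_size_mean / sum(baseline)
  names(baseline) <- feats

  pairs <- sim$truth$linked_pairs
  hit_genes <- pairs$gene_id[pairs$locus_id %in% target_locus_ids]
  ko_fold <- stats::setNames(rep(1, nf), feats)
  ko_fold[target_locus_ids] <- 1e-3
  ko_fold[hit_genes] <- 2^(sim$truth$gene_log2_fold[hit_genes])

  n_tot <- n_hom + n_other
  lib <- stats::rlnorm(n_tot, 0, config$library_log_sd)
  mu <- outer(baseline, lib)
  mu[, seq_len(n_hom)] <- mu[, seq_len(n_hom)] * ko_fold
  cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                               size = 1 / config$nb_dispersion),
                nrow = nf)
  rownames(cnt) <- feats
  colnames(cnt) <- sprintf("KO_%02d", seq_len(n_tot))
  sheet <- tibble::tibble(
    sample_id = colnames(cnt),
    condition = "KO_treated",
    genotype_true = rep(c("hom_ko", "other"), c(n_hom, n_other))
  )
  list(counts = count_matrix(cnt, lens), sheet = sheet)
}

#' Write a simulated data set to a directory
#'
#' Emits the same formats the readers consume: `te.bed` (BED6+3),
#' `genes.tsv`, `counts.tsv`, `sheet.tsv`, `truth.tsv`, and the ChIP tables
#' `chip_loci.tsv` / `chip_bins.tsv` when provided.
#'
#' @param sim Result of [simulate_annotation()].
#' @param rna Result of [simulate_rnaseq()].
#' @param dir Output directory (created if needed).
#' @param chip Optional result of [simulate_chip()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, rna, dir, chip = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_te_bed(sim$loci, file.path(dir, "te.bed"))
  write_gene_table(sim$genes, file.path(dir, "genes.tsv"))
  write_count_matrix(rna$counts, file.path(dir, "counts.tsv"))
  utils::write.table(rna$sheet, file.path(dir, "sheet.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- truth_table(sim)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(chip)) {
    utils::write.table(chip$locus_counts, file.path(dir, "chip_loci.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(chip$bin_counts, file.path(dir, "chip_bins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

# Flatten ground truth into one TSV-able table.
truth_table <- function(sim) {
  pairs <- sim$truth$linked_pairs
  linked_locus <- stats::setNames(pairs$locus_id, pairs$gene_id)
  tibble::tibble(
    feature_id = c(sim$loci$locus_id, sim$genes$gene_id),
    type = rep(c("te", "gene"), c(nrow(sim$loci), nrow(sim$genes))),
    log2_fold = c(sim$truth$te_log2_fold[sim$loci$locus_id],
                  sim$truth$gene_log2_fold[sim$genes$gene_id]),
    repressed = c(sim$loci$locus_id %in% sim$truth$repressed_locus_ids,
                  rep(FALSE, nrow(sim$genes))),
    enhancer = c(sim$loci$locus_id %in% sim$truth$enhancer_locus_ids,
                 rep(FALSE, nrow(sim$genes))),
    linked_locus = c(rep(NA_character_, nrow(sim$loci)),
                     unname(linked_locus[sim$genes$gene_id]))
  )
}

# Rebuild the truth list from a truth.tsv written by write_simulation().
read_truth_table <- function(path, slope) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  te <- df[df$type == "te", ]
  gene <- df[df$type == "gene", ]
  linked <- gene[!is.na(gene$linked_locus), ]
  list(
    repressed_locus_ids = te$feature_id[te$repressed],
    enhancer_locus_ids = te$feature_id[te$enhancer],
    linked_pairs = tibble::tibble(locus_id = linked$linked_locus,
                                  gene_id = linked$feature_id,
                                  slope = slope),
    te_log2_fold = stats::setNames(te$log2_fold, te$feature_id),
    gene_log2_fold = stats::setNames(gene$log2_fold, gene$feature_id)
  )
}
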