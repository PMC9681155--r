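#' Pipeline run configuration
#'
#' Gathers every analysis threshold (with the published defaults), the
#' simulation configuration, and the output directory. The same `RunConfig`
#' drives both the simulate path and the load path (re-running on the
#' emitted TSVs).
#'
#' @param sim A [sim_config()] describing the synthetic data (also supplies
#'   the master seed and, on the load path, the stage sub-seeds).
#' @param inputs Optional directory containing a data set previously written
#'   by [run_pipeline()] (files `te.bed`, `genes.tsv`, `counts.tsv`,
#'   `sheet.tsv`, `truth.tsv`, `chip_loci.tsv`, `chip_bins.tsv`). When
#'   `NULL` the data are simulated from `sim`.
#' @param out_dir Output directory for TSVs, `report.json` and the log.
#' @param log2fc_cut,padj_cut Differential thresholds (|log2 ratio| >= 1,
#'   adjusted p < 0.1).
#' @param enhancer_cut Enhancer-like threshold on log2 ChIP/input (1.5).
#' @param expressed_mean Expressed filter: mean reads per embryo (1).
#' @param ko_tpm_cut Homozygous-KO call threshold (TPM < 5).
#' @param pseudocount Pseudocount for all expression/enrichment ratios (0.5).
#' @param proximal_window,distal_window TSS-distance windows in bp.
#' @param run_ko Whether to run the knockout-validation stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       inputs = NULL,
                       out_dir = tempfile("ervscan_run_"),
                       log2fc_cut = 1,
                       padj_cut = 0.1,
                       enhancer_cut = 1.5,
                       expressed_mean = 1,
                       ko_tpm_cut = 5,
                       pseudocount = 0.5,
                       proximal_window = c(5000, 50000),
                       distal_window = c(50000, 200000),
                       run_ko = TRUE) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$log2fc_cut > 0, cfg$padj_cut > 0, cfg$enhancer_cut > 0,
    cfg$expressed_mean > 0, cfg$ko_tpm_cut > 0,
    cfg$proximal_window[1] < cfg$proximal_window[2],
    cfg$proximal_window[2] == cfg$distal_window[1],
    cfg$distal_window[1] < cfg$distal_window[2]
  )
  structure(cfg, class = "run_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the end-to-end analysis
#'
#' Orchestrates simulate/load, quantification, differential classification,
#' ChIP enrichment and enhancer-like classification, nearby-gene linkage
#' with ratio correlation, and the knockout-validation stage. Writes
#' `diff.tsv`, `enrichment.tsv`, `linkage.tsv`, `composition.tsv`, `ko.tsv`,
#' a reusable copy of the inputs, `report.json` and `log.txt` into
#' `cfg$out_dir`. Two runs under the same configuration produce
#' byte-identical reports; re-running on the emitted input TSVs reproduces
#' all downstream numbers exactly.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `report` (the report structure),
#'   `diff`, `enrichment`, `pairs`, `composition`, `tpm`, `sim`, and
#'   `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$sim$seed

  # ---- data: simulate or load -------------------------------------------
  dat <- run_stage("data", {
    if (is.null(cfg$inputs)) {
      sim <- simulate_annotation(cfg$sim)
      rna <- simulate_rnaseq(sim, cfg$sim)
      sizes <- stats::setNames(rep(cfg$sim$chrom_length, cfg$sim$n_chrom),
                               sprintf("chr%d", seq_len(cfg$sim$n_chrom)))
      bins <- make_bins(sizes)
      chip <- simulate_chip(sim, cfg$sim, bins)
      list(sim = sim, rna = rna, chip = chip)
    } else {
      loci <- read_te_annotation(file.path(cfg$inputs, "te.bed"),
                                 dialect = "bed6+3")
      genes <- read_gene_table(file.path(cfg$inputs, "genes.tsv"))
      counts <- read_count_matrix(file.path(cfg$inputs, "counts.tsv"))
      sheet <- read_sample_sheet(file.path(cfg$inputs, "sheet.tsv"))
      truth <- read_truth_table(file.path(cfg$inputs, "truth.tsv"),
                                slope = cfg$sim$linkage_slope)
      chip <- list(
        locus_counts = tibble::as_tibble(utils::read.delim(
          file.path(cfg$inputs, "chip_loci.tsv"))),
        bin_counts = tibble::as_tibble(utils::read.delim(
          file.path(cfg$inputs, "chip_bins.tsv")))
      )
      list(sim = list(loci = loci, genes = genes, truth = truth),
           rna = list(counts = counts, sheet = sheet), chip = chip)
    }
  })
  sim <- dat$sim
  sim$loci <- filter_autosomes(sim$loci)
  sim$genes <- filter_autosomes(sim$genes)
  rna <- dat$rna
  chip <- dat$chip

  # ---- quantify ----------------------------------------------------------
  q <- run_stage("quantify", {
    expressed <- filter_expressed(rna$counts, cfg$expressed_mean)
    factors <- rle_size_factors(expressed)
    tpm <- compute_tpm(expressed)
    list(expressed = expressed, factors = factors, tpm = tpm)
  })

  # ---- differential ------------------------------------------------------
  diff <- run_stage("differential", {
    d <- nb_wald_test(rna$counts, rna$sheet, size_factors = q$factors,
                      pseudocount = cfg$pseudocount,
                      expressed_min_mean = cfg$expressed_mean)
    classify_differential(d, log2fc_cut = cfg$log2fc_cut,
                          padj_cut = cfg$padj_cut)
  })
  te_diff <- diff[diff$feature_id %in% sim$loci$locus_id, ]
  composition <- run_stage("differential", {
    dplyr::bind_rows(
      composition_summary(diff, sim$loci, level = "family"),
      composition_summary(diff, sim$loci, level = "subfamily")
    )
  })

  # ---- enrichment --------------------------------------------------------
  enr <- run_stage("enrichment", {
    n_loci <- nrow(chip$locus_counts)
    merge_track <- function(track) {
      reps <- lapply(1:2, function(r) {
        c(chip$locus_counts[[paste0(track, "_", r)]],
          chip$bin_counts[[paste0(track, "_", r)]])
      })
      ds <- downsample_to_match(
        reps, seed = stage_seed(seed, paste0("downsample_", track)))
      list(locus = ds$merged[seq_len(n_loci)],
           bin = ds$merged[-seq_len(n_loci)])
    }
    chip_m <- merge_track("chip")
    input_m <- merge_track("input")
    lc <- tibble::tibble(
      locus_id = chip$locus_counts$locus_id,
      length = chip$locus_counts$length,
      chip = chip_m$locus, input = input_m$locus
    )
    rec <- te_enrichment(lc, chip_bin_total = sum(chip_m$bin),
                         input_bin_total = sum(input_m$bin),
                         mark = "H3K27ac", stage = "morula",
                         threshold = cfg$enhancer_cut)
    rec
  })

  ervk_ids <- sim$loci$locus_id[sim$loci$family == "ERVK"]
  expressed_ervk <- intersect(
    ervk_ids, te_diff$feature_id[te_diff$klass != "untested"])
  scnt_low_ids <- te_diff$feature_id[te_diff$klass == "SCNT_low"]
  enhancer_ids <- enr$locus_id[enr$enhancer_like]
  fisher <- run_stage("enrichment", {
    if (length(expressed_ervk) > 0) {
      overlap_fisher(intersect(scnt_low_ids, expressed_ervk),
                     intersect(enhancer_ids, expressed_ervk),
                     expressed_ervk)
    } else NULL
  })
  mean_planted_enrichment <- if (length(sim$truth$enhancer_locus_ids)) {
    mean(enr$log2_enrichment[enr$locus_id %in% sim$truth$enhancer_locus_ids])
  } else NA_real_

  # ---- linkage -----------------------------------------------------------
  link <- run_stage("linkage", {
    subset_ids <- intersect(intersect(scnt_low_ids, ervk_ids),
                            rownames(q$tpm))
    subset_loci <- sim$loci[sim$loci$locus_id %in% subset_ids, ]
    pairs <- link_nearby_genes(subset_loci, sim$genes,
                               proximal = cfg$proximal_window,
                               distal = cfg$distal_window)
    pairs <- pairs[pairs$gene_id %in% rownames(q$tpm), ]
    if (nrow(pairs)) {
      pairs$te_log2_ratio <- unname(condition_log2_ratio(
        q$tpm, rna$sheet, pairs$locus_id, pseudocount = cfg$pseudocount))
      pairs$gene_log2_ratio <- unname(condition_log2_ratio(
        q$tpm, rna$sheet, pairs$gene_id, pseudocount = cfg$pseudocount))
    } else {
      pairs$te_log2_ratio <- numeric(0)
      pairs$gene_log2_ratio <- numeric(0)
    }
    pairs
  })
  safe_spearman <- function(x, y) {
    tryCatch(spearman_cor(x, y),
             error = function(e) list(rho = NA_real_, p = NA_real_,
                                      n = length(x), slope = NA_real_,
                                      intercept = NA_real_))
  }
  link_cor <- list(pooled = safe_spearman(link$te_log2_ratio,
                                          link$gene_log2_ratio))
  for (w in unique(link$window)) {
    sel <- link$window == w
    link_cor[[w]] <- safe_spearman(link$te_log2_ratio[sel],
                                   link$gene_log2_ratio[sel])
  }
  planted <- sim$truth$linked_pairs
  planted <- planted[planted$locus_id %in% rownames(q$tpm) &
                       planted$gene_id %in% rownames(q$tpm), ]
  planted_cor <- if (nrow(planted) >= 3) {
    safe_spearman(
      unname(condition_log2_ratio(q$tpm, rna$sheet, planted$locus_id,
                                  pseudocount = cfg$pseudocount)),
      unname(condition_log2_ratio(q$tpm, rna$sheet, planted$gene_id,
                                  pseudocount = cfg$pseudocount))
    )
  } else list(rho = NA_real_, p = NA_real_, n = nrow(planted))

  # ---- knockout validation ----------------------------------------------
  ko_res <- NULL
  ko_table <- NULL
  if (isTRUE(cfg$run_ko) && length(sim$truth$enhancer_locus_ids) >= 2) {
    ko_res <- run_stage("ko", {
      fold <- sim$truth$te_log2_fold[sim$truth$enhancer_locus_ids]
      targets <- names(sort(fold))[1:2]
      ko <- simulate_ko(sim, cfg$sim, targets)
      ko_tpm <- compute_tpm(ko$counts)
      calls <- call_homozygous_ko(ko_tpm, targets, tpm_cut = cfg$ko_tpm_cut)
      # expressed genes within 2 Mb of either target locus
      tloci <- sim$loci[match(targets, sim$loci$locus_id), ]
      near <- unique(unlist(lapply(seq_len(2), function(i) {
        g <- sim$genes
        g$gene_id[g$chrom == tloci$chrom[i] &
                    abs(g$tss - (tloci$start[i] + tloci$end[i]) / 2) <= 2e6]
      })))
      near <- intersect(near, rownames(ko_tpm))
      near <- near[rowMeans(ko_tpm[near, , drop = FALSE]) >= 1]
      cmp <- compare_adjacent_genes(ko_tpm, calls, near,
                                    pseudocount = cfg$pseudocount)
      shared <- intersect(near, rownames(q$tpm))
      cor_ks <- if (length(shared) >= 3) {
        scnt_r <- condition_log2_ratio(q$tpm, rna$sheet, shared,
                                       pseudocount = cfg$pseudocount)
        ko_r <- cmp$log2_ratio[match(shared, cmp$gene_id)]
        safe_spearman(ko_r, unname(scnt_r))
      } else list(rho = NA_real_, p = NA_real_, n = length(shared))
      set.seed(stage_seed(seed, "mendelian"))
      gcounts <- as.vector(stats::rmultinom(1, 32, c(0.25, 0.5, 0.25)))
      mend <- mendelian_chisq(gcounts[1], gcounts[2], gcounts[3])
      list(targets = targets, calls = calls, adjacent = cmp,
           ko_scnt_cor = cor_ks, genotype_counts = gcounts, mendelian = mend)
    })
    ko_table <- ko_res$adjacent
  }

  # ---- report and outputs ------------------------------------------------
  pct <- function(n, total) {
    list(n = n, total = total,
         fraction = if (total > 0) n / total else NA_real_,
         percent = round_percent(n, total))
  }
  n_expressed <- sum(te_diff$klass != "untested")
  n_low <- sum(te_diff$klass == "SCNT_low")
  n_high <- sum(te_diff$klass == "SCNT_high")
  low_ervk <- intersect(scnt_low_ids, ervk_ids)
  low_ervk_enh <- intersect(low_ervk, enhancer_ids)
  rltr_ids <- sim$loci$locus_id[sim$loci$subfamily == cfg$sim$repressed_subfamily]
  low_rltr <- intersect(scnt_low_ids, rltr_ids)
  low_rltr_enh <- intersect(low_rltr, enhancer_ids)

  cor_entry <- function(cc) list(rho = cc$rho, p = cc$p, n = cc$n)
  report <- list(
    seed = seed,
    thresholds = list(
      log2fc_cut = cfg$log2fc_cut, padj_cut = cfg$padj_cut,
      enhancer_cut = cfg$enhancer_cut, expressed_mean = cfg$expressed_mean,
      ko_tpm_cut = cfg$ko_tpm_cut, pseudocount = cfg$pseudocount,
      proximal_window = cfg$proximal_window,
      distal_window = cfg$distal_window
    ),
    differential = list(
      n_te_expressed = n_expressed,
      n_scnt_low = n_low,
      n_scnt_high = n_high,
      ervk_of_expressed = pct(length(expressed_ervk), n_expressed),
      ervk_of_scnt_low = pct(length(low_ervk), n_low)
    ),
    composition = as.list(stats::setNames(
      lapply(seq_len(nrow(composition)), function(i) {
        as.list(composition[i, c("n", "total", "percent")])
      }),
      paste(composition$stratum, composition$label, sep = ":"))),
    enrichment = list(
      n_enhancer_like = length(enhancer_ids),
      enhancer_of_scnt_low_ervk = pct(length(low_ervk_enh),
                                      length(low_ervk)),
      enhancer_of_scnt_low_rltr45 = pct(length(low_rltr_enh),
                                        length(low_rltr)),
      fisher_odds_ratio = if (!is.null(fisher)) fisher$odds_ratio else NA,
      fisher_p = if (!is.null(fisher)) fisher$p else NA,
      mean_planted_enrichment = mean_planted_enrichment
    ),
    linkage = c(
      list(n_pairs = nrow(link)),
      lapply(link_cor, cor_entry),
      list(planted = cor_entry(planted_cor))
    ),
    ko = if (!is.null(ko_res)) list(
      targets = ko_res$targets,
      n_hom_called = sum(ko_res$calls$genotype == "hom_ko"),
      n_adjacent_genes = nrow(ko_res$adjacent),
      frac_adjacent_down = mean(ko_res$adjacent$log2_ratio < 0),
      ko_scnt_cor = cor_entry(ko_res$ko_scnt_cor),
      genotype_counts = ko_res$genotype_counts,
      mendelian_chi2 = ko_res$mendelian$chi2,
      mendelian_p = ko_res$mendelian$p
    ) else NULL
  )

  out <- cfg$out_dir
  wt <- function(df, f) utils::write.table(
    df, file.path(out, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(diff, "diff.tsv")
  wt(enr, "enrichment.tsv")
  wt(link, "linkage.tsv")
  wt(composition, "composition.tsv")
  if (!is.null(ko_table)) wt(ko_table, "ko.tsv")
  if (is.null(cfg$inputs)) {
    write_simulation(sim, rna, file.path(out, "inputs"), chip = chip)
  }
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  writeLines(c(
    paste("ervscan version:", as.character(utils::packageVersion("ervscan"))),
    paste("R version:", R.version.string),
    paste("seed:", seed),
    paste("run time (UTC): <not recorded; report is content-addressed>")
  ), file.path(out, "log.txt"))

  invisible(list(report = report, diff = diff, enrichment = enr,
                 pairs = link, composition = composition, tpm = q$tpm,
                 factors = q$factors, sim = sim, ko = ko_res,
                 out_dir = out))
}
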