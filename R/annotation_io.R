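#' Read a TE locus annotation
#'
#' Parses a repeat annotation into a tibble of TE loci, one row per locus,
#' with 0-based half-open coordinates. Two dialects are supported:
#'
#' * `"bed6+3"` — BED with either 6 columns (column 4 holding
#'   `subfamily:family:class`) or 9+ columns (column 4 a locus id, columns
#'   7-9 subfamily, family, class). BED coordinates are taken as-is.
#' * `"repeatmasker_out"` — a RepeatMasker `.out` file (3 header lines,
#'   whitespace-separated fields). The 1-based inclusive begin position is
#'   converted to 0-based by `begin - 1`; the `class/family` field is split
#'   into `class_label` and `family`; strand `C` becomes `-`.
#'
#' When the input carries no explicit locus id one is derived as
#' `chrom:start-end|subfamily`.
#'
#' @param path Path to the annotation file.
#' @param dialect One of `"bed6+3"` or `"repeatmasker_out"`.
#' @return A tibble with columns `locus_id`, `chrom`, `start`, `end`,
#'   `strand`, `subfamily`, `family`, `class_label`.
#' @export
read_te_annotation <- function(path, dialect = c("bed6+3", "repeatmasker_out")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "repeatmasker_out") {
    # drop header lines: records start with an integer Smith-Waterman score
    is_header <- !grepl("^[0-9]", trimws(lines)) & seq_along(lines) <= 3
    lines <- lines[!is_header]
  }
  if (length(lines) == 0L) {
    warning("empty annotation file: ", path)
    return(empty_te_annotation())
  }
  recs <- if (dialect == "bed6+3") {
    parse_bed_te(lines)
  } else {
    parse_repeatmasker_out(lines)
  }
  validate_te_annotation(recs)
  recs
}

empty_te_annotation <- function() {
  tibble::tibble(
    locus_id = character(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    subfamily = character(), family = character(), class_label = character()
  )
}

parse_bed_te <- function(lines) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop("malformed BED line (fewer than 6 fields) at line ",
         which(nf < 6L)[1])
  }
  get <- function(i) vapply(fields, `[`, character(1), i)
  chrom <- get(1)
  start <- parse_int_col(get(2), "start")
  end <- parse_int_col(get(3), "end")
  name <- get(4)
  strand <- get(6)
  if (all(nf >= 9L)) {
    locus_id <- name
    subfamily <- get(7)
    family <- get(8)
    class_label <- get(9)
  } else {
    toks <- strsplit(name, ":", fixed = TRUE)
    subfamily <- vapply(toks, function(x) x[1], character(1))
    family <- vapply(toks, function(x) if (length(x) >= 2) x[2] else x[1],
                     character(1))
    class_label <- vapply(toks, function(x) if (length(x) >= 3) x[3] else "",
                          character(1))
    locus_id <- sprintf("%s:%d-%d|%s", chrom, start, end, subfamily)
  }
  tibble::tibble(locus_id, chrom, start, end, strand,
                 subfamily, family, class_label)
}

parse_repeatmasker_out <- function(lines) {
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop("malformed RepeatMasker record (fewer than 11 fields) at line ",
         which(nf < 11L)[1])
  }
  get <- function(i) vapply(fields, `[`, character(1), i)
  chrom <- get(5)
  begin <- parse_int_col(get(6), "begin")
  end <- parse_int_col(get(7), "end")
  strand <- ifelse(get(9) == "C", "-", get(9))
  subfamily <- get(10)
  clsfam <- strsplit(get(11), "/", fixed = TRUE)
  class_label <- vapply(clsfam, function(x) x[1], character(1))
  family <- vapply(clsfam, function(x) if (length(x) >= 2) x[2] else x[1],
                   character(1))
  start <- begin - 1L
  tibble::tibble(
    locus_id = sprintf("%s:%d-%d|%s", chrom, start, end, subfamily),
    chrom, start, end, strand, subfamily, family, class_label
  )
}

parse_int_col <- function(x, what) {
  v <- suppressWarnings(as.integer(x))
  if (anyNA(v)) {
    stop("non-integer ", what, " at line ", which(is.na(v))[1])
  }
  v
}

validate_te_annotation <- function(recs) {
  bad <- which(recs$end <= recs$start)
  if (length(bad)) {
    stop("end <= start for locus at record ", bad[1],
         " (", recs$locus_id[bad[1]], ")")
  }
  if (anyDuplicated(recs$locus_id)) {
    stop("duplicated locus_id: ",
         recs$locus_id[anyDuplicated(recs$locus_id)])
  }
  if (any(!nzchar(recs$subfamily))) {
    stop("empty subfamily label at record ", which(!nzchar(recs$subfamily))[1])
  }
  invisible(recs)
}

#' Write a TE locus annotation as BED6+3
#'
#' @param loci Tibble as returned by [read_te_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_te_bed <- function(loci, path) {
  df <- data.frame(
    loci$chrom, loci$start, loci$end, loci$locus_id, 0L, loci$strand,
    loci$subfamily, loci$family, loci$class_label
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Drop features on sex chromosomes
#'
#' Removes rows whose `chrom` is one of `chrX`, `X`, `chrY`, `Y`
#' (case-sensitive), keeping all other rows in input order. Applied before
#' any group comparison because IVF embryo pools mix sexes while SCNT embryos
#' share the donor's sex, so X/Y dosage differs systematically between
#' conditions.
#'
#' @param x A data frame with a `chrom` column (TE loci or gene models).
#' @return The same type of data frame, autosomal rows only.
#' @export
filter_autosomes <- function(x) {
  stopifnot("chrom" %in% names(x))
  x[!(x$chrom %in% c("chrX", "X", "chrY", "Y")), , drop = FALSE]
}

#' Read or write a minimal gene table
#'
#' The gene table is a TSV with columns `gene_id`, `chrom`, `tss`, `strand`,
#' `gene_start`, `gene_end` (0-based half-open body, `tss` 0-based). The TSS
#' must lie inside the gene body.
#'
#' @param path File path.
#' @return A tibble of gene models.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand", "gene_start", "gene_end")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("gene table missing columns: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("duplicated gene_id")
  bad <- which(!(df$gene_start <= df$tss & df$tss < df$gene_end))
  if (length(bad)) {
    stop("TSS outside gene body for ", df$gene_id[bad[1]])
  }
  tibble::as_tibble(df[need])
}

#' @rdname read_gene_table
#' @param genes Tibble of gene models.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `condition`, `replicate`. Sample ids must be
#' unique; conditions are free strings (typically `IVF`, `SCNT`,
#' `KO_treated`).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "replicate")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("sample sheet missing columns: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id")
  tibble::as_tibble(df[need])
}

#' Construct a validated count matrix
#'
#' The container for features-by-samples integer counts plus per-feature
#' lengths (bp), used by every quantification and testing step.
#'
#' @param counts Integer matrix, features in rows (named), samples in columns
#'   (named). All cells must be non-negative integers.
#' @param lengths Numeric vector of feature lengths in bp, named by feature or
#'   in row order.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `lengths`.
#' @export
count_matrix <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) ||
      (nrow(counts) > 0 && is.null(rownames(counts)))) {
    stop("counts must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicated feature id: ",
         rownames(counts)[anyDuplicated(rownames(counts))])
  }
  bad <- which(!is.finite(counts) | counts < 0 |
                 abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-integer or negative count at feature '",
         rownames(counts)[bad[1, 1]], "', sample '",
         colnames(counts)[bad[1, 2]], "'")
  }
  storage.mode(counts) <- "double"
  counts <- round(counts)
  if (!is.null(names(lengths))) {
    if (!all(rownames(counts) %in% names(lengths))) {
      stop("lengths missing for some features")
    }
    lengths <- lengths[rownames(counts)]
  } else {
    if (length(lengths) != nrow(counts)) stop("lengths/feature mismatch")
    names(lengths) <- rownames(counts)
  }
  if (any(lengths <= 0)) stop("feature lengths must be > 0")
  structure(list(counts = counts, lengths = lengths), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x",
      ncol(x$counts), "samples\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix from TSV
#'
#' Expected layout: header row; first column `feature_id`, second column
#' `length` (bp), remaining columns one per sample.
#'
#' @param path File path.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, fill = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("count matrix needs feature_id, length, >=1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicated feature id: ", ids[anyDuplicated(ids)])
  }
  lengths <- df[[2]]
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- ids
  names(lengths) <- ids
  count_matrix(m, lengths)
}

#' Write a count matrix as TSV
#'
#' Inverse of [read_count_matrix()]; a write/read round trip reproduces the
#' counts exactly.
#'
#' @param m A [count_matrix()].
#' @param path Output path.
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(feature_id = rownames(m$counts),
                   length = as.integer(m$lengths),
                   m$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
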