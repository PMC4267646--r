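# All coordinates in the package are 0-based, half-open (BED-native).
# 1-based formats (GTF, IRanges) are converted at the boundary.

NARROWPEAK_FIELDS <- c("chrom", "start", "end", "name", "score", "strand",
                       "signal_value", "pvalue_log10", "qvalue_log10",
                       "peak_offset")

#' Read an ENCODE narrowPeak (BED6+4) file
#'
#' Parses a tab-separated narrowPeak file into a peak table. The summit is
#' resolved to an absolute 0-based coordinate (`start + peak_offset`); a
#' peak offset of -1 (callers that do not report summits) falls back to the
#' floor midpoint of the interval. `fold_enrichment` is taken from the
#' signalValue column, which MACS2 fills with fold enrichment over the
#' input sample; `qvalue` is recovered from the -log10 qValue column.
#'
#' @param path Path to a narrowPeak file. `track`/`browser`/comment lines
#'   are skipped.
#' @return A data.frame with one row per peak and columns `chrom`, `start`,
#'   `end` (0-based half-open), `name`, `score`, `strand`,
#'   `fold_enrichment`, `pvalue_log10`, `qvalue_log10`, `summit`
#'   (absolute bp) and `qvalue` (10^-qvalue_log10; `NA` when the column
#'   is -1).
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) stop("narrowPeak file not found: ", path)
  raw <- readLines(path)
  keep <- nzchar(trimws(raw)) & !grepl("^(track|browser|#)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) return(empty_peak_table())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 10L)) {
    bad <- which(nf != 10L)[1L]
    stop(sprintf(
      "malformed narrowPeak record at line %d: expected 10 tab-separated fields, found %d",
      lineno[bad], nf[bad]))
  }
  m <- matrix(unlist(fields, use.names = FALSE), ncol = 10L, byrow = TRUE)

  num <- function(j) suppressWarnings(as.numeric(m[, j]))
  start <- num(2); end <- num(3)
  fe <- num(7); plog <- num(8); qlog <- num(9); offset <- num(10)
  for (j in c(2, 3, 7, 8, 9, 10)) {
    v <- num(j)
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("malformed narrowPeak record at line %d: non-numeric '%s' in column %d",
                   lineno[bad], m[bad, j], j))
    }
  }
  if (any(start < 0) || any(start >= end)) {
    bad <- which(start < 0 | start >= end)[1L]
    stop(sprintf("invalid interval at line %d: start=%s end=%s",
                 lineno[bad], m[bad, 2], m[bad, 3]))
  }
  width <- end - start
  if (any(offset >= width)) {
    bad <- which(offset >= width)[1L]
    stop(sprintf("summit offset >= peak width at line %d (offset %s, width %d)",
                 lineno[bad], m[bad, 10], as.integer(width[bad])))
  }
  if (any(fe <= 0)) {
    bad <- which(fe <= 0)[1L]
    stop(sprintf("fold enrichment must be > 0 at line %d (found %s)",
                 lineno[bad], m[bad, 7]))
  }
  summit <- ifelse(offset < 0, start + floor(width / 2), start + offset)
  data.frame(
    chrom = m[, 1], start = start, end = end, name = m[, 4],
    score = num(5), strand = m[, 6], fold_enrichment = fe,
    pvalue_log10 = plog, qvalue_log10 = qlog, summit = summit,
    qvalue = ifelse(qlog < 0, NA_real_, 10^(-qlog)),
    stringsAsFactors = FALSE)
}

empty_peak_table <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             name = character(0), score = numeric(0), strand = character(0),
             fold_enrichment = numeric(0), pvalue_log10 = numeric(0),
             qvalue_log10 = numeric(0), summit = numeric(0),
             qvalue = numeric(0), stringsAsFactors = FALSE)
}

# reversible decimal formatting for round-tripping peak files
fmt_num <- function(x) formatC(x, format = "g", digits = 15, width = 1)

#' Write a peak table as ENCODE narrowPeak
#'
#' Inverse of [read_narrowpeak()]: `read(write(x))` reproduces `x` on all
#' retained fields. The summit is written back as a relative peak offset.
#'
#' @param peaks Peak data.frame as returned by [read_narrowpeak()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  validate_peak_table(peaks)
  if (nrow(peaks) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- paste(peaks$chrom, fmt_num(peaks$start), fmt_num(peaks$end),
                 peaks$name, fmt_num(peaks$score), peaks$strand,
                 fmt_num(peaks$fold_enrichment), fmt_num(peaks$pvalue_log10),
                 fmt_num(peaks$qvalue_log10),
                 fmt_num(peaks$summit - peaks$start),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

validate_peak_table <- function(peaks) {
  need <- c("chrom", "start", "end", "name", "score", "strand",
            "fold_enrichment", "pvalue_log10", "qvalue_log10", "summit")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stop("peak table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(peaks)) {
    stopifnot(all(peaks$start < peaks$end),
              all(peaks$summit >= peaks$start),
              all(peaks$summit < peaks$end),
              all(peaks$fold_enrichment > 0))
  }
  invisible(peaks)
}

#' Read a gene annotation (TSV or GTF/GFF)
#'
#' A gene annotation holds, per gene, the chromosome, strand and
#' transcription start site (TSS) used for peak-to-gene distance
#' calculations. Plain tables must be tab-separated with columns
#' `gene_id`, `chrom`, `strand` and `tss` (0-based). For GTF/GFF input the
#' `gene` features are extracted and the TSS is the feature start on the
#' plus strand and the feature end on the minus strand, converted to
#' 0-based coordinates.
#'
#' @param path Path to a TSV, GTF or GFF file (GTF/GFF detected by
#'   extension).
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `tss`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (grepl("\\.(gtf|gff3?|gff)(\\.gz)?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    if ("type" %in% names(S4Vectors::mcols(gr))) {
      gr <- gr[as.character(gr$type) == "gene"]
    }
    if (length(gr) == 0L) stop("no gene features found in ", path)
    strand <- as.character(GenomicRanges::strand(gr))
    ann <- data.frame(
      gene_id = as.character(gr$gene_id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = strand,
      tss = ifelse(strand == "+",
                   GenomicRanges::start(gr) - 1L,
                   GenomicRanges::end(gr) - 1L),
      stringsAsFactors = FALSE)
  } else {
    ann <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "tss")
    miss <- setdiff(need, names(ann))
    if (length(miss)) stop("annotation lacks columns: ", paste(miss, collapse = ", "))
    ann <- ann[, need]
  }
  if (!all(ann$strand %in% c("+", "-"))) {
    bad <- unique(ann$strand[!ann$strand %in% c("+", "-")])
    stop("unknown strand symbol(s): ", paste(bad, collapse = ", "))
  }
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup)) stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "))
  if (any(ann$tss < 0)) stop("negative TSS coordinate")
  rownames(ann) <- NULL
  ann
}

#' Write a gene annotation table
#'
#' @param annotation data.frame as returned by [read_gene_annotation()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pseudo-count log2 fold change
#'
#' Recalculates log2 fold changes after adding a pseudo-count (default
#' 0.1 FPKM) to both conditions, which tames unrealistically large ratios
#' for genes with near-zero expression in one condition and makes the
#' fold change of a (0, 0) pair exactly zero.
#'
#' @param treated,control Non-negative expression values (FPKM).
#' @param pseudo Pseudo-count added to both values; default 0.1.
#' @return `log2((treated + pseudo) / (control + pseudo))`.
#' @export
compute_log2fc <- function(treated, control, pseudo = 0.1) {
  stopifnot(pseudo >= 0)
  if (any(treated < 0) || any(control < 0)) stop("negative expression value")
  log2((treated + pseudo) / (control + pseudo))
}

#' Read a time-course expression table
#'
#' Expects a tab-separated table with columns `gene_id`, `time_h`,
#' `fpkm_control`, `fpkm_treated` and `qvalue` (the per-time-point FDR of
#' the upstream differential test). The log2 fold change is always
#' recomputed with the pseudo-count rule of [compute_log2fc()], replacing
#' any `log2fc` column present in the file. A sparse table (genes missing
#' some time points) is allowed.
#'
#' @param path Path to the TSV file.
#' @param pseudo Pseudo-count in FPKM units; default 0.1.
#' @return data.frame with columns `gene_id`, `time_h`, `fpkm_control`,
#'   `fpkm_treated`, `qvalue`, `log2fc`.
#' @export
read_expression_table <- function(path, pseudo = 0.1) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "time_h", "fpkm_control", "fpkm_treated", "qvalue")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("expression table lacks columns: ", paste(miss, collapse = ", "))
  x <- x[, need]
  for (col in c("time_h", "fpkm_control", "fpkm_treated")) {
    if (!is.numeric(x[[col]])) stop("non-numeric values in column ", col)
  }
  if (!is.numeric(x$qvalue) || anyNA(x$qvalue)) {
    stop("missing or non-numeric q-values are not allowed")
  }
  if (any(x$qvalue < 0 | x$qvalue > 1)) stop("q-values must lie in [0, 1]")
  if (any(x$fpkm_control < 0) || any(x$fpkm_treated < 0)) {
    stop("negative FPKM value")
  }
  x$log2fc <- compute_log2fc(x$fpkm_treated, x$fpkm_control, pseudo)
  if (any(!is.finite(x$log2fc))) {
    stop("non-finite log2 fold change; a positive pseudo-count is required ",
         "when zero FPKM values are present")
  }
  x
}

#' Write a time-course expression table
#'
#' @param expression data.frame as returned by [read_expression_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expression, path) {
  utils::write.table(expression, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
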