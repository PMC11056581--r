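#' Read a gene annotation from GFF3 or GTF
#'
#' Loads gene-level features and converts them to the 0-based half-open
#' coordinate convention used throughout the package. The gene body is taken
#' as the full TSS-to-TES interval of the `gene` feature; transcript and
#' exon structure is deliberately ignored. Genes on organellar chromosomes
#' (mitochondrial or plastid) are flagged `nuclear = FALSE` so downstream
#' steps can restrict themselves to the nuclear-encoded universe.
#'
#' @param path Path to a GFF3 or GTF file.
#' @param format `"auto"` (from the file extension), `"gff3"` or `"gtf"`.
#' @param organelle_chroms Chromosome names treated as organellar. The
#'   default covers the common TAIR-style dialects.
#' @param feature_type Feature type(s) in column 3 treated as genes.
#' @return A `gene_annotation` data frame with columns `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand` and `nuclear`.
#' @export
read_annotation <- function(path,
                            format = c("auto", "gff3", "gtf"),
                            organelle_chroms = c("ChrM", "ChrC", "Mt", "Pt"),
                            feature_type = "gene") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gtf")) "gtf" else "gff3"
  }
  validate_gxf_lines(path)
  gr <- rtracklayer::import(path, format = if (format == "gtf") "gtf" else "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  if (length(gr) == 0L) {
    stop("no gene-level features of type '",
         paste(feature_type, collapse = "/"), "' in ", path, call. = FALSE)
  }
  ids <- if (format == "gtf") gr$gene_id else (gr$ID %||% gr$Name)
  if (is.null(ids) || anyNA(ids)) {
    stop("gene features without an ID/gene_id attribute in ", path, call. = FALSE)
  }
  ann <- gene_annotation(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    # GFF/GTF are 1-based inclusive; internal convention is 0-based half-open
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    organelle_chroms = organelle_chroms
  )
  ann
}

#' Construct a gene annotation from vectors
#'
#' Coordinates are 0-based half-open (BED convention).
#'
#' @param gene_id,chrom,start,end,strand Per-gene fields.
#' @param organelle_chroms Chromosomes whose genes are flagged non-nuclear.
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return A `gene_annotation` data frame sorted by (chrom, start).
#' @export
gene_annotation <- function(gene_id, chrom, start, end, strand,
                            organelle_chroms = c("ChrM", "ChrC", "Mt", "Pt"),
                            chrom_lengths = NULL) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id(s): ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) {
    bad <- which(start >= end)[1L]
    stop(sprintf("gene %s has start >= end (%d >= %d)",
                 gene_id[bad], start[bad], end[bad]), call. = FALSE)
  }
  strand <- as.character(strand)
  strand[strand == "*" | strand == "."] <- "+"
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  ann <- data.frame(
    gene_id = gene_id,
    chrom = as.character(chrom),
    start = start,
    end = end,
    strand = strand,
    nuclear = !(as.character(chrom) %in% organelle_chroms),
    stringsAsFactors = FALSE
  )
  ann <- ann[order(ann$chrom, ann$start, ann$gene_id), , drop = FALSE]
  rownames(ann) <- NULL
  attr(ann, "chrom_lengths") <- chrom_lengths
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Write a gene annotation as GFF3
#'
#' Inverse of [read_annotation()]: internal 0-based half-open coordinates
#' are converted back to the 1-based inclusive GFF3 convention.
#'
#' @param ann A `gene_annotation`.
#' @param path Output path.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "gene_annotation"))
  gr <- as_granges(ann)
  gr$type <- "gene"
  gr$ID <- ann$gene_id
  gr$source <- "coldmark"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# GRanges view of the annotation (1-based inclusive, as GRanges requires)
as_granges <- function(ann) {
  GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand
  )
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes on %d chromosome(s), %d nuclear\n",
              nrow(x), length(unique(x$chrom)), sum(x$nuclear)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

# Shallow structural validation of a GFF3/GTF file so that malformed rows
# are reported with their line number before the real parser runs.
validate_gxf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 8L) {
      stop(sprintf("%s: line %d: expected >= 8 tab-separated fields, got %d",
                   path, i, length(fields)), call. = FALSE)
    }
    if (is.na(suppressWarnings(as.numeric(fields[4L]))) ||
        is.na(suppressWarnings(as.numeric(fields[5L])))) {
      stop(sprintf("%s: line %d: non-numeric start/end", path, i),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
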