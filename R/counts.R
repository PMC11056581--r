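#' Construct a count matrix with sample metadata
#'
#' The container used for both ChIP gene-body counts and RNA-seq counts:
#' a non-negative integer genes x samples matrix plus a sample sheet.
#'
#' @param counts Integer matrix, rownames = gene ids, colnames = sample ids.
#' @param samples Data frame with columns `sample_id`, `assay`
#'   (`"chip"`/`"rna"`), `mark` (NA for RNA), `condition`, `replicate`.
#' @param gene_lengths Optional named vector of gene lengths in bp
#'   (required for [rpkm()]).
#' @param library_sizes Optional named vector of total mapped reads per
#'   sample; defaults to column sums where needed.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, samples, gene_lengths = NULL,
                         library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  req <- c("sample_id", "assay", "condition", "replicate")
  if (!all(req %in% names(samples))) {
    stop("samples metadata must have columns: ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (!"mark" %in% names(samples)) samples$mark <- NA_character_
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  if (!setequal(colnames(counts), samples$sample_id)) {
    stop("counts columns and samples$sample_id do not match", call. = FALSE)
  }
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (!is.null(gene_lengths)) {
    gene_lengths <- gene_lengths[rownames(counts)]
    if (anyNA(gene_lengths)) stop("gene_lengths missing for some genes",
                                  call. = FALSE)
  }
  if (!is.null(library_sizes)) {
    library_sizes <- library_sizes[colnames(counts)]
    if (anyNA(library_sizes)) stop("library_sizes missing for some samples",
                                   call. = FALSE)
  }
  structure(list(counts = counts, samples = samples,
                 gene_lengths = gene_lengths, library_sizes = library_sizes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$assay), collapse = "+")))
  print(x$samples)
  invisible(x)
}

#' Read a count matrix from TSV
#'
#' @param path Counts TSV: first column `gene_id`, one column per sample.
#' @param metadata_path Sample sheet TSV (`sample_id`, `assay`, `mark`,
#'   `condition`, `replicate`).
#' @param gene_lengths_path Optional TSV with `gene_id`, `length`.
#' @return A `count_matrix`.
#' @export
read_counts <- function(path, metadata_path, gene_lengths_path = NULL) {
  tab <- read_tsv(path)
  if (names(tab)[1L] != "gene_id") {
    stop("first column of ", path, " must be 'gene_id'", call. = FALSE)
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab$gene_id
  meta <- read_tsv(metadata_path)
  lens <- NULL
  if (!is.null(gene_lengths_path)) {
    lt <- read_tsv(gene_lengths_path)
    lens <- stats::setNames(lt$length, lt$gene_id)
  }
  count_matrix(m, meta, gene_lengths = lens)
}

#' Write a count matrix (and its sample sheet) as TSV
#' @param x A `count_matrix`.
#' @param path Counts TSV output path.
#' @param metadata_path Optional sample sheet output path.
#' @export
write_counts <- function(x, path, metadata_path = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  if (!is.null(metadata_path)) write_tsv(x$samples, metadata_path)
  invisible(path)
}

#' Median-of-ratios size factors
#'
#' The library-size normalization used for all count matrices: for each
#' sample the size factor is the median, over reference genes, of the ratio
#' of the gene's count to its geometric mean across samples. Reference
#' genes are those with strictly positive counts in every sample. With an
#' even number of reference genes the median is the midpoint of the two
#' central ratios.
#'
#' @param x A `count_matrix` or plain counts matrix.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(x) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref)) {
    stop(paste("no gene has positive counts in all samples;",
               "filter genes or use an alternative normalization"),
         call. = FALSE)
  }
  sub <- m[ref, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  sf <- apply(sub / geo, 2, stats::median)
  stats::setNames(sf, colnames(m))
}

#' Divide counts by size factors
#'
#' @param x A `count_matrix` or matrix.
#' @param sf Size factors, named by sample; defaults to [size_factors()].
#' @return Numeric matrix of normalized counts.
#' @export
normalize_counts <- function(x, sf = NULL) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (is.null(sf)) sf <- size_factors(m)
  if (!is.null(names(sf))) {
    idx <- match_samples(colnames(m), names(sf))
    sf <- sf[idx]
  } else if (length(sf) != ncol(m)) {
    stop("size factors not aligned to samples", call. = FALSE)
  }
  if (any(sf <= 0)) stop("size factors must be positive", call. = FALSE)
  sweep(m, 2, sf, "/")
}

#' Pseudocounted log2 fold change between two sample groups
#'
#' Per gene, `log2((mean_B + pc) / (mean_A + pc))` of normalized counts,
#' with group B (e.g. cold) relative to group A (e.g. naive). The
#' pseudocount keeps the value finite for all-zero genes.
#'
#' @param norm Normalized counts matrix (genes x samples).
#' @param group_a,group_b Disjoint character vectors of sample ids.
#' @param pseudocount Added to both group means, default 0.5.
#' @return A `fold_change_table` data frame: `gene_id`, `base_mean_a`,
#'   `base_mean_b`, `log2fc`.
#' @export
log2_fold_change <- function(norm, group_a, group_b, pseudocount = 0.5) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (length(intersect(group_a, group_b))) {
    stop("groups must be disjoint", call. = FALSE)
  }
  ia <- match_samples(group_a, colnames(norm))
  ib <- match_samples(group_b, colnames(norm))
  ma <- rowMeans(norm[, ia, drop = FALSE])
  mb <- rowMeans(norm[, ib, drop = FALSE])
  fc <- data.frame(
    gene_id = rownames(norm),
    base_mean_a = ma,
    base_mean_b = mb,
    log2fc = log2((mb + pseudocount) / (ma + pseudocount)),
    stringsAsFactors = FALSE
  )
  rownames(fc) <- NULL
  class(fc) <- c("fold_change_table", "data.frame")
  fc
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm[i, j] = counts[i, j] * 1e9 / (length_i * library_size_j)`.
#' Library sizes default to column sums of the count matrix when the
#' object does not carry externally measured totals.
#'
#' @param x A `count_matrix` with `gene_lengths`.
#' @return Numeric matrix of RPKM values.
#' @export
rpkm <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(x$gene_lengths)) {
    stop("gene_lengths are required for RPKM", call. = FALSE)
  }
  lib <- x$library_sizes %||% colSums(x$counts)
  if (any(lib <= 0)) stop("library sizes must be positive", call. = FALSE)
  x$counts * 1e9 / outer(as.numeric(x$gene_lengths), as.numeric(lib))
}
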