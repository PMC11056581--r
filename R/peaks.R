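#' Read a peak file (BED3+ / broadPeak)
#'
#' Only the first three columns (chrom, start, end; BED convention, 0-based
#' half-open) are used, so plain BED, MACS2 broadPeak and narrowPeak all
#' load. Intervals on the same chromosome are sorted and merged (overlapping
#' or book-ended intervals are unioned), matching the assumption downstream
#' that a `peak_set` is a disjoint interval cover.
#'
#' @param path Path to the peak file.
#' @param mark Histone mark label (e.g. `"H3K4me3"`).
#' @param condition Condition label (e.g. `"N"`, `"3h"`, `"3d"`).
#' @return A `peak_set` data frame (`chrom`, `start`, `end`) with
#'   attributes `mark` and `condition`.
#' @export
read_peaks <- function(path, mark, condition) {
  if (!file.exists(path)) stop("peak file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !(lines == "" | startsWith(lines, "#") | startsWith(lines, "track"))
  rows <- which(keep)
  if (length(rows) == 0L) {
    return(peak_set(character(), integer(), integer(),
                    mark = mark, condition = condition))
  }
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    bad <- rows[which(nf < 3L)[1L]]
    stop(sprintf("%s: line %d: expected >= 3 tab-separated columns", path, bad),
         call. = FALSE)
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- rows[which(is.na(start) | is.na(end))[1L]]
    stop(sprintf("%s: line %d: non-numeric start/end", path, bad), call. = FALSE)
  }
  if (any(start >= end)) {
    bad <- rows[which(start >= end)[1L]]
    stop(sprintf("%s: line %d: start >= end", path, bad), call. = FALSE)
  }
  peak_set(chrom, start, end, mark = mark, condition = condition)
}

#' Construct a peak set
#'
#' Intervals are 0-based half-open; overlapping or adjacent intervals are
#' merged on construction.
#'
#' @param chrom,start,end Interval fields.
#' @param mark,condition Labels carried as attributes.
#' @return A `peak_set` data frame.
#' @export
peak_set <- function(chrom, start, end, mark = NA_character_,
                     condition = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) && any(start >= end)) stop("start >= end", call. = FALSE)
  if (length(start)) {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      seqnames = as.character(chrom),
      ranges = IRanges::IRanges(start = start + 1L, end = end)
    ))
    ps <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE
    )
    ps <- ps[order(ps$chrom, ps$start), , drop = FALSE]
    rownames(ps) <- NULL
  } else {
    ps <- data.frame(chrom = character(), start = integer(), end = integer(),
                     stringsAsFactors = FALSE)
  }
  attr(ps, "mark") <- mark
  attr(ps, "condition") <- condition
  class(ps) <- c("peak_set", "data.frame")
  ps
}

#' Write a peak set as BED3
#' @param peaks A `peak_set`.
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  utils::write.table(as.data.frame(peaks)[, c("chrom", "start", "end")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d merged interval(s) [mark=%s, condition=%s]\n",
              nrow(x), attr(x, "mark"), attr(x, "condition")))
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Per-gene peak overlap in base pairs
#'
#' For every gene, the number of gene-body base pairs covered by a single
#' peak (the maximum over peaks), or with `cumulative = TRUE` the total
#' covered by all peaks. Intervals are half-open, so book-ended gene/peak
#' pairs do not overlap.
#'
#' @param ann A `gene_annotation`.
#' @param peaks A `peak_set` (already merged).
#' @param cumulative Sum overlap across peaks instead of taking the best
#'   single peak. With merged peaks the two differ only for genes spanned
#'   by several distinct peaks.
#' @return Named integer vector of base pairs, one entry per gene.
#' @export
peak_overlap_bp <- function(ann, peaks, cumulative = FALSE) {
  stopifnot(inherits(ann, "gene_annotation"), inherits(peaks, "peak_set"))
  out <- stats::setNames(integer(nrow(ann)), ann$gene_id)
  if (nrow(peaks) == 0L || nrow(ann) == 0L) return(out)
  g <- as_granges(ann)
  p <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
  # disjoint seqlevels (gene and peak sets on different chromosomes) are a
  # legitimate no-overlap case, not a user error
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(g, p, ignore.strand = TRUE)
  )
  if (length(hits) == 0L) return(out)
  qi <- S4Vectors::queryHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(g)[qi],
    GenomicRanges::ranges(p)[S4Vectors::subjectHits(hits)]
  ))
  agg <- if (cumulative) {
    tapply(ov, qi, sum)
  } else {
    tapply(ov, qi, max)
  }
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}

#' Best single-peak overlap for one gene
#'
#' Scalar convenience wrapper around [peak_overlap_bp()].
#'
#' @param gene One-row `gene_annotation` (or a row subset by gene).
#' @param peaks A `peak_set`.
#' @return Base pairs of the largest single-peak overlap (0 if none).
#' @export
max_single_peak_overlap <- function(gene, peaks) {
  stopifnot(nrow(gene) == 1L)
  unname(peak_overlap_bp(gene, peaks)[1L])
}

#' Call mark target genes
#'
#' A gene is a target of a mark when at least `min_bp` of its TSS-TES body
#' lies within a single peak of that mark in at least one condition. The
#' threshold is inclusive.
#'
#' @param ann A `gene_annotation`.
#' @param peaksets List of `peak_set` objects for one mark, one per
#'   condition.
#' @param min_bp Minimum single-peak overlap, default 150 bp.
#' @param cumulative Use cumulative overlap across peaks instead of the
#'   best single peak (sensitivity-analysis mode).
#' @return Named logical vector over `ann$gene_id`.
#' @export
is_target <- function(ann, peaksets, min_bp = 150, cumulative = FALSE) {
  if (inherits(peaksets, "peak_set")) peaksets <- list(peaksets)
  if (length(peaksets) == 0L) {
    stop("`peaksets` must contain at least one peak_set", call. = FALSE)
  }
  marks <- unique(vapply(peaksets, function(p) as.character(attr(p, "mark")),
                         ""))
  marks <- marks[!is.na(marks)]
  if (length(marks) > 1L) {
    stop("peaksets mix marks: ", paste(marks, collapse = ", "), call. = FALSE)
  }
  hit <- rep(FALSE, nrow(ann))
  for (ps in peaksets) {
    hit <- hit | (peak_overlap_bp(ann, ps, cumulative = cumulative) >= min_bp)
  }
  stats::setNames(hit, ann$gene_id)
}
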