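#' Construct a coverage track
#'
#' Piecewise-constant coverage as sorted, non-overlapping, half-open
#' segments per chromosome. Positions not covered by any segment have
#' coverage 0.
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, `value`.
#' @return A `coverage_track`: per-chromosome segment tables with
#'   precomputed prefix integrals for fast binned queries.
#' @export
coverage_track <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  if (any(df$start >= df$end)) stop("segment start >= end", call. = FALSE)
  if (any(df$value < 0)) stop("coverage values must be >= 0", call. = FALSE)
  chroms <- split(df, df$chrom)
  trk <- lapply(chroms, function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)])) {
      stop("overlapping segments on chromosome ", d$chrom[1L], call. = FALSE)
    }
    list(start = as.numeric(d$start), end = as.numeric(d$end),
         value = as.numeric(d$value),
         # integral of coverage over [0, start_i)
         pref = cumsum(c(0, (d$end - d$start) * d$value))[seq_len(nrow(d))])
  })
  structure(trk, class = "coverage_track")
}

#' Read a bedGraph coverage track
#'
#' @param path 4-column bedGraph (chrom, start, end, value; 0-based
#'   half-open). Overlapping segments are an error reported with the
#'   offending line numbers; gaps are implicit zero coverage.
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("bedGraph not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rows <- which(!(lines == "" | startsWith(lines, "#") |
                    startsWith(lines, "track")))
  if (length(rows) == 0L) {
    return(coverage_track(data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), value = numeric())))
  }
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  if (any(lengths(parts) < 4L)) {
    bad <- rows[which(lengths(parts) < 4L)[1L]]
    stop(sprintf("%s: line %d: expected 4 columns", path, bad), call. = FALSE)
  }
  df <- data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.numeric(vapply(parts, `[[`, "", 2L)),
    end = as.numeric(vapply(parts, `[[`, "", 3L)),
    value = as.numeric(vapply(parts, `[[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$value)) {
    bad <- rows[which(is.na(df$start) | is.na(df$end) | is.na(df$value))[1L]]
    stop(sprintf("%s: line %d: non-numeric field", path, bad), call. = FALSE)
  }
  # overlap check with original line numbers
  for (ch in unique(df$chrom)) {
    idx <- which(df$chrom == ch)
    o <- idx[order(df$start[idx])]
    if (length(o) > 1L) {
      ov <- which(df$start[o][-1L] < df$end[o][-length(o)])
      if (length(ov)) {
        stop(sprintf("%s: overlapping segments at lines %d and %d",
                     path, rows[o[ov[1L]]], rows[o[ov[1L] + 1L]]),
             call. = FALSE)
      }
    }
  }
  coverage_track(df)
}

#' Write a coverage track as bedGraph
#' @param track A `coverage_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  rows <- lapply(names(track), function(ch) {
    t <- track[[ch]]
    data.frame(chrom = ch, start = t$start, end = t$end, value = t$value,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# integral of the coverage step function over [0, x), vectorized over x
track_integral <- function(track, chrom, x) {
  t <- track[[chrom]]
  if (is.null(t)) return(numeric(length(x)))
  i <- findInterval(x, t$start)
  out <- numeric(length(x))
  pos <- i > 0L
  if (any(pos)) {
    ii <- i[pos]
    out[pos] <- t$pref[ii] +
      t$value[ii] * pmin(pmax(x[pos] - t$start[ii], 0), t$end[ii] - t$start[ii])
  }
  out
}

#' Scaled coverage profile of a single gene
#'
#' Flanks are binned at native resolution (`bin_bp`); the gene body is
#' resampled to `body_bp / bin_bp` bins by length-weighted averaging of
#' the underlying coverage, which conserves the mean body signal exactly.
#' Minus-strand genes are reversed so that bin 1 is always the most
#' upstream position relative to the TSS. Flank regions outside the
#' chromosome contribute zero coverage.
#'
#' @param track A `coverage_track`.
#' @param gene One-row `gene_annotation` (or list with `chrom`, `start`,
#'   `end`, `strand`).
#' @param flank_bp Flank size, default 500.
#' @param body_bp Scaled body length, default 2000.
#' @param bin_bp Bin size, default 10.
#' @return Numeric vector of `(2 * flank_bp + body_bp) / bin_bp` bins
#'   (300 under the defaults).
#' @export
gene_profile <- function(track, gene, flank_bp = 500, body_bp = 2000,
                         bin_bp = 10) {
  chrom <- as.character(gene$chrom[1L])
  s <- as.numeric(gene$start[1L]); e <- as.numeric(gene$end[1L])
  n_flank <- as.integer(flank_bp / bin_bp)
  n_body <- as.integer(body_bp / bin_bp)
  up <- if (n_flank > 0L) s - flank_bp + bin_bp * (0:(n_flank - 1L)) else numeric(0)
  down <- if (n_flank > 0L) e + bin_bp * (1:n_flank) else numeric(0)
  breaks <- c(up, s + (e - s) * (0:n_body) / n_body, down)
  ci <- track_integral(track, chrom, breaks)
  prof <- diff(ci) / diff(breaks)
  if (as.character(gene$strand[1L]) == "-") prof <- rev(prof)
  prof
}

#' Metagene profile over a gene set
#'
#' Bin-wise arithmetic mean of [gene_profile()] over the given genes.
#'
#' @param track A `coverage_track`.
#' @param ann A `gene_annotation`.
#' @param genes Optional character vector of gene ids (default: all genes
#'   in `ann`).
#' @inheritParams gene_profile
#' @return A `metagene_profile`: list with `profile`, `n_genes` and the
#'   binning parameters.
#' @export
metagene_profile <- function(track, ann, genes = NULL, flank_bp = 500,
                             body_bp = 2000, bin_bp = 10) {
  if (!is.null(genes)) {
    miss <- setdiff(genes, ann$gene_id)
    if (length(miss)) stop("genes not in annotation: ",
                           paste(utils::head(miss, 5L), collapse = ", "),
                           call. = FALSE)
    ann <- ann[ann$gene_id %in% genes, , drop = FALSE]
  }
  if (nrow(ann) == 0L) stop("empty gene set", call. = FALSE)
  acc <- NULL
  for (i in seq_len(nrow(ann))) {
    p <- gene_profile(track, ann[i, , drop = FALSE], flank_bp = flank_bp,
                      body_bp = body_bp, bin_bp = bin_bp)
    acc <- if (is.null(acc)) p else acc + p
  }
  structure(list(profile = acc / nrow(ann), n_genes = nrow(ann),
                 flank_bp = flank_bp, body_bp = body_bp, bin_bp = bin_bp),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("metagene_profile: %d bins over %d genes (flank %d bp, body scaled to %d bp)\n",
              length(x$profile), x$n_genes, x$flank_bp, x$body_bp))
  invisible(x)
}

#' @method plot metagene_profile
#' @export
plot.metagene_profile <- function(x, ..., main = "Metagene profile") {
  nf <- x$flank_bp / x$bin_bp
  nb <- x$body_bp / x$bin_bp
  graphics::plot(seq_along(x$profile), x$profile, type = "l",
                 xlab = "bin", ylab = "mean coverage", main = main,
                 xaxt = "n", ...)
  graphics::axis(1, at = c(1, nf + 0.5, nf + nb + 0.5, 2 * nf + nb),
                 labels = c(sprintf("-%d bp", x$flank_bp), "TSS", "TES",
                            sprintf("+%d bp", x$flank_bp)))
  graphics::abline(v = c(nf + 0.5, nf + nb + 0.5), lty = 2, col = "grey50")
  invisible(x)
}
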