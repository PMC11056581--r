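# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use the most literal formulation of
# each definition and share no code with the package internals.

# max single-peak overlap by an all-pairs scan
brute_max_overlap <- function(g_chrom, g_start, g_end, peaks) {
  best <- 0L
  for (i in seq_len(nrow(peaks))) {
    if (peaks$chrom[i] != g_chrom) next
    ov <- min(g_end, peaks$end[i]) - max(g_start, peaks$start[i])
    if (ov > best) best <- ov
  }
  as.integer(max(best, 0L))
}

# median-of-ratios size factors, direct formula
brute_size_factors <- function(m) {
  ref <- which(apply(m, 1, function(r) all(r > 0)))
  geo <- apply(m[ref, , drop = FALSE], 1, function(r) prod(r)^(1 / length(r)))
  sapply(seq_len(ncol(m)), function(j) {
    stats::median(m[ref, j] / geo)
  })
}

# textbook BH step-up: p_(i) * m / i, cumulative minimum from the largest
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# exclusive intersection counts by per-element enumeration
brute_exclusive <- function(sets) {
  universe <- unique(unlist(sets))
  if (length(universe) == 0L) return(table(character(0)))
  sig <- sapply(universe, function(el) {
    paste(names(sets)[vapply(sets, function(s) el %in% s, TRUE)],
          collapse = "&")
  })
  table(sig)
}

# exact two-sided rank-sum p-value by full enumeration of group assignments
brute_wilcoxon <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  p <- 2 * min(mean(ws <= obs), mean(ws >= obs))
  min(p, 1)
}

# Spearman rho via the explicit mid-rank covariance formula
brute_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  sxy <- sum((rx - mean(rx)) * (ry - mean(ry)))
  sxx <- sum((rx - mean(rx))^2)
  syy <- sum((ry - mean(ry))^2)
  sxy / sqrt(sxx * syy)
}

# tiny annotation builder for interval tests
tiny_annotation <- function(starts, ends, chrom = "Chr1", strand = NULL,
                            ids = NULL) {
  n <- length(starts)
  gene_annotation(
    gene_id = ids %||% sprintf("g%03d", seq_len(n)),
    chrom = rep(chrom, length.out = n),
    start = starts, end = ends,
    strand = strand %||% rep("+", n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
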