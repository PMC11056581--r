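#' Method-of-moments NB dispersion estimates
#'
#' Per-gene dispersion `alpha` in the NB variance parameterization
#' `Var = mu + alpha * mu^2`, estimated from normalized counts as
#' `(pooled within-group variance - mean) / mean^2`, floored at a small
#' positive value. An optional shrinkage step pulls each estimate toward
#' the median dispersion of genes with similar expression, trading
#' per-gene noise for bias.
#'
#' @param norm Normalized counts matrix.
#' @param group_a,group_b Sample ids of the two groups (>= 2 replicates
#'   each).
#' @param floor Lower bound for alpha, default `1e-8`.
#' @param shrink Logical; apply trend shrinkage (off by default).
#' @param shrink_weight Weight on the per-gene estimate when shrinking.
#' @param bin_size Genes per expression bin for the trend median.
#' @return Named numeric vector of dispersions, one per gene.
#' @export
estimate_dispersion <- function(norm, group_a, group_b, floor = 1e-8,
                                shrink = FALSE, shrink_weight = 0.5,
                                bin_size = 100L) {
  ia <- match_samples(group_a, colnames(norm))
  ib <- match_samples(group_b, colnames(norm))
  na <- length(ia); nb <- length(ib)
  if (na < 2L || nb < 2L) {
    stop("need >= 2 replicates per group to estimate dispersion",
         call. = FALSE)
  }
  a <- norm[, ia, drop = FALSE]; b <- norm[, ib, drop = FALSE]
  va <- rowSums((a - rowMeans(a))^2) / (na - 1L)
  vb <- rowSums((b - rowMeans(b))^2) / (nb - 1L)
  s2 <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
  mu <- (rowMeans(a) + rowMeans(b)) / 2
  alpha <- pmax(floor, (s2 - mu) / pmax(mu, .Machine$double.eps)^2)
  alpha[mu == 0] <- floor
  if (shrink) {
    ord <- order(mu)
    trend <- numeric(length(alpha))
    grp <- ceiling(seq_along(ord) / bin_size)
    med <- tapply(alpha[ord], grp, stats::median)
    trend[ord] <- med[grp]
    alpha <- pmax(floor, shrink_weight * alpha + (1 - shrink_weight) * trend)
  }
  stats::setNames(alpha, rownames(norm))
}

#' Simplified NB Wald test for two-group differential expression
#'
#' A transparent stand-in for a full GLM-based differential-expression
#' engine: the statistic is the pseudocounted log2 fold change of
#' normalized group means divided by its delta-method standard error under
#' the NB model at the estimated means and dispersions, referred to a
#' Student t distribution with `nA + nB - 2` degrees of freedom (the
#' residual degrees of freedom of the dispersion estimate; a small-sample
#' correction without which the plug-in Wald test is anticonservative at
#' typical replicate numbers). Genes with zero counts in every sample get
#' p = 1.
#'
#' @param x A `count_matrix` or counts matrix.
#' @param group_a,group_b Disjoint sample-id vectors, >= 2 replicates each.
#' @param sf Size factors; computed with [size_factors()] when `NULL`.
#' @param dispersion Optional named dispersion vector; estimated by
#'   [estimate_dispersion()] when `NULL`.
#' @param pseudocount Pseudocount for the fold change, default 0.5.
#' @return Data frame: `gene_id`, `base_mean_a`, `base_mean_b`, `log2fc`,
#'   `stat`, `pvalue`.
#' @export
nb_wald_test <- function(x, group_a, group_b, sf = NULL, dispersion = NULL,
                         pseudocount = 0.5) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (length(intersect(group_a, group_b))) {
    stop("groups must be disjoint", call. = FALSE)
  }
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("need >= 2 replicates per group", call. = FALSE)
  if (is.null(sf)) sf <- size_factors(m)
  norm <- normalize_counts(m, sf)
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(norm, group_a, group_b)
  }
  fc <- log2_fold_change(norm, group_a, group_b, pseudocount = pseudocount)
  ma <- fc$base_mean_a; mb <- fc$base_mean_b
  # Var(mean of k normalized NB counts) ~ (mu + alpha mu^2) / k at the
  # plug-in group means; delta method onto the log2 scale.
  vma <- (ma + dispersion * ma^2) / na
  vmb <- (mb + dispersion * mb^2) / nb
  se <- sqrt(vma / (ma + pseudocount)^2 + vmb / (mb + pseudocount)^2) / log(2)
  stat <- ifelse(se > 0, fc$log2fc / se, 0)
  p <- 2 * stats::pt(-abs(stat), df = na + nb - 2L)
  allzero <- rowSums(m[, c(group_a, group_b), drop = FALSE]) == 0
  p[allzero] <- 1
  stat[allzero] <- 0
  data.frame(gene_id = fc$gene_id, base_mean_a = ma, base_mean_b = mb,
             log2fc = fc$log2fc, stat = stat, pvalue = p,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment. Thin validated wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must be numbers in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Full differential-expression table for one contrast
#'
#' Runs [nb_wald_test()], adjusts p-values with [bh_adjust()] and assigns
#' the DEG class: `up` for `log2fc >= lfc_threshold` (inclusive) with
#' `padj < alpha` (strict), `down` symmetrically, `none` otherwise.
#'
#' @inheritParams nb_wald_test
#' @param nuclear Optional named logical; genes absent or FALSE are
#'   still tested but flagged, so the nuclear-only DEG filter can be
#'   applied by [call_degs()].
#' @param lfc_threshold Absolute log2FC threshold, default 1.
#' @param alpha Adjusted-p threshold, default 0.05.
#' @return A `de_table` data frame.
#' @export
de_test <- function(x, group_a, group_b, sf = NULL, dispersion = NULL,
                    pseudocount = 0.5, nuclear = NULL,
                    lfc_threshold = 1, alpha = 0.05) {
  res <- nb_wald_test(x, group_a, group_b, sf = sf, dispersion = dispersion,
                      pseudocount = pseudocount)
  res$padj <- bh_adjust(res$pvalue)
  res$de_class <- ifelse(
    res$padj < alpha & res$log2fc >= lfc_threshold, "up",
    ifelse(res$padj < alpha & res$log2fc <= -lfc_threshold, "down", "none")
  )
  res$nuclear <- if (is.null(nuclear)) TRUE else {
    unname(nuclear[res$gene_id]) %in% TRUE
  }
  class(res) <- c("de_table", "data.frame")
  res
}

#' Extract up/down DEG sets from a DE table
#'
#' @param de A `de_table` (or data frame with `gene_id`, `log2fc`, `padj`,
#'   `nuclear`).
#' @param lfc_threshold Inclusive absolute log2FC threshold, default 1.
#' @param alpha Strict adjusted-p threshold, default 0.05.
#' @param nuclear_only Keep only nuclear-encoded genes (default TRUE).
#' @return List with character vectors `up` and `down`.
#' @export
call_degs <- function(de, lfc_threshold = 1, alpha = 0.05,
                      nuclear_only = TRUE) {
  keep <- if (nuclear_only && "nuclear" %in% names(de)) de$nuclear else TRUE
  sig <- de$padj < alpha & keep
  list(up = de$gene_id[sig & de$log2fc >= lfc_threshold],
       down = de$gene_id[sig & de$log2fc <= -lfc_threshold])
}
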