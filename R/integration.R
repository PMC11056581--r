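#' Exclusive intersection counts (UpSet semantics)
#'
#' Every element of the union of the input sets is assigned to exactly one
#' membership signature (the subset of sets containing it); counts over
#' signatures therefore sum to the size of the union.
#'
#' @param sets Named list of character vectors.
#' @return Data frame `signature` (set names joined by `&`), `degree`,
#'   `count`, sorted by degree then signature.
#' @export
exclusive_intersections <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  if (length(universe) == 0L) {
    return(data.frame(signature = character(), degree = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1L)
  sig <- apply(member, 1L, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  tab <- table(sig)
  out <- data.frame(signature = names(tab),
                    degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(out$degree, out$signature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-mark DM intersections at one timepoint
#'
#' Builds the four DM sets (gain and loss for each of two marks), computes
#' their exclusive intersection counts, and tallies genes that are DM for
#' both marks in the same direction (gain/gain or loss/loss) versus
#' opposite directions.
#'
#' @param dm_tables Named list (by mark) of exactly two `dm_table` objects
#'   for the same contrast.
#' @return List with `exclusive` (data frame), `same_direction`,
#'   `opposite_direction` and `union_size`.
#' @export
intersect_dm_sets <- function(dm_tables) {
  stopifnot(is.list(dm_tables), length(dm_tables) == 2L,
            !is.null(names(dm_tables)))
  mk <- names(dm_tables)
  sets <- list()
  for (m in mk) {
    sets[[paste0(m, "_gain")]] <- dm_genes(dm_tables[[m]], "gain")
    sets[[paste0(m, "_loss")]] <- dm_genes(dm_tables[[m]], "loss")
  }
  excl <- exclusive_intersections(sets)
  same <- length(intersect(sets[[paste0(mk[1L], "_gain")]],
                           sets[[paste0(mk[2L], "_gain")]])) +
          length(intersect(sets[[paste0(mk[1L], "_loss")]],
                           sets[[paste0(mk[2L], "_loss")]]))
  opp <- length(intersect(sets[[paste0(mk[1L], "_gain")]],
                          sets[[paste0(mk[2L], "_loss")]])) +
         length(intersect(sets[[paste0(mk[1L], "_loss")]],
                          sets[[paste0(mk[2L], "_gain")]]))
  list(exclusive = excl, same_direction = same, opposite_direction = opp,
       union_size = length(unique(unlist(sets, use.names = FALSE))))
}

#' Persistence of DM calls across the two cold timepoints
#'
#' For one mark and one direction, counts genes DM at 3 h only, at 3 d
#' only, and at both timepoints. The headline `fraction_both` uses the
#' union of the two sets as denominator; the per-timepoint fractions are
#' also reported since the denominator convention matters for small sets.
#'
#' @param dm_3h,dm_3d `dm_table` objects for the same mark.
#' @param direction `"gain"` or `"loss"`.
#' @return One-row data frame: `direction`, `n_3h_only`, `n_3d_only`,
#'   `n_both`, `fraction_both` (NA when both sets are empty),
#'   `frac_of_3h`, `frac_of_3d`.
#' @export
dm_persistence <- function(dm_3h, dm_3d, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  s1 <- dm_genes(dm_3h, direction)
  s2 <- dm_genes(dm_3d, direction)
  both <- length(intersect(s1, s2))
  uni <- length(union(s1, s2))
  data.frame(
    direction = direction,
    n_3h_only = length(s1) - both,
    n_3d_only = length(s2) - both,
    n_both = both,
    fraction_both = if (uni > 0) both / uni else NA_real_,
    frac_of_3h = if (length(s1) > 0) both / length(s1) else NA_real_,
    frac_of_3d = if (length(s2) > 0) both / length(s2) else NA_real_,
    stringsAsFactors = FALSE
  )
}

# all permutations of 1..n as an (n! x n) integer matrix; used by the
# exact Spearman permutation test (n <= 8 keeps this below 40320 rows)
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[as.vector(sub)], nrow(sub)))
  }))
}

#' Spearman rank correlation
#'
#' Rho is the Pearson correlation of mid-ranks (ties receive average
#' ranks). The two-sided p-value is computed by exhaustive permutation of
#' one rank vector for `n <= exact_max` (default 8) and by the usual t
#' approximation above that; study-scale gene sets are in the hundreds to
#' thousands, where the t approximation is standard.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param exact_max Largest n for the exact permutation p-value.
#' @return A `cor_result` list: `rho`, `pvalue`, `n`, `method`.
#' @export
spearman_cor <- function(x, y, exact_max = 8L) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported",
                                 call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    pm <- perm_matrix(n)
    # Pearson cor of rx with each permutation of ry, vectorized
    rperm <- matrix(ry[pm], nrow(pm))
    num <- rperm %*% (rx - mean(rx))
    rho_perm <- as.vector(num) / ((n - 1L) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  structure(list(rho = rho, pvalue = min(p, 1), n = n, method = method),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f, p = %.3g, n = %d (%s)\n",
              x$rho, x$pvalue, x$n, x$method))
  invisible(x)
}

#' Correlate methylation and expression changes
#'
#' Restricts to genes that are differentially expressed at the considered
#' expression timepoint and targeted by the mark, then computes the
#' Spearman correlation between methylation and expression log2 fold
#' changes. Supplying fold-change tables from different timepoints gives
#' the cross-timepoint correlation matrix.
#'
#' @param fc_meth,fc_expr `fold_change_table` objects (any timepoint
#'   combination).
#' @param de_genes Character vector of DE gene ids at the expression
#'   timepoint.
#' @param targets Named logical target status for the mark.
#' @return A `cor_result` (see [spearman_cor()]); errors when fewer than
#'   3 genes survive the restriction.
#' @export
correlate_dm_de <- function(fc_meth, fc_expr, de_genes, targets) {
  tset <- names(targets)[targets %in% TRUE]
  genes <- intersect(intersect(de_genes, tset),
                     intersect(fc_meth$gene_id, fc_expr$gene_id))
  if (length(genes) < 3L) {
    stop("fewer than 3 genes in the restricted set", call. = FALSE)
  }
  xm <- fc_meth$log2fc[match(genes, fc_meth$gene_id)]
  xe <- fc_expr$log2fc[match(genes, fc_expr$gene_id)]
  spearman_cor(xm, xe)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null distribution when the smaller group has at most 8
#' observations and there are no ties; normal approximation with tie
#' correction otherwise.
#'
#' @param a,b Non-empty numeric vectors.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both inputs must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- min(length(a), length(b)) <= 8L && !ties
  res <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = !exact)
  )
  unname(res$p.value)
}

#' Pairwise rank-sum comparisons of gene categories
#'
#' Compares a per-gene quantity (e.g. log2 RPKM or expression log2FC)
#' between the `gain`, `loss` and `non_DM` induced-gene categories with
#' two-sided Wilcoxon rank-sum tests. The `both` category is excluded
#' from testing and its size reported separately; pairs where either
#' category has fewer than 2 members are flagged untestable.
#'
#' @param values Named numeric vector (gene id -> value).
#' @param categories Data frame from [assign_induced_categories()].
#' @return Data frame of pairwise results with attribute `n_both`.
#' @export
compare_categories <- function(values, categories) {
  lv <- c("gain", "loss", "non_DM")
  groups <- lapply(lv, function(l) {
    g <- categories$gene_id[categories$category == l]
    v <- values[intersect(g, names(values))]
    v[!is.na(v)]
  })
  names(groups) <- lv
  if (sum(lengths(groups) > 0L) < 2L) {
    stop("need at least two non-empty categories", call. = FALSE)
  }
  pairs <- utils::combn(lv, 2L)
  rows <- apply(pairs, 2L, function(pr) {
    va <- groups[[pr[1L]]]; vb <- groups[[pr[2L]]]
    testable <- length(va) >= 2L && length(vb) >= 2L
    data.frame(category_a = pr[1L], category_b = pr[2L],
               n_a = length(va), n_b = length(vb),
               pvalue = if (testable) wilcoxon_rank_sum(va, vb) else NA_real_,
               testable = testable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_both") <- sum(categories$category == "both")
  out
}

#' Co-targeting contingency counts for two marks
#'
#' @param targets_a,targets_b Named logical vectors over the same gene
#'   universe.
#' @return List `both`, `only_a`, `only_b`, `neither`, `universe`; the
#'   four counts sum to the universe size.
#' @export
co_target_counts <- function(targets_a, targets_b) {
  if (!setequal(names(targets_a), names(targets_b))) {
    stop("the two target vectors must cover the same gene universe",
         call. = FALSE)
  }
  b <- targets_b[names(targets_a)]
  a <- targets_a
  list(both = sum(a & b), only_a = sum(a & !b), only_b = sum(!a & b),
       neither = sum(!a & !b), universe = length(a))
}
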