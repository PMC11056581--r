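test_that("exclusive intersections match brute-force enumeration on random set systems", {
  set.seed(71)
  for (i in 1:200) {
    k <- sample(1:4, 1)
    sets <- lapply(seq_len(k), function(j) {
      sample(letters[1:20], sample(0:12, 1))
    })
    names(sets) <- LETTERS[seq_len(k)]
    got <- exclusive_intersections(sets)
    want <- brute_exclusive(sets)
    expect_equal(sum(got$count),
                 length(unique(unlist(sets))))
    for (s in got$signature) {
      expect_equal(got$count[got$signature == s], unname(want[[s]]))
    }
    expect_equal(nrow(got), length(want))
  }
})

test_that("cross-mark DM intersections tally same and opposite directions", {
  mk_dm <- function(ids, cls) {
    structure(data.frame(gene_id = ids, is_target = TRUE, log2fc = 0,
                         dm_class = cls, stringsAsFactors = FALSE),
              class = c("dm_table", "data.frame"))
  }
  ids <- c("a", "b", "c", "d")
  k4 <- mk_dm(ids, c("gain", "gain", "none", "loss"))
  k27 <- mk_dm(ids, c("none", "gain", "gain", "loss"))
  res <- intersect_dm_sets(list(H3K4me3 = k4, H3K27me3 = k27))
  expect_equal(res$same_direction, 2L)     # b (gain/gain), d (loss/loss)
  expect_equal(res$opposite_direction, 0L)
  expect_equal(res$union_size, 4L)
  expect_equal(sum(res$exclusive$count), res$union_size)
  k27b <- mk_dm(ids, c("loss", "none", "none", "none"))
  res2 <- intersect_dm_sets(list(H3K4me3 = k4, H3K27me3 = k27b))
  expect_equal(res2$opposite_direction, 1L)  # a: gain vs loss
})

test_that("persistence uses the union denominator and honours edge cases", {
  mk_dm <- function(ids, cls) {
    structure(data.frame(gene_id = ids, is_target = TRUE, log2fc = 0,
                         dm_class = cls, stringsAsFactors = FALSE),
              class = c("dm_table", "data.frame"))
  }
  ids <- c("a", "b", "c", "d", "e")
  d1 <- mk_dm(ids, c("gain", "gain", "gain", "none", "none"))
  d2 <- mk_dm(ids, c("none", "gain", "gain", "gain", "none"))
  p <- dm_persistence(d1, d2, "gain")
  expect_equal(p$n_both, 2L)
  expect_equal(p$fraction_both, 0.5)
  expect_equal(p$n_3h_only, 1L)
  expect_equal(p$n_3d_only, 1L)
  expect_equal(dm_persistence(d1, d1, "gain")$fraction_both, 1.0)
  d3 <- mk_dm(ids, c("none", "none", "none", "gain", "gain"))
  d4 <- mk_dm(ids, c("gain", "gain", "none", "none", "none"))
  expect_equal(dm_persistence(d4, d3, "gain")$fraction_both, 0.0)
  expect_true(is.na(dm_persistence(d1, d2, "loss")$fraction_both))
  # adding a shared gene never decreases the fraction
  set.seed(72)
  for (i in 1:20) {
    s1 <- sample(letters, 10); s2 <- sample(letters, 10)
    mk <- function(s) mk_dm(letters, ifelse(letters %in% s, "gain", "none"))
    base_frac <- dm_persistence(mk(s1), mk(s2), "gain")$fraction_both
    extra <- setdiff(letters, union(s1, s2))[1]
    if (is.na(extra)) next
    new_frac <- dm_persistence(mk(c(s1, extra)), mk(c(s2, extra)),
                               "gain")$fraction_both
    expect_gte(new_frac, base_frac)
  }
})

test_that("spearman rho equals the mid-rank formula, including ties", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, rev(1:10))$rho, -1)
  x <- c(1, 2, 2, 4); y <- c(10, 20, 30, 40)
  expect_equal(spearman_cor(x, y)$rho, brute_spearman_rho(x, y))
  set.seed(73)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    x <- sample(1:8, n, TRUE); y <- sample(1:8, n, TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_cor(x, y)$rho, brute_spearman_rho(x, y),
                 tolerance = 1e-12)
  }
  expect_error(spearman_cor(1:5, rep(2, 5)), "constant")
  expect_error(spearman_cor(1:2, 2:1), "at least 3")
  # invariance under strictly monotone transforms
  set.seed(74)
  x <- rnorm(40); y <- rnorm(40)
  r0 <- spearman_cor(x, y)$rho
  expect_equal(spearman_cor(exp(x), y)$rho, r0)
  expect_equal(spearman_cor(x, y^3 + 5 * y)$rho, r0)
})

test_that("spearman p-values: exact permutation for small n, t approximation above", {
  # n = 3, observed rho = 0.5: every permutation has |rho| >= 0.5
  r <- spearman_cor(c(1, 2, 3), c(10, 30, 20))
  expect_equal(r$rho, 0.5)
  expect_equal(r$pvalue, 1)
  expect_equal(r$method, "exact permutation")
  # n = 4, perfect monotone: only identity and reversal reach |rho| = 1
  r4 <- spearman_cor(1:4, c(3, 7, 20, 100))
  expect_equal(r4$rho, 1)
  expect_equal(r4$pvalue, 2 / 24)
  big <- spearman_cor(1:30, sin(1:30))
  expect_equal(big$method, "t approximation")
  expect_true(big$pvalue >= 0 && big$pvalue <= 1)
})

test_that("rank-sum exact mode matches full enumeration (incl. complete separation)", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12)), 0.1)
  set.seed(75)
  for (i in 1:30) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- sample(seq(0, 1, by = 0.001), n1)
    b <- sample(setdiff(seq(0, 1, by = 0.001), a), n2)
    expect_equal(wilcoxon_rank_sum(a, b), brute_wilcoxon(a, b),
                 tolerance = 1e-12)
  }
  # identical multisets give p = 1 (tie-corrected approximation path)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")
  # large-sample approximation close to exact at n = 8/8
  set.seed(76)
  diffs <- replicate(20, {
    a <- sample(1:1000, 8); b <- sample(setdiff(1:1000, a), 8)
    abs(wilcoxon_rank_sum(a, b) - brute_wilcoxon(a, b))
  })
  expect_equal(max(diffs), 0)  # both exact here
  # force the approximation with a tie and compare to enumeration
  a <- c(1, 4, 6, 9, 11, 13, 15, 17)
  b <- c(2, 3, 5, 8, 10, 12, 14, 17)
  expect_lt(abs(wilcoxon_rank_sum(a, b) - brute_wilcoxon(a, b)), 0.01)
})

test_that("category comparisons detect planted shifts and flag degenerate pairs", {
  set.seed(77)
  ids <- sprintf("g%03d", 1:150)
  cats <- data.frame(
    gene_id = ids,
    category = factor(rep(c("gain", "loss", "non_DM"), each = 50),
                      levels = c("gain", "loss", "both", "non_DM")),
    stringsAsFactors = FALSE
  )
  vals <- setNames(rnorm(150), ids)
  vals[1:50] <- vals[1:50] + 2   # gain shifted
  cmp <- compare_categories(vals, cats)
  gl <- cmp$pvalue[cmp$category_a == "gain" & cmp$category_b == "non_DM"]
  expect_lt(gl, 0.05)
  expect_true(all(cmp$testable))
  # identical distributions: large p
  vals2 <- setNames(rep(1:50, 3), ids)
  cmp2 <- compare_categories(vals2, cats)
  expect_true(all(cmp2$pvalue > 0.9))
  # single-member category flagged, no p emitted
  cats3 <- cats; cats3$category[cats3$category == "loss"] <- "non_DM"
  cats3$category[1] <- "loss"
  cats3$category <- factor(as.character(cats3$category),
                           levels = levels(cats$category))
  cmp3 <- compare_categories(vals, cats3)
  bad <- cmp3[cmp3$category_a == "loss" | cmp3$category_b == "loss", ]
  expect_true(all(!bad$testable))
  expect_true(all(is.na(bad$pvalue)))
})

test_that("co-targeting counts partition the universe", {
  u <- c("a", "b", "c", "d")
  ta <- setNames(u %in% c("a", "b"), u)
  tb <- setNames(u %in% c("b", "c"), u)
  ct <- co_target_counts(ta, tb)
  expect_equal(ct[c("both", "only_a", "only_b", "neither")],
               list(both = 1L, only_a = 1L, only_b = 1L, neither = 1L))
  expect_equal(co_target_counts(ta, ta)$both, 2L)
  set.seed(78)
  for (i in 1:20) {
    u <- sprintf("g%02d", 1:30)
    ta <- setNames(runif(30) < 0.4, u)
    tb <- setNames(runif(30) < 0.6, u)
    ct <- co_target_counts(ta, sample(tb))
    expect_equal(ct$both + ct$only_a + ct$only_b + ct$neither, 30L)
    expect_equal(ct$both, sum(ta & tb))
  }
})
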