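make_cm <- function(m, assay = "rna") {
  count_matrix(m, data.frame(sample_id = colnames(m), assay = assay,
                             mark = NA, condition = "N",
                             replicate = seq_len(ncol(m))))
}

test_that("size factors follow the median-of-ratios definition", {
  # constant-ratio case: factors proportional to the column scaling
  m <- matrix(c(10L, 20L, 40L, 20L, 40L, 80L), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  sf <- size_factors(m)
  expect_equal(unname(sf[2] / sf[1]), 2)
  # identical columns give equal factors
  m2 <- cbind(s1 = c(5L, 9L, 14L), s2 = c(5L, 9L, 14L))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(diff(size_factors(m2))), 0)

  set.seed(7)
  r <- matrix(rnbinom(2000, mu = 50, size = 5), 500, 4,
              dimnames = list(paste0("g", 1:500), paste0("s", 1:4)))
  expect_equal(unname(size_factors(r)), brute_size_factors(r),
               tolerance = 1e-12)

  # genes with any zero are excluded from the reference
  z <- r; z[1:450, 1] <- 0L
  expect_equal(unname(size_factors(z)), brute_size_factors(z),
               tolerance = 1e-12)
  allz <- matrix(c(0L, 1L, 1L, 0L), 2, 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors(allz), "no gene")
})

test_that("scaling one sample's counts by c scales its relative size factor by exactly c", {
  # The geometric-mean reference includes the scaled sample, so the raw
  # factors all pick up a common c^(1/m) term; the identity that holds
  # exactly is on factors relative to any unscaled sample.
  set.seed(8)
  m <- matrix(rnbinom(800, mu = 100, size = 10) + 1L, 200, 4,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:4)))
  sf <- size_factors(m)
  for (c_ in c(2L, 5L)) {
    m2 <- m
    m2[, 3] <- m2[, 3] * c_
    sf2 <- size_factors(m2)
    expect_equal(unname((sf2[3] / sf2[1]) / (sf[3] / sf[1])), c_,
                 tolerance = 1e-12)
    # unaffected samples keep their relative factors
    expect_equal(unname(sf2[-3] / sf2[1]), unname(sf[-3] / sf[1]),
                 tolerance = 1e-12)
  }
})

test_that("size factors agree with DESeq2's median-of-ratios on an odd reference", {
  skip_if_not_installed("DESeq2")
  set.seed(9)
  m <- matrix(rnbinom(2004, mu = 80, size = 8) + 1L, 501, 4,
              dimnames = list(paste0("g", 1:501), paste0("s", 1:4)))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("normalization divides by the factor and equalizes constant-ratio columns", {
  m <- matrix(c(10L, 30L, 20L, 60L), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  norm1 <- normalize_counts(m, c(s1 = 1, s2 = 1))
  expect_equal(norm1, m + 0)
  expect_equal(normalize_counts(m, c(s1 = 2, s2 = 2))["g1", "s1"], 5)
  norm <- normalize_counts(m)
  expect_equal(unname(colSums(norm)[1]), unname(colSums(norm)[2]))
  expect_error(normalize_counts(m, c(bad = 1, s2 = 1)), "unknown sample")
})

test_that("log2 fold changes are pseudocounted, antisymmetric and zero-safe", {
  norm <- matrix(c(3.5, 0, 7, 15.5, 0, 7), 3, 2,
                 dimnames = list(c("g1", "g2", "g3"), c("a1", "b1")))
  fc <- log2_fold_change(norm, "a1", "b1")
  expect_equal(fc$log2fc[fc$gene_id == "g1"], 2)   # log2(16/4)
  expect_equal(fc$log2fc[fc$gene_id == "g2"], 0)   # 0/0 guarded
  expect_equal(fc$log2fc[fc$gene_id == "g3"], 0)   # equal means
  rev_fc <- log2_fold_change(norm, "b1", "a1")
  expect_equal(fc$log2fc, -rev_fc$log2fc)
  expect_error(log2_fold_change(norm, character(), "b1"), "non-empty")
  expect_error(log2_fold_change(norm, "a1", "a1"), "disjoint")
})

test_that("rpkm matches its unit definition and scaling properties", {
  m <- matrix(c(10L, 0L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  cm <- count_matrix(m, data.frame(sample_id = "s1", assay = "rna",
                                   mark = NA, condition = "N", replicate = 1),
                     gene_lengths = c(g1 = 1000, g2 = 500),
                     library_sizes = c(s1 = 1e6))
  r <- rpkm(cm)
  expect_equal(r["g1", "s1"], 10)
  expect_equal(r["g2", "s1"], 0)
  cm2 <- cm; cm2$library_sizes <- c(s1 = 2e6)
  expect_equal(rpkm(cm2), r / 2)
  # scaling counts and library sizes together cancels
  cm3 <- cm; cm3$counts <- cm$counts * 3L; cm3$library_sizes <- cm$library_sizes * 3
  expect_equal(rpkm(cm3), r)
  expect_error(rpkm(make_cm(m)), "gene_lengths")
})
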