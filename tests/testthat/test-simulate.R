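small_cfg <- function(seed = 5, ...) sim_config(n_genes = 400, seed = seed, ...)

test_that("the generator is fully deterministic given config + seed", {
  cfg <- small_cfg()
  a1 <- simulate_genome(cfg); a2 <- simulate_genome(cfg)
  expect_identical(a1, a2)
  t1 <- simulate_truth(cfg, a1); t2 <- simulate_truth(cfg, a2)
  expect_identical(t1, t2)
  c1 <- simulate_counts(cfg, a1, t1); c2 <- simulate_counts(cfg, a2, t2)
  expect_identical(c1$chip$counts, c2$chip$counts)
  expect_identical(c1$rna$counts, c2$rna$counts)
  s1 <- simulate_assays(cfg); s2 <- simulate_assays(cfg)
  expect_identical(s1, s2)
  # a different seed changes the data
  other <- simulate_genome(small_cfg(seed = 6))
  expect_false(identical(a1$start, other$start))
})

test_that("simulated genes are pairwise disjoint within chromosomes", {
  ann <- simulate_genome(small_cfg(seed = 7))
  for (ch in unique(ann$chrom)) {
    g <- ann[ann$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1L) {
      # brute-force pairwise check on the sorted intervals
      expect_true(all(g$start[-1L] >= g$end[-nrow(g)]))
    }
  }
  expect_true(all(ann$end > ann$start))
  expect_equal(sum(!ann$nuclear), round(400 * 0.01))
})

test_that("planted target status is recovered exactly from the simulated peaks", {
  cfg <- small_cfg(seed = 8)
  ann <- simulate_genome(cfg)
  truth <- simulate_truth(cfg, ann)
  peaks <- simulate_peaks(cfg, ann, truth)
  for (m in cfg$marks) {
    tg <- is_target(ann, peaks[[m]], min_bp = 150)
    expect_identical(unname(tg[truth$gene_id]),
                     truth[[paste0("target_", m)]])
  }
  # organellar genes are never targets
  org <- truth$gene_id[!truth$nuclear]
  for (m in cfg$marks) {
    expect_false(any(truth[[paste0("target_", m)]][truth$gene_id %in% org]))
  }
})

test_that("simulated counts match their negative-binomial design", {
  cfg <- sim_config(n_genes = 3000, seed = 9, dispersion = 1e-4,
                    size_factor_range = c(1, 1), depth_sdlog = 0)
  ann <- simulate_genome(cfg)
  truth <- simulate_truth(cfg, ann)
  cnt <- simulate_counts(cfg, ann, truth)
  rna_n <- cnt$rna$counts[, cnt$rna$samples$condition == "N"]
  # near-Poisson limit: variance/mean ratio centred on 1 across genes
  # (the mean, not the median: a 2-df variance estimate has median ~0.69)
  vm <- apply(rna_n, 1, var) / pmax(rowMeans(rna_n), 1)
  expect_lt(abs(mean(vm) - 1), 0.1)
  # planted null genes show small observed fold changes at depth 200
  cfg2 <- sim_config(n_genes = 2000, seed = 10)
  ann2 <- simulate_genome(cfg2)
  truth2 <- simulate_truth(cfg2, ann2)
  cnt2 <- simulate_counts(cfg2, ann2, truth2)
  rna <- cnt2$rna
  norm <- normalize_counts(rna)
  meta <- rna$samples
  fc <- log2_fold_change(norm, meta$sample_id[meta$condition == "N"],
                         meta$sample_id[meta$condition == "3h"])
  null_genes <- truth2$gene_id[truth2$expr_lfc_3h == 0]
  # at dispersion 0.05 the per-gene log2FC noise SD is ~0.28 (3 reps),
  # so the median absolute null fold change sits near 0.19
  expect_lt(median(abs(fc$log2fc[fc$gene_id %in% null_genes])), 0.25)
  # at low dispersion the same quantity drops below 0.1
  cfg3 <- sim_config(n_genes = 2000, seed = 10, dispersion = 0.01)
  ann3 <- simulate_genome(cfg3)
  truth3 <- simulate_truth(cfg3, ann3)
  rna3 <- simulate_counts(cfg3, ann3, truth3)$rna
  fc3 <- log2_fold_change(normalize_counts(rna3),
                          rna3$samples$sample_id[rna3$samples$condition == "N"],
                          rna3$samples$sample_id[rna3$samples$condition == "3h"])
  null3 <- truth3$gene_id[truth3$expr_lfc_3h == 0]
  expect_lt(median(abs(fc3$log2fc[fc3$gene_id %in% null3])), 0.1)
  # planted effects are centred near their nominal size
  up_genes <- truth2$gene_id[truth2$de_class_3h == "up"]
  expect_equal(median(fc$log2fc[fc$gene_id %in% up_genes]), 2,
               tolerance = 0.15)
})

test_that("simulated coverage is background plus peak increments", {
  cfg <- small_cfg(seed = 11)
  ann <- simulate_genome(cfg)
  truth <- simulate_truth(cfg, ann)
  peaks <- simulate_peaks(cfg, ann, truth)
  trk <- simulate_coverage(cfg, ann, peaks)[["H3K4me3_N"]]
  # a non-target gene without a peak sits at background level
  nont <- truth$gene_id[!truth$target_H3K4me3]
  covered <- peak_overlap_bp(ann, peaks$H3K4me3$N) > 0
  clean <- setdiff(nont, ann$gene_id[covered])
  g <- ann[ann$gene_id == clean[1L], ]
  prof <- gene_profile(trk, g, flank_bp = 0)
  expect_true(all(abs(prof - cfg$coverage_background) < 1e-9))
  # a target gene's body is elevated over the peak
  tg <- truth$gene_id[truth$target_H3K4me3][1L]
  g2 <- ann[ann$gene_id == tg, ]
  prof2 <- gene_profile(trk, g2, flank_bp = 0)
  expect_gt(max(prof2), cfg$coverage_background + cfg$coverage_peak_height / 2)
  # round trip through the bedGraph writer/reader is the identity
  p <- tempfile(fileext = ".bedgraph")
  write_bedgraph(trk, p)
  expect_equal(read_bedgraph(p), trk)
})

test_that("simulated assays encode the planted LT50s and fold changes", {
  cfg <- small_cfg(seed = 12, el_noise_sd = 0, ct_noise_sd = 0)
  assays <- simulate_assays(cfg)
  for (s in names(cfg$el_lt50)) {
    sub <- assays$el[assays$el$sample == s, ]
    fit <- fit_lt50(sub$temperature_c, sub$leakage_fraction)
    expect_equal(fit$lt50, unname(cfg$el_lt50[[s]]), tolerance = 0.01)
  }
  ab <- delta_ct_expression(assays$ct, "SYNCOR1")
  cold <- mean(ab[startsWith(names(ab), "3h")])
  naive <- mean(ab[startsWith(names(ab), "N")])
  expect_equal(cold / naive, 16, tolerance = 1e-6)
})

test_that("sim_config validates its fields", {
  expect_error(sim_config(n_genes = 5), "n_genes")
  expect_error(sim_config(target_prob = c(H3K4me3 = 1.2, H3K27me3 = 0.3)),
               "\\[0, 1\\]")
  expect_error(sim_config(meth_effect = -1), "positive")
  expect_error(sim_config(nope = 1), "unknown")
})
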