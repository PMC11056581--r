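flat_track <- function(value = 3, len = 100000, chrom = "Chr1") {
  coverage_track(data.frame(chrom = chrom, start = 0, end = len,
                            value = value))
}

test_that("bedGraph round trip is the identity and validation names offending lines", {
  df <- data.frame(chrom = c("Chr1", "Chr1", "Chr2"),
                   start = c(0, 500, 10), end = c(200, 900, 60),
                   value = c(1.5, 2, 0))
  trk <- coverage_track(df)
  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(trk, path)
  back <- read_bedgraph(path)
  expect_equal(back, trk)

  ov <- tempfile(fileext = ".bedgraph")
  writeLines(c("Chr1\t0\t200\t1", "Chr1\t100\t300\t2"), ov)
  expect_error(read_bedgraph(ov), "lines 1 and 2")
  short <- tempfile(fileext = ".bedgraph")
  writeLines("Chr1\t0\t200", short)
  expect_error(read_bedgraph(short), "4 columns")
})

test_that("queries in track gaps return zero and adjacent segments behave as one", {
  trk <- coverage_track(data.frame(chrom = "Chr1",
                                   start = c(1000, 1500, 3000),
                                   end = c(1500, 2000, 3500),
                                   value = c(5, 5, 2)))
  gene_gap <- tiny_annotation(2200, 2800)  # entirely in the gap
  prof <- gene_profile(trk, gene_gap[1, ], flank_bp = 100, body_bp = 200,
                       bin_bp = 10)
  expect_equal(prof[11:30], rep(0, 20))
  # two adjacent value-5 segments behave as a single segment
  gene_in <- tiny_annotation(1100, 1900)
  prof2 <- gene_profile(trk, gene_in[1, ], flank_bp = 0, body_bp = 200,
                        bin_bp = 10)
  expect_equal(prof2, rep(5, 20))
})

test_that("constant coverage gives a flat profile equal to the constant", {
  trk <- flat_track(value = 4.25)
  genes <- tiny_annotation(c(2000, 10000), c(3500, 17321),
                           strand = c("+", "-"))
  for (i in 1:2) {
    prof <- gene_profile(trk, genes[i, ])
    expect_length(prof, 300)
    expect_equal(prof, rep(4.25, 300))
  }
  mg <- metagene_profile(trk, genes)
  expect_equal(mg$profile, rep(4.25, 300))
  expect_equal(mg$n_genes, 2L)
})

test_that("relabeling a gene to the minus strand exactly reverses its profile", {
  set.seed(91)
  segs <- data.frame(chrom = "Chr1",
                     start = seq(0, 49990, by = 10),
                     end = seq(10, 50000, by = 10),
                     value = round(runif(5000) * 10, 2))
  trk <- coverage_track(segs)
  g_plus <- tiny_annotation(12345, 15000, strand = "+")
  g_minus <- tiny_annotation(12345, 15000, strand = "-")
  expect_equal(gene_profile(trk, g_minus[1, ]),
               rev(gene_profile(trk, g_plus[1, ])))
})

test_that("body resampling conserves the length-weighted mean and is exact at 2000 bp", {
  set.seed(92)
  segs <- data.frame(chrom = "Chr1",
                     start = seq(0, 29990, by = 10),
                     end = seq(10, 30000, by = 10),
                     value = round(runif(3000) * 8, 3))
  trk <- coverage_track(segs)
  # arbitrary body length: mean of body bins == raw mean over the body
  g <- tiny_annotation(5003, 12347)
  prof <- gene_profile(trk, g[1, ])
  body <- prof[51:250]
  # independent integral: sum of value * overlap over the raw segments
  ov <- pmax(0, pmin(segs$end, 12347) - pmax(segs$start, 5003))
  raw_mean <- sum(segs$value * ov) / (12347 - 5003)
  expect_equal(mean(body), raw_mean, tolerance = 1e-9)
  # 2000 bp body: scaled bins equal the native 10 bp bins
  g2 <- tiny_annotation(6000, 8000)
  prof2 <- gene_profile(trk, g2[1, ])
  native <- segs$value[segs$start >= 6000 & segs$end <= 8000]
  expect_equal(prof2[51:250], native, tolerance = 1e-12)
})

test_that("profiles are invariant under splitting segments into equal-valued halves", {
  segs <- data.frame(chrom = "Chr1", start = c(0, 4000), end = c(4000, 9000),
                     value = c(2, 7))
  half <- data.frame(chrom = "Chr1", start = c(0, 2000, 4000, 6500),
                     end = c(2000, 4000, 6500, 9000),
                     value = c(2, 2, 7, 7))
  g <- tiny_annotation(1000, 6000)
  expect_equal(gene_profile(coverage_track(segs), g[1, ]),
               gene_profile(coverage_track(half), g[1, ]))
})

test_that("aggregation is the bin-wise mean over genes", {
  trk <- coverage_track(data.frame(chrom = "Chr1", start = c(0, 50000),
                                   end = c(50000, 100000), value = c(2, 4)))
  genes <- tiny_annotation(c(10000, 60000), c(12000, 62000))
  mg <- metagene_profile(trk, genes)
  expect_equal(mg$profile, rep(3, 300))
  one <- metagene_profile(trk, genes, genes = "g001")
  expect_equal(one$profile, gene_profile(trk, genes[1, ]))
  expect_error(metagene_profile(trk, genes, genes = "nope"), "not in annotation")
})
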