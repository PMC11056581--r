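#' Configuration for the synthetic cold-stress dataset
#'
#' Builds and validates the parameter set for the synthetic-data
#' generator. The defaults emulate the design of the study the package
#' analyses: two histone marks (H3K4me3, H3K27me3) profiled in naive
#' plants and after 3 h and 3 d of cold with 2 ChIP replicates, RNA-seq
#' with 3 replicates, negative-binomially distributed gene-body counts,
#' planted differential-methylation and differential-expression labels
#' with configurable effect sizes, and a coupling parameter `rho` that
#' plants the observed preference of cold-induced genes to gain H3K4me3
#' and lose H3K27me3 (`rho = 0` gives the null of independent DM and DE).
#'
#' @param n_genes Number of genes (default 5000).
#' @param n_chroms Nuclear chromosomes (default 3; organellar genes go on
#'   ChrM/ChrC).
#' @param seed Mandatory integer seed; every output is reproducible from
#'   the configuration plus this seed.
#' @param ... Overrides for any default listed below.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 5000, n_chroms = 3, seed = 1, ...) {
  cfg <- list(
    n_genes = n_genes,
    n_chroms = n_chroms,
    seed = seed,
    gene_length_meanlog = log(2000),
    gene_length_sdlog = 0.5,
    min_gene_length = 300,
    intergenic_gap = 300,
    organelle_fraction = 0.01,
    marks = c("H3K4me3", "H3K27me3"),
    conditions = c("N", "3h", "3d"),
    chip_replicates = 2L,
    rna_replicates = 3L,
    target_prob = c(H3K4me3 = 0.64, H3K27me3 = 0.30),
    dm_fraction = list(H3K4me3 = c("3h" = 0.21, "3d" = 0.13),
                       H3K27me3 = c("3h" = 0.09, "3d" = 0.11)),
    gain_share = 2 / 3,
    persistence = c(H3K4me3 = 0.11, H3K27me3 = 0.45),
    meth_effect = 1.5,
    de_fraction = list(up = c("3h" = 0.06, "3d" = 0.06),
                       down = c("3h" = 0.05, "3d" = 0.05)),
    de_overlap = 0.5,
    expr_effect = 2,
    rho = c(H3K4me3 = 0.3, H3K27me3 = 0.15),
    rho_direction = c(H3K4me3 = "gain", H3K27me3 = "loss"),
    dispersion = 0.05,
    mean_depth = 200,
    depth_sdlog = 0.5,
    background_depth_factor = 0.1,
    size_factor_range = c(0.5, 2),
    coverage_background = 1,
    coverage_peak_height = 8,
    el_lt50 = c(N = -5, "3d" = -8.5),
    el_bottom = 0.05,
    el_top = 0.95,
    el_slope = -0.5,
    el_noise_sd = 0.02,
    el_temperatures = c(-1, -3, -5, -7, -9, -11),
    el_replicates = 4L,
    ct_housekeeping = c(ACTIN2 = 24, PDF = 25, TIP41 = 26),
    ct_targets = list(SYNCOR1 = c(N = 1, "3h" = 16, "3d" = 4),
                      SYNCOR2 = c(N = 1, "3h" = 2, "3d" = 8)),
    ct_noise_sd = 0.1,
    qpcr_replicates = 3L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (is.null(cfg$seed) || !is.numeric(cfg$seed)) {
    stop("sim_config requires a numeric seed", call. = FALSE)
  }
  if (cfg$n_genes < 10) stop("n_genes must be >= 10", call. = FALSE)
  probs <- c(cfg$target_prob, unlist(cfg$dm_fraction),
             unlist(cfg$de_fraction), cfg$organelle_fraction,
             cfg$persistence, cfg$rho, cfg$de_overlap, cfg$gain_share)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities/fractions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (cfg$meth_effect <= 0 || cfg$expr_effect <= 0) {
    stop("effect sizes must be positive", call. = FALSE)
  }
  if (!all(names(cfg$dm_fraction) %in% cfg$marks)) {
    stop("dm_fraction must be keyed by mark", call. = FALSE)
  }
  if (length(cfg$conditions) < 2L) {
    stop("need a baseline condition plus >= 1 stress timepoint",
         call. = FALSE)
  }
  invisible(TRUE)
}

sim_timepoints <- function(cfg) cfg$conditions[-1L]

#' Simulate a gene annotation
#'
#' Places non-overlapping genes (log-normal lengths, median 2 kb by
#' default) on `n_chroms` nuclear chromosomes, with roughly
#' `organelle_fraction` of genes on ChrM/ChrC so that the nuclear-encoded
#' filter has something to remove.
#'
#' @param cfg A `sim_config`.
#' @return A `gene_annotation` with chromosome lengths attached.
#' @export
simulate_genome <- function(cfg) {
  with_seed(cfg$seed + 101, {
    n <- cfg$n_genes
    n_org <- round(n * cfg$organelle_fraction)
    n_nuc <- n - n_org
    chroms <- c(rep(paste0("Chr", seq_len(cfg$n_chroms)),
                    length.out = n_nuc),
                rep(c("ChrM", "ChrC"), length.out = n_org))
    lens <- pmax(cfg$min_gene_length,
                 round(stats::rlnorm(n, cfg$gene_length_meanlog,
                                     cfg$gene_length_sdlog)))
    gaps <- cfg$intergenic_gap + round(stats::rexp(n, 1 / 200))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    ids <- sprintf("SYNG%05d", seq_len(n))
    start <- integer(n); end <- integer(n)
    chrom_lengths <- c()
    for (ch in unique(chroms)) {
      idx <- which(chroms == ch)
      s <- cumsum(gaps[idx] + c(0, lens[idx][-length(idx)]))
      start[idx] <- s
      end[idx] <- s + lens[idx]
      chrom_lengths[ch] <- max(end[idx]) + 1000L
    }
    gene_annotation(gene_id = ids, chrom = chroms, start = start, end = end,
                    strand = strand, chrom_lengths = chrom_lengths)
  })
}

#' Plant the ground-truth labels
#'
#' Draws per-mark target status, differential-expression classes per
#' timepoint (with the configured overlap between timepoints) and
#' differential-methylation classes per mark and timepoint (with the
#' configured cross-timepoint persistence and gain share), then applies
#' the DM-DE coupling: an up-regulated target gene is converted to the
#' mark's coupled DM direction with probability `rho[mark]`.
#'
#' @param cfg A `sim_config`.
#' @param ann Annotation from [simulate_genome()].
#' @return A `sim_truth` data frame with one row per gene: `nuclear`,
#'   `target_<mark>`, `de_class_<tp>`, `expr_lfc_<tp>`,
#'   `dm_<mark>_<tp>`, `meth_lfc_<mark>_<tp>`.
#' @export
simulate_truth <- function(cfg, ann) {
  with_seed(cfg$seed + 202, {
    genes <- ann$gene_id
    n <- length(genes)
    tps <- sim_timepoints(cfg)
    truth <- data.frame(gene_id = genes, nuclear = ann$nuclear,
                        stringsAsFactors = FALSE)
    for (m in cfg$marks) {
      tg <- stats::rbinom(n, 1L, cfg$target_prob[[m]]) == 1L
      tg[!ann$nuclear] <- FALSE
      truth[[paste0("target_", m)]] <- tg
    }
    # --- differential expression, with cross-timepoint overlap ---
    pick_overlapping <- function(frac_by_tp, pool_by_tp) {
      sets <- list()
      prev <- character()
      for (tp in tps) {
        want <- round(frac_by_tp[[tp]] * n)
        pool <- pool_by_tp[[tp]]
        n_shared <- min(round(cfg$de_overlap * want),
                        length(intersect(prev, pool)))
        shared <- if (n_shared > 0) {
          sample(intersect(prev, pool), n_shared)
        } else character()
        rest_pool <- setdiff(pool, prev)
        n_new <- min(want - length(shared), length(rest_pool))
        sets[[tp]] <- c(shared, if (n_new > 0) sample(rest_pool, n_new))
        prev <- sets[[tp]]
      }
      sets
    }
    up_pool <- stats::setNames(rep(list(genes), length(tps)), tps)
    up <- pick_overlapping(cfg$de_fraction$up, up_pool)
    down_pool <- lapply(tps, function(tp) setdiff(genes, unlist(up)))
    names(down_pool) <- tps
    down <- pick_overlapping(cfg$de_fraction$down, down_pool)
    for (tp in tps) {
      cl <- rep("none", n)
      cl[genes %in% up[[tp]]] <- "up"
      cl[genes %in% down[[tp]]] <- "down"
      truth[[paste0("de_class_", tp)]] <- cl
      truth[[paste0("expr_lfc_", tp)]] <-
        ifelse(cl == "up", cfg$expr_effect,
               ifelse(cl == "down", -cfg$expr_effect, 0))
    }
    # --- differential methylation, per mark, with persistence ---
    pick_persistent <- function(eligible, n1, n2, p) {
      n1 <- min(n1, length(eligible)); n2 <- min(n2, length(eligible))
      a <- if (n1 > 0) sample(eligible, n1) else character()
      n_both <- min(round(p * (n1 + n2) / (1 + p)), n1, n2)
      shared <- if (n_both > 0) sample(a, n_both) else character()
      rest <- setdiff(eligible, a)
      n_new <- min(n2 - length(shared), length(rest))
      b <- c(shared, if (n_new > 0) sample(rest, n_new))
      stats::setNames(list(a, b), tps[1:2])
    }
    for (m in cfg$marks) {
      targ <- genes[truth[[paste0("target_", m)]]]
      fr <- cfg$dm_fraction[[m]]
      nt <- length(targ)
      gain <- pick_persistent(targ,
                              round(fr[[tps[1L]]] * cfg$gain_share * nt),
                              round(fr[[tps[2L]]] * cfg$gain_share * nt),
                              cfg$persistence[[m]])
      loss_pool <- lapply(tps[1:2], function(tp) setdiff(targ, gain[[tp]]))
      loss <- pick_persistent(Reduce(union, loss_pool),
                              round(fr[[tps[1L]]] * (1 - cfg$gain_share) * nt),
                              round(fr[[tps[2L]]] * (1 - cfg$gain_share) * nt),
                              cfg$persistence[[m]])
      for (tp in tps) {
        cl <- rep("none", n)
        cl[genes %in% gain[[tp]]] <- "gain"
        cl[genes %in% loss[[tp]] & cl == "none"] <- "loss"
        cl[!(genes %in% targ)] <- "none"
        # DM-DE coupling: induced targets flip to the coupled direction
        induced <- truth[[paste0("de_class_", tp)]] == "up" & genes %in% targ
        flip <- induced & stats::rbinom(n, 1L, cfg$rho[[m]]) == 1L
        cl[flip] <- cfg$rho_direction[[m]]
        truth[[paste0("dm_", m, "_", tp)]] <- cl
        truth[[paste0("meth_lfc_", m, "_", tp)]] <-
          ifelse(cl == "gain", cfg$meth_effect,
                 ifelse(cl == "loss", -cfg$meth_effect, 0))
      }
    }
    class(truth) <- c("sim_truth", "data.frame")
    truth
  })
}

#' Simulate peak calls consistent with the planted target status
#'
#' Target genes carry a peak covering 80% of the body (well above the
#' 150 bp target threshold) in every condition; genes planted as gaining
#' a mark get an enlarged peak and genes losing it a shrunken peak in the
#' corresponding cold condition. A third of non-target genes receive a
#' decoy peak overlapping exactly 100 bp of the body -- below the target
#' threshold in every condition -- so that the overlap gate is actually
#' exercised.
#'
#' @param cfg A `sim_config`.
#' @param ann Annotation from [simulate_genome()].
#' @param truth Truth table from [simulate_truth()].
#' @return Nested list: `peaks[[mark]][[condition]]` is a `peak_set`.
#' @export
simulate_peaks <- function(cfg, ann, truth) {
  with_seed(cfg$seed + 303, {
    n <- nrow(ann)
    L <- ann$end - ann$start
    out <- list()
    for (m in cfg$marks) {
      targ <- truth[[paste0("target_", m)]]
      decoy <- !targ & stats::rbinom(n, 1L, 1 / 3) == 1L
      out[[m]] <- list()
      for (cond in cfg$conditions) {
        dmcl <- if (cond == cfg$conditions[1L]) rep("none", n) else
          truth[[paste0("dm_", m, "_", cond)]]
        ps <- ifelse(dmcl == "gain", ann$start + floor(0.02 * L),
                     ifelse(dmcl == "loss", ann$start + floor(0.35 * L),
                            ann$start + floor(0.1 * L)))
        pe <- ifelse(dmcl == "gain", ann$end - floor(0.02 * L),
                     ifelse(dmcl == "loss", ann$start + floor(0.65 * L),
                            ann$start + floor(0.1 * L) + floor(0.8 * L)))
        keep <- targ
        chrom <- c(ann$chrom[keep], ann$chrom[decoy])
        s <- c(ps[keep], ann$start[decoy])
        e <- c(pe[keep], ann$start[decoy] + 100L)
        out[[m]][[cond]] <- peak_set(chrom, s, e, mark = m, condition = cond)
      }
    }
    out
  })
}

sim_sample_sheet <- function(cfg, assay, mark = NA_character_) {
  reps <- if (assay == "chip") cfg$chip_replicates else cfg$rna_replicates
  grid <- expand.grid(replicate = seq_len(reps), condition = cfg$conditions,
                      stringsAsFactors = FALSE)
  prefix <- if (assay == "chip") mark else "rna"
  data.frame(
    sample_id = sprintf("%s_%s_r%d", prefix, grid$condition, grid$replicate),
    assay = assay, mark = mark, condition = grid$condition,
    replicate = grid$replicate, stringsAsFactors = FALSE
  )
}

#' Simulate ChIP and RNA count matrices
#'
#' Per gene and sample, counts are negative binomial with mean
#' `mu_gene * 2^(planted log2FC at the sample's condition) * sf_sample`
#' and the configured dispersion; baseline means are log-normal around
#' `mean_depth` (scaled down by `background_depth_factor` for ChIP
#' signal on non-target genes) and true per-sample size factors are
#' drawn log-uniformly from `size_factor_range`.
#'
#' @param cfg A `sim_config`.
#' @param ann Annotation (for gene lengths).
#' @param truth Truth table from [simulate_truth()].
#' @return List with `chip` and `rna` `count_matrix` objects and the
#'   `true_size_factors` used.
#' @export
simulate_counts <- function(cfg, ann, truth) {
  with_seed(cfg$seed + 404, {
    n <- nrow(truth)
    lens <- stats::setNames(ann$end - ann$start, ann$gene_id)
    draw_sf <- function(k) {
      exp(stats::runif(k, log(cfg$size_factor_range[1L]),
                       log(cfg$size_factor_range[2L])))
    }
    nb <- function(mu) stats::rnbinom(length(mu), mu = mu,
                                      size = 1 / max(cfg$dispersion, 1e-12))
    sheets <- lapply(cfg$marks, function(m) sim_sample_sheet(cfg, "chip", m))
    chip_meta <- do.call(rbind, sheets)
    chip_sf <- stats::setNames(draw_sf(nrow(chip_meta)), chip_meta$sample_id)
    chip <- matrix(0L, n, nrow(chip_meta),
                   dimnames = list(truth$gene_id, chip_meta$sample_id))
    for (m in cfg$marks) {
      targ <- truth[[paste0("target_", m)]]
      base <- stats::rlnorm(n, log(cfg$mean_depth), cfg$depth_sdlog)
      base[!targ] <- base[!targ] * cfg$background_depth_factor
      for (j in which(chip_meta$mark == m)) {
        cond <- chip_meta$condition[j]
        lfc <- if (cond == cfg$conditions[1L]) 0 else
          truth[[paste0("meth_lfc_", m, "_", cond)]]
        chip[, j] <- nb(base * 2^lfc * chip_sf[j])
      }
    }
    rna_meta <- sim_sample_sheet(cfg, "rna")
    rna_sf <- stats::setNames(draw_sf(nrow(rna_meta)), rna_meta$sample_id)
    rna <- matrix(0L, n, nrow(rna_meta),
                  dimnames = list(truth$gene_id, rna_meta$sample_id))
    base_e <- stats::rlnorm(n, log(cfg$mean_depth), cfg$depth_sdlog)
    for (j in seq_len(nrow(rna_meta))) {
      cond <- rna_meta$condition[j]
      lfc <- if (cond == cfg$conditions[1L]) 0 else
        truth[[paste0("expr_lfc_", cond)]]
      rna[, j] <- nb(base_e * 2^lfc * rna_sf[j])
    }
    list(
      chip = count_matrix(chip, chip_meta, gene_lengths = lens),
      rna = count_matrix(rna, rna_meta, gene_lengths = lens),
      true_size_factors = list(chip = chip_sf, rna = rna_sf)
    )
  })
}

#' Simulate coverage tracks matching the simulated peaks
#'
#' Piecewise-constant coverage: a flat background plus a constant
#' increment over every peak interval. Deterministic given the peaks.
#'
#' @param cfg A `sim_config`.
#' @param ann Annotation (for chromosome lengths).
#' @param peaks Output of [simulate_peaks()].
#' @return Named list `"<mark>_<condition>"` of `coverage_track` objects.
#' @export
simulate_coverage <- function(cfg, ann, peaks) {
  chrom_lengths <- attr(ann, "chrom_lengths")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(ann$end, ann$chrom, max) + 1000
  }
  out <- list()
  for (m in names(peaks)) {
    for (cond in names(peaks[[m]])) {
      pk <- peaks[[m]][[cond]]
      segs <- list()
      for (ch in names(chrom_lengths)) {
        cl <- as.numeric(chrom_lengths[[ch]])
        p <- pk[pk$chrom == ch, , drop = FALSE]
        bound <- sort(unique(c(0, p$start, p$end, cl)))
        s <- bound[-length(bound)]; e <- bound[-1L]
        inpeak <- vapply(s, function(x) {
          any(p$start <= x & x < p$end)
        }, logical(1L))
        segs[[ch]] <- data.frame(
          chrom = ch, start = s, end = e,
          value = cfg$coverage_background +
            ifelse(inpeak, cfg$coverage_peak_height, 0),
          stringsAsFactors = FALSE
        )
      }
      out[[paste0(m, "_", cond)]] <- coverage_track(do.call(rbind, segs))
    }
  }
  out
}

#' Simulate electrolyte-leakage curves and qPCR Ct tables
#'
#' EL curves follow the four-parameter logistic with the configured LT50
#' per sample plus Gaussian noise; Ct tables encode known fold changes
#' between conditions via `Ct = mean(housekeeping) - log2(abundance)`.
#'
#' @param cfg A `sim_config`.
#' @return List with `el` (data frame: sample, temperature_c,
#'   leakage_fraction, replicate) and `ct` (data frame: sample, gene, ct,
#'   is_housekeeping, condition).
#' @export
simulate_assays <- function(cfg) {
  with_seed(cfg$seed + 505, {
    rows <- list()
    for (s in names(cfg$el_lt50)) {
      for (temp in cfg$el_temperatures) {
        mu <- cfg$el_bottom + (cfg$el_top - cfg$el_bottom) /
          (1 + 10^(cfg$el_slope * (cfg$el_lt50[[s]] - temp)))
        for (r in seq_len(cfg$el_replicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample = s, temperature_c = temp,
            leakage_fraction = min(1, max(0, mu +
              stats::rnorm(1L, 0, cfg$el_noise_sd))),
            replicate = r, stringsAsFactors = FALSE
          )
        }
      }
    }
    el <- do.call(rbind, rows)
    ct_rows <- list()
    hk <- cfg$ct_housekeeping
    for (cond in cfg$conditions) {
      for (r in seq_len(cfg$qpcr_replicates)) {
        sample <- sprintf("%s_r%d", cond, r)
        for (g in names(hk)) {
          ct_rows[[length(ct_rows) + 1L]] <- data.frame(
            sample = sample, gene = g,
            ct = hk[[g]] + stats::rnorm(1L, 0, cfg$ct_noise_sd),
            is_housekeeping = TRUE, condition = cond,
            stringsAsFactors = FALSE
          )
        }
        for (g in names(cfg$ct_targets)) {
          abundance <- cfg$ct_targets[[g]][[cond]]
          ct_rows[[length(ct_rows) + 1L]] <- data.frame(
            sample = sample, gene = g,
            ct = mean(hk) - log2(abundance) +
              stats::rnorm(1L, 0, cfg$ct_noise_sd),
            is_housekeeping = FALSE, condition = cond,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    list(el = el, ct = do.call(rbind, ct_rows))
  })
}

#' Generate and write the full synthetic dataset
#'
#' Runs every simulation step and writes the dataset in the plain-text
#' formats the pipeline consumes: GFF3 annotation, one BED peak file per
#' (mark, condition), count and sample-sheet TSVs, bedGraph coverage
#' tracks, assay CSVs, the ground-truth table (JSON) and the resolved
#' configuration (JSON). Output is byte-identical across runs with the
#' same configuration and seed.
#'
#' @param cfg A `sim_config`.
#' @param dir Output directory (created if needed).
#' @param coverage Also write bedGraph tracks (default TRUE).
#' @return Invisibly, a manifest list of the files written.
#' @export
simulate_dataset <- function(cfg, dir, coverage = TRUE) {
  validate_sim_config(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(dir, "assays"), showWarnings = FALSE)
  ann <- simulate_genome(cfg)
  truth <- simulate_truth(cfg, ann)
  peaks <- simulate_peaks(cfg, ann, truth)
  counts <- simulate_counts(cfg, ann, truth)
  assays <- simulate_assays(cfg)
  manifest <- list()
  add <- function(key, path) manifest[[key]] <<- path
  write_annotation(ann, file.path(dir, "annotation.gff3"))
  add("annotation", "annotation.gff3")
  for (m in names(peaks)) {
    for (cond in names(peaks[[m]])) {
      rel <- file.path("peaks", sprintf("%s_%s.bed", m, cond))
      write_peaks(peaks[[m]][[cond]], file.path(dir, rel))
      add(paste0("peaks_", m, "_", cond), rel)
    }
  }
  write_counts(counts$chip, file.path(dir, "counts_chip.tsv"),
               file.path(dir, "samples_chip.tsv"))
  write_counts(counts$rna, file.path(dir, "counts_rna.tsv"),
               file.path(dir, "samples_rna.tsv"))
  add("counts_chip", "counts_chip.tsv"); add("counts_rna", "counts_rna.tsv")
  add("samples_chip", "samples_chip.tsv"); add("samples_rna", "samples_rna.tsv")
  write_tsv(data.frame(gene_id = ann$gene_id, length = ann$end - ann$start,
                       stringsAsFactors = FALSE),
            file.path(dir, "gene_lengths.tsv"))
  add("gene_lengths", "gene_lengths.tsv")
  if (coverage) {
    dir.create(file.path(dir, "coverage"), showWarnings = FALSE)
    tracks <- simulate_coverage(cfg, ann, peaks)
    for (nm in names(tracks)) {
      rel <- file.path("coverage", paste0(nm, ".bedgraph"))
      write_bedgraph(tracks[[nm]], file.path(dir, rel))
      add(paste0("coverage_", nm), rel)
    }
  }
  utils::write.csv(assays$el,
                   file.path(dir, "assays", "electrolyte_leakage.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(assays$ct, file.path(dir, "assays", "qpcr_ct.csv"),
                   row.names = FALSE, quote = FALSE)
  add("el", file.path("assays", "electrolyte_leakage.csv"))
  add("ct", file.path("assays", "qpcr_ct.csv"))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  add("truth", "truth.json")
  cfg_out <- unclass(cfg)
  cfg_out$ct_targets <- lapply(cfg_out$ct_targets, as.list)
  jsonlite::write_json(cfg_out, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  add("config", "config.json")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a ground-truth table written by [simulate_dataset()]
#' @param path Path to `truth.json`.
#' @return A `sim_truth` data frame.
#' @export
read_truth <- function(path) {
  lst <- jsonlite::fromJSON(path)
  truth <- as.data.frame(lst, stringsAsFactors = FALSE)
  class(truth) <- c("sim_truth", "data.frame")
  truth
}
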