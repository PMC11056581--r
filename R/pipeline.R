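#' Analysis-pipeline configuration
#'
#' Thresholds and parameters for [run_analysis()], with the study's
#' defaults: DM |log2FC| >= 0.5 on mark targets (>= 150 bp single-peak
#' body overlap in any condition), DEGs at |log2FC| >= 1 with BH-adjusted
#' p < 0.05 restricted to nuclear-encoded genes, and metagene profiles
#' with a 2000 bp scaled body, 500 bp flanks and 10 bp bins.
#'
#' @param ... Overrides for any default field.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    baseline_condition = "N",
    dm_lfc = 0.5,
    de_lfc = 1,
    alpha = 0.05,
    min_overlap_bp = 150,
    pseudocount = 0.5,
    nuclear_only = TRUE,
    organelle_chroms = c("ChrM", "ChrC", "Mt", "Pt"),
    flank_bp = 500,
    body_bp = 2000,
    bin_bp = 10,
    metagene_max_genes = 1000,
    rpkm_log_pseudocount = 0.5
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown pipeline_config field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(dots)] <- dots
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  problems <- character()
  for (f in c("dm_lfc", "de_lfc", "alpha", "min_overlap_bp", "pseudocount",
              "flank_bp", "body_bp", "bin_bp")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      problems <- c(problems, sprintf("%s must be a single positive number", f))
    }
  }
  if (is.numeric(cfg$alpha) && length(cfg$alpha) == 1L &&
      is.finite(cfg$alpha) && cfg$alpha >= 1) {
    problems <- c(problems, "alpha must be < 1")
  }
  if (length(problems)) {
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] fields
#'   (and optionally a `simulate:` block of [sim_config()] fields).
#' @return A `pipeline_config`; any `simulate` block is attached as the
#'   `simulate` attribute.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- y$simulate
  y$simulate <- NULL
  cfg <- do.call(pipeline_config, y)
  attr(cfg, "simulate") <- sim
  cfg
}

#' Generate a synthetic dataset directory
#'
#' Thin wrapper over [simulate_dataset()] accepting either a
#' `sim_config` or a plain list of its fields.
#'
#' @param sim A `sim_config` or a list of [sim_config()] arguments.
#' @param out_dir Output directory.
#' @return Invisibly, the written-file manifest.
#' @export
run_simulate <- function(sim, out_dir) {
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, as.list(sim))
  simulate_dataset(sim, out_dir)
}

# discover peak files "<mark>_<condition>.bed" in a dataset directory
discover_peaks <- function(data_dir) {
  files <- list.files(file.path(data_dir, "peaks"), pattern = "\\.bed$")
  if (length(files) == 0L) return(NULL)
  stem <- sub("\\.bed$", "", files)
  parts <- regmatches(stem, regexpr("_[^_]+$", stem))
  data.frame(file = file.path(data_dir, "peaks", files),
             mark = sub("_[^_]+$", "", stem),
             condition = sub("^_", "", parts), stringsAsFactors = FALSE)
}

preflight <- function(data_dir) {
  problems <- character()
  need <- c("annotation.gff3", "counts_chip.tsv", "samples_chip.tsv",
            "counts_rna.tsv", "samples_rna.tsv")
  for (f in need) {
    if (!file.exists(file.path(data_dir, f))) {
      problems <- c(problems, paste("missing input:", f))
    }
  }
  pk <- discover_peaks(data_dir)
  if (is.null(pk)) problems <- c(problems, "missing input: peaks/*.bed")
  if (length(problems)) {
    stop("pre-flight validation failed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Run the full gene-centric analysis on a dataset directory
#'
#' Reads the annotation, peak calls and count matrices, then computes:
#' per-mark target status, per-contrast methylation fold changes and DM
#' calls, per-contrast differential expression (NB Wald + BH) and DEG
#' sets, cross-mark DM intersections with same/opposite-direction
#' tallies, DM persistence across timepoints, the mark-by-timepoint
#' Spearman correlation matrix between methylation and expression
#' changes, induced-gene DM categories with pairwise expression
#' comparisons, and (when coverage tracks are present) metagene profiles
#' over target genes. All tables are written as TSV and the headline
#' numbers as `summary.json`. The analysis is deterministic: rerunning
#' on the same inputs reproduces every output byte for byte.
#'
#' @param data_dir Dataset directory (layout as written by
#'   [simulate_dataset()]).
#' @param out_dir Output directory for tables and the summary.
#' @param config A `pipeline_config`.
#' @return Invisibly, the summary list.
#' @export
run_analysis <- function(data_dir, out_dir, config = pipeline_config()) {
  validate_pipeline_config(config)
  preflight(data_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ann <- read_annotation(file.path(data_dir, "annotation.gff3"),
                         organelle_chroms = config$organelle_chroms)
  nuclear <- stats::setNames(ann$nuclear, ann$gene_id)
  pk_files <- discover_peaks(data_dir)
  marks <- unique(pk_files$mark)
  peaksets <- lapply(marks, function(m) {
    rows <- pk_files[pk_files$mark == m, , drop = FALSE]
    stats::setNames(
      lapply(seq_len(nrow(rows)), function(i) {
        read_peaks(rows$file[i], mark = m, condition = rows$condition[i])
      }),
      rows$condition
    )
  })
  names(peaksets) <- marks
  chip <- read_counts(file.path(data_dir, "counts_chip.tsv"),
                      file.path(data_dir, "samples_chip.tsv"),
                      gene_lengths_path =
                        if (file.exists(file.path(data_dir, "gene_lengths.tsv")))
                          file.path(data_dir, "gene_lengths.tsv") else NULL)
  rna <- read_counts(file.path(data_dir, "counts_rna.tsv"),
                     file.path(data_dir, "samples_rna.tsv"),
                     gene_lengths_path =
                       if (file.exists(file.path(data_dir, "gene_lengths.tsv")))
                         file.path(data_dir, "gene_lengths.tsv") else NULL)
  base <- config$baseline_condition
  tps <- setdiff(unique(chip$samples$condition), base)
  contrast_name <- function(tp) paste0(tp, "_vs_", base)

  targets <- lapply(marks, function(m) {
    is_target(ann, peaksets[[m]], min_bp = config$min_overlap_bp)
  })
  names(targets) <- marks

  # --- ChIP fold changes and DM calls ---
  fc_meth <- list(); dm <- list()
  for (m in marks) {
    cols <- chip$samples$sample_id[chip$samples$mark == m]
    sub <- chip$counts[, cols, drop = FALSE]
    sf <- size_factors(sub)
    norm <- normalize_counts(sub, sf)
    meta <- chip$samples[match(cols, chip$samples$sample_id), ]
    for (tp in tps) {
      fc <- log2_fold_change(norm,
                             meta$sample_id[meta$condition == base],
                             meta$sample_id[meta$condition == tp],
                             pseudocount = config$pseudocount)
      key <- paste0(m, ".", tp)
      fc_meth[[key]] <- fc
      dm[[key]] <- call_dm(fc, targets[[m]], lfc_threshold = config$dm_lfc,
                           mark = m, contrast = contrast_name(tp))
      write_tsv(cbind(fc[, c("gene_id", "base_mean_a", "base_mean_b")],
                      log2fc = fc$log2fc,
                      is_target = dm[[key]]$is_target,
                      dm_class = dm[[key]]$dm_class),
                file.path(out_dir, sprintf("dm_%s_%s.tsv", m,
                                           contrast_name(tp))))
    }
  }

  # --- differential expression ---
  rna_sf <- size_factors(rna)
  de <- list(); degs <- list()
  for (tp in tps) {
    meta <- rna$samples
    de[[tp]] <- de_test(rna,
                        meta$sample_id[meta$condition == base],
                        meta$sample_id[meta$condition == tp],
                        sf = rna_sf, pseudocount = config$pseudocount,
                        nuclear = nuclear, lfc_threshold = config$de_lfc,
                        alpha = config$alpha)
    degs[[tp]] <- call_degs(de[[tp]], lfc_threshold = config$de_lfc,
                            alpha = config$alpha,
                            nuclear_only = config$nuclear_only)
    write_tsv(as.data.frame(de[[tp]]),
              file.path(out_dir, sprintf("de_%s.tsv", contrast_name(tp))))
  }

  # --- integration ---
  summary <- list(
    n_genes = nrow(ann),
    n_nuclear = sum(ann$nuclear),
    targets = lapply(targets, sum),
    dm_counts = dm_summary(dm),
    de_counts = lapply(de, function(d) {
      dg <- call_degs(d, lfc_threshold = config$de_lfc,
                      alpha = config$alpha,
                      nuclear_only = config$nuclear_only)
      list(up = length(dg$up), down = length(dg$down))
    })
  )
  if (length(marks) == 2L) {
    summary$co_targets <- co_target_counts(targets[[marks[1L]]],
                                           targets[[marks[2L]]])
    inter <- list()
    for (tp in tps) {
      pair <- stats::setNames(
        list(dm[[paste0(marks[1L], ".", tp)]],
             dm[[paste0(marks[2L], ".", tp)]]), marks)
      inter[[tp]] <- intersect_dm_sets(pair)
      write_tsv(inter[[tp]]$exclusive,
                file.path(out_dir, sprintf("intersections_%s.tsv", tp)))
    }
    summary$cross_mark <- lapply(inter, function(x) {
      list(same_direction = x$same_direction,
           opposite_direction = x$opposite_direction,
           union_size = x$union_size)
    })
  }
  if (length(tps) >= 2L) {
    pers <- list()
    for (m in marks) {
      for (dir in c("gain", "loss")) {
        row <- dm_persistence(dm[[paste0(m, ".", tps[1L])]],
                              dm[[paste0(m, ".", tps[2L])]], dir)
        row <- cbind(mark = m, row)
        pers[[paste0(m, "_", dir)]] <- row
      }
    }
    pers_df <- do.call(rbind, pers)
    rownames(pers_df) <- NULL
    write_tsv(pers_df, file.path(out_dir, "persistence.tsv"))
    summary$persistence <- pers_df
  }
  # correlation matrix over (mark, meth timepoint, expr timepoint)
  cor_rows <- list()
  for (m in marks) {
    for (t_meth in tps) {
      for (t_expr in tps) {
        dg <- degs[[t_expr]]
        res <- tryCatch(
          correlate_dm_de(fc_meth[[paste0(m, ".", t_meth)]],
                          de[[t_expr]][, c("gene_id", "log2fc")],
                          c(dg$up, dg$down), targets[[m]]),
          error = function(e) NULL
        )
        cor_rows[[length(cor_rows) + 1L]] <- data.frame(
          mark = m, meth_timepoint = t_meth, expr_timepoint = t_expr,
          rho = if (is.null(res)) NA_real_ else res$rho,
          pvalue = if (is.null(res)) NA_real_ else res$pvalue,
          n = if (is.null(res)) 0L else res$n, stringsAsFactors = FALSE
        )
      }
    }
  }
  cor_df <- do.call(rbind, cor_rows)
  write_tsv(cor_df, file.path(out_dir, "correlation_matrix.tsv"))
  summary$correlations <- cor_df

  # --- induced-gene categories ---
  if (length(tps) >= 2L) {
    induced <- unique(unlist(lapply(degs, `[[`, "up")))
    summary$induced <- list(n_induced = length(induced))
    for (m in marks) {
      cats <- assign_induced_categories(dm[[paste0(m, ".", tps[1L])]],
                                        dm[[paste0(m, ".", tps[2L])]],
                                        induced)
      write_tsv(cats, file.path(out_dir,
                                sprintf("induced_categories_%s.tsv", m)))
      tab <- table(cats$category)
      summary$induced[[m]] <- stats::setNames(as.list(as.integer(tab)),
                                              names(tab))
      if (nrow(cats) >= 4L && sum(table(cats$category) > 1L) >= 2L) {
        vals <- stats::setNames(de[[tps[length(tps)]]]$log2fc,
                                de[[tps[length(tps)]]]$gene_id)
        cmp <- tryCatch(compare_categories(vals, cats),
                        error = function(e) NULL)
        if (!is.null(cmp)) {
          write_tsv(cmp, file.path(out_dir,
                                   sprintf("category_tests_%s.tsv", m)))
        }
      }
    }
  }

  # --- metagene profiles over target genes ---
  cov_dir <- file.path(data_dir, "coverage")
  if (dir.exists(cov_dir)) {
    for (m in marks) {
      tg <- names(targets[[m]])[targets[[m]]]
      if (length(tg) > config$metagene_max_genes) {
        idx <- round(seq(1L, length(tg),
                         length.out = config$metagene_max_genes))
        tg <- tg[idx]
      }
      if (length(tg) == 0L) next
      for (cond in c(base, tps)) {
        f <- file.path(cov_dir, sprintf("%s_%s.bedgraph", m, cond))
        if (!file.exists(f)) next
        prof <- metagene_profile(read_bedgraph(f), ann, genes = tg,
                                 flank_bp = config$flank_bp,
                                 body_bp = config$body_bp,
                                 bin_bp = config$bin_bp)
        write_tsv(data.frame(bin = seq_along(prof$profile),
                             mean_coverage = prof$profile),
                  file.path(out_dir,
                            sprintf("metagene_%s_%s.tsv", m, cond)))
      }
    }
  }

  summary$config <- unclass(config)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(summary)
}

#' Render a human-readable report from an analysis directory
#'
#' Writes `report.md` (plus PNG figures where the corresponding tables
#' exist) summarizing target counts, DM/DE calls, persistence,
#' correlations and metagene profiles. Missing tables are noted in the
#' report rather than raising errors, so partial analysis directories
#' still produce a (partial) report. Output is deterministic.
#'
#' @param analysis_dir Directory written by [run_analysis()].
#' @param out_dir Output directory, defaults to `analysis_dir`.
#' @return Invisibly, the path of the markdown report.
#' @export
run_report <- function(analysis_dir, out_dir = analysis_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lines <- c("# Cold-stress histone methylation report", "")
  sfile <- file.path(analysis_dir, "summary.json")
  if (!file.exists(sfile)) {
    lines <- c(lines, "summary.json is missing; no numbers to report.")
    writeLines(lines, file.path(out_dir, "report.md"))
    return(invisible(file.path(out_dir, "report.md")))
  }
  s <- jsonlite::fromJSON(sfile)
  lines <- c(lines, "## Gene universe",
             sprintf("- %d genes, %d nuclear-encoded", s$n_genes, s$n_nuclear),
             "")
  if (!is.null(s$targets)) {
    lines <- c(lines, "## Mark targets",
               vapply(names(s$targets), function(m) {
                 sprintf("- %s: %d target genes", m, s$targets[[m]])
               }, ""), "")
  }
  if (!is.null(s$dm_counts)) {
    dmc <- as.data.frame(s$dm_counts)
    lines <- c(lines, "## Differential methylation",
               "",
               "| mark | contrast | targets | gain | loss | DM/targets |",
               "|---|---|---|---|---|---|",
               apply(dmc, 1L, function(r) {
                 sprintf("| %s | %s | %s | %s | %s | %.3f |",
                         r[["mark"]], r[["contrast"]], r[["n_targets"]],
                         r[["n_gain"]], r[["n_loss"]],
                         as.numeric(r[["frac_dm_of_targets"]]))
               }), "")
  } else lines <- c(lines, "## Differential methylation", "(table missing)", "")
  if (!is.null(s$de_counts)) {
    lines <- c(lines, "## Differential expression",
               vapply(names(s$de_counts), function(tp) {
                 sprintf("- %s: %d up / %d down", tp,
                         s$de_counts[[tp]]$up, s$de_counts[[tp]]$down)
               }, ""), "")
  }
  pfile <- file.path(analysis_dir, "persistence.tsv")
  if (file.exists(pfile)) {
    p <- read_tsv(pfile)
    lines <- c(lines, "## Persistence across timepoints",
               apply(p, 1L, function(r) {
                 sprintf("- %s %s: %s of DM genes at both timepoints",
                         r[["mark"]], r[["direction"]],
                         ifelse(is.na(r[["fraction_both"]]), "NA",
                                sprintf("%.1f%%",
                                        100 * as.numeric(r[["fraction_both"]]))))
               }), "")
  } else {
    lines <- c(lines, "## Persistence across timepoints", "(table missing)", "")
  }
  cfile <- file.path(analysis_dir, "correlation_matrix.tsv")
  if (file.exists(cfile)) {
    cm <- read_tsv(cfile)
    lines <- c(lines, "## Methylation x expression correlation (Spearman)",
               "",
               "| mark | meth tp | expr tp | rho | p | n |",
               "|---|---|---|---|---|---|",
               apply(cm, 1L, function(r) {
                 sprintf("| %s | %s | %s | %.3f | %.3g | %s |",
                         r[["mark"]], r[["meth_timepoint"]],
                         r[["expr_timepoint"]], as.numeric(r[["rho"]]),
                         as.numeric(r[["pvalue"]]), r[["n"]])
               }), "")
  } else {
    lines <- c(lines, "## Methylation x expression correlation",
               "(table missing)", "")
  }
  mg <- list.files(analysis_dir, pattern = "^metagene_.*\\.tsv$")
  if (length(mg)) {
    fig <- file.path(out_dir, "metagene_profiles.png")
    grDevices::png(fig, width = 900, height = 600)
    graphics::par(mar = c(4, 4, 2, 1))
    first <- TRUE
    cols <- grDevices::hcl.colors(length(mg), "Dark 3")
    for (i in seq_along(mg)) {
      d <- read_tsv(file.path(analysis_dir, mg[i]))
      if (first) {
        graphics::plot(d$bin, d$mean_coverage, type = "l", col = cols[i],
                       xlab = "bin (50 flank / 200 body / 50 flank)",
                       ylab = "mean coverage", main = "Metagene profiles")
        first <- FALSE
      } else graphics::lines(d$bin, d$mean_coverage, col = cols[i])
    }
    graphics::legend("topright", legend = sub("\\.tsv$", "", sub("^metagene_", "", mg)),
                     col = cols, lty = 1, cex = 0.8)
    grDevices::dev.off()
    lines <- c(lines, "## Metagene profiles",
               "![metagene profiles](metagene_profiles.png)", "")
  }
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(file.path(out_dir, "report.md"))
}
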