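#' Call differentially methylated (DM) genes
#'
#' A gene is DM for a mark and contrast when it is a target of the mark
#' (peak-coverage gate, see [is_target()]) and its gene-body signal changes
#' by an absolute log2 fold change of at least `lfc_threshold` (inclusive).
#' No significance test is attached: the call is a pure coverage-gated
#' fold-change criterion.
#'
#' @param fc A `fold_change_table` from [log2_fold_change()] for one mark
#'   and one contrast (cold vs naive; naive is the denominator).
#' @param targets Named logical vector of target status covering every
#'   gene in `fc`.
#' @param lfc_threshold Inclusive absolute log2FC threshold, default 0.5.
#' @param mark,contrast Optional labels stored as attributes.
#' @return A `dm_table` data frame: `gene_id`, `is_target`, `log2fc`,
#'   `dm_class` in `{gain, loss, none}`.
#' @export
call_dm <- function(fc, targets, lfc_threshold = 0.5,
                    mark = NULL, contrast = NULL) {
  stop_if_not_scalar_number(lfc_threshold, "lfc_threshold")
  tg <- targets[fc$gene_id]
  if (anyNA(tg)) {
    stop("genes missing from `targets`: ",
         paste(utils::head(fc$gene_id[is.na(tg)], 5L), collapse = ", "),
         call. = FALSE)
  }
  tg <- as.logical(tg)
  dm <- data.frame(
    gene_id = fc$gene_id,
    is_target = tg,
    log2fc = fc$log2fc,
    dm_class = ifelse(tg & fc$log2fc >= lfc_threshold, "gain",
                      ifelse(tg & fc$log2fc <= -lfc_threshold, "loss",
                             "none")),
    stringsAsFactors = FALSE
  )
  attr(dm, "mark") <- mark %||% NA_character_
  attr(dm, "contrast") <- contrast %||% NA_character_
  class(dm) <- c("dm_table", "data.frame")
  dm
}

dm_genes <- function(dm, direction) dm$gene_id[dm$dm_class == direction]

#' Summarize DM calls across marks and contrasts
#'
#' @param dm_list List of `dm_table` objects (each labelled with `mark`
#'   and `contrast` attributes, see [call_dm()]).
#' @return Data frame with one row per table: target totals, gain/loss
#'   counts and DM as a fraction of targets.
#' @export
dm_summary <- function(dm_list) {
  if (inherits(dm_list, "dm_table")) dm_list <- list(dm_list)
  rows <- lapply(dm_list, function(dm) {
    n_gain <- sum(dm$dm_class == "gain")
    n_loss <- sum(dm$dm_class == "loss")
    n_targets <- sum(dm$is_target)
    data.frame(
      mark = as.character(attr(dm, "mark")),
      contrast = as.character(attr(dm, "contrast")),
      n_genes = nrow(dm),
      n_targets = n_targets,
      n_gain = n_gain,
      n_loss = n_loss,
      n_dm = n_gain + n_loss,
      frac_dm_of_targets = if (n_targets > 0) (n_gain + n_loss) / n_targets
                           else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Categorize cold-induced target genes by their DM behaviour
#'
#' Restricted to genes that are both induced (up-regulated at any
#' timepoint) and targets of the mark, each gene is labelled `gain` if it
#' gains the mark at either timepoint and never loses it, `loss`
#' symmetrically, `both` if it gains at one timepoint and loses at the
#' other, and `non_DM` otherwise. The four categories partition the
#' induced target set; `both` is reported explicitly rather than folded
#' into gain or loss.
#'
#' @param dm_3h,dm_3d `dm_table` objects for the same mark at the early
#'   and late timepoint.
#' @param induced Character vector of induced (up-DEG at any timepoint)
#'   gene ids.
#' @return Data frame `gene_id`, `category` (factor with levels
#'   gain/loss/both/non_DM).
#' @export
assign_induced_categories <- function(dm_3h, dm_3d, induced) {
  if (!identical(dm_3h$gene_id, dm_3d$gene_id)) {
    stop("the two dm_tables must share the same gene universe",
         call. = FALSE)
  }
  targets <- dm_3h$gene_id[dm_3h$is_target]
  genes <- intersect(induced, targets)
  g3h <- genes %in% dm_genes(dm_3h, "gain")
  l3h <- genes %in% dm_genes(dm_3h, "loss")
  g3d <- genes %in% dm_genes(dm_3d, "gain")
  l3d <- genes %in% dm_genes(dm_3d, "loss")
  any_gain <- g3h | g3d
  any_loss <- l3h | l3d
  cat <- ifelse(any_gain & any_loss, "both",
                ifelse(any_gain, "gain",
                       ifelse(any_loss, "loss", "non_DM")))
  data.frame(gene_id = genes,
             category = factor(cat,
                               levels = c("gain", "loss", "both", "non_DM")),
             stringsAsFactors = FALSE)
}
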