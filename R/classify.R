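#' Classify genes from DE and promoter ChIP quantitation
#'
#' Applies the gene-class definitions of the analysis to a gene table and
#' appends one logical column per class:
#'
#' * `induced` — RA-induction fold change `>= induce_fc` (inclusive) and
#'   `padj < induce_padj` (strict) in wild-type cells.
#' * `underinduced` — induced, and mutant-vs-wild-type fold change
#'   `< under_fc` with `padj < under_padj` (both strict). Underinduction is
#'   only defined among normally induced genes.
#' * `fbxl19_bound` — promoter ChIP counts `> bound_counts` and ChIP fold
#'   change `> bound_fold` (both strict, "more than").
#' * `responsive` — bound and underinduced.
#' * `stably_induced` — bound, induced, not underinduced.
#' * `not_induced` — bound and not induced.
#'
#' The three bound sub-classes partition the bound genes (mutually exclusive
#' and exhaustive). Genes with missing values in any field a classifier needs
#' fail closed: they are assigned to no class and a warning reports how many
#' were skipped.
#'
#' @param genes Tibble with columns `gene_id`, `fc_wt_ra_vs_esc`, `padj_wt`,
#'   `fc_mut_vs_wt_ra`, `padj_mut`, `chip_fs2_counts`, `chip_fold_fs2_vs_dcxxc`
#'   (fold changes linear).
#' @param thresholds [classification_thresholds()] object.
#' @return `genes` with the six logical class columns appended.
#' @examples
#' g <- tibble::tibble(
#'   gene_id = "g1", fc_wt_ra_vs_esc = 3, padj_wt = 0.01,
#'   fc_mut_vs_wt_ra = 0.5, padj_mut = 0.01,
#'   chip_fs2_counts = 50, chip_fold_fs2_vs_dcxxc = 1.5
#' )
#' classify_genes(g)$responsive
#' @export
classify_genes <- function(genes, thresholds = classification_thresholds()) {
  need <- c("gene_id", "fc_wt_ra_vs_esc", "padj_wt", "fc_mut_vs_wt_ra",
            "padj_mut", "chip_fs2_counts", "chip_fold_fs2_vs_dcxxc")
  stopifnot(all(need %in% names(genes)))
  t <- thresholds

  complete <- complete.cases(genes[need[-1]])
  if (any(!complete)) {
    warn(paste0(sum(!complete),
                " gene(s) with missing values excluded from every class."))
  }
  strict_lt <- function(x, bound) !is.na(x) & x < bound
  strict_gt <- function(x, bound) !is.na(x) & x > bound

  genes |>
    mutate(
      induced = complete &
        .data$fc_wt_ra_vs_esc >= t$induce_fc &
        strict_lt(.data$padj_wt, t$induce_padj),
      underinduced = .data$induced &
        strict_lt(.data$fc_mut_vs_wt_ra, t$under_fc) &
        strict_lt(.data$padj_mut, t$under_padj),
      fbxl19_bound = complete &
        strict_gt(.data$chip_fs2_counts, t$bound_counts) &
        strict_gt(.data$chip_fold_fs2_vs_dcxxc, t$bound_fold),
      responsive = .data$fbxl19_bound & .data$underinduced,
      stably_induced = .data$fbxl19_bound & .data$induced & !.data$underinduced,
      not_induced = .data$fbxl19_bound & !.data$induced
    )
}
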