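#' Analysis parameter registry
#'
#' Central registry of the numeric constants used throughout the downstream
#' Capture-C analysis. Every default is the value used in the published
#' analysis this package implements; any of them can be overridden per call.
#'
#' @param score_threshold Minimum upstream-caller interaction score for an
#'   interaction to be called significant (inclusive). Default 5.
#' @param merge_gap_fragments Significant other-end fragments closer than this
#'   many DpnII fragments are merged into one interaction peak. Default 4
#'   (a gap of exactly 4 fragments does *not* merge).
#' @param tss_flank_bp Half-width of the promoter window around a TSS used for
#'   "TSS-overlapping" annotation, in bp. Default 1000.
#' @param cdk8_overlap_window_bp Maximum gap (bp, inclusive) between an ATAC
#'   peak and a CDK8 peak for the site to count as CDK8-overlapping.
#'   Default 100.
#' @param peak_annotation_window_bp Maximum gap (bp, inclusive) between an
#'   interaction peak and a CDK8/regulatory site for the peak to be flagged
#'   CDK8-positive or regulatory. Default 300.
#' @param expr_pseudocount Pseudocount added before log10 transformation of
#'   expression counts. Default 8.
#' @param signal_pseudocount Pseudocount added before log2 transformation of
#'   ChIP signal, and used in the fold-change ratio of
#'   [classify_signal_change()]. Default 1.
#' @param n_bins Number of equal-occupancy expression bins for matched
#'   resampling. Default 10.
#' @param n_samplings Number of random samplings for empirical p-values.
#'   Default 1000.
#' @param min_consistent,n_replicates Replicate-consistency rule for
#'   gained/lost interaction calls: a direction is called when at least
#'   `min_consistent` of `n_replicates` treated replicates agree in both score
#'   and normalized count. Defaults 3 of 4.
#' @param signal_fold Fold cut-off for classifying a signal gain/loss.
#'   Default 2.
#' @param fpkm_cutoff FPKM above which a gene counts as expressed when
#'   filtering non-genic sites. Default 1.1435.
#' @param min_capture_fragment_bp Minimum captured-fragment length for probe
#'   design, in bp (strict: the fragment must be larger than this).
#'   Default 200.
#' @param probe_len_range Probe length range in bp; recorded as metadata only
#'   (probe sequence design is out of scope). Default c(70, 120).
#' @param smoothing_window_fragments Default window (fragments, odd) of the
#'   running-mean viewpoint profile smoother. Default 11.
#' @param thresholds Gene classification thresholds, see
#'   [classification_thresholds()].
#'
#' @return A named list of parameters with class `promcap_params`.
#' @examples
#' p <- analysis_params()
#' p$score_threshold
#' analysis_params(n_samplings = 10000)$n_samplings
#' @export
analysis_params <- function(score_threshold = 5,
                            merge_gap_fragments = 4,
                            tss_flank_bp = 1000,
                            cdk8_overlap_window_bp = 100,
                            peak_annotation_window_bp = 300,
                            expr_pseudocount = 8,
                            signal_pseudocount = 1,
                            n_bins = 10,
                            n_samplings = 1000,
                            min_consistent = 3,
                            n_replicates = 4,
                            signal_fold = 2,
                            fpkm_cutoff = 1.1435,
                            min_capture_fragment_bp = 200,
                            probe_len_range = c(70, 120),
                            smoothing_window_fragments = 11,
                            thresholds = classification_thresholds()) {
  p <- list(
    score_threshold = score_threshold,
    merge_gap_fragments = merge_gap_fragments,
    tss_flank_bp = tss_flank_bp,
    cdk8_overlap_window_bp = cdk8_overlap_window_bp,
    peak_annotation_window_bp = peak_annotation_window_bp,
    expr_pseudocount = expr_pseudocount,
    signal_pseudocount = signal_pseudocount,
    n_bins = n_bins,
    n_samplings = n_samplings,
    min_consistent = min_consistent,
    n_replicates = n_replicates,
    signal_fold = signal_fold,
    fpkm_cutoff = fpkm_cutoff,
    min_capture_fragment_bp = min_capture_fragment_bp,
    probe_len_range = probe_len_range,
    smoothing_window_fragments = smoothing_window_fragments,
    thresholds = thresholds
  )
  stopifnot(p$min_consistent <= p$n_replicates, p$n_bins >= 1)
  structure(p, class = "promcap_params")
}

#' Gene classification thresholds
#'
#' Thresholds for the induced / underinduced / FBXL19-bound gene classifiers.
#' The binding cut-offs are the linear-scale equivalents of the log2 cut-offs
#' 5.3 (promoter ChIP counts) and 0.35 (ChIP fold change) chosen from bimodal
#' signal distributions; they are configuration constants and are not
#' re-derived here.
#'
#' @param induce_fc Minimum linear RA-induction fold change (inclusive).
#'   Default 2.
#' @param induce_padj Adjusted-p bound for induction (strict). Default 0.1.
#' @param under_fc Maximum mutant-vs-wild-type fold change (strict) for an
#'   induced gene to count as underinduced. Default 0.667.
#' @param under_padj Adjusted-p bound for underinduction (strict). Default 0.1.
#' @param bound_counts Minimum promoter ChIP counts (strict, linear scale;
#'   log2 5.3). Default 39.39662.
#' @param bound_fold Minimum ChIP fold change over the CxxC-deleted control
#'   (strict, linear scale; log2 0.35). Default 1.274561.
#'
#' @return Named list with class `promcap_thresholds`.
#' @examples
#' classification_thresholds()$bound_counts
#' @export
classification_thresholds <- function(induce_fc = 2,
                                      induce_padj = 0.1,
                                      under_fc = 0.667,
                                      under_padj = 0.1,
                                      bound_counts = 39.39662,
                                      bound_fold = 1.274561) {
  t <- list(
    induce_fc = induce_fc, induce_padj = induce_padj,
    under_fc = under_fc, under_padj = under_padj,
    bound_counts = bound_counts, bound_fold = bound_fold
  )
  stopifnot(all(unlist(t) > 0))
  structure(t, class = "promcap_thresholds")
}

#' Pseudocounted log transforms
#'
#' `log2_p1(x)` computes `log2(x + 1)` (ChIP signal convention);
#' `log10_p8(x)` computes `log10(x + 8)` (expression-count convention).
#'
#' @param x Non-negative numeric vector.
#' @return Numeric vector of transformed values.
#' @examples
#' log2_p1(0)    # 0
#' log10_p8(92)  # 2
#' @export
log2_p1 <- function(x) log2(x + 1)

#' @rdname log2_p1
#' @export
log10_p8 <- function(x) log10(x + 8)
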