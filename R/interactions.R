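#' Normalize interaction read counts to library depth and capture size
#'
#' Each (replicate, condition) pair is one capture library. Raw read counts are
#' divided by the total read count aligning to captured gene promoters in that
#' library (the sum of `raw_count` over all its records) and further by the
#' number of promoters in the capture design, so profiles are comparable across
#' libraries and capture experiments of different sizes. Only observed records
#' enter the library total; fragments absent from a library are treated as zero
#' when profiles are materialized but contribute nothing to the total.
#'
#' @param records Interaction tibble with at least `viewpoint_id`,
#'   `raw_count`, `replicate_id`, `condition_id`.
#' @param design Capture design: a tibble of captured promoters (one row per
#'   viewpoint, column `gene_id`), or a single count of promoters.
#'
#' @return `records` with a `normalized_count` column appended. For every
#'   library the normalized counts sum to `1 / n_promoters`.
#' @examples
#' recs <- tibble::tibble(
#'   viewpoint_id = "g1", other_chrom = "chrA", other_fragment_index = 5:6,
#'   raw_count = c(10, 90), score = 1, replicate_id = "rep1", condition_id = "UNT"
#' )
#' normalize_counts(recs, design = 2)$normalized_count  # 0.05, 0.45
#' @export
normalize_counts <- function(records, design) {
  stopifnot(all(c("viewpoint_id", "raw_count", "replicate_id", "condition_id")
                %in% names(records)))
  if (any(records$raw_count < 0)) abort("negative raw counts.")
  if (is.data.frame(design)) {
    n_promoters <- length(unique(design$gene_id))
    unknown <- setdiff(unique(records$viewpoint_id), design$gene_id)
    if (length(unknown) > 0L) {
      abort(paste0("viewpoints absent from capture design: ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
  } else {
    n_promoters <- as.numeric(design)
    stopifnot(length(n_promoters) == 1L, n_promoters >= 1)
  }
  out <- records |>
    group_by(.data$replicate_id, .data$condition_id) |>
    mutate(.lib_total = sum(.data$raw_count)) |>
    ungroup()
  if (any(out$.lib_total == 0)) {
    abort("library with zero total promoter-aligned reads cannot be normalized.")
  }
  out |>
    mutate(normalized_count = .data$raw_count / .data$.lib_total / n_promoters) |>
    select(-".lib_total")
}

#' Pool normalized counts across replicates
#'
#' Sums normalized counts over replicates for each
#' (viewpoint, other-end fragment, condition), emulating the pooled read counts
#' of the upstream caller's data tables with an unweighted sum. Interaction
#' scores are pooled alongside as the replicate mean (scores are
#' log-probability-like and not additive across libraries).
#'
#' @param records Output of [normalize_counts()] (must carry
#'   `normalized_count`; `score` is optional).
#' @return Tibble keyed by `viewpoint_id`, `other_chrom`,
#'   `other_fragment_index`, `condition_id` with `pooled_count` (sum of
#'   normalized counts), `pooled_score` (mean score over the replicates that
#'   observed the fragment, when `score` is present) and `n_replicates_observed`.
#' @export
pool_replicates <- function(records) {
  stopifnot("normalized_count" %in% names(records))
  has_score <- "score" %in% names(records)
  out <- records |>
    group_by(.data$viewpoint_id, .data$other_chrom,
             .data$other_fragment_index, .data$condition_id) |>
    summarise(
      pooled_count = sum(.data$normalized_count),
      pooled_score = if (has_score) mean(.data$score) else NA_real_,
      n_replicates_observed = dplyr::n(),
      .groups = "drop"
    )
  out
}

#' Filter interactions at the significance score threshold
#'
#' Keeps records whose upstream-caller score is at or above the threshold
#' (inclusive: a score of exactly 5 is significant).
#'
#' @param records Tibble with a `score` column.
#' @param score_threshold Minimum score, inclusive. Default 5.
#' @return The significant subset, same columns.
#' @examples
#' call_significant(tibble::tibble(score = c(5, 4.999)))
#' @export
call_significant <- function(records, score_threshold = 5) {
  stopifnot("score" %in% names(records))
  filter(records, .data$score >= score_threshold)
}

#' Centered running mean with truncated edges
#'
#' Smooths a per-fragment series with a centered moving average of odd window
#' size; at the series edges the window is truncated to the available
#' positions, so the output has the same length as the input. Used to draw
#' viewpoint interaction profiles as line plots.
#'
#' @param values Numeric series ordered by fragment index.
#' @param window Odd positive integer window, in fragments. Default 11.
#' @return Numeric vector of the same length.
#' @examples
#' running_mean(c(0, 0, 3, 0, 0), window = 3)  # 0 1 1 1 0
#' @export
running_mean <- function(values, window = 11) {
  if (length(window) != 1L || is.na(window) || window < 1 || window %% 2 == 0) {
    abort("`window` must be a positive odd integer.")
  }
  n <- length(values)
  if (n == 0L) return(numeric(0))
  half <- (window - 1) / 2
  cs <- cumsum(c(0, values))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Smoothed per-viewpoint interaction profile
#'
#' Materializes the pooled normalized-count profile of one viewpoint over a
#' contiguous fragment range (unobserved fragments as zero), smooths it with
#' [running_mean()], and attaches fragment coordinates so the result can be
#' exported as a bedGraph track or plotted.
#'
#' @param pooled Output of [pool_replicates()], restricted or not; only rows of
#'   `viewpoint` are used.
#' @param fragments Fragment map from [digest()].
#' @param viewpoint Viewpoint (gene) identifier.
#' @param chrom Chromosome of the profile (cis profile).
#' @param window Smoothing window in fragments (odd). Default 11.
#' @param range Optional `c(first, last)` fragment-index range; defaults to the
#'   observed index range of the viewpoint on `chrom`.
#' @return Tibble with `chrom`, `start`, `end`, `index`, `condition_id`,
#'   `value` (pooled normalized count) and `smoothed`.
#' @export
viewpoint_profile <- function(pooled, fragments, viewpoint, chrom,
                              window = 11, range = NULL) {
  rec <- pooled |>
    filter(.data$viewpoint_id == viewpoint, .data$other_chrom == chrom)
  if (nrow(rec) == 0L) abort("no records for this viewpoint/chromosome.")
  if (is.null(range)) {
    range <- c(min(rec$other_fragment_index), max(rec$other_fragment_index))
  }
  idx <- seq(range[1], range[2])
  coords <- fragments |>
    filter(.data$chrom == !!chrom, .data$index %in% idx) |>
    select("chrom", "start", "end", "index")
  purrr::map_dfr(unique(rec$condition_id), function(cond) {
    v <- rec |> filter(.data$condition_id == cond)
    series <- setNames(rep(0, length(idx)), idx)
    series[as.character(v$other_fragment_index)] <- v$pooled_count
    coords |>
      mutate(condition_id = cond,
             value = unname(series[as.character(.data$index)]),
             smoothed = running_mean(.data$value, window = window))
  })
}
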