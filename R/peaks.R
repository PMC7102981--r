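#' Merge significant interactions into interaction peaks
#'
#' Single-linkage clustering of significant other-end fragments on
#' restriction-fragment distance: two fragments are linked when they are fewer
#' than `gap` fragments apart, and each connected chain becomes one interaction
#' peak. A gap of exactly `gap` fragments does not merge. Records must come
#' from one viewpoint and should be the union of all conditions (filtered at
#' the significance threshold beforehand), so peak coordinates are identical
#' across conditions and paired per-peak comparisons are possible. Fragments on
#' different chromosomes are never merged.
#'
#' @param records Significant interaction tibble for a single viewpoint, with
#'   `viewpoint_id`, `other_chrom`, `other_fragment_index`.
#' @param gap Merge threshold in fragments (merge when distance < `gap`).
#'   Default 4.
#' @return Tibble of peaks: `viewpoint_id`, `peak_id`, `chrom`,
#'   `first_fragment`, `last_fragment`, `n_fragments` (span size, observed or
#'   not), `member_fragments` (list column of the observed member indices) and
#'   `n_members`. The result is independent of record order.
#' @examples
#' recs <- tibble::tibble(
#'   viewpoint_id = "g1", other_chrom = "chrA",
#'   other_fragment_index = c(10, 12, 13, 20)
#' )
#' merge_peaks(recs, gap = 4)
#' @export
merge_peaks <- function(records, gap = 4) {
  stopifnot(all(c("viewpoint_id", "other_chrom", "other_fragment_index")
                %in% names(records)))
  vp <- unique(records$viewpoint_id)
  if (length(vp) > 1L) {
    abort("merge_peaks() operates on a single viewpoint; split the table first.")
  }
  if (nrow(records) == 0L) {
    return(tibble(
      viewpoint_id = character(), peak_id = character(), chrom = character(),
      first_fragment = integer(), last_fragment = integer(),
      n_fragments = integer(), member_fragments = list(), n_members = integer()
    ))
  }
  members <- records |>
    distinct(.data$other_chrom, .data$other_fragment_index) |>
    arrange(.data$other_chrom, .data$other_fragment_index)
  peaks <- members |>
    group_by(.data$other_chrom) |>
    mutate(cluster = cumsum(c(1L, diff(.data$other_fragment_index) >= gap))) |>
    group_by(.data$other_chrom, .data$cluster) |>
    summarise(
      first_fragment = min(.data$other_fragment_index),
      last_fragment = max(.data$other_fragment_index),
      member_fragments = list(sort(.data$other_fragment_index)),
      n_members = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(.data$other_chrom, .data$first_fragment)
  peaks |>
    transmute(
      viewpoint_id = vp,
      peak_id = paste0(vp, ":", .data$other_chrom, ":",
                       .data$first_fragment, "-", .data$last_fragment),
      chrom = .data$other_chrom,
      first_fragment = as.integer(.data$first_fragment),
      last_fragment = as.integer(.data$last_fragment),
      n_fragments = as.integer(.data$last_fragment - .data$first_fragment + 1L),
      member_fragments = .data$member_fragments,
      n_members = as.integer(.data$n_members)
    )
}

#' Merge peaks for every viewpoint of an interaction table
#'
#' Convenience wrapper applying [merge_peaks()] viewpoint by viewpoint.
#'
#' @inheritParams merge_peaks
#' @export
merge_peaks_all <- function(records, gap = 4) {
  records |>
    group_by(.data$viewpoint_id) |>
    group_split() |>
    purrr::map_dfr(merge_peaks, gap = gap)
}

#' Per-peak mean score and normalized count per condition
#'
#' For each interaction peak and condition, sums the per-fragment pooled values
#' (normalized read counts and interaction scores) across *all* fragments in
#' the peak's span — fragments without an observation contribute zero — and
#' divides by the number of restriction fragments in the span. Sparse peaks are
#' therefore penalized, matching a per-fragment normalization of the peak sum.
#'
#' With `by_replicate = TRUE` the same span average is computed per replicate
#' (normalized counts and scores of the individual library), which is the input
#' to the replicate-consistency differential caller.
#'
#' @param peaks Peak tibble from [merge_peaks()] / [merge_peaks_all()].
#' @param records Normalized interaction records ([normalize_counts()] output);
#'   all conditions, all replicates.
#' @param by_replicate Compute per-replicate values instead of pooled ones.
#' @return A tibble with one row per peak x condition (x replicate), carrying
#'   `mean_score` and `mean_norm_count`. Every condition (and replicate)
#'   present in `records` is reported for every peak, with zeros where the peak
#'   has no observation.
#' @export
aggregate_peaks <- function(peaks, records, by_replicate = FALSE) {
  stopifnot("normalized_count" %in% names(records))
  conditions <- distinct(records, .data$condition_id)
  libraries <- distinct(records, .data$condition_id, .data$replicate_id)

  per_fragment <- if (by_replicate) {
    records |>
      group_by(.data$viewpoint_id, .data$other_chrom, .data$other_fragment_index,
               .data$condition_id, .data$replicate_id) |>
      summarise(count = sum(.data$normalized_count),
                score = mean(.data$score), .groups = "drop")
  } else {
    pool_replicates(records) |>
      rename(count = "pooled_count", score = "pooled_score")
  }

  grid <- if (by_replicate) {
    tidyr::crossing(peaks["peak_id"], libraries)
  } else {
    tidyr::crossing(peaks["peak_id"], conditions)
  }

  span <- peaks |>
    select("peak_id", "viewpoint_id", "chrom", "first_fragment", "last_fragment",
           "n_fragments")
  vals <- span |>
    inner_join(grid, by = "peak_id") |>
    left_join(
      per_fragment,
      by = c("viewpoint_id", chrom = "other_chrom", "condition_id",
             if (by_replicate) "replicate_id"),
      relationship = "many-to-many"
    ) |>
    mutate(in_span = !is.na(.data$other_fragment_index) &
             .data$other_fragment_index >= .data$first_fragment &
             .data$other_fragment_index <= .data$last_fragment) |>
    group_by(dplyr::across(dplyr::all_of(c(
      "peak_id", "viewpoint_id", "chrom", "first_fragment", "last_fragment",
      "n_fragments", "condition_id", if (by_replicate) "replicate_id"
    )))) |>
    summarise(
      mean_score = sum(.data$score[.data$in_span]) / .data$n_fragments[1],
      mean_norm_count = sum(.data$count[.data$in_span]) / .data$n_fragments[1],
      .groups = "drop"
    ) |>
    mutate(mean_score = tidyr::replace_na(.data$mean_score, 0),
           mean_norm_count = tidyr::replace_na(.data$mean_norm_count, 0)) |>
    arrange(.data$peak_id, .data$condition_id)
  vals
}
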