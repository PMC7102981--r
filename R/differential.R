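#' Per-condition peak summary with paired test
#'
#' Summarises per-peak mean scores and normalized counts for two conditions
#' and compares them with a paired t-test across peaks (peaks are defined on
#' the pooled conditions, so the pairing is by peak identity). When every
#' per-peak difference is zero the comparison is degenerate and the p-value is
#' reported as 1.
#'
#' @param peak_values Output of [aggregate_peaks()] (pooled, not
#'   per-replicate): one row per peak x condition with `mean_score` and
#'   `mean_norm_count`.
#' @param condition_a,condition_b The two condition identifiers to compare.
#' @return A tibble with one row per metric (`score`, `norm_count`):
#'   per-condition means, mean paired difference (a minus b), paired-t
#'   p-value and the number of peaks.
#' @export
condition_summary <- function(peak_values, condition_a, condition_b) {
  need <- c("peak_id", "condition_id", "mean_score", "mean_norm_count")
  stopifnot(all(need %in% names(peak_values)))
  present <- unique(peak_values$condition_id)
  if (!all(c(condition_a, condition_b) %in% present)) {
    abort("both conditions must be present in `peak_values`.")
  }
  wide <- peak_values |>
    filter(.data$condition_id %in% c(condition_a, condition_b)) |>
    tidyr::pivot_wider(
      id_cols = "peak_id", names_from = "condition_id",
      values_from = c("mean_score", "mean_norm_count")
    )
  if (nrow(wide) < 2L) abort("paired comparison needs at least 2 peaks.")

  paired_p <- function(a, b) {
    d <- a - b
    if (all(d == 0)) return(1)
    if (stats::sd(d) == 0) return(0)  # constant nonzero shift
    t.test(a, b, paired = TRUE)$p.value
  }
  one <- function(metric) {
    a <- wide[[paste0("mean_", metric, "_", condition_a)]]
    b <- wide[[paste0("mean_", metric, "_", condition_b)]]
    tibble(
      metric = metric,
      mean_a = mean(a), mean_b = mean(b), mean_diff = mean(a - b),
      p_value = paired_p(a, b), n_peaks = length(a)
    )
  }
  bind_rows(one("score"), one("norm_count"))
}

#' Call gained and lost interactions by replicate consistency
#'
#' For each peak, every treated replicate's span-averaged interaction score
#' and normalized read coverage are compared with the untreated reference (the
#' mean over untreated replicates). A replicate is consistently *lost* when
#' both metrics are strictly lower, consistently *gained* when both are
#' strictly higher; a direction is called when at least `min_consistent` of
#' `n_replicates` treated replicates agree, otherwise `none`. Exact ties count
#' as inconsistent.
#'
#' @param replicate_values Output of `aggregate_peaks(..., by_replicate =
#'   TRUE)`: one row per peak x condition x replicate with `mean_score` and
#'   `mean_norm_count`.
#' @param treated,untreated Condition identifiers.
#' @param min_consistent Minimum number of agreeing replicates. Default 3.
#' @param n_replicates Required number of treated replicates. Default 4.
#' @return One row per peak: `peak_id`, `viewpoint_id`, `n_gained`, `n_lost`,
#'   `direction` (`gained`, `lost` or `none`). Swapping `treated` and
#'   `untreated` swaps gained and lost.
#' @export
call_gained_lost <- function(replicate_values, treated, untreated,
                             min_consistent = 3, n_replicates = 4) {
  need <- c("peak_id", "condition_id", "replicate_id",
            "mean_score", "mean_norm_count")
  stopifnot(all(need %in% names(replicate_values)),
            min_consistent <= n_replicates)

  ref <- replicate_values |>
    filter(.data$condition_id == untreated) |>
    group_by(.data$peak_id) |>
    summarise(ref_score = mean(.data$mean_score),
              ref_count = mean(.data$mean_norm_count), .groups = "drop")
  trt <- replicate_values |>
    filter(.data$condition_id == treated)
  if (nrow(trt) == 0L || nrow(ref) == 0L) {
    abort("both treated and untreated conditions must be present.")
  }
  counts <- trt |>
    count(.data$peak_id)
  if (any(counts$n != n_replicates)) {
    abort(paste0("every peak needs exactly ", n_replicates,
                 " treated replicate values."))
  }
  vp <- replicate_values |>
    distinct(.data$peak_id, viewpoint_id = .data$viewpoint_id)

  trt |>
    inner_join(ref, by = "peak_id") |>
    group_by(.data$peak_id) |>
    summarise(
      n_gained = sum(.data$mean_score > .data$ref_score &
                       .data$mean_norm_count > .data$ref_count),
      n_lost = sum(.data$mean_score < .data$ref_score &
                     .data$mean_norm_count < .data$ref_count),
      .groups = "drop"
    ) |>
    mutate(direction = dplyr::case_when(
      .data$n_gained >= min_consistent & .data$n_lost < min_consistent ~ "gained",
      .data$n_lost >= min_consistent & .data$n_gained < min_consistent ~ "lost",
      TRUE ~ "none"
    )) |>
    left_join(vp, by = "peak_id") |>
    select("peak_id", "viewpoint_id", "n_gained", "n_lost", "direction")
}

#' Classify signal gain/loss at a fold cut-off
#'
#' Classifies the change of a signal (e.g. H3K27ac enrichment) between an
#' untreated and a treated state using the pseudocounted ratio
#' `r = (treated + pc) / (untreated + pc)`: `gain` when `r >= fold`, `loss`
#' when `r <= 1/fold`, otherwise `stable`.
#'
#' @param value_unt,value_treated Non-negative signal values (vectorized).
#' @param fold Fold cut-off. Default 2.
#' @param pseudocount Added to both values. Default 1.
#' @return Character vector in `{gain, loss, stable}`.
#' @examples
#' classify_signal_change(c(10, 10, 10), c(25, 4, 15))
#' @export
classify_signal_change <- function(value_unt, value_treated, fold = 2,
                                   pseudocount = 1) {
  if (any(value_unt < 0) || any(value_treated < 0)) {
    abort("signal values must be non-negative.")
  }
  r <- (value_treated + pseudocount) / (value_unt + pseudocount)
  dplyr::case_when(
    r >= fold ~ "gain",
    r <= 1 / fold ~ "loss",
    TRUE ~ "stable"
  )
}
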