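#' Equal-occupancy expression bins
#'
#' Bins a per-gene covariate (typically FPKM) into `n_bins` quantile bins of
#' (as nearly as the data permit) equal occupancy. Tied values always fall in
#' the same bin, so realized bin sizes can deviate minimally from equality;
#' the assignment is deterministic. Binning on a monotone transform of the
#' covariate (e.g. `log10(x + 8)`) yields the same bins.
#'
#' @param genes Tibble with a `gene_id` column.
#' @param value Column (tidy-eval) holding the matching covariate.
#' @param n_bins Number of bins. Default 10. Requires at least `n_bins` genes.
#' @return Tibble `gene_id`, `value`, `bin` (integer in `1..n_bins`), with the
#'   numeric bin boundaries in attribute `"boundaries"`.
#' @examples
#' g <- tibble::tibble(gene_id = paste0("g", 1:100), fpkm = rexp(100))
#' table(quantile_bins(g, fpkm)$bin)
#' @export
quantile_bins <- function(genes, value, n_bins = 10) {
  stopifnot("gene_id" %in% names(genes), n_bins >= 1)
  v <- dplyr::pull(genes, {{ value }})
  if (length(v) < n_bins) {
    abort("fewer genes than bins; reduce `n_bins`.")
  }
  if (anyNA(v)) abort("matching covariate contains missing values.")
  breaks <- unique(quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) == 1L) breaks <- c(breaks, breaks + 1)  # all values tied
  bin <- cut(v, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  out <- tibble(gene_id = genes$gene_id, value = v, bin = as.integer(bin))
  attr(out, "boundaries") <- breaks
  out
}

#' Bin-matched random control sample
#'
#' Draws, without replacement, a random control gene set from `pool` whose
#' per-bin histogram exactly equals that of `target`, so the sample is matched
#' to the genes of interest on the binned covariate.
#'
#' @param target Character vector of gene ids (the genes of interest).
#' @param pool Character vector of candidate control gene ids.
#' @param bins [quantile_bins()] assignment covering both sets.
#' @return Character vector of sampled gene ids, `length(target)` of them.
#'   An error names the first bin whose pool is too small.
#' @export
matched_sample <- function(target, pool, bins) {
  b <- setNames(bins$bin, bins$gene_id)
  if (anyNA(b[target]) || anyNA(b[pool])) {
    abort("all target and pool genes must appear in `bins`.")
  }
  tgt_hist <- table(factor(b[target], levels = sort(unique(bins$bin))))
  out <- character(0)
  for (bn in names(tgt_hist)[tgt_hist > 0]) {
    need <- tgt_hist[[bn]]
    avail <- pool[b[pool] == as.integer(bn)]
    if (length(avail) < need) {
      abort(paste0("bin ", bn, ": pool has ", length(avail),
                   " genes but target needs ", need, "."))
    }
    out <- c(out, sample(avail, need, replace = FALSE))
  }
  # per-bin histogram of every draw must equal the target's histogram
  stopifnot(identical(
    as.integer(table(factor(b[out], levels = names(tgt_hist)))),
    as.integer(tgt_hist)
  ))
  out
}

#' Empirical p-value from expression-matched resampling
#'
#' Compares a statistic of the target gene set against its null distribution
#' over `n_samplings` bin-matched random control sets, and reports the add-one
#' empirical p-value `(1 + #{null >= observed}) / (n + 1)` (alternative
#' `"greater"`; `"less"` is symmetric, `"two_sided"` doubles the smaller tail
#' and caps at 1). The p-value can never be smaller than `1 / (n + 1)`.
#'
#' @param target Character vector of gene ids of interest.
#' @param pool Character vector of candidate control gene ids.
#' @param bins [quantile_bins()] assignment covering target and pool.
#' @param statistic Function mapping a character vector of gene ids to one
#'   number, e.g. from [fraction_statistic()].
#' @param n_samplings Number of random samplings. Default 1000.
#' @param alternative `"greater"` (default, enrichment), `"less"` or
#'   `"two_sided"`.
#' @param exclude_target Drop target genes from the pool before sampling
#'   (default TRUE: controls are contrasted against the genes of interest).
#' @param seed Optional integer seed; when supplied the draw sequence is
#'   reproducible and the RNG state of the session is left untouched.
#' @return A `promcap_resample` object: list with `observed`, `null_values`,
#'   `p_value`, `n_samplings`, `alternative`, `n_target`, `n_pool`, `seed`.
#'   Methods: [print()], [tidy()], [glance()], [ggplot2::autoplot()].
#' @export
empirical_p <- function(target, pool, bins, statistic, n_samplings = 1000,
                        alternative = c("greater", "less", "two_sided"),
                        exclude_target = TRUE, seed = NULL) {
  alternative <- match.arg(alternative)
  if (n_samplings < 1) abort("`n_samplings` must be at least 1.")
  if (length(target) == 0L) abort("empty target set.")
  if (exclude_target) pool <- setdiff(pool, target)

  draw_all <- function() {
    observed <- statistic(target)
    null_values <- vapply(
      seq_len(n_samplings),
      function(i) statistic(matched_sample(target, pool, bins)),
      numeric(1)
    )
    list(observed = observed, null_values = null_values)
  }
  d <- if (!is.null(seed)) withr::with_seed(seed, draw_all()) else draw_all()

  p_greater <- (1 + sum(d$null_values >= d$observed)) / (n_samplings + 1)
  p_less <- (1 + sum(d$null_values <= d$observed)) / (n_samplings + 1)
  p <- switch(alternative,
    greater = p_greater,
    less = p_less,
    two_sided = min(1, 2 * min(p_greater, p_less))
  )
  structure(
    list(
      observed = d$observed, null_values = d$null_values, p_value = p,
      n_samplings = n_samplings, alternative = alternative,
      n_target = length(target), n_pool = length(pool), seed = seed
    ),
    class = "promcap_resample"
  )
}

#' Fraction-of-genes statistics for resampling tests
#'
#' Builds the statistic used by the enrichment bar charts: the fraction of a
#' gene set satisfying a predicate (FBXL19-bound, interacts with an ATAC peak,
#' interaction is TSS-overlapping, interacts with a CDK8 site, ...).
#'
#' @param predicate Either a function mapping gene ids to a logical vector, or
#'   a named logical vector over the gene universe.
#' @return A function mapping a non-empty character vector of gene ids to the
#'   fraction in `[0, 1]`.
#' @examples
#' is_bound <- c(g1 = TRUE, g2 = FALSE, g3 = TRUE)
#' fraction_statistic(is_bound)(c("g1", "g2", "g3"))  # 2/3
#' @export
fraction_statistic <- function(predicate) {
  fn <- if (is.function(predicate)) {
    predicate
  } else {
    lookup <- predicate
    function(genes) {
      v <- lookup[genes]
      if (anyNA(v)) abort("predicate undefined for some genes.")
      as.logical(v)
    }
  }
  function(genes) {
    if (length(genes) == 0L) abort("statistic undefined on an empty gene set.")
    mean(fn(genes))
  }
}

#' @export
print.promcap_resample <- function(x, ...) {
  cat("Expression-matched resampling test\n")
  cat(sprintf("  observed statistic: %.4g (target n = %d)\n",
              x$observed, x$n_target))
  cat(sprintf("  null: %d matched samplings from pool of %d (mean %.4g)\n",
              x$n_samplings, x$n_pool, mean(x$null_values)))
  cat(sprintf("  empirical p (%s): %.4g\n", x$alternative, x$p_value))
  invisible(x)
}

#' Tidy a resampling result
#'
#' `tidy()` returns a one-row tibble with the observed statistic, the null
#' mean/sd and the empirical p-value; `glance()` returns the test setup.
#'
#' @param x A `promcap_resample` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.promcap_resample <- function(x, ...) {
  tibble(
    observed = x$observed,
    null_mean = mean(x$null_values),
    null_sd = stats::sd(x$null_values),
    p_value = x$p_value
  )
}

#' @rdname tidy.promcap_resample
#' @export
glance.promcap_resample <- function(x, ...) {
  tibble(
    n_samplings = x$n_samplings, n_target = x$n_target, n_pool = x$n_pool,
    alternative = x$alternative,
    seed = if (is.null(x$seed)) NA_integer_ else x$seed
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
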