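#' TSS-overlap annotation
#'
#' An interval is TSS-overlapping when it intersects the promoter window
#' `[tss - flank, tss + flank]` (closed, in bp) of any TSS. Intervals are
#' 0-based half-open, so an interval ending exactly at the window start does
#' not overlap.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param tss Tibble with `chrom` and `tss` (0-based position).
#' @param flank Promoter half-width in bp. Default 1000.
#' @return Logical vector, one per interval row; independent of TSS order.
#' @examples
#' iv <- tibble::tibble(chrom = "chr1", start = 5000, end = 5100)
#' overlaps_tss(iv, tibble::tibble(chrom = "chr1", tss = 5500))  # TRUE
#' overlaps_tss(iv, tibble::tibble(chrom = "chr1", tss = 7000))  # FALSE
#' @export
overlaps_tss <- function(intervals, tss, flank = 1000) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)),
            all(c("chrom", "tss") %in% names(tss)))
  windows <- tibble(
    chrom = tss$chrom,
    start = tss$tss - flank,       # closed window in 0-based coordinates
    end = tss$tss + flank + 1      # half-open end
  )
  interval_overlaps(intervals, windows)
}

# strict overlap: non-empty intersection; touching half-open intervals do not
# overlap (unlike a gap-0 proximity test)
interval_overlaps <- function(intervals, subjects) {
  if (nrow(intervals) == 0L) return(logical(0))
  if (nrow(subjects) == 0L) return(rep(FALSE, nrow(intervals)))
  lv <- union(intervals$chrom, subjects$chrom)
  q <- GenomicRanges::GRanges(
    factor(intervals$chrom, levels = lv),
    IRanges::IRanges(start = intervals$start + 1, end = intervals$end)
  )
  s <- GenomicRanges::GRanges(
    factor(subjects$chrom, levels = lv),
    IRanges::IRanges(start = subjects$start + 1, end = subjects$end)
  )
  GenomicRanges::countOverlaps(q, s, ignore.strand = TRUE) > 0
}

#' Proximity annotation against a peak set
#'
#' TRUE when the minimum gap between the interval and any peak is at most
#' `window` bp (inclusive; overlap counts as gap 0). With `window = 0` this is
#' an overlap test; used with 100 bp for CDK8-overlap of ATAC sites and with
#' 300 bp for CDK8-positive / regulatory annotation of interaction peaks.
#'
#' @param intervals,peaks Tibbles with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param window Maximum gap in bp, inclusive.
#' @return Logical vector, one per interval row.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
#' b <- tibble::tibble(chrom = "chr1", start = 200, end = 300)
#' near_peak(a, b, window = 100)  # gap exactly 100 -> TRUE
#' near_peak(a, b, window = 99)   # FALSE
#' @export
near_peak <- function(intervals, peaks, window) {
  stopifnot(window >= 0)
  interval_gap_within(intervals, peaks, window = window)
}

# shared gap machinery: TRUE when min gap between interval i and any subject
# interval (same chrom) is <= window; overlap -> gap 0
interval_gap_within <- function(intervals, subjects, window) {
  if (nrow(intervals) == 0L) return(logical(0))
  if (nrow(subjects) == 0L) return(rep(FALSE, nrow(intervals)))
  lv <- union(intervals$chrom, subjects$chrom)
  q <- GenomicRanges::GRanges(
    factor(intervals$chrom, levels = lv),
    IRanges::IRanges(start = intervals$start + 1, end = intervals$end)
  )
  s <- GenomicRanges::GRanges(
    factor(subjects$chrom, levels = lv),
    IRanges::IRanges(start = subjects$start + 1, end = subjects$end)
  )
  hits <- GenomicRanges::distanceToNearest(q, s, ignore.strand = TRUE)
  out <- rep(FALSE, nrow(intervals))
  out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance <= window
  out
}

#' Quantify a signal track over a window
#'
#' Sums per-base signal of a bedGraph-style track over each query window
#' (positions not covered by any track run count as zero); `stat = "mean"`
#' divides by the window width. The pseudocounted transforms of the analysis
#' are available via `transform`: `"log2_p1"` for ChIP signal
#' (`log2(x + 1)`) and `"log10_p8"` for expression counts (`log10(x + 8)`).
#'
#' @param track Tibble with `chrom`, `start`, `end`, `value` (0-based
#'   half-open runs, values >= 0).
#' @param windows Tibble with `chrom`, `start`, `end`.
#' @param transform One of `"none"`, `"log2_p1"`, `"log10_p8"`.
#' @param stat `"sum"` (default) or `"mean"`.
#' @return Numeric vector, one value per window.
#' @examples
#' tr <- tibble::tibble(chrom = "chr1", start = 0, end = 100, value = 1)
#' quantify_signal(tr, tibble::tibble(chrom = "chr1", start = 0, end = 100))
#' @export
quantify_signal <- function(track, windows,
                            transform = c("none", "log2_p1", "log10_p8"),
                            stat = c("sum", "mean")) {
  transform <- match.arg(transform)
  stat <- match.arg(stat)
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)),
            all(c("chrom", "start", "end") %in% names(windows)))
  if (any(track$value < 0)) abort("signal values must be non-negative.")
  bounds <- track |>
    group_by(.data$chrom) |>
    summarise(max_end = max(.data$end), .groups = "drop")
  chk <- windows |> left_join(bounds, by = "chrom")
  if (any(is.na(chk$max_end)) || any(chk$start < 0) ||
      any(chk$end > chk$max_end)) {
    abort("window outside the covered span of the signal track.")
  }
  lv <- union(windows$chrom, track$chrom)
  q <- GenomicRanges::GRanges(
    factor(windows$chrom, levels = lv),
    IRanges::IRanges(windows$start + 1, windows$end)
  )
  s <- GenomicRanges::GRanges(
    factor(track$chrom, levels = lv),
    IRanges::IRanges(track$start + 1, track$end)
  )
  ov <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  width_ov <- pmin(BiocGenerics::end(q)[qi], BiocGenerics::end(s)[si]) -
    pmax(BiocGenerics::start(q)[qi], BiocGenerics::start(s)[si]) + 1
  raw <- rep(0, nrow(windows))
  if (length(qi) > 0L) {
    sums <- tapply(width_ov * track$value[si], qi, sum)
    raw[as.integer(names(sums))] <- sums
  }
  if (stat == "mean") raw <- raw / (windows$end - windows$start)
  switch(transform,
    none = raw,
    log2_p1 = log2_p1(raw),
    log10_p8 = log10_p8(raw)
  )
}

#' Drop sites overlapping expressed genes
#'
#' Removes candidate sites that overlap any gene expressed above the FPKM
#' cutoff (strict: FPKM > cutoff counts as expressed), keeping only non-genic
#' sites for nascent-transcription quantitation.
#'
#' @param sites Tibble with `chrom`, `start`, `end`.
#' @param genes Tibble with `chrom`, `start`, `end`, `fpkm`.
#' @param fpkm_cutoff Expression cutoff. Default 1.1435.
#' @return The subset of `sites` overlapping no expressed gene.
#' @export
filter_nongenic_sites <- function(sites, genes, fpkm_cutoff = 1.1435) {
  stopifnot(all(c("chrom", "start", "end", "fpkm") %in% names(genes)))
  expressed <- genes |> filter(.data$fpkm > fpkm_cutoff)
  if (nrow(expressed) == 0L || nrow(sites) == 0L) return(sites)
  hit <- interval_overlaps(sites, expressed)
  sites[!hit, , drop = FALSE]
}

#' Annotate interaction peaks against TSS, CDK8 and regulatory interval sets
#'
#' Converts each peak's fragment span to bp coordinates via the fragment map
#' and sets the three annotation flags of the analysis: `tss_overlapping`
#' (peak intersects a TSS +/- `tss_flank_bp` window), `cdk8_positive` (CDK8
#' peak within `peak_window_bp`) and `regulatory` (regulatory/ATAC site within
#' `peak_window_bp`).
#'
#' @param peaks Peak tibble from [merge_peaks_all()].
#' @param fragments Fragment map from [digest()].
#' @param tss Tibble with `chrom`, `tss`; optional.
#' @param cdk8_peaks,regulatory_sites Interval tibbles (`chrom`, `start`,
#'   `end`); optional.
#' @param tss_flank_bp,peak_window_bp Window parameters, see
#'   [analysis_params()]. Defaults 1000 and 300.
#' @return `peaks` with bp coordinates (`start`, `end`) and logical flag
#'   columns appended.
#' @export
annotate_peaks <- function(peaks, fragments, tss = NULL, cdk8_peaks = NULL,
                           regulatory_sites = NULL, tss_flank_bp = 1000,
                           peak_window_bp = 300) {
  first <- fragments |>
    select("chrom", "index", first_start = "start")
  last <- fragments |>
    select("chrom", "index", last_end = "end")
  out <- peaks |>
    left_join(first, by = c("chrom", first_fragment = "index")) |>
    left_join(last, by = c("chrom", last_fragment = "index")) |>
    rename(start = "first_start", end = "last_end")
  if (any(is.na(out$start) | is.na(out$end))) {
    abort("peak fragments missing from the fragment map.")
  }
  iv <- out |> select("chrom", "start", "end")
  out$tss_overlapping <- if (!is.null(tss)) {
    overlaps_tss(iv, tss, flank = tss_flank_bp)
  } else NA
  out$cdk8_positive <- if (!is.null(cdk8_peaks)) {
    near_peak(iv, cdk8_peaks, window = peak_window_bp)
  } else NA
  out$regulatory <- if (!is.null(regulatory_sites)) {
    near_peak(iv, regulatory_sites, window = peak_window_bp)
  } else NA
  out
}
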