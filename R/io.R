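#' Read and write genome FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] returning/consuming the tibble genome
#' representation used by [digest()].
#'
#' @param path FASTA file path.
#' @return `read_genome_fasta()`: tibble with `chrom`, `sequence`.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble(chrom = sub("\\s.*$", "", names(ss)),
         sequence = unname(as.character(ss)))
}

#' @rdname read_genome_fasta
#' @param genome Tibble with `chrom`, `sequence`.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- as_genome_set(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read and write BED intervals
#'
#' BED3/BED4/BED6 via rtracklayer, converted to/from 0-based half-open
#' tibbles (`chrom`, `start`, `end`, then `name`, `score`, `strand` when
#' present). Writing validates `start < end` first.
#'
#' @param path BED file path.
#' @return `read_bed()`: interval tibble.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr)
  )
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$name)) out$name <- mc$name
  if (!is.null(mc$score)) out$score <- mc$score
  strands <- as.character(BiocGenerics::strand(gr))
  if (any(strands != "*")) out$strand <- strands
  out
}

#' @rdname read_bed
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start >= intervals$end)) {
    bad <- which(intervals$start >= intervals$end)[1]
    abort(paste0("interval with start >= end at row ", bad, "."))
  }
  # BED columns are positional: emit exactly as many as the data carry,
  # padding name/score with placeholders only when strand forces BED6
  cols <- intervals[c("chrom", "start", "end")]
  has <- names(intervals)
  if ("strand" %in% has || "score" %in% has || "name" %in% has) {
    cols$name <- if ("name" %in% has) intervals$name else "."
  }
  if ("strand" %in% has || "score" %in% has) {
    cols$score <- if ("score" %in% has) intervals$score else 0L
  }
  if ("strand" %in% has) cols$strand <- intervals$strand
  readr::write_tsv(cols, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

interaction_columns <- c(
  "viewpoint_id", "other_chrom", "other_start", "other_end",
  "other_fragment_index", "raw_count", "score", "replicate_id", "condition_id"
)

#' Read and write interaction tables
#'
#' The interaction TSV dialect is a flattened, headered form of an upstream
#' caller's per-interaction export: one row per
#' (viewpoint, other-end fragment, replicate, condition) with raw read count
#' and caller score. Reading validates the schema strictly (exact column set,
#' non-negative counts and scores); writing round-trips exactly.
#'
#' @param path TSV file path.
#' @return `read_interactions()`: interaction tibble.
#' @export
read_interactions <- function(path) {
  rec <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(interaction_columns, names(rec))
  extra <- setdiff(names(rec), interaction_columns)
  if (length(missing) > 0L) {
    abort(paste0("missing interaction columns: ", paste(missing, collapse = ", ")))
  }
  if (length(extra) > 0L) {
    abort(paste0("unknown interaction columns: ", paste(extra, collapse = ", ")))
  }
  if (any(rec$raw_count < 0)) abort("negative raw counts in interaction table.")
  if (any(rec$score < 0)) abort("negative scores in interaction table.")
  rec[interaction_columns]
}

#' @rdname read_interactions
#' @param records Interaction tibble with exactly the dialect's columns.
#' @export
write_interactions <- function(records, path) {
  stopifnot(all(interaction_columns %in% names(records)))
  readr::write_tsv(records[interaction_columns], path, progress = FALSE)
  invisible(path)
}

#' Write a viewpoint profile as bedGraph
#'
#' Exports per-fragment values as a bedGraph track (sorted; adjacent
#' contiguous fragments with equal values are run-length merged when
#' `merge_adjacent` is on). bedGraph text is the signal contract; binary
#' bigWig generation is out of scope.
#'
#' @param profile Tibble with `chrom`, `start`, `end` and a value column
#'   (`value` by default, `smoothed` also accepted via `value_col`).
#' @param path Output path.
#' @param value_col Name of the value column. Default `"value"`.
#' @param merge_adjacent Run-length merge equal-value contiguous runs.
#'   Default TRUE.
#' @param name Track name written to the header line.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(profile, path, value_col = "value",
                           merge_adjacent = TRUE, name = "promcapr") {
  stopifnot(all(c("chrom", "start", "end", value_col) %in% names(profile)))
  prof <- profile |>
    transmute(.data$chrom, .data$start, .data$end,
              value = .data[[value_col]]) |>
    arrange(.data$chrom, .data$start)
  if (merge_adjacent && nrow(prof) > 1L) {
    prof <- prof |>
      group_by(.data$chrom) |>
      mutate(run = cumsum(c(1, (.data$value[-1] != .data$value[-dplyr::n()]) |
                              (.data$start[-1] != .data$end[-dplyr::n()])))) |>
      group_by(.data$chrom, .data$run) |>
      summarise(start = min(.data$start), end = max(.data$end),
                value = .data$value[1], .groups = "drop") |>
      select(-"run") |>
      arrange(.data$chrom, .data$start)
  }
  lines <- c(
    sprintf("track type=bedGraph name=\"%s\"", name),
    if (nrow(prof) > 0L) {
      sprintf("%s\t%d\t%d\t%s", prof$chrom, prof$start, prof$end,
              formatC(prof$value, format = "g", digits = 6))
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bedgraph
#' @return `read_bedgraph()`: tibble with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    value = gr$score
  )
}
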