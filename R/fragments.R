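#' In-silico restriction digestion of a genome
#'
#' Cuts each chromosome at every occurrence of the restriction motif
#' (DpnII: `GATC`) and returns the resulting fragment map. The cut position is
#' the first base of the motif, so fragments begin at the G of GATC — the
#' convention used by standard Hi-C digestion tools. Overlapping motif
#' occurrences each produce a cut; `N` (or any non-ACGT base) never matches
#' the motif. A chromosome without any motif occurrence yields one fragment
#' spanning the whole chromosome.
#'
#' @param genome Genome sequences: a tibble with columns `chrom` and
#'   `sequence`, a named character vector, or a [Biostrings::DNAStringSet].
#' @param motif Recognition sequence, non-empty ACGT string. Default `"GATC"`.
#'
#' @return A tibble (the fragment map) with columns `chrom`, `start`, `end`
#'   (0-based half-open bp) and `index` (0-based ordinal within chromosome).
#'   Fragments tile each chromosome without gaps or overlaps.
#' @examples
#' digest(tibble::tibble(chrom = "chrA", sequence = "AAGATCTT"))
#' @export
digest <- function(genome, motif = "GATC") {
  genome <- as_genome_set(genome)
  if (length(genome) == 0L) abort("`genome` contains no sequences.")
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) == 0L) {
    abort("`motif` must be a single non-empty string.")
  }
  if (any(duplicated(names(genome)))) abort("chromosome names must be unique.")
  if (any(Biostrings::width(genome) == 0L)) abort("empty chromosome sequence.")

  purrr::map2_dfr(names(genome), seq_along(genome), function(chrom, i) {
    len <- Biostrings::width(genome)[i]
    hits <- Biostrings::matchPattern(motif, genome[[i]], fixed = TRUE)
    cuts <- BiocGenerics::start(hits) - 1L  # to 0-based motif starts
    bounds <- sort(unique(c(0L, cuts, len)))
    tibble(
      chrom = chrom,
      start = bounds[-length(bounds)],
      end = bounds[-1L],
      index = seq_len(length(bounds) - 1L) - 1L
    )
  })
}

as_genome_set <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.data.frame(genome)) {
    stopifnot(all(c("chrom", "sequence") %in% names(genome)))
    return(Biostrings::DNAStringSet(setNames(genome$sequence, genome$chrom)))
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) abort("character genome must be named by chromosome.")
    return(Biostrings::DNAStringSet(genome))
  }
  abort("`genome` must be a tibble(chrom, sequence), named character vector or DNAStringSet.")
}

#' Locate the fragment containing a genomic position
#'
#' @param fragments Fragment map from [digest()].
#' @param chrom,pos Vectors (recycled to common length) of chromosome names
#'   and 0-based positions.
#' @return Integer vector of fragment indices, the unique fragments with
#'   `start <= pos < end`. Positions at or beyond the chromosome end, or on
#'   unknown chromosomes, are errors.
#' @examples
#' fm <- digest(tibble::tibble(chrom = "chrA", sequence = "TGATCGATCA"))
#' locate_fragment(fm, "chrA", c(0, 4, 5))
#' @export
locate_fragment <- function(fragments, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(as.numeric(pos), n)
  out <- integer(n)
  for (ch in unique(chrom)) {
    fr <- fragments[fragments$chrom == ch, , drop = FALSE]
    if (nrow(fr) == 0L) abort(paste0("unknown chromosome: ", ch))
    fr <- fr[order(fr$start), , drop = FALSE]
    sel <- which(chrom == ch)
    p <- pos[sel]
    if (any(p < 0 | p >= max(fr$end))) {
      abort(paste0("position out of range on ", ch))
    }
    out[sel] <- fr$index[findInterval(p, fr$start)]
  }
  out
}

#' Distance between two fragments in fragment units
#'
#' The number of restriction fragments separating two fragments on the same
#' chromosome: the absolute difference of their ordinal indices. This is the
#' distance the `< 4 fragments` peak-merging rule operates on.
#' Inter-chromosomal distances are undefined and raise an error.
#'
#' @param a,b Data frames (recycled row-wise) with columns `chrom` and `index`.
#' @return Non-negative integer vector.
#' @examples
#' fragment_gap(
#'   tibble::tibble(chrom = "chrA", index = 10),
#'   tibble::tibble(chrom = "chrA", index = 13)
#' )
#' @export
fragment_gap <- function(a, b) {
  stopifnot(all(c("chrom", "index") %in% names(a)),
            all(c("chrom", "index") %in% names(b)))
  n <- max(nrow(a), nrow(b))
  ca <- rep_len(a$chrom, n); cb <- rep_len(b$chrom, n)
  if (any(ca != cb)) abort("fragments lie on different chromosomes; distance undefined.")
  abs(rep_len(a$index, n) - rep_len(b$index, n))
}

#' Select eligible captured fragments for viewpoint promoters
#'
#' For each gene, the captured fragment is the restriction fragment containing
#' its TSS, provided that fragment is longer than `min_len` bp and contains no
#' TSS of any other gene. When the TSS fragment fails either rule the
#' immediately upstream fragment is tried, then the immediately downstream one
#' (in this order, in coordinate terms), under the same rules. Genes with no
#' eligible fragment are returned as rejections, not errors.
#'
#' @param fragments Fragment map from [digest()].
#' @param tss Tibble with columns `gene_id`, `chrom`, `tss` (0-based bp) and
#'   optionally `strand`. All rows together form the TSS universe used for the
#'   no-other-TSS rule.
#' @param min_len Minimum captured-fragment length in bp (strict). Default 200.
#'
#' @return A tibble with one row per input gene: `gene_id`, `chrom`, `tss`,
#'   `strand`, `captured_fragment_index` (NA when rejected), `selection`
#'   (`tss_fragment`, `upstream`, `downstream` or NA), `accepted` and `reason`.
#'   The result is independent of the row order of `tss`.
#' @export
select_capture_fragments <- function(fragments, tss, min_len = 200) {
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(tss)))
  if (!"strand" %in% names(tss)) tss$strand <- "+"
  tss <- arrange(tss, .data$gene_id)

  tss$tss_fragment <- locate_fragment(fragments, tss$chrom, tss$tss)
  frag_key <- paste(fragments$chrom, fragments$index)
  width <- setNames(fragments$end - fragments$start, frag_key)
  max_index <- tapply(fragments$index, fragments$chrom, max)
  # TSS count per fragment, by gene, for the unique-TSS rule
  tss_by_frag <- tss |>
    mutate(key = paste(.data$chrom, .data$tss_fragment)) |>
    group_by(.data$key) |>
    summarise(genes = list(unique(.data$gene_id)), .groups = "drop")
  genes_in <- setNames(tss_by_frag$genes, tss_by_frag$key)

  eligible <- function(chrom, idx, gene) {
    if (is.na(idx) || idx < 0L || idx > max_index[[chrom]]) return("missing")
    key <- paste(chrom, idx)
    if (width[[key]] <= min_len) return("too_short")
    others <- setdiff(genes_in[[key]] %||% character(), gene)
    if (length(others) > 0L) return("other_tss")
    "ok"
  }

  res <- purrr::pmap_dfr(
    list(tss$gene_id, tss$chrom, tss$tss, tss$strand, tss$tss_fragment),
    function(gene, chrom, pos, strand, idx) {
      cand <- c(tss_fragment = idx, upstream = idx - 1L, downstream = idx + 1L)
      verdicts <- vapply(cand, function(i) eligible(chrom, i, gene), character(1))
      hit <- which(verdicts == "ok")
      if (length(hit) > 0L) {
        sel <- names(cand)[hit[1L]]
        tibble(
          gene_id = gene, chrom = chrom, tss = pos, strand = strand,
          captured_fragment_index = unname(cand[hit[1L]]),
          selection = sel, accepted = TRUE, reason = NA_character_
        )
      } else {
        tibble(
          gene_id = gene, chrom = chrom, tss = pos, strand = strand,
          captured_fragment_index = NA_integer_,
          selection = NA_character_, accepted = FALSE,
          reason = paste(verdicts, collapse = ";")
        )
      }
    }
  )
  res
}
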