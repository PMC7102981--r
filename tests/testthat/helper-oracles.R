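# Independent oracles used by the property-style suites. These stay free of
# the package's own code paths: plain substring scans and graph components.

# brute-force motif scan: fragment boundaries from a character-by-character
# comparison, overlap-aware
oracle_digest <- function(sequence, motif = "GATC") {
  L <- nchar(sequence)
  m <- nchar(motif)
  cuts <- integer(0)
  if (L >= m) {
    for (i in seq_len(L - m + 1)) {
      if (substr(sequence, i, i + m - 1) == motif) cuts <- c(cuts, i - 1L)
    }
  }
  bounds <- sort(unique(c(0L, cuts, L)))
  tibble::tibble(
    start = bounds[-length(bounds)],
    end = bounds[-1],
    index = seq_along(bounds[-1]) - 1L
  )
}

# single-linkage clustering of fragment indices via graph connectivity:
# indices linked when |i - j| < gap, clusters = connected components
oracle_single_linkage <- function(indices, gap = 4) {
  indices <- sort(unique(indices))
  n <- length(indices)
  if (n == 1) return(list(indices))
  pairs <- which(
    abs(outer(indices, indices, "-")) < gap & upper.tri(matrix(0, n, n)),
    arr.ind = TRUE
  )
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(pairs) > 0) g <- igraph::add_edges(g, t(pairs))
  comp <- igraph::components(g)$membership
  unname(lapply(split(seq_len(n), comp), function(i) indices[i]))
}

# random A/C/G/T sequence of length n (no motif guarantees)
random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small config for fast simulator tests
small_sim_config <- function(seed = 7, ...) {
  sim_config(
    seed = seed, n_chromosomes = 1, chrom_length = 8e4, n_viewpoints = 8,
    n_genes = 80, interaction_window = 25, min_distal_gap = 10,
    max_distal_gap = 18, n_atac_decoys = 10, n_signal_sites = 60, ...
  )
}
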