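#' Configuration for the synthetic Capture-C study generator
#'
#' Bundles every knob of the seeded generator. The defaults define a compact
#' study with the statistical structure the downstream analysis assumes:
#' a fragment-tiled two-chromosome genome, four conditions
#' (`UNT`, `TAM_fbxl19`, `TAM_med13`, `RA`) with four replicates each,
#' distance-decay interaction counts with planted promoter-distal peaks whose
#' enrichment varies by gene class and condition (strong in the untreated ESC
#' state, modestly reduced on FBXL19 loss, strongly reduced on MED13/13L loss,
#' near background after RA differentiation), a gene table with planted class
#' labels, and accessible distal sites with a planted minority of 2-fold
#' H3K27ac gains.
#'
#' @param seed Integer seed; fixes every downstream draw.
#' @param n_chromosomes,chrom_length Genome shape. Defaults 2 x 300 kb.
#' @param gatc_rate Expected GATC cut density per bp. Default 1/256, the
#'   expectation for an iid uniform ACGT sequence.
#' @param n_viewpoints Number of captured promoters. Default 40.
#' @param class_fractions Named fractions (`responsive`, `stably_induced`,
#'   `not_induced`, `control`) of the viewpoints; must sum to <= 1.
#' @param n_genes Total gene universe incl. non-captured background genes.
#'   Default 1200.
#' @param amplitude,alpha Distance-decay background: expected count at
#'   fragment distance `d` is `amplitude * (1 + d)^(-alpha)`. Defaults 50, 1.
#' @param dispersion Negative-binomial size parameter for replicate scatter.
#'   Default 10.
#' @param enrichment Named list per gene class of per-condition multiplicative
#'   enrichments of the planted promoter-distal peak.
#' @param conditions Condition identifiers.
#' @param n_replicates Replicates per condition. Default 4.
#' @param interaction_window Fragments simulated on each side of a viewpoint.
#'   Default 60.
#' @param min_distal_gap,max_distal_gap Fragment distance range of the planted
#'   distal site from its viewpoint. Defaults 25-45.
#' @param n_atac_decoys Accessible (ATAC) decoy peaks without planted
#'   interactions. Default 60.
#' @param h3k27ac_gain_fraction Fraction of responsive-interacting sites
#'   planted to gain >= 2-fold H3K27ac after RA. Default 0.19.
#' @param n_signal_sites Number of responsive-interacting sites in the H3K27ac
#'   table (the design's own distal sites padded with extra synthetic
#'   responsive-interacting sites). Default 400.
#' @param min_capture_fragment_bp Minimum captured-fragment length. Default 200.
#' @return Named list with class `promcap_sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 2,
                       chrom_length = 3e5,
                       gatc_rate = 1 / 256,
                       n_viewpoints = 40,
                       class_fractions = c(responsive = 0.3,
                                           stably_induced = 0.3,
                                           not_induced = 0.2,
                                           control = 0.2),
                       n_genes = 1200,
                       amplitude = 50,
                       alpha = 1,
                       dispersion = 10,
                       enrichment = list(
                         responsive = c(UNT = 8, TAM_fbxl19 = 5.5,
                                        TAM_med13 = 2, RA = 1.2),
                         stably_induced = c(UNT = 8, TAM_fbxl19 = 8,
                                            TAM_med13 = 8, RA = 8),
                         not_induced = c(UNT = 8, TAM_fbxl19 = 8,
                                         TAM_med13 = 8, RA = 8),
                         control = c(UNT = 8, TAM_fbxl19 = 8,
                                     TAM_med13 = 8, RA = 8)
                       ),
                       conditions = c("UNT", "TAM_fbxl19", "TAM_med13", "RA"),
                       n_replicates = 4,
                       interaction_window = 60,
                       min_distal_gap = 25,
                       max_distal_gap = 45,
                       n_atac_decoys = 60,
                       h3k27ac_gain_fraction = 0.19,
                       n_signal_sites = 400,
                       min_capture_fragment_bp = 200) {
  cfg <- as.list(environment())
  stopifnot(
    sum(class_fractions) <= 1 + 1e-9,
    all(unlist(enrichment) > 0),
    dispersion > 0, amplitude > 0,
    all(conditions %in% names(enrichment[[1]])),
    n_genes >= n_viewpoints,
    h3k27ac_gain_fraction >= 0, h3k27ac_gain_fraction <= 1
  )
  structure(cfg, class = "promcap_sim_config")
}

# random sequence (letter vector) guaranteed to contain no GATC occurrence
motif_free_fill <- function(n) {
  if (n <= 0) return(character(0))
  x <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (n >= 4) {
    i <- seq_len(n - 3)
    hit <- which(x[i] == "G" & x[i + 1] == "A" & x[i + 2] == "T" & x[i + 3] == "C")
    # breaking the A leaves GCTC; cannot create a new occurrence
    if (length(hit) > 0) x[hit + 1] <- "C"
  }
  x
}

#' Simulate a genome with a target restriction-site density
#'
#' Generates random chromosome sequences whose expected GATC density matches
#' `gatc_rate`: cut sites are planted at geometric spacings (minimum 4 bp) and
#' the intervening sequence is random but motif-free, so the planted cuts are
#' exactly the digestion cuts. With `gatc_rate = 0` each chromosome digests
#' into a single fragment.
#'
#' @param config [sim_config()] object (uses `seed`, `n_chromosomes`,
#'   `chrom_length`, `gatc_rate`).
#' @return Tibble with `chrom`, `sequence`, ready for [digest()].
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "promcap_sim_config"))
  if (config$chrom_length <= 0) abort("chrom_length must be positive.")
  withr::with_seed(config$seed + 101L, {
    purrr::map_dfr(seq_len(config$n_chromosomes), function(i) {
      L <- config$chrom_length
      if (config$gatc_rate <= 0) {
        seqv <- motif_free_fill(L)
      } else {
        # spacings between cut starts; >= 4 so planted motifs never overlap
        n_guess <- ceiling(L * config$gatc_rate * 1.5) + 10
        gaps <- stats::rgeom(n_guess, config$gatc_rate) + 4
        while (sum(gaps) < L) {
          gaps <- c(gaps, stats::rgeom(n_guess, config$gatc_rate) + 4)
        }
        cuts <- cumsum(gaps)
        cuts <- cuts[cuts <= L - 4]
        seqv <- character(L)
        prev <- 0
        for (cut in cuts) {
          if (cut > prev) seqv[(prev + 1):cut] <- motif_free_fill(cut - prev)
          seqv[(cut + 1):(cut + 4)] <- c("G", "A", "T", "C")
          prev <- cut + 4
        }
        if (prev < L) seqv[(prev + 1):L] <- motif_free_fill(L - prev)
      }
      tibble(chrom = sprintf("chr%d", i),
             sequence = paste(seqv, collapse = ""))
    })
  })
}

apportion_classes <- function(fractions, n) {
  counts <- diff(c(0, round(cumsum(fractions) * n)))
  leftover <- n - sum(counts)
  rep(c(names(fractions), if (leftover > 0) "control"),
      c(counts, if (leftover > 0) leftover))
}

#' Simulate the capture design: viewpoints, TSS, CDK8 and ATAC peaks
#'
#' Places viewpoints on capture-eligible fragments (longer than the minimum
#' probe-design length, single TSS, away from chromosome termini), assigns
#' gene classes by deterministic apportioning of `class_fractions`, plants one
#' distal interacting site per viewpoint at 25-45 fragments distance, marks the
#' distal sites of responsive and stably induced viewpoints as CDK8-bound, and
#' places ATAC peaks at every distal site plus unlinked decoys. Background
#' (non-captured) genes fill the gene universe on the remaining fragments.
#'
#' @param config [sim_config()] object.
#' @param fragments Fragment map from [digest()] of [simulate_genome()].
#' @return List with tibbles `tss` (all genes), `viewpoints`, `cdk8_peaks`,
#'   `atac_peaks`, and `truth` (list of `genes` and `peaks`; emitted alongside
#'   the data and never consumed by the pipeline).
#' @export
simulate_design <- function(config, fragments) {
  stopifnot(inherits(config, "promcap_sim_config"))
  W <- config$interaction_window + config$max_distal_gap + 2
  eligible <- fragments |>
    group_by(.data$chrom) |>
    mutate(max_index = max(.data$index)) |>
    ungroup() |>
    filter(.data$end - .data$start > config$min_capture_fragment_bp,
           .data$index > W, .data$index < .data$max_index - W)
  if (nrow(eligible) < config$n_viewpoints) {
    abort("genome too small for the requested number of viewpoints.")
  }
  withr::with_seed(config$seed + 202L, {
    vp_frags <- eligible |> slice_sample(n = config$n_viewpoints) |>
      arrange(.data$chrom, .data$index)
    classes <- apportion_classes(config$class_fractions, config$n_viewpoints)

    viewpoints <- vp_frags |>
      mutate(
        gene_id = sprintf("gene%04d", dplyr::row_number()),
        class = classes,
        tss = floor((.data$start + .data$end) / 2),
        strand = sample(c("+", "-"), dplyr::n(), replace = TRUE)
      ) |>
      select("gene_id", "class", "chrom", "tss", "strand",
             fragment_index = "index")

    # background genes on fragments not used by viewpoints
    n_bg <- config$n_genes - config$n_viewpoints
    bg_frags <- fragments |>
      anti_join(vp_frags, by = c("chrom", "index")) |>
      filter(.data$end - .data$start >= 2) |>
      slice_sample(n = n_bg, replace = FALSE)
    background <- bg_frags |>
      mutate(
        gene_id = sprintf("bg%05d", dplyr::row_number()),
        class = "background",
        tss = floor((.data$start + .data$end) / 2),
        strand = sample(c("+", "-"), dplyr::n(), replace = TRUE)
      ) |>
      select("gene_id", "class", "chrom", "tss", "strand",
             fragment_index = "index")

    # one planted distal site per viewpoint
    peaks_truth <- viewpoints |>
      mutate(
        gap = sample(seq(config$min_distal_gap, config$max_distal_gap),
                     dplyr::n(), replace = TRUE),
        side = sample(c(-1L, 1L), dplyr::n(), replace = TRUE),
        distal_index = .data$fragment_index + .data$side * .data$gap
      )
    distal_coords <- peaks_truth |>
      left_join(fragments, by = c("chrom", distal_index = "index")) |>
      mutate(
        width = .data$end - .data$start,
        site_start = .data$start + pmax(0L, floor((.data$width - 200) / 2)),
        site_end = pmin(.data$end, .data$site_start + 200)
      )
    enr <- purrr::map_dfr(distal_coords$class, function(cl) {
      as_tibble(as.list(config$enrichment[[cl]][config$conditions]))
    }) |>
      rename_with(~ paste0("enr_", .x))
    truth_peaks <- bind_cols(
      distal_coords |>
        mutate(cdk8 = .data$class %in% c("responsive", "stably_induced")) |>
        select(viewpoint_id = "gene_id", "class", "chrom",
               viewpoint_fragment = "fragment_index",
               distal_fragment = "distal_index",
               "site_start", "site_end", "cdk8"),
      enr
    )

    cdk8_peaks <- truth_peaks |>
      filter(.data$cdk8) |>
      select("chrom", start = "site_start", end = "site_end")

    decoys <- fragments |>
      anti_join(vp_frags, by = c("chrom", "index")) |>
      anti_join(truth_peaks, by = c("chrom", index = "distal_fragment")) |>
      slice_sample(n = config$n_atac_decoys) |>
      mutate(width = .data$end - .data$start,
             start = .data$start + pmax(0L, floor((.data$width - 200) / 2)),
             end = pmin(.data$end, .data$start + 200)) |>
      select("chrom", "start", "end")
    atac_peaks <- bind_rows(
      truth_peaks |> select("chrom", start = "site_start", end = "site_end"),
      decoys
    ) |>
      arrange(.data$chrom, .data$start)

    tss <- bind_rows(viewpoints, background) |>
      select("gene_id", "chrom", "tss", "strand")
    truth_genes <- bind_rows(viewpoints |> mutate(is_viewpoint = TRUE),
                             background |> mutate(is_viewpoint = FALSE))

    list(
      tss = tss,
      viewpoints = viewpoints,
      cdk8_peaks = cdk8_peaks,
      atac_peaks = atac_peaks,
      truth = list(genes = truth_genes, peaks = truth_peaks)
    )
  })
}

#' Simulate the gene expression / promoter ChIP table
#'
#' Emits one row per gene in the universe with the schema consumed by
#' [classify_genes()]: RA-induction DE statistics, mutant-vs-wild-type DE
#' statistics and promoter ChIP quantitation. Values are drawn with noise but
#' inside the regions their planted class prescribes, so classification
#' recovers the planted labels; background/control genes violate at least one
#' binding condition by construction.
#'
#' @param design Output of [simulate_design()] (uses `truth$genes`).
#' @param config [sim_config()] object.
#' @return Tibble of gene records (one per gene) with a `planted_class`
#'   column carried along for truth bookkeeping.
#' @export
simulate_expression <- function(design, config) {
  genes <- design$truth$genes
  withr::with_seed(config$seed + 303L, {
    n <- nrow(genes)
    cl <- genes$class
    induced_like <- cl %in% c("responsive", "stably_induced")
    bg_induced <- cl == "background" & runif(n) < 0.3
    ctl_induced <- cl == "control" & runif(n) < 0.5

    fc_wt <- ifelse(induced_like | bg_induced | ctl_induced,
                    runif(n, 2.2, 9), runif(n, 0.3, 1.8))
    padj_wt <- ifelse(induced_like | bg_induced | ctl_induced,
                      runif(n, 1e-6, 0.08), runif(n, 0.15, 1))
    under <- cl == "responsive"
    fc_mut <- ifelse(under, runif(n, 0.25, 0.6), runif(n, 0.75, 1.35))
    padj_mut <- ifelse(under, runif(n, 1e-6, 0.08), runif(n, 0.2, 1))
    bound <- cl %in% c("responsive", "stably_induced", "not_induced")
    chip_counts <- ifelse(bound, runif(n, 55, 300), runif(n, 1, 35))
    chip_fold <- ifelse(bound, runif(n, 1.4, 4), runif(n, 0.6, 1.25))

    fpkm_esc <- rlnorm(n, meanlog = 1.5, sdlog = 1)
    fpkm_ra <- fpkm_esc * fc_wt * rlnorm(n, 0, 0.1)

    genes |>
      transmute(
        gene_id = .data$gene_id,
        fpkm_esc = fpkm_esc,
        fpkm_ra = fpkm_ra,
        fc_wt_ra_vs_esc = fc_wt,
        padj_wt = padj_wt,
        fc_mut_vs_wt_ra = fc_mut,
        padj_mut = padj_mut,
        chip_fs2_counts = chip_counts,
        chip_fold_fs2_vs_dcxxc = chip_fold,
        planted_class = .data$class
      )
  })
}

#' Simulate per-replicate interaction tables
#'
#' For every viewpoint, fragments within `interaction_window` fragments on
#' either side receive distance-decay background counts with expectation
#' `mu(d) = amplitude * (1 + d)^(-alpha)`; the planted distal fragment's
#' expectation is multiplied by the (class, condition) enrichment. Counts are
#' negative-binomial with the configured dispersion, independently per
#' replicate and condition. The emulated caller score of an observation is the
#' -log10 Poisson upper-tail probability of the observed count under the
#' background expectation `mu(d)` (floored at 0) — a deliberate simplification
#' of the upstream caller that preserves the one property the pipeline
#' consumes: a score monotone in enrichment with a meaningful >= 5 threshold.
#' Zero-count fragment/library pairs are omitted, as in sparse caller exports.
#'
#' @param design Output of [simulate_design()].
#' @param fragments Fragment map the design was built on.
#' @param config [sim_config()] object.
#' @return Interaction tibble: `viewpoint_id`, `other_chrom`, `other_start`,
#'   `other_end`, `other_fragment_index`, `raw_count`, `score`,
#'   `replicate_id`, `condition_id`.
#' @export
simulate_interactions <- function(design, fragments, config) {
  vps <- design$truth$peaks
  W <- config$interaction_window
  base <- vps |>
    select(viewpoint_id = "viewpoint_id", "class", "chrom",
           vp_index = "viewpoint_fragment", distal_fragment = "distal_fragment") |>
    tidyr::crossing(offset = c(-W:-1, 1:W)) |>
    mutate(other_fragment_index = .data$vp_index + .data$offset,
           d = abs(.data$offset),
           mu_bg = config$amplitude * (1 + .data$d)^(-config$alpha))
  libraries <- tidyr::crossing(
    condition_id = config$conditions,
    replicate_id = sprintf("rep%d", seq_len(config$n_replicates))
  )
  enr_long <- vps |>
    select("viewpoint_id", starts_with("enr_")) |>
    tidyr::pivot_longer(starts_with("enr_"),
                        names_to = "condition_id", values_to = "enrichment",
                        names_prefix = "enr_")

  grid <- base |>
    tidyr::crossing(libraries) |>
    left_join(enr_long, by = c("viewpoint_id", "condition_id")) |>
    mutate(enrichment = ifelse(
      .data$other_fragment_index == .data$distal_fragment, .data$enrichment, 1
    ))

  withr::with_seed(config$seed + 404L, {
    grid$raw_count <- rnbinom(nrow(grid),
                              mu = grid$mu_bg * grid$enrichment,
                              size = config$dispersion)
  })
  coords <- fragments |> select("chrom", "index", "start", "end")
  grid |>
    filter(.data$raw_count > 0) |>
    mutate(score = pmax(0, -ppois(.data$raw_count - 1, .data$mu_bg,
                                  lower.tail = FALSE, log.p = TRUE) / log(10))) |>
    left_join(coords, by = c(chrom = "chrom",
                             other_fragment_index = "index")) |>
    transmute(
      viewpoint_id = .data$viewpoint_id,
      other_chrom = .data$chrom,
      other_start = .data$start,
      other_end = .data$end,
      other_fragment_index = as.integer(.data$other_fragment_index),
      raw_count = as.integer(.data$raw_count),
      score = .data$score,
      replicate_id = .data$replicate_id,
      condition_id = .data$condition_id
    ) |>
    arrange(.data$condition_id, .data$replicate_id, .data$viewpoint_id,
            .data$other_chrom, .data$other_fragment_index)
}

#' Simulate H3K27ac signal at promoter-interacting distal sites
#'
#' Emits per-site H3K27ac enrichment values for the untreated (ESC) and
#' RA-treated states. A planted fraction of responsive-interacting sites gains
#' at least 2-fold signal (on the pseudocounted ratio used by
#' [classify_signal_change()]); all remaining sites are drawn stable, strictly
#' inside the 2-fold band. The design's own distal sites come first; the table
#' is padded with extra synthetic responsive-interacting accessible sites until
#' it holds `n_signal_sites` responsive-interacting ones, so gain-fraction
#' recovery can be assessed at a realistic site count.
#'
#' @param design Output of [simulate_design()].
#' @param config [sim_config()] object.
#' @return Tibble: `site_id`, `chrom`, `start`, `end`, `interacting_class`,
#'   `value_unt`, `value_ra`, `planted_change` (`gain`/`stable`).
#' @export
simulate_signal_sites <- function(design, config) {
  base <- design$truth$peaks |>
    transmute(chrom = .data$chrom, start = .data$site_start,
              end = .data$site_end, interacting_class = .data$class)
  n_resp <- sum(base$interacting_class == "responsive")
  n_extra <- max(0L, config$n_signal_sites - n_resp)
  if (n_extra > 0L) {
    extra <- tibble(
      chrom = "chrS",  # synthetic padding contig, not part of the genome
      start = seq_len(n_extra) * 1000L,
      end = seq_len(n_extra) * 1000L + 200L,
      interacting_class = "responsive"
    )
    base <- bind_rows(base, extra)
  }
  withr::with_seed(config$seed + 505L, {
    n <- nrow(base)
    responsive <- base$interacting_class == "responsive"
    gains <- responsive & runif(n) < config$h3k27ac_gain_fraction
    value_unt <- runif(n, 20, 100)
    ratio <- ifelse(gains, runif(n, 2.05, 4), runif(n, 0.6, 1.6))
    value_ra <- pmax(0, (value_unt + 1) * ratio - 1)
    base |>
      mutate(
        site_id = sprintf("site%04d", dplyr::row_number()),
        value_unt = value_unt,
        value_ra = value_ra,
        planted_change = ifelse(gains, "gain", "stable")
      ) |>
      select("site_id", "chrom", "start", "end", "interacting_class",
             "value_unt", "value_ra", "planted_change")
  })
}

#' Run the full synthetic study generator
#'
#' Convenience orchestrator: genome, digestion, design, expression table,
#' interaction tables and signal sites from one [sim_config()]. Fully
#' deterministic under the config seed.
#'
#' @param config [sim_config()] object.
#' @return List with class `promcap_simulation`: `config`, `genome`,
#'   `fragments`, `design` (incl. `truth`), `genes`, `interactions`,
#'   `signal_sites`.
#' @examples
#' \donttest{
#' sim <- simulate_capture_study(sim_config(seed = 1, n_viewpoints = 6,
#'                                          n_genes = 60, chrom_length = 1e5))
#' names(sim)
#' }
#' @export
simulate_capture_study <- function(config = sim_config()) {
  genome <- simulate_genome(config)
  fragments <- digest(genome)
  design <- simulate_design(config, fragments)
  genes <- simulate_expression(design, config)
  interactions <- simulate_interactions(design, fragments, config)
  signal_sites <- simulate_signal_sites(design, config)
  structure(
    list(config = config, genome = genome, fragments = fragments,
         design = design, genes = genes, interactions = interactions,
         signal_sites = signal_sites),
    class = "promcap_simulation"
  )
}

#' Write a simulated study to disk
#'
#' Emits the plain-text file set of a study: genome FASTA, fragment map BED4,
#' TSS BED6, CDK8/ATAC peak BED3, interaction TSV, gene table TSV, signal-site
#' TSV and truth TSVs. Byte-identical across runs with the same config.
#'
#' @param sim `promcap_simulation` from [simulate_capture_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "promcap_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    fragments = file.path(dir, "fragments.bed"),
    tss = file.path(dir, "tss.bed"),
    cdk8 = file.path(dir, "cdk8_peaks.bed"),
    atac = file.path(dir, "atac_peaks.bed"),
    interactions = file.path(dir, "interactions.tsv"),
    genes = file.path(dir, "genes.tsv"),
    signal = file.path(dir, "signal_sites.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_peaks = file.path(dir, "truth_peaks.tsv")
  )
  write_genome_fasta(sim$genome, paths["genome"])
  write_bed(sim$fragments |>
              transmute(.data$chrom, .data$start, .data$end,
                        name = as.character(.data$index)),
            paths["fragments"])
  write_bed(sim$design$tss |>
              transmute(.data$chrom, start = .data$tss, end = .data$tss + 1,
                        name = .data$gene_id, score = 0L, strand = .data$strand),
            paths["tss"])
  write_bed(sim$design$cdk8_peaks, paths["cdk8"])
  write_bed(sim$design$atac_peaks, paths["atac"])
  write_interactions(sim$interactions, paths["interactions"])
  readr::write_tsv(sim$genes, paths["genes"])
  readr::write_tsv(sim$signal_sites, paths["signal"])
  readr::write_tsv(sim$design$truth$genes, paths["truth_genes"])
  readr::write_tsv(sim$design$truth$peaks, paths["truth_peaks"])
  invisible(paths)
}
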