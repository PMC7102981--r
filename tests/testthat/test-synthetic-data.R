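test_that("the generator is deterministic under its seed", {
  cfg <- small_sim_config(seed = 7)
  s1 <- simulate_capture_study(cfg)
  s2 <- simulate_capture_study(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$interactions, s2$interactions)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$signal_sites, s2$signal_sites)
  # and different under a different seed
  s3 <- simulate_capture_study(small_sim_config(seed = 8))
  expect_false(identical(s1$genome$sequence, s3$genome$sequence))
})

test_that("genome simulation hits the target cut density and the rate-0 edge", {
  cfg <- sim_config(seed = 3, n_chromosomes = 3, chrom_length = 5e4)
  fm <- digest(simulate_genome(cfg))
  expect_equal(length(unique(fm$chrom)), 3)
  mean_width <- mean(fm$end - fm$start)
  expect_gt(mean_width, 200)   # expected ~ 1/rate = 256 bp
  expect_lt(mean_width, 330)

  cfg0 <- sim_config(seed = 3, n_chromosomes = 2, chrom_length = 2e4,
                     gatc_rate = 0)
  fm0 <- digest(simulate_genome(cfg0))
  expect_equal(nrow(fm0), 2)   # one fragment per chromosome
})

test_that("the design apportions classes deterministically and places distal sites", {
  cfg <- sim_config(seed = 5, n_viewpoints = 20, n_genes = 100,
                    chrom_length = 2e5)
  sim <- simulate_capture_study(cfg)
  vp <- sim$design$viewpoints
  expect_equal(unname(table(vp$class)[c("responsive", "stably_induced",
                                        "not_induced", "control")]),
               c(6, 6, 4, 4), ignore_attr = TRUE)

  truth <- sim$design$truth$peaks
  # every planted distal site is on a different fragment than its viewpoint
  expect_true(all(truth$distal_fragment != truth$viewpoint_fragment))
  expect_true(all(abs(truth$distal_fragment - truth$viewpoint_fragment) >=
                    cfg$min_distal_gap))
  # at least one planted peak per responsive viewpoint
  resp <- vp$gene_id[vp$class == "responsive"]
  expect_true(all(resp %in% truth$viewpoint_id))
  # CDK8 sites mark responsive and stably induced distal ends
  expect_equal(truth$cdk8, truth$class %in% c("responsive", "stably_induced"))
  # viewpoints pass the capture-eligibility rules they were placed for
  sel <- select_capture_fragments(
    sim$fragments, sim$design$tss |> dplyr::semi_join(vp, by = "gene_id")
  )
  expect_true(all(sel$accepted))
  expect_true(all(sel$selection == "tss_fragment"))
})

test_that("planted gene classes are recovered exactly by classification", {
  sim <- simulate_capture_study(small_sim_config(seed = 9))
  lab <- classify_genes(sim$genes)
  expect_equal(lab$responsive, lab$planted_class == "responsive")
  expect_equal(lab$stably_induced, lab$planted_class == "stably_induced")
  expect_equal(lab$not_induced, lab$planted_class == "not_induced")
  # unbound genes are never called responsive
  expect_false(any(lab$responsive[lab$planted_class %in% c("control", "background")]))
})

test_that("emulated scores separate planted peaks from matched background", {
  sim <- simulate_capture_study(small_sim_config(seed = 1))
  truth <- sim$design$truth$peaks
  unt <- sim$interactions |> dplyr::filter(condition_id == "UNT")
  planted <- unt |>
    dplyr::inner_join(truth, by = c(viewpoint_id = "viewpoint_id",
                                    other_fragment_index = "distal_fragment"))
  # distance-matched background: the fragment mirrored across the viewpoint
  mirrored <- truth |>
    dplyr::mutate(mirror = 2 * viewpoint_fragment - distal_fragment)
  background <- unt |>
    dplyr::inner_join(mirrored, by = c(viewpoint_id = "viewpoint_id",
                                       other_fragment_index = "mirror"))
  expect_gt(mean(planted$score), mean(background$score) + 2)
  expect_gt(mean(planted$score), 5)  # planted peaks typically significant
})

test_that("an all-ones enrichment yields a calibrated null dataset", {
  cfg <- small_sim_config(
    seed = 4,
    enrichment = list(
      responsive = c(UNT = 1, TAM_fbxl19 = 1, TAM_med13 = 1, RA = 1),
      stably_induced = c(UNT = 1, TAM_fbxl19 = 1, TAM_med13 = 1, RA = 1),
      not_induced = c(UNT = 1, TAM_fbxl19 = 1, TAM_med13 = 1, RA = 1),
      control = c(UNT = 1, TAM_fbxl19 = 1, TAM_med13 = 1, RA = 1)
    )
  )
  sim <- simulate_capture_study(cfg)
  # false-positive ceiling: almost no record reaches the significance score
  expect_lt(mean(sim$interactions$score >= 5), 0.01)
})

test_that("signal sites honour the planted gain fraction including the extremes", {
  sim0 <- simulate_capture_study(small_sim_config(seed = 2,
                                                  h3k27ac_gain_fraction = 0))
  k0 <- classify_signal_change(sim0$signal_sites$value_unt,
                               sim0$signal_sites$value_ra)
  expect_false(any(k0 == "gain"))

  sim1 <- simulate_capture_study(small_sim_config(seed = 2,
                                                  h3k27ac_gain_fraction = 1))
  resp <- sim1$signal_sites$interacting_class == "responsive"
  k1 <- classify_signal_change(sim1$signal_sites$value_unt[resp],
                               sim1$signal_sites$value_ra[resp])
  expect_true(all(k1 == "gain"))

  # classification recovers the planted per-site labels exactly
  sim <- simulate_capture_study(small_sim_config(seed = 2))
  k <- classify_signal_change(sim$signal_sites$value_unt,
                              sim$signal_sites$value_ra)
  expect_equal(k == "gain", sim$signal_sites$planted_change == "gain")
})

test_that("written simulation files round-trip through the package readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_capture_study(small_sim_config(seed = 6))
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))

  genome <- read_genome_fasta(paths["genome"])
  expect_equal(genome$sequence, sim$genome$sequence)

  frags <- read_bed(paths["fragments"])
  expect_equal(frags$start, sim$fragments$start)
  expect_equal(as.integer(frags$name), sim$fragments$index)

  inter <- read_interactions(paths["interactions"])
  expect_equal(inter, sim$interactions)

  tss <- read_bed(paths["tss"])
  expect_equal(nrow(tss), nrow(sim$design$tss))
  expect_true(all(tss$strand %in% c("+", "-")))

  # byte-identical on re-write with the same config (full determinism)
  dir2 <- withr::local_tempdir()
  write_simulation(simulate_capture_study(small_sim_config(seed = 6)), dir2)
  for (f in names(paths)) {
    expect_identical(readLines(paths[[f]]), readLines(file.path(dir2, basename(paths[[f]]))),
                     info = f)
  }
})
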