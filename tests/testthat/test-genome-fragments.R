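test_that("digest cuts at motif starts and tiles the chromosome", {
  # no cut site: one fragment covering the chromosome
  fm <- digest(tibble::tibble(chrom = "chrA", sequence = "AAAA"))
  expect_equal(fm$start, 0)
  expect_equal(fm$end, 4)
  expect_equal(fm$index, 0)

  fm <- digest(tibble::tibble(chrom = "chrA", sequence = "AAGATCTT"))
  expect_equal(fm$start, c(0, 2))
  expect_equal(fm$end, c(2, 8))

  fm <- digest(tibble::tibble(chrom = "chrA", sequence = "TGATCGATCA"))
  expect_equal(fm$start, c(0, 1, 5))
  expect_equal(fm$end, c(1, 5, 10))
  expect_equal(fm$index, 0:2)
})

test_that("digest rejects empty input and never matches through N", {
  expect_error(digest(tibble::tibble(chrom = character(), sequence = character())))
  expect_error(digest(tibble::tibble(chrom = "c", sequence = "ACGT"), motif = ""))
  # ambiguous bases do not match the motif: an all-N chromosome is one fragment
  fm <- digest(tibble::tibble(chrom = "cN", sequence = strrep("N", 50)))
  expect_equal(nrow(fm), 1)
  expect_equal(fm$end, 50)
  # N inside a would-be motif blocks the cut
  fm2 <- digest(tibble::tibble(chrom = "c", sequence = "AAGANCTT"))
  expect_equal(nrow(fm2), 1)
})

test_that("digest agrees with a brute-force motif-scan oracle on random genomes", {
  withr::with_seed(42, {
    for (i in 1:30) {
      s <- random_sequence(1000)
      got <- digest(tibble::tibble(chrom = "c", sequence = s))
      exp <- oracle_digest(s)
      expect_equal(got$start, exp$start)
      expect_equal(got$end, exp$end)
      # fragments tile [0, length) with no gaps or overlaps
      expect_equal(got$start[1], 0)
      expect_equal(got$end[nrow(got)], 1000)
      if (nrow(got) > 1) {
        expect_equal(got$start[-1], got$end[-nrow(got)])
      }
      expect_equal(got$index, seq_len(nrow(got)) - 1L)
    }
  })
})

test_that("locate_fragment honours half-open fragment bounds", {
  fm <- digest(tibble::tibble(chrom = "chrA", sequence = "TGATCGATCA"))
  expect_equal(locate_fragment(fm, "chrA", 0), 0)
  expect_equal(locate_fragment(fm, "chrA", 5), 2)  # boundary belongs to the next fragment
  expect_equal(locate_fragment(fm, "chrA", 4), 1)
  expect_error(locate_fragment(fm, "chrA", 10), "out of range")
  expect_error(locate_fragment(fm, "chrB", 1), "unknown chromosome")
})

test_that("locate_fragment round-trips with digest on random positions", {
  withr::with_seed(11, {
    s <- random_sequence(5000)
    fm <- digest(tibble::tibble(chrom = "c", sequence = s))
    pos <- sample(0:4999, 200)
    idx <- locate_fragment(fm, "c", pos)
    f <- fm[match(idx, fm$index), ]
    expect_true(all(f$start <= pos & pos < f$end))
  })
})

test_that("fragment_gap is the absolute index difference, cis only", {
  a <- tibble::tibble(chrom = "chrA", index = 10)
  expect_equal(fragment_gap(a, a), 0)
  expect_equal(fragment_gap(a, tibble::tibble(chrom = "chrA", index = 13)), 3)
  expect_equal(fragment_gap(tibble::tibble(chrom = "chrA", index = 13), a), 3)
  expect_error(fragment_gap(a, tibble::tibble(chrom = "chrB", index = 10)),
               "different chromosomes")
})

test_that("capture fragments follow the unique-TSS and length rules with fallback", {
  # TSS inside a 400 bp fragment containing no other TSS -> that fragment
  fm <- tibble::tibble(chrom = "chr1", start = c(0, 100, 500),
                       end = c(100, 500, 1000), index = 0:2)
  tss <- tibble::tibble(gene_id = "gA", chrom = "chr1", tss = 300)
  sel <- select_capture_fragments(fm, tss)
  expect_true(sel$accepted)
  expect_equal(sel$captured_fragment_index, 1)
  expect_equal(sel$selection, "tss_fragment")

  # TSS fragment 150 bp; upstream fragment 250 bp without another TSS
  fm2 <- tibble::tibble(chrom = "chr1", start = c(0, 250, 400),
                        end = c(250, 400, 800), index = 0:2)
  sel2 <- select_capture_fragments(
    fm2, tibble::tibble(gene_id = "gA", chrom = "chr1", tss = 300)
  )
  expect_true(sel2$accepted)
  expect_equal(sel2$captured_fragment_index, 0)
  expect_equal(sel2$selection, "upstream")

  # upstream fails, downstream eligible -> downstream (in this order)
  fm3 <- tibble::tibble(chrom = "chr1", start = c(0, 100, 250, 400),
                        end = c(100, 250, 400, 800), index = 0:3)
  sel3 <- select_capture_fragments(
    fm3, tibble::tibble(gene_id = "gA", chrom = "chr1", tss = 300)
  )
  expect_equal(sel3$selection, "downstream")
  expect_equal(sel3$captured_fragment_index, 3)

  # second TSS in the captured fragment and in both neighbours -> rejection
  fm4 <- tibble::tibble(chrom = "chr1", start = c(0, 300, 600),
                        end = c(300, 600, 900), index = 0:2)
  tss4 <- tibble::tibble(
    gene_id = c("gA", "gB", "gC", "gD"),
    chrom = "chr1", tss = c(350, 400, 100, 700)
  )
  sel4 <- select_capture_fragments(fm4, tss4)
  gA <- sel4[sel4$gene_id == "gA", ]
  expect_false(gA$accepted)
  expect_true(is.na(gA$captured_fragment_index))
})

test_that("capture selection is order-independent in the TSS list", {
  fm <- tibble::tibble(chrom = "chr1", start = c(0, 300, 600, 900),
                       end = c(300, 600, 900, 1500), index = 0:3)
  tss <- tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr1", tss = c(100, 450, 1200)
  )
  s1 <- select_capture_fragments(fm, tss)
  s2 <- select_capture_fragments(fm, tss[c(3, 1, 2), ])
  expect_equal(s1, s2)
})
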