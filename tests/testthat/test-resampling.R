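test_that("quantile bins are equal-occupancy with ties kept together", {
  g <- tibble::tibble(gene_id = sprintf("g%03d", 1:100), fpkm = qexp(1:100 / 101))
  b <- quantile_bins(g, fpkm)
  expect_equal(unname(as.vector(table(b$bin))), rep(10, 10))

  # n distinct values equal to n_bins: one gene per bin
  g10 <- tibble::tibble(gene_id = letters[1:10], fpkm = 1:10)
  expect_equal(sort(as.vector(table(quantile_bins(g10, fpkm)$bin))), rep(1L, 10))

  # all values identical: a single occupied bin (documented degenerate case)
  gsame <- tibble::tibble(gene_id = letters[1:20], fpkm = 3)
  expect_equal(length(unique(quantile_bins(gsame, fpkm)$bin)), 1)

  expect_error(quantile_bins(g10[1:5, ], fpkm), "fewer genes than bins")

  # binning is invariant under a monotone transform of the covariate
  b2 <- quantile_bins(g |> dplyr::mutate(fpkm = log10(fpkm + 8)), fpkm)
  expect_equal(b$bin, b2$bin)
})

test_that("matched samples reproduce the target's per-bin histogram exactly", {
  withr::with_seed(14, {
    g <- tibble::tibble(gene_id = sprintf("g%04d", 1:500), fpkm = rexp(500))
    b <- quantile_bins(g, fpkm)
    target <- sample(g$gene_id, 40)
    pool <- setdiff(g$gene_id, target)
    bin_of <- setNames(b$bin, b$gene_id)
    for (i in 1:25) {
      s <- matched_sample(target, pool, b)
      expect_length(s, 40)
      expect_true(all(s %in% pool))
      expect_false(any(duplicated(s)))
      expect_equal(table(factor(bin_of[s], levels = 1:10)),
                   table(factor(bin_of[target], levels = 1:10)))
    }
    # a fixed seed reproduces the sample
    s1 <- withr::with_seed(99, matched_sample(target, pool, b))
    s2 <- withr::with_seed(99, matched_sample(target, pool, b))
    expect_identical(s1, s2)
  })
})

test_that("an exhausted bin is reported by name", {
  g <- tibble::tibble(gene_id = sprintf("g%02d", 1:40), fpkm = 1:40)
  b <- quantile_bins(g, fpkm, n_bins = 2)
  # target takes 3 genes from bin 1; pool offers only 2 more there
  target <- g$gene_id[1:3]
  pool <- g$gene_id[4:5]
  expect_error(matched_sample(target, pool, b), "bin 1")
})

test_that("empirical p-values use the add-one estimator with the stated floor", {
  g <- tibble::tibble(gene_id = sprintf("g%04d", 1:400), fpkm = rep(1:100, 4))
  b <- quantile_bins(g, fpkm)
  bound <- setNames(g$gene_id %in% g$gene_id[1:50], g$gene_id)
  stat <- fraction_statistic(bound)

  # the target is exactly the bound genes: no null can beat it, p = 1/(n+1)
  r <- empirical_p(g$gene_id[1:50], g$gene_id, b, stat,
                   n_samplings = 200, seed = 5)
  expect_equal(r$observed, 1)
  expect_equal(r$p_value, 1 / 201)
  expect_length(r$null_values, 200)

  # constant statistic: every null ties the observed value, p = 1
  r1 <- empirical_p(g$gene_id[1:20], g$gene_id, b,
                    function(s) 1, n_samplings = 50, seed = 5)
  expect_equal(r1$p_value, 1)

  expect_error(empirical_p(g$gene_id[1:5], g$gene_id, b, stat, n_samplings = 0))
  expect_error(empirical_p(character(0), g$gene_id, b, stat, n_samplings = 10))
})

test_that("resampling is reproducible under seed and leaves observed unchanged", {
  withr::with_seed(70, {
    g <- tibble::tibble(gene_id = sprintf("g%04d", 1:300), fpkm = rexp(300))
    b <- quantile_bins(g, fpkm)
    z <- setNames(rnorm(300), g$gene_id)
    stat <- function(s) mean(z[s])
    target <- sample(g$gene_id, 25)
  })
  ra <- empirical_p(target, g$gene_id, b, stat, n_samplings = 100, seed = 12)
  rb <- empirical_p(target, g$gene_id, b, stat, n_samplings = 100, seed = 12)
  expect_identical(ra$null_values, rb$null_values)
  expect_identical(ra$p_value, rb$p_value)
  # doubling the samplings with the same seed stream leaves observed unchanged
  rc <- empirical_p(target, g$gene_id, b, stat, n_samplings = 200, seed = 12)
  expect_identical(ra$observed, rc$observed)
  expect_identical(rc$null_values[1:100], ra$null_values)
})

test_that("fraction statistics compute the predicate fraction and reject empty sets", {
  pred <- c(g1 = TRUE, g2 = FALSE, g3 = TRUE, g4 = TRUE, g5 = FALSE)
  stat <- fraction_statistic(pred)
  expect_equal(stat(names(pred)), 0.6)
  expect_equal(stat(c("g1", "g3", "g4")), 1)
  expect_error(stat(character(0)), "empty")
  expect_error(stat("unknown"), "undefined")
  fn_stat <- fraction_statistic(function(ids) grepl("^g[13]", ids))
  expect_equal(fn_stat(names(pred)), 0.4)
})

test_that("tidy, glance, print and autoplot summarise a resampling result", {
  g <- tibble::tibble(gene_id = sprintf("g%03d", 1:100), fpkm = 1:100)
  b <- quantile_bins(g, fpkm)
  r <- empirical_p(g$gene_id[seq(1, 100, 10)], g$gene_id, b,
                   function(s) mean(match(s, g$gene_id)),
                   n_samplings = 50, seed = 3)
  td <- generics::tidy(r)
  expect_equal(nrow(td), 1)
  expect_named(td, c("observed", "null_mean", "null_sd", "p_value"))
  gl <- generics::glance(r)
  expect_equal(gl$n_samplings, 50)
  expect_equal(gl$seed, 3)
  expect_output(print(r), "empirical p")
  expect_s3_class(ggplot2::autoplot(r), "ggplot")
})
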