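# promcapr

Downstream analysis of promoter Capture-C / Capture Hi-C interaction data,
written for regulatory-genomics analysts who receive an upstream interaction
caller's per-viewpoint tables (other-end fragment, read count, interaction
score) and need everything that comes after: restriction-fragment arithmetic,
library normalization, significant-interaction filtering and peak merging,
regulatory-element annotation, gene classification from DE and promoter ChIP
tables, expression-matched resampling enrichment tests, and
replicate-consistency calling of gained/lost interactions. A seeded synthetic
study generator emulates the caller's output so the whole pipeline is
testable end to end without any download.

## The methods in brief

* **Fragment map.** Chromosomes are digested in silico at every `GATC`
  (DpnII); fragments are 0-based half-open intervals indexed in coordinate
  order, and all interaction distances are measured in fragment units.
  Captured promoter fragments must be > 200 bp with a unique TSS, with an
  upstream-then-downstream fallback.
* **Normalization.** Per library (replicate × condition),
  `normalized = raw / total promoter-aligned reads / n promoters`, so every
  library's normalized counts sum to 1/n_promoters.
* **Peaks.** Interactions with caller score ≥ 5 (inclusive), pooled across
  conditions, are merged by single linkage when < 4 fragments apart; per peak
  and condition, values are summed over the full fragment span and divided by
  the span's fragment count.
* **Gene classes.** Induced: fold change ≥ 2, padj < 0.1. Underinduced
  (among induced): mutant fold change < 0.667, padj < 0.1. Bound: promoter
  ChIP counts > 39.39662 (log2 5.3) and fold > 1.274561 (log2 0.35).
  Responsive = bound ∧ underinduced; bound genes partition into
  responsive / stably induced / not induced.
* **Matched resampling.** The expression covariate is cut into 10
  equal-occupancy bins; random control sets reproduce the target's per-bin
  histogram exactly; empirical p = (1 + #{null ≥ obs}) / (n + 1) with
  n = 1000 samplings by default.
* **Differential calls.** A peak is lost (gained) when at least 3 of 4
  treated replicates are strictly lower (higher) than the untreated mean in
  *both* score and normalized coverage; H3K27ac changes classify on the
  pseudocounted ratio (x + 1) at a 2-fold cut-off.

See the methods vignette (`vignettes/promcapr-methods.Rmd`) for the full
account, including every boundary convention and the generator's study
conditions.

## Worked example

Everything below runs from a seeded synthetic study — no external data.

```r
library(promcapr)
library(dplyr)

sim   <- simulate_capture_study(sim_config(seed = 1))
norm  <- normalize_counts(sim$interactions, design = sim$design$viewpoints)
peaks <- merge_peaks_all(call_significant(norm, score_threshold = 5))
vals  <- aggregate_peaks(peaks, norm)

# annotate peaks against CDK8 and accessible sites (300 bp windows)
annotate_peaks(peaks, sim$fragments, tss = sim$design$tss,
               cdk8_peaks = sim$design$cdk8_peaks,
               regulatory_sites = sim$design$atac_peaks) |>
  count(cdk8_positive, regulatory)
#>   cdk8_positive regulatory     n
#> 1 FALSE         FALSE         20
#> 2 FALSE         TRUE          21
#> 3 TRUE          TRUE          26

# paired per-peak comparison of conditions (here: ESC vs RA-differentiated)
condition_summary(vals, "UNT", "RA")
#>   metric        mean_a    mean_b mean_diff p_value n_peaks
#> 1 score      4.95      3.83      1.12       0.0182      67
#> 2 norm_count 0.0000924 0.0000808 0.0000116  0.0124      67

# are underinduced genes enriched for promoter-bound genes, at matched expression?
lab  <- classify_genes(sim$genes)
bins <- quantile_bins(lab, fpkm_esc)
res  <- empirical_p(lab$gene_id[lab$underinduced], lab$gene_id, bins,
                    fraction_statistic(setNames(lab$fbxl19_bound, lab$gene_id)),
                    n_samplings = 1000, seed = 1)
res
#> Expression-matched resampling test
#>   observed statistic: 1 (target n = 12)
#>   null: 1000 matched samplings from pool of 1188 (mean 0.01858)
#>   empirical p (greater): 0.000999

# gained/lost interactions after MED13/13L loss (3-of-4 replicate rule)
byrep <- aggregate_peaks(peaks, norm, by_replicate = TRUE)
call_gained_lost(byrep, treated = "TAM_med13", untreated = "UNT") |>
  count(direction)
#>   direction     n
#> 1 gained       13
#> 2 lost         36
#> 3 none         18
```

Reading the output: 26 of 67 merged peaks sit within 300 bp of a CDK8 site
(all planted responsive/stably-induced distal ends, plus chance proximity);
interaction scores drop after RA differentiation (paired t, p ≈ 0.02); all
12 underinduced genes are promoter-bound versus a null expectation of ~1.9%
in expression-matched controls (the floor p = 1/1001 of 1000 samplings); and
the consistency caller flags the planted MED13-dependent losses.

`tidy()`, `glance()` and `autoplot()` work on resampling results;
`plot_viewpoint_profile()` and `plot_condition_scores()` draw the profile
line plots and condition boxplots.

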