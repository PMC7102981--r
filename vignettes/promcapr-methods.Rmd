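---
title: "Methods: downstream analysis of promoter Capture-C interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: downstream analysis of promoter Capture-C interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promcapr)
library(dplyr)
```

# Scope and model

promcapr implements the downstream half of a promoter Capture-C experiment:
everything after an upstream interaction caller has turned aligned reads into
per-viewpoint tables of (other-end fragment, read count, interaction score).
The package does not re-derive the caller's background model; its scores are
consumed as given, filtered at the published significance threshold
(score ≥ 5, inclusive).

The coordinate backbone is the in-silico DpnII fragment map: every chromosome
is cut at each `GATC` occurrence, with the cut placed at the motif's first
base (the convention of standard Hi-C digestion tools; the original analysis
does not state its in-silico convention, so we adopt the common one).
All coordinates are 0-based half-open, which makes BED input/output exact.
Ambiguous bases never match the motif — an undocumented corner in the source
analysis; treating `N` as a wildcard would invent cut sites, so no-match is
the conservative choice. Only the DpnII layer is modelled: the original probe
design also pre-filtered on HindIII fragments, but the published analysis
itself operates purely on DpnII fragments, so the HindIII constraint is
dropped here.

## Captured-fragment selection

A promoter's captured fragment must be longer than 200 bp (probe design) and
contain no TSS of another gene. When the TSS fragment fails, the immediately
upstream fragment is tried, then the downstream one — in this order, in
genomic coordinates — under the same rules. Rejection is a value, not an
error, so design pipelines can report why a promoter was excluded. Probe
length (70–120 bp) is carried as metadata only; oligo design is out of scope.

## Normalization and profiles

Each (replicate, condition) is one library. Normalized count =
raw count / (total promoter-aligned reads of the library) / (number of
promoters in the capture design), so every library's normalized counts sum to
1 / n_promoters and profiles are invariant under uniform rescaling of raw
counts. Only observed records enter the library total; zeros are materialized
later when profiles or peak spans need them.

Replicate pooling is an unweighted sum of normalized counts. The upstream
caller's own "weighted pooled" counts use a proprietary weighting we cannot
(and should not) re-derive; the unweighted sum preserves the only property
used downstream — a per-fragment, per-condition intensity. Scores are pooled
as the replicate mean, since they are −log10-probability-like and not
additive across libraries.

Viewpoint profiles are smoothed with a centered running mean whose window is
truncated at the series edges. The published line plots do not state their
window; it is therefore an explicit parameter with a package default of 11
fragments (odd, so the window is symmetric; at ~256 bp per fragment this
spans roughly 3 kb, a typical choice for Capture-C line plots).

## Peak merging and aggregation

Significant interactions from *all* conditions are pooled before merging, so
peak coordinates are identical across conditions and per-peak comparisons are
paired. Merging is single-linkage on fragment-index distance with the rule
"merge when fewer than 4 fragments apart": chains merge transitively, and a
gap of exactly 4 never merges. Single linkage (not complete linkage) matches
the semantics of collapsing runs of nearby significant fragments into one
peak. Trans (inter-chromosomal) merging is not performed — the analysis is
cis-only.

Per peak and condition, the sum of per-fragment values across **all**
fragments in the peak's span — observed or not — is divided by the number of
fragments in the span. The alternative (observed-fragments-only denominator)
was rejected because the published procedure sums "across all overlapping
fragments" of a peak; sparse peaks are therefore penalized, which is the
intended behaviour.

## Annotation windows

"Within N bp" bounds are inclusive throughout: TSS windows are the closed
interval ±1000 bp around the TSS, CDK8-overlap uses 100 bp, and peak-level
CDK8/regulatory annotation uses 300 bp. The gap between half-open intervals
[a,b) and [c,d) with b ≤ c is c − b, and overlap counts as gap 0. A plain
overlap test (used for TSS windows and the expressed-gene filter) is strict:
touching intervals do not overlap. Signal quantitation is the per-base sum
over the window (read-count-style enrichment); a mean option exists but is
not the default. The two pseudocounted transforms of the analysis are
log2(x + 1) for ChIP signal and log10(x + 8) for expression counts, and the
expressed-gene FPKM cutoff 1.1435 is strict (FPKM > cutoff means expressed).

## Gene classes

Classes follow the printed thresholds exactly, with the printed boundary
semantics locked by tests: induced means fold change ≥ 2 (inclusive) with
padj < 0.1 (strict); underinduced is defined only among induced genes and
requires mutant fold change < 0.667 with padj < 0.1 (both strict); bound
requires promoter ChIP counts > 39.39662 and ChIP fold change > 1.274561
(both strict, "more than"). These two binding constants are the linear-scale
inversions of log2 cut-offs 5.3 and 0.35 that were chosen from bimodal signal
distributions; the bimodality procedure is not algorithmically specified, so
the constants are configuration values, not re-derived quantities. Bound
genes partition exhaustively into responsive (bound ∧ underinduced), stably
induced (bound ∧ induced ∧ ¬underinduced) and not induced (bound ∧
¬induced). Genes with missing values fail closed — excluded from every
class, with a warning — because a silently mis-assigned gene is worse than a
dropped one. DE statistics are consumed from a table; no DE model is fitted
here.

## Expression-matched resampling

The null for gene-set enrichment questions is resampling matched on
expression: the covariate is binned into 10 equal-occupancy quantile bins,
and each random control set reproduces the target's per-bin histogram
exactly, sampled without replacement within a draw. Binning uses
`stats::quantile` breaks with ties kept in one bin, so realized bin sizes can
deviate minimally when the covariate has ties; binning on any monotone
transform (e.g. log10(x + 8)) gives identical bins, so raw FPKM is the
implemented default. Target genes are excluded from the control pool by
default, since the question contrasts genes of interest against controls; the
exclusion is configurable, and the calibration analyses keep the target in
the pool so that observed and null draws are exchangeable.

The empirical p-value uses the add-one estimator
p = (1 + #{null ≥ observed}) / (n + 1), the standard permutation-test form:
it can never return 0, its floor is 1/(n + 1), and under the null it is
uniform on that grid. The published analysis says only "empirical P-values";
one-sided "greater" is the default because every published use is an
enrichment question, and a two-sided option (double the smaller tail, capped
at 1) is provided. n = 1000 samplings is the default, matching most figures;
10 000 was used for one figure and is a parameter.

## Differential calls

Gained/lost interaction calls use the replicate-consistency rule: a treated
replicate is consistent when **both** its span-averaged score and its
normalized coverage are strictly lower (or both strictly higher) than the
untreated reference, and a direction is called at ≥ 3 of 4 consistent
replicates. Libraries are not naturally paired between conditions, so the
untreated reference is the mean over untreated replicates — the defensible
reading of an unstated pairing. Exact ties count as inconsistent, so
degenerate equal data yields "none". With clearly separated values the rule
is antisymmetric (swapping conditions swaps gained and lost).

Condition-level summaries compare per-peak means with a paired t-test across
peaks (pairing by peak identity, which the pooled-condition merging
guarantees). When every per-peak difference is zero the t statistic is
undefined and p is reported as 1.

H3K27ac changes are classified on the pseudocounted ratio
(treated + 1)/(untreated + 1) at a 2-fold cut-off: gain when r ≥ 2, loss when
r ≤ 1/2, else stable. The ratio uses the module-wide ChIP pseudocount of 1
and no log transform.

# The synthetic study generator

The generator emulates the upstream caller's output so that the entire
pipeline is testable without any external download. Its defaults define the
study conditions used in the tests and are not tuned per run:

* **Genome**: 2 chromosomes × 300 kb; GATC cuts planted at geometric
  spacings with expected density 1/256 per bp (the iid-uniform ACGT
  expectation, giving the familiar ~256 bp mean DpnII fragment), with
  motif-free random fill between cuts so planted cuts are exactly the
  digestion cuts.
* **Design**: 40 viewpoints on capture-eligible fragments, class fractions
  0.3 / 0.3 / 0.2 / 0.2 (responsive / stably induced / not induced /
  control), one planted distal site per viewpoint at 25–45 fragments
  distance; CDK8 peaks mark responsive and stably-induced distal ends; ATAC
  peaks sit at every distal site plus 60 decoys; 1200 genes in total
  (non-captured background genes fill the universe for binning pools).
* **Counts**: background expectation μ(d) = 50·(1 + d)^(−1) at fragment
  distance d, negative-binomial with size 10 for replicate scatter; the
  planted fragment's μ is multiplied by the class/condition enrichment —
  responsive↔CDK8: 8 (UNT), 5.5 (TAM_fbxl19), 2 (TAM_med13), 1.2 (RA);
  all other classes constant 8. These defaults reproduce the qualitative
  ordering of the published condition effects (modest reduction on FBXL19
  loss, strong reduction on MED13/13L loss, near-complete loss after RA) and
  are all configurable.
* **Scores**: the emulated caller score is −log10 of the Poisson upper-tail
  probability of the observed count under the background μ(d). This is a
  deliberate simplification of the real caller's model; it preserves the only
  properties the pipeline consumes — monotone in enrichment, meaningful at
  the ≥ 5 threshold — and makes planted peaks typically significant while
  background rarely is (< 1% of records under an all-ones enrichment).
* **Gene table**: values are drawn with noise but inside the regions their
  planted class prescribes, so classification recovers planted labels;
  control/background genes violate at least one binding condition by
  construction.
* **H3K27ac sites**: a planted fraction (default 0.19) of
  responsive-interacting sites gains ≥ 2-fold on the pseudocounted ratio;
  the rest are drawn strictly inside the 2-fold band. The design itself
  yields only ~a dozen responsive distal sites, so the site table is padded
  with synthetic responsive-interacting sites (on a clearly separate
  `chrS` padding contig) to 400, a realistic site count for fraction
  recovery.

Every stage draws from a seed offset deterministically from the config seed,
so repeated runs are byte-identical on disk. The planted truth is emitted
alongside the data and never consumed by the pipeline.

**What the generator does not emulate** — and therefore what passing tests do
not show about real data: read-level artefacts (ligation junctions,
mappability, GC bias), the real caller's p-value weighting and its
distance-dependent dispersion, trans interactions, multi-fragment distal
elements, correlated replicates, and any coupling between expression level
and interaction strength. Published dataset-level fractions (e.g. the share
of underinduced genes that are FBXL19-bound) depend on the deposited
accessions and are represented here only as configurable planted truths.

# Problem sizes and numerical choices

The test and acceptance suites run the generator at its defaults (40
viewpoints, 4 conditions × 4 replicates, ~2300 fragments, ~60 000 interaction
records) and smaller variants for unit tests; resampling calibration uses 200
simulated datasets at 200 samplings each — sizes chosen so the full suite
completes in a few minutes on a laptop while leaving the planted effects
comfortably detectable. Other numerical choices: the running-mean smoother
requires an odd window and errors otherwise (no silent recentering);
`quantile_bins` errors when there are fewer genes than bins and collapses to
a single occupied bin when all values tie (documented degenerate case);
`matched_sample` errors naming the first exhausted bin; score emulation uses
`log.p = TRUE` tail probabilities so large counts do not underflow to
infinite scores; and bedGraph export run-length merges only runs that are
both equal-valued and contiguous.

# Known limitations

* The caller-score emulation is Poisson-tail based and intentionally crude;
  absolute score magnitudes are not comparable with any specific caller, only
  orderings and thresholds are meaningful.
* The unweighted replicate pooling may differ from the upstream caller's
  weighted pooling in ways the published text does not let us quantify.
* The 3-of-4 consistency caller compares each treated replicate with the
  untreated mean; if libraries were in fact paired, a matched-pairs variant
  would be slightly more powerful.
* `condition_summary` applies a paired t-test to span-averaged peak values,
  whose distribution is right-skewed; with few peaks the p-value should be
  read qualitatively, as in the original figures.
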