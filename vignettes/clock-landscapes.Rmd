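---
title: "Genome landscapes of regional molecular clock rate variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome landscapes of regional molecular clock rate variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clockscape)
```

## The model

Orthologous proteins accumulate amino-acid differences roughly linearly in
time. For a pair of species separated for `t` million years, percent protein
divergence follows the molecular-clock law

    PD% = k * t

where `k` (% divergence per My) is the clock constant of that protein. `k`
varies enormously between proteins — about two orders of magnitude between
the slowest and fastest percentiles — so the genome-wide average

    PDav% = kav * t

is the quantity that behaves like a clock. `clockscape` fits `kav` by a
through-origin regression of `PDav%` on `t` across all species pairs; on a
cohort of 16 mammals (12 Eutheria in three clades of four, 4 Metatheria)
there are 120 pairs spanning roughly 60–160 My of separation.

Dividing each gene's divergence by the pair average removes time entirely:

    nPD% = PD% / PDav% = k / kav

`nPD%` is a gene's clock rate relative to the genome average. By
construction its mean over the included genes of any pair is exactly 1, an
identity the tests exercise end to end.

Individual genes are noisy, so regional structure is read from a sliding
window: genes are ranked along a reference genome (a `genome_order`) and the
windowed value at rank `k` is the mean over the centered gene and its 100
neighbors (50 per side). Windowed `nPD%` tracks, averaged over all pairs
within a lineage (66 intra-Eutherian or 6 intra-Metatherian comparisons),
form the landscape in which regional accelerations stand out.

## Deciding what is "accelerated"

Whether a windowed peak is remarkable depends on what random gene orders
produce. `random_order_null()` permutes the per-gene values uniformly over
the same chromosome partition (three random orders by default), recomputes
the windows, pools all window values, and sets the threshold at

    pooled mean + 3 * pooled SD

which for heavy-tailed per-gene rates lands roughly 30% above the genome
mean. Windows strictly above the threshold form the exceedance set; each
gene centers one window, so genes and windows are interchangeable counts.
Two conventions are fixed here and exposed as options:

* the SD is computed over the pooled window values of all replicates
  (a per-replicate mean-of-SDs mode exists);
* exceedance is a strict inequality, so a landscape exactly at the threshold
  is empty.

Before permuting, the value vector is sorted into a canonical order. This
makes the null depend only on the value multiset, the chromosome partition,
and the seed — relabeling genes cannot change the threshold, which turns a
distributional invariance into an exact, testable one.

Subtelomeres are defined positionally: the first and last 50 genes of every
chromosome (2,300 windows on a 23-chromosome order of 15,727 genes, about
15%). Enrichment of the exceedance set in subtelomeres is reported as
observed fraction, expected fraction, and their fold ratio.

## Pairwise divergence

Protein identity is computed from optimal global alignments (BLOSUM62,
affine gaps, end gaps penalized), the scheme of the EMBOSS Stretcher tool.
The tool's protein defaults, gap open 12 and extend 2, are used; a gap of
length L costs `open + L * ext`. Identity is

    100 * matches / (alignment length - gap-containing columns)

i.e. identity over aligned residue-pair columns, which avoids punishing
incomplete sequences for their missing tails. Identities below 30% are
discarded (masked) rather than treated as divergence, and

    PD% = 100 - identity%.

Only the score of an optimal alignment is contractual: co-optimal alignments
can differ in identity, so identity is asserted only on unambiguous
fixtures while scores are checked against an independently written
affine-gap dynamic-programming oracle on hundreds of random short pairs.

## What the synthetic cohort emulates

The generator (`sim_config()`, `simulate_study()`) reproduces the
statistical structure the analysis assumes, so that every stage is testable
without any sequence download:

* **Design**: 16 species, 15,727 shared genes, 120 pairs; divergence times
  from a fixed ultrametric (70 My within Eutherian clades, 96 My between
  Euarchontoglires and Laurasiatheria, 104 My to Afrotheria, 158.5 My to
  Metatheria, 60 My within Metatheria).
* **Orders**: a human-like order A (23 chromosomes, human-like relative
  gene counts) and an opossum-like order B (8 large autosomes + X) carrying
  the same genes in an independent random order, reflecting the karyotype
  independence of the two lineages.
* **Rates**: per-gene `k` is lognormal with genome mean 0.13 %/My (1.3% per
  10 My) and log-SD 0.9, which spreads the 1st–99th percentiles over about
  two orders of magnitude — the observed scale of inter-protein rate
  variation.
* **Regional effects**: three 300-gene blocks per lineage with a 3x rate
  multiplier at named subtelomeres of the lineage's own order (human-like
  4p, 14q, Xq for Eutheria; opossum-like 1q, 6q, Xq for Metatheria).
  Cross-lineage pairs average the two lineage multipliers, since each
  lineage's regional effect acts on its own branch of the path.
* **Noise**: realized PD is `100 * Binomial(450, d/100) / 450` with
  `d = min(k * mult * t, 95)` — 450 sites is a typical protein length, and
  the 95% cap keeps the linear law sane at extreme rates. Realized PD above
  70% is masked, mirroring the 30% identity floor of the alignment path.
* **GC/GARP**: smooth regional profiles per lineage on its own order, with
  subtelomeric GC elevation, species-level wiggle, gene-level noise, and a
  GARP track coupled to the regional GC profile with coefficient 0.93, so
  windowed within-species GC–GARP correlations land near 0.93 while the two
  lineages' landscapes differ.
* **Sequences** (optional, slow path): root proteins uniform over 20
  residues evolved along the dated species tree with Poisson substitutions
  at `k/200` per site per My per branch, exercising the aligner end to end.

The "generator truth" recovered by the clock regression is the implied
genome-wide constant — the through-origin slope of the *expected included*
PDav% on `t`, accounting for the cap, the identity floor and the planted
multipliers (`implied_k_av()`). The raw lognormal mean is not the estimand:
the planted blocks inflate every pair class's expected divergence by the
same factor, and the floor/cap truncate the heavy tail, all of which are
part of what the pipeline should estimate.

## What the generator does not emulate

Real data add several things the cohort deliberately omits: alignment error
and incomplete gene models, lineage-specific gene loss, within-lineage rate
variation for the same gene (a relaxed clock across branches), mutational
saturation beyond a hard cap, and correlated rates of neighboring genes
outside the planted blocks. Passing tests therefore demonstrate that the
pipeline's statistics behave as designed under the stated generative law,
not that the biological conclusions of any particular real dataset are
correct.

## Numerical and design choices

* **Windows at edges**: the default `"concatenated"` policy runs windows
  over the whole ranked gene list across chromosome joins, truncating only
  at the two genome ends; a `"per-chromosome-truncated"` policy is provided
  because displayed landscapes demarcate chromosomes. The window definition
  itself is purely rank-based, so either is defensible; the default avoids
  high-variance short windows at every chromosome end.
* **Missing data**: dropped from window means; a window is missing only if
  all contributors are. Genes masked in every pair of a class contribute
  missing values to that class's landscape.
* **Chromosome display order** is file order of first appearance, never
  lexicographic.
* **Ties in gene ranking** break by gene id, making orders reproducible.
* **Through-origin regression** is the default clock fit, matching the
  neutral expectation that divergence vanishes at `t = 0`; a free-intercept
  fit is one flag away. R² is the squared Pearson correlation between
  observed and fitted values, which stays well behaved for through-origin
  fits.
* **Equal weight per pair** in clade means (not per species); windowing and
  averaging commute on missing-free data, and the per-gene-mean-first path
  used by the acceleration analysis equals the window-first path there.
* **Link coloring margins**: the 50-gene subtelomere margin matches the
  window scale, but planted accelerated regions span ~300 genes, so
  `run_study()` classifies cross-genome links at a coarser, block-scale end
  margin (300 genes) — the analogue of a low-resolution synteny view —
  while subtelomere enrichment always uses the 50-gene labels.

## Problem sizes and statistical margins

The test suite runs the full 15,727-gene, 120-pair cohort for the
end-to-end checks (a few seconds per cohort) and smaller instances
elsewhere; oracle batteries use hundreds of short alignments and windows up
to 2,000 genes.

One statistical margin deserves honesty: with no planted effects, the
fraction of windows above the mean + 3 SD threshold has median ≈ 0.3–0.4%
(the same order as randomized-order sets in real data), but its across-seed
distribution is right-skewed — window means of 101 heavy-tailed values keep
skewness ≈ 0.45, and exceedances arrive in runs of correlated windows. For
any rate law with a 50-fold-or-more percentile spread, roughly 3% of seeds
produce a fraction touching 1%. The sub-1% behavior is typical, not a
uniform guarantee.

## Known limitations

* Identity of co-optimal alignments is implementation-defined; only scores
  are contractual.
* The 95% divergence cap and the 70% masking rule make extreme-rate genes
  partially observable; estimates of `kav` are defined with respect to the
  included-gene expectation, not the latent mean rate.
* `gc_percent()` operates on coding sequence; untranslated regions are out
  of scope.
* No multiple-testing machinery beyond the mean + 3 SD rule, and no
  correction for saturation of PD — both deliberate, to match the method
  being reimplemented.
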