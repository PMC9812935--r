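---
title: "Linking promoter binding to absolute germ-cell expression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking promoter binding to absolute germ-cell expression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meioreg)
```

## The analysis this package implements

During male meiosis in the mouse, the transcription factors A-MYB and
TCFL5 reprogram germ-cell gene expression. Asking *which* genes a factor
controls, and *when* those genes are expressed, requires joining two
measurements: promoter occupancy (CUT&RUN and ChIP-seq peak sets per
replicate) and stage-resolved transcript abundance in FACS-purified
germ-cell populations (spermatogonia, primary spermatocytes, secondary
spermatocytes, round spermatids). `meioreg` implements that join as a
reusable, testable pipeline:

1. **Absolute quantification.** With a known quantity of ERCC spike-in
   RNA added per library, a gene's abundance in molecules per cell is
   `reads × total_spike_molecules / (n_cells × spike_reads)`; the
   default `total_spike_molecules` is 623,291,645, the loading of a
   1:100 dilution of ERCC mix 1, and it is configurable. Because cell
   types differ enormously in size, abundances are compared as
   *transcript concentration*: molecules per cell divided by relative
   cell volume. RPKM is also computed for within-sample comparisons.
2. **Stage classification.** Genes are classified from their
   concentrations: *mitosis-specific* (spermatogonia more than twice
   primary spermatocytes), *meiosis I-specific* (primary spermatocytes
   more than twice both spermatogonia and secondary spermatocytes), and
   *persistent* (primary more than twice spermatogonia, with secondary
   and round-spermatid levels essentially unchanged relative to
   primary). Everything else is unclassified.
3. **Promoter binding.** For each gene the signed distance from its TSS
   to the nearest peak summit is computed (positive = downstream in
   gene orientation). A replicate supports binding when a summit lies
   within 500 bp of the TSS (inclusive). Replicate evidence is combined
   per TF: TCFL5 requires peaks in both CUT&RUN replicates, or in one
   CUT&RUN replicate plus two of three ChIP-seq replicates; A-MYB
   requires both CUT&RUN replicates, or one CUT&RUN replicate plus its
   single ChIP-seq replicate.
4. **Differential expression.** Mutant-versus-control fold changes are
   filtered at mutant/control < 0.5 and Benjamini–Hochberg FDR < 0.05,
   both strict.
5. **Circuits.** Bound genes become signed activating edges of a
   regulatory graph (repression must be asserted explicitly); the
   package enumerates feedforward triads with the standard
   coherent/incoherent 8-type labels, autoregulatory edges, and mutual
   feedback pairs, tests gene-set binding enrichment with a 2×2
   chi-square, and scans sequences for the TCFL5 consensus `WANSWCGW`.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `window_bp` | 500 | promoter window half-width (bp), inclusive |
| `total_spike_molecules` | 623291645 | spike-in molecules per library |
| `fold` (categories) | 2 | "more than twice", strict |
| `unchanged_band` | [0.5, 2] | "essentially unchanged", inclusive |
| `max_fold`, `max_fdr` | 0.5, 0.05 | DE filter, both strict |
| `rel_volume` | user-supplied | relative cell volumes per type |

Interpretation decisions that the thresholds alone do not settle, and
how this package resolves them:

* **"Within 500 bp" is a closed interval**: |distance| = 500 counts.
  The phrase "within the range of 500 bp" reads as inclusive; the
  boundary case is exercised in the tests.
* **"More than twice" is strict**: a gene at exactly 2× is not
  classified. Ties at a threshold are treated as failures throughout.
* **"Essentially unchanged" is quantified** as a ratio to the
  primary-spermatocyte concentration within [0.5, 2.0] inclusive; no
  published number exists, so the band is exposed in `category_rules()`.
* **Nearest-summit ties** (two summits equidistant from a TSS) prefer
  the upstream summit, then the peak with the smaller start — an
  arbitrary but deterministic rule.
* **Minus-strand TSS** is `end − 1` of the half-open interval, i.e. the
  last covered base; all internal coordinates are 0-based half-open.
* **Unknown strands are rejected**, not guessed: the sign of a
  summit-to-TSS distance depends on strand.
* **Multi-isoform genes** are represented by a single TSS per
  `gene_id`; isoform collapsing is the caller's responsibility.
* **FDR control is Benjamini–Hochberg** (`stats::p.adjust`), the
  community default; the procedure behind published "FDR" values is
  often unnamed.
* **The chi-square enrichment test uses no continuity correction**; an
  exact (Fisher/hypergeometric) p-value is reported alongside whenever
  an expected cell drops below 5. The gene universe is always an
  explicit argument and never inferred.
* **Averaging across replicate libraries** of one cell type uses the
  mean of per-sample molecule estimates (median available).
* **ChIP replicate evidence is per replicate file**, never pooled; a
  peak set carrying replicates beyond a rule's declared totals is a
  configuration error rather than something to reinterpret.

## The differential-expression engine is a placeholder

`de_test()` is deliberately plain: spike-in (or library-size) scale
factors, a 0.5 pseudocount, fold change as the ratio of group means,
and a two-sided Welch test on `log2(normalized + 0.5)`, with
zero-variance groups mapped to p = 1 (identical means) or p = 0
(separated means). It exists so the pipeline runs end to end without an
external DE package; it applies no dispersion shrinkage and will be
underpowered at small counts. Externally computed tables (for example
from a count-model DE package) can be fed directly to `bh_fdr()` and
`de_filter()`, which accept any per-gene fold-change/p-value table.
Spike-in normalization is the default because a genotype that globally
reduces transcription violates the equal-library-composition assumption
behind library-size scaling.

## What the synthetic-data generator emulates

The generator (`sim_config()` plus `gen_*()`) plants known ground truth
with the study's design: four germ-cell types, two expression
replicates each; TCFL5 profiled by 2 CUT&RUN + 3 ChIP-seq replicates
and A-MYB by 2 CUT&RUN + 1 ChIP-seq; promoter peaks jittered uniformly
within ±`jitter_bp` of the TSS with optional per-replicate dropout;
decoy peaks placed strictly outside every promoter window; category
proportions defaulting to roughly the reported class sizes; and
negative-binomial counts whose per-category concentration patterns use
a planted 4-fold change — comfortably above the 2-fold classification
thresholds, so noise-free recovery is exact rather than marginal.

Choices worth knowing when interpreting results on this synthetic
data:

* **TSSs sit on a 5 kb grid**, so a planted peak of one gene can never
  fall inside another gene's promoter window. Real promoters cluster
  and overlap; perfect specificity on synthetic data therefore does not
  promise perfect specificity on a real genome.
* **Bound genes are planted as exact counts** (`round(fraction × n)`
  per category), not per-gene coin flips, so a configured bound
  fraction is the dataset's true fraction by construction.
* **One global reads-per-molecule scale** is shared by all samples, so
  read counts stay proportional to molecule numbers across cell types —
  the premise of spike-in calibration. Per-sample totals consequently
  average, rather than exactly equal, the configured depth, while
  spike-in rows receive exactly `spike_fraction × total_reads` reads in
  noise-free mode (largest-remainder apportionment across 24 spike-in
  species spanning three orders of magnitude).
* **`dispersion = 0` is the exact noise-free mode** (counts are rounded
  expected means); positive values draw negative-binomial counts with
  `size = 1/dispersion`. Negative values are rejected.
* **Relative cell volumes are arbitrary** (spermatogonia 1, primary
  spermatocytes 2.5, secondary 1.5, round spermatids 1): the real
  correction factors are not published, so these defaults exist only to
  exercise the volume-correction arithmetic and are fully configurable.
* **In the two-genotype dataset spike-in reads are constant across
  samples** and libraries are not renormalized to a common depth, so
  spike-in normalization recovers the planted fold exactly in
  noise-free mode. A real experiment adds pipetting noise to the spike
  amounts; the generator does not model that.
* The generator does not simulate raw reads, fragment coverage,
  peak-caller behavior, GC or length bias, isoforms, or cell-type
  cross-contamination from FACS. Tests passing on this synthetic data
  validate the *rules and arithmetic* of the pipeline, not the upstream
  measurement process.

Every generator call derives its RNG stream from `sim_config()$seed`
and restores the caller's RNG state, so a configuration is a complete,
reproducible description of a dataset.

## Numerical and degenerate-input conventions

* Result tables are written with 17 significant digits so that
  write-then-read round-trips are bit-identical.
* `molecules_per_cell()` promotes integer inputs to double before
  multiplying (the calibration constant exceeds integer range).
* Genes silent in all four cell types are unclassified and flagged
  `silent`; ratios against a zero primary-spermatocyte concentration
  never classify a gene.
* A TF with no peak on a gene's chromosome yields a missing nearest
  distance and a not-bound call, not an error.
* A degenerate enrichment margin (gene set empty or equal to the
  universe) returns a zero statistic with a warning instead of an
  error, so callers can proceed over many gene sets.
* An `N` in a scanned sequence is treated as fully ambiguous (it may
  pair with any pattern symbol). Degenerate motif positions are not
  scored: scanning is hit/no-hit, which is all a consensus supports —
  position-weight-matrix scoring is out of scope.

## Problem sizes used in validation

The shipped tests and the acceptance script validate at 2,000 genes on
two 60 Mb chromosomes (plus smaller fixtures), 20-seed null-calibration
batches of 3-versus-3 replicate comparisons, 50-node random graphs for
the feedforward-loop oracle, and 10 kb random sequences for the motif
oracle — sizes chosen so the full suite re-runs in well under a minute
on one core while still exercising every code path at realistic
densities.

## Known limitations

* The binding-evidence rule set is the fixed two-clause family
  "all CUT&RUN, or ≥1 CUT&RUN and ≥k ChIP"; arbitrary predicate
  expressions are not supported.
* `de_test()` is intentionally simple (see above).
* The pipeline classifies expression from exactly the four germ-cell
  types; whole-testis samples are carried through quantification but
  ignored by classification.
* Motif scanning reports consensus matches only; no E-values or PWM
  scores.
* Chi-square enrichment requires the caller to choose a defensible
  universe (e.g. all protein-coding genes with measurable expression);
  the package deliberately refuses to guess it.
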