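---
title: "Scoring pooled CRISPRi dropout screens against a non-targeting-control null"
author: "crisprdrop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pooled CRISPRi dropout screens against a non-targeting-control null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprdrop)
```

## The screen and its readout

A pooled CRISPRi growth ("dropout") screen infects a dividing cell
population with a lentiviral library of single guide RNAs at low
multiplicity of infection (MOI ~ 0.3, so most infected cells carry one
guide) and lets the pool grow for an extended window — here 21 days.
Guides that silence a gene required for growth deplete relative to the
starting material; guides against growth suppressors enrich. The
starting material is the *plasmid pool* (the cloned library before
infection), which serves as the reference sample. Sequencing the guide
cassette in the plasmid pool and at the endpoint yields a guide-by-sample
count table; everything downstream is inference on those counts.

The library design this package's defaults emulate targets the
transcription start sites (TSSs) of 2342 lncRNAs with 10 guides each,
plus 700 non-targeting control guides (NTCs — spacers matching nowhere
in the genome) and 50 growth-essential protein-coding genes as positive
controls, about 25,000 guides in all.

## From counts to gene calls

1. **Spacer counting** (`count_spacers()`): a read is assigned to a guide
   when the window `[trim5, trim5 + spacer_len)` equals a library spacer
   exactly. Exact matching with zero mismatches keeps counting
   deterministic and unambiguous; reads shorter than the window, or
   matching nothing, are tallied as unmatched, so matched + unmatched
   always equals the number of reads. FASTQ records are the plain 4-line
   form, plain or gzipped; a flag also searches each read's reverse
   complement.

2. **Median normalization** (`median_normalize()`): every sample is
   rescaled so its median guide count equals the reference median,
   removing depth differences while staying on the familiar read scale.
   A zero median is refused rather than patched — such a sample is
   unusable.

3. **Per-guide log2 fold change** (`guide_lfc()`):
   `lfc = log2((norm_endpoint + 1) / (norm_reference + 1))`. The
   pseudocount of 1 read caps the dynamic range (a guide sequenced to
   zero at the endpoint bottoms out near `-log2(norm_reference + 1)`)
   and makes dropout and enrichment symmetric on the log scale. Guides
   with fewer than 10 raw plasmid reads are flagged and excluded from
   gene scoring: guides that were barely present before selection
   produce fold changes dominated by sampling noise.

4. **NTC centering** (inside `score_screen()`): all fold changes are
   shifted so the median NTC fold change is zero. The NTC population
   defines "no effect", and this step matters more than it looks: when
   an appreciable fraction of guides genuinely drops out, the endpoint
   median (computed over all guides, dying ones included) sits below the
   median of the surviving population, so every surviving guide's raw
   lfc is shifted slightly positive. Without re-centering, nearly every
   NTC pseudo-gene takes the enrichment direction, the null's mean moves
   away from zero, and neutral genes whose guide median happens to land
   on the other side are scored against the wrong tail — we measured
   ~2% spurious dropout calls in simulations with a 10% planted hit
   burden. Centering restores a balanced null and brings the false-call
   rate back under 1%.

5. **Gene statistic and z-score** (`build_ntc_null()`, `score_gene()`):
   a gene's direction is the sign of its median guide fold change (a
   tie defaults to dropout, the screen's direction of interest), and its
   phenotype is the mean of its `k = 3` most extreme guides in that
   direction — echoing the convention of ranking hits by their three
   best-performing guides, and robust to the sizeable fraction of
   designed guides that are simply inert. The null distribution of this
   statistic is built by resampling *pseudo-genes*: 10,000 draws of
   `pseudo_gene_size` NTC fold changes (default: the library's
   guides-per-gene) scored by exactly the same rule. The gene's z-score
   standardizes its statistic against the pooled mean and standard
   deviation of the pseudo-gene scores. Genes with `z < -3` are called
   positive regulators of growth (their guides dropped out); `z > +3`,
   negative regulators. Because the pooled null mixes both directions,
   its standard deviation is wider than either directional lobe, which
   makes the +/-3 cut conservative; per-direction moments are stored in
   the null object as diagnostics.

6. **Rank-sum support** (`mann_whitney_gene()`): each gene's guide fold
   changes are additionally compared with the NTC fold changes by a
   Mann-Whitney U test. When the number of group assignments
   `choose(n+m, n)` is at most 1e5 the two-sided p-value is exact, by
   full enumeration with mid-ranks for ties, defining extremeness as
   `|U - nm/2|`; beyond that, the normal approximation with tie
   correction and continuity correction takes over (the screen-scale
   case: 10 guides against hundreds of NTCs). P-values accompany the
   z-calls; a Benjamini-Hochberg column is emitted for information but
   hit calling uses the z threshold alone, mirroring how such screens
   are reported.

7. **Ranking** (`rank_hits()`): hits are sorted by z (ascending for
   dropout), with ties broken by smaller Mann-Whitney p and then gene
   id, and each hit carries its top-3 guide fold changes.

## Classifying lncRNA hits by genomic context

`classify_lnc_category()` assigns each lncRNA exactly one label relative
to its same-chromosome neighbors, with overlap-based labels taking
precedence over distance-based ones:

* **protein_coding** — the locus is annotated protein-coding (some hits
  in older annotations are re-annotated this way);
* **antisense** — overlaps a neighbor on the opposite strand;
* **intronic** — contained in one intron of a neighbor;
* **bidirectional** — TSS within 1 kb of an opposite-strand neighbor's
  TSS, without overlap (a shared divergent promoter);
* **intergenic** — no overlap and every neighbor's TSS at least 1 kb
  away (its own promoter).

Coordinates are 0-based half-open throughout (BED convention), and the
TSS of a minus-strand gene is `end - 1`; stating this once avoids
off-by-one drift between readers. "Promoter" is operationalized as the
TSS point, since no promoter width is part of the definitions. A gene
satisfying no rule (e.g. a same-strand overlap) raises an error naming
it rather than guessing — classification is a partition or a refusal,
never a silent default.

## The simulator and what it does (not) emulate

`simulate_screen()` generates screens with known ground truth in five
seeded stages: log-normal plasmid abundances (sigma 0.5, emulating
uneven cloning); Poisson founding of clones at `coverage` cells per
guide, thinned by the probability that an infected cell carries a single
integration at the chosen MOI (`moi * exp(-moi) / (1 - exp(-moi))`, ~0.86
at MOI 0.3); deterministic exponential growth of expected clone sizes at
rate `ln(2)/doubling_time * (1 - gene_effect * guide_efficacy)`;
and multinomial sequencing of `depth` reads per sample (a
Dirichlet-multinomial when `dispersion > 0`). Guide efficacy is
all-or-nothing: a targeting guide is active with probability 0.7 and
then achieves a knockdown of 0.9 — a deliberately simple stand-in for
the observed bimodality of TSS-targeting guide performance. Defaults
(MOI 0.3, coverage 1000, 21 days, 1-day doublings, 500 reads per guide)
are the screen conditions stated above.

Deliberate omissions: no cell-level birth-death noise (at 1000x coverage
founding and sequencing dominate), no separate puromycin-selection
phase (selection completes before the growth window; pre-selection
dynamics are absorbed into founding), no off-target effects or
chromatin-silencing kinetics, and no guide-level variability beyond the
active/inert dichotomy. Passing calibration and recovery tests on these
simulations therefore demonstrates the statistics behave correctly under
the stated generative model — not that real screens are free of the
artifacts the model omits (PCR jackpots, position effects, heterogeneous
TSS annotation quality).

## The competition assay

The mixed-cell validation assay grows marker-positive knockdown cells
1:1 with unmarked cells and follows the marker-positive fraction `f(t)`
by flow cytometry. Enrichment is defined on odds,
`E(t) = [f(t)/(1-f(t))] / [f(0)/(1-f(0))]`, because odds — not raw
fractions — evolve exponentially under constant relative growth rates:
with growth deficit `d` and doubling time `Td`,
`E(t) = 2^(-t d / Td)` exactly. Percent decreased growth is
`100 * (1 - E_target / median(E_controls))`; the median over control
lines tolerates one aberrant control. Fractions of exactly 0 or 1 are
rejected (undefined odds — in practice a gating failure).
`simulate_assay()` generates trajectories from the same odds model with
multiplicative log-normal measurement noise, and `fit_deficit()` inverts
it by regressing `log2 E(t)` on `t` through the origin; on noiseless
series the recovery is exact, which the tests use as an inversion
oracle.

## Numerical and design choices

* **Seeding**: every stochastic routine takes an explicit seed and
  restores the caller's RNG state; multi-stage procedures derive
  per-stage seeds from the master seed, so outputs are bit-identical
  across reruns. Pipeline outputs other than the timestamped log are
  byte-reproducible.
* **Duplicate spacers** in a user library are an error by default (a
  flag downgrades to a warning): exact-match counting cannot attribute
  reads between identical spacers.
* **Degenerate NTCs** (no spread) make the null's sigma undefined and
  raise an error suggesting more varied controls, never a silent
  sigma of zero.
* **Unscorable genes** (fewer usable guides than `k`) are flagged
  unscored rather than raising, so one bad gene cannot stop a screen.
* **Direction ties** (median lfc exactly 0) default to dropout.
* **Exact-test threshold**: enumeration up to 1e5 assignments keeps the
  exact branch well inside interactive latency while covering every
  group-size pair a desk-scale analysis meets.

## Problem sizes used by the test suite

Calibration and recovery checks run on a scaled screen — 200 lncRNA
genes x 10 guides, 100 NTCs, coverage 1000, 500 reads per guide, 20
simulation seeds, 10,000 pseudo-genes per null — chosen so the full
suite exercises every stage of the pipeline at meaningful statistical
resolution (4,000 gene scores per check) on a laptop. At these
conditions the neutral |z| >= 3 rate stays under 1%, NTC pseudo-gene
z-scores are standard to within |mean| < 0.1 and sd in [0.8, 1.2], and
genes planted at a 0.5 growth deficit are recovered at z <= -3 in over
90% of cases.

## Known limitations

* The z construction declares one specific, seeded aggregation (top-3
  mean against NTC pseudo-genes); published screens rarely specify
  theirs exactly, so absolute z values are comparable only within a
  scoring configuration.
* With few NTCs the pseudo-gene null resamples a small empirical
  distribution; its extreme tails are bounded by the observed NTC
  extremes, so very small NTC sets (well under 100 usable guides)
  understate tail risk. The library default of 700 NTCs is comfortable.
* Exact spacer matching ignores sequencing errors; a one-mismatch
  tolerance would recover ~1% more reads at the cost of ambiguity
  between near-identical spacers. Unmatched counts are reported so the
  loss is visible.
* Screens with multiple endpoint replicates are scored per column; a
  mean-lfc mode exists but replicate-aware variance modeling
  (DESeq-style) is out of scope.
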