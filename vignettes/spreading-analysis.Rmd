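---
title: "Profiling secondary and tertiary 22G-RNAs at piRNA targets"
author: "piRNAspread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling secondary and tertiary 22G-RNAs at piRNA targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piRNAspread)
```

## The biological question and the measurement model

In the *C. elegans* germline, a piRNA (21 nt, 5′ U, bound by PRG-1) that
recognizes a complementary site on an mRNA triggers RdRP-dependent synthesis
of secondary siRNAs — 22G-RNAs, characteristically 22 nt with a 5′ G,
antisense to the target. These secondary 22G-RNAs map close to the piRNA
target site (operationally: within 200 bp). When secondary 22G-RNAs engage
the nuclear Argonaute HRDE-1 and the nuclear RNAi factors NRDE-1/-4, a
second, genetically separable population is produced: tertiary 22G-RNAs,
which map across the remainder of the transcript, far from the initiating
site. The two populations are distinguishable purely positionally, given
per-nucleotide profiles of antisense 22G reads and the genotype of the
animal the library came from:

* loss of the piRNA/Mutator axis (*prg-1*, *mut-16*, *rrf-1;ego-1*,
  *drh-3*) removes **both** populations;
* loss of nuclear RNAi (*hrde-1*, *nrde-1*, *nrde-4*) removes **only** the
  distal population — the epistasis the package's genotype model encodes as
  `tertiary_active ⇒ secondary_active`.

This package implements the full positional analysis: antisense 22G read
profiling on reporter transgenes and spliced transcripts, proximal/distal
partitioning, length-normalized 10-bin summaries, k-means clustering of
per-gene spreading patterns across genotypes, piRNA target-site prediction
with positional enrichment statistics, Argonaute-IP fold enrichment, and
the exact small-sample tests those statistics need. A genotype-aware read
simulator generates libraries with this structure so every stage is
exercisable, and testable against known ground truth, without sequencing
data.

## Coordinates and read classification

All positions are 0-based, half-open, on the spliced transcript, with the
construct start (start codon) at 0 — matching the x-axes of transgene
profile plots. A read is counted once, at its 5′ end; for a hit interval
`[start, end)` antisense to the transcript that position is `end − 1`.
Profiles are read-count histograms, not coverage; a `full_coverage` rule is
retained for visualization only. Whether published per-transcript
histograms counted 5′ ends or midpoints is generally not recoverable from
figure legends; the 5′-end rule is this package's documented default, and
every conservation invariant (profile total = filtered hit count; 10-bin
total = profile total; proximal + distal = total) is exact under it.

"22G" is a configurable class, defaulting to length 21–23 nt with a 5′ G:
the class is *defined* by the characteristic 22 nt/5′ G, and field practice
tolerates ±1 nt. The 5′/3′ transcript halves split at `floor(L/2)`, with
the midpoint of an odd-length transcript assigned 3′ — deterministic and
symmetric to within one position.

Alignment is exact matching of error-free reads against the supplied
reference set (sense and reverse-complement), and *uniqueness is defined
across that reference set only* — the package does not do genome-scale
alignment (out of scope), so "unique match" means unique among the
transgene(s) and transcripts provided. This is a documented divergence from
analyses that define uniqueness genome-wide.

## Normalization

Two normalizations are provided, mirroring the two conventions used for
transgene and endogenous-gene profiles respectively:

* `per_his58`: profile values divided by the number of reads matching the
  his-58 (Histone 2B) segment shared across the reporter constructs. A
  normalizer read is one *fully contained* in the his-58 segment, in either
  orientation, any length or class — containment avoids edge
  double-counting, and the orientation-agnostic rule reflects that the
  normalizer count is a proxy for library depth, not a 22G quantity.
* `per_million`: reads per million of the library total.

Both are ratio statistics, so duplicating every input read leaves them
bit-identical (tested exactly).

## The synthetic-data generator

The generator emits the read populations the analysis assumes, nothing
more. Region read counts are Poisson; antisense 5′-end positions are
uniform over the *template-C* positions of the region, which enforces the
5′ G without a rejection step; read lengths are drawn from a configurable
distribution over 21–23 nt (default 0.15/0.70/0.15 — the exact proportions
are unstated in the literature, so they are config, not constants). Every
emitted read is an exact reverse-complement substring of its spliced
template, so exact alignment recovers each read at its generated position,
and no read touches an intron.

For the sensor construct (GFP 870 nt; his-58 370 nt; 21-nt target site ±50
bp flanks; 3′UTR 200 nt — the published segment layout, with synthetic
random nucleotide content, which suffices because the analysis depends only
on positions and self-consistent matching), the populations are:

* **proximal** (secondary): uniform over target site ± 200 nt, present when
  the genotype makes secondary siRNAs;
* **distal** (tertiary): uniform over the remaining coding sequence,
  present when it makes tertiary siRNAs;
* **background**: a low uniform antisense rate over the whole construct;
* **normalizer**: his-58 fragments at a fixed expected rate. These are
  emitted sense-strand (degradation-fragment-like): emitting antisense
  normalizer reads would feed ~25% of them (the 5′-G fraction) into the
  antisense-22G channel itself and blur the proximal/distal contrast the
  generator is supposed to encode as truth. The *counting* of normalizer
  reads remains orientation-agnostic.

Default rates (2×10⁻⁵ reads/nt per unit depth for proximal and distal,
2×10⁻⁷ background, 0.02 normalizer, depth 10⁵) were chosen once for
detectability — roughly 10³ proximal, 2×10³ distal and 2×10³ normalizer
reads per library — and are not biological estimates; no quantitative
secondary:tertiary abundance ratio is established in the literature.

The genome panel simulates 300 genes (default), 900–1800 nt, 1–3 exons,
both strands, in four pattern classes: `cluster6_like` genes (50%) carry
1–3 perfect piRNA sites implanted in their 3′ half, read coverage over the
whole gene in wild type, and lose their 5′-half (tertiary) reads in the
nuclear RNAi mutant; `cluster1_like` genes (20%) mirror this;
`hotspot` genes have a localized single-bin read peak (with a site at a
random position) plus low uniform body coverage, unchanged across
genotypes; `uniform` genes are untargeted and flat. The *prg-1* library
removes all reads from targeted genes (background only). The hotspot/uniform
mixture exists because genome-wide 22G patterns are multi-modal: k-means
with k in the 7–8 range needs more pattern archetypes than the two
directional ones, or it will split them. Hotspot genes carry body-wide
coverage (0.3 × the peak rate) because truly zero-coverage bins are
unrealistic for 22G-targeted transcripts and put per-cluster ratio curves
into a pseudocount-dominated regime where their value is noise, not signal.

The IP simulator resamples a base library with weight `ip_fold` on
construct-antisense reads and weight 1 otherwise; the control IP (from the
deletion mutant) resamples uniformly. The bundled `sensor_ip` base dilutes
a wild-type sensor library ~1:100 in nonspecific background reads, because
the per-million profile ratio recovers the generative weight only when the
enriched fraction is small: the measured fold is `F/(fF + 1 − f)` in
expectation for construct fraction `f`, i.e. ≈ 9.1 of a generative 10 at
`f ≈ 0.01`. The residual compression is a property of ratio-of-composition
measurements, not an estimator bug, and the simulation check allows for it.

What the generator does **not** model: sequencing error, adapter artifacts,
5′-phosphorylation chemistry, multigenerational population dynamics, and
any RNA secondary-structure or thermodynamic component of targeting.
Passing tests therefore demonstrate that the *analysis* recovers the
structure it is designed to see, not that real libraries have that
structure.

## Clustering and spreading calls

Per-gene 10-bin vectors (bin `b` covers `[floor(bL/10), floor((b+1)L/10))`,
so totals are conserved exactly) are computed in the clustering condition
(default the nuclear RNAi mutant). Genes with no antisense 22G signal there
(< 1 read, configurable) are excluded — clustering is over "22G-targeted
transcripts". Rows are scaled to proportions before clustering so clusters
capture the *shape* of the distribution, not abundance; raw-count
clustering is available behind a flag. This scaling is a package decision:
published methods state only that binned data were the k-means input.

k-means is Lloyd's algorithm with k-means++ seeding under a fixed RNG, with
"converged" operationalized as a maximum centroid shift ≤ 10⁻⁶ within 300
iterations (these were open choices; all three are exposed). The
within-cluster sum of squares is recorded per iteration and asserted
non-increasing. `select_k` scans k = 2…8 and keeps the largest k that
converged; on well-behaved data all k converge and 8 is chosen — the
historical analysis this mirrors had its k = 8 run fail to converge and
proceeded with 7, an outcome that depends on implementation details
(initialization, convergence rule) that are not recoverable, so the rule,
not the outcome, is reproduced. Emptied clusters are re-seeded at the
worst-fit point.

Per-cluster curves are `log2` of (mean mutant bin count / mutant library
size + ε) over (mean wild-type bin count / WT library size + ε), ε = one
read per million (no published pseudocount exists; 1 RPM is the smallest
round unit on the normalized scale). The spreading index is the mean curve
over bins 1–5 minus bins 6–10; |index| > 0.5 log2 units calls
`loss_5prime` or `loss_3prime` (threshold exposed). The call is exactly
antisymmetric under bin-order reversal.

## Target-site prediction and statistics

`predict_sites` scans every transcript position for windows within 3
mismatches (default) of the reverse complement of each 21-nt piRNA —
ungapped, end-to-end, N counting as a mismatch, overlapping hits all
reported. This reproduces the aligner-in-mismatch-mode convention of
upstream work; no seed-region weighting or thermodynamics.

The 3′-vs-5′-half enrichment of a cluster's sites is tested with a
one-sided Fisher's exact test on (cluster 3′, cluster 5′; background 3′,
background 5′); whether the historical comparison was within-cluster or
cluster-vs-background is not recoverable, so a within-cluster binomial
against 0.5 is also reported, with the Fisher table primary. The log2
enrichment display uses a 0.5 per-cell pseudocount; the test never does.

`fisher_exact` and `wilcoxon_signed_rank` are implemented from first
principles (log-gamma hypergeometric mass; exact sign-flip null up to
n = 12 tie-free, else normal approximation with tie and continuity
correction; zeros dropped by default, Pratt's treatment optional). The
two-sided Fisher rule is the probability-mass convention (all tables at
most as probable as the observed, with 10⁻⁷ relative slack) — conventions
differ, so this is documented. Both functions are verified against full
enumeration oracles and against R's independent implementations in the
test suite. Per-gene mutant/WT comparisons use the paired signed-rank test
per cluster, one-sided in the direction of loss, on library-normalized
counts.

## Problem sizes, defaults and known limitations

The test suite and the acceptance script run the generator at depth 10⁵
with 300-gene panels over five seeds — sizes at which every recovery
property has comfortable stochastic margin while a full panel analysis
(simulate, align, filter, bin, cluster, test) completes in well under a
minute; these are the package's standard study conditions.

Known limitations, deliberately accepted:

* Cluster membership is read-pattern-driven, so untargeted flat genes that
  sit geometrically between archetypes can be absorbed into a directional
  cluster; they dilute that cluster's per-gene level-change statistic (the
  smaller mirrored cluster is affected more). The recovery of the planted
  directional classes themselves is unaffected.
* The measured IP fold is compressed toward 1 by the composition effect
  described above; comparisons across libraries with very different
  enriched fractions should use the per-bin table, not the single fold.
* Exact alignment is correct only for error-free (synthetic or
  pre-cleaned) reads; supply external alignments via the 6-column TSV
  interface for anything else.
* The built-in constructs and piRNA panel are synthetic stand-ins with the
  published segment *layout* but random content; analyses that depend on
  real sequence (e.g. off-target matching against a genome) are out of
  scope.

## A worked example

```{r example, eval = FALSE}
cons <- sensor_construct()
cfg <- sim_config(seed = 1, depth = 1e5)
sim <- simulate_sensor_scenario(cfg, "wild_type", cons)
hits <- align_exact(sim$reads, cons)
norm <- normalization_factors(sim$reads, hits, construct = cons)
prof <- positional_profile(filter_hits(hits), cons, norm, mode = "per_his58")
proximal_distal(prof, cons$target_site_interval)
plot(prof, construct = cons)

## full pipelines
sensor <- run_sensor_analysis(list(outdir = "out_sensor", seed = 1))
panel <- run_genome_analysis(list(outdir = "out_panel", seed = 1))
make_report(list(sensor = sensor, genome = panel), "report.md")
```
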