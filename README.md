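# piRNAspread

Positional analysis of secondary and tertiary 22G-RNAs at piRNA targets in
*C. elegans* small-RNA sequencing data.

## What this is for

In the nematode germline, a piRNA (21U-RNA) bound by PRG-1 that recognizes
a site on an mRNA triggers RdRP synthesis of antisense secondary siRNAs
(22G-RNAs: ~22 nt, 5′ G) near the target site. When these engage the
nuclear Argonaute HRDE-1 and the nuclear RNAi factors, a distinct tertiary
22G-RNA population appears across the rest of the transcript. The two
populations are separable *positionally* — proximal (within ~200 bp of the
site) versus distal — and *genetically*: piRNA/Mutator-pathway mutants
(*prg-1*, *mut-16*) lose both, nuclear RNAi mutants (*hrde-1*, *nrde-1*,
*nrde-4*) lose only the distal class.

`piRNAspread` gives small-RNA and epigenetic-inheritance labs the complete
computational side of that analysis:

* per-nucleotide antisense 22G profiles on transgene constructs and spliced
  transcripts (5′-end counting; his-58-normalized or reads-per-million),
  with proximal/distal and exon/intron partitions;
* length-normalized 10-bin summaries per gene, k-means clustering of
  spreading patterns (Lloyd + k-means++, k selected by a convergence rule
  over 2–8), per-cluster mutant/WT log2 ratio curves and directional
  spreading calls;
* piRNA target-site prediction by ungapped antisense matching with up to 3
  mismatches, and one-sided Fisher tests of 3′- vs 5′-half site enrichment
  per cluster;
* per-gene 22G level changes between genotypes with paired Wilcoxon
  signed-rank tests, and IP/input fold-enrichment tracks;
* exact Fisher and Wilcoxon signed-rank implementations (enumeration-backed)
  used by all of the above;
* a genotype-aware synthetic read generator (sensor, operon, RNAi-feeding
  and genome-panel scenarios, with ground-truth provenance) so the whole
  pipeline runs and is testable without any sequencing download.

The statistics at the core, in the field's usual notation: for a cluster
*c* with site counts *a* (3′ half) and *b* (5′ half) against background
counts *(c, d)*, enrichment is `log2[(a/b)/(c/d)]` with Fisher's exact
`P(X ≥ a)` under the hypergeometric null; per-gene changes are
`log2[(n_mut/N_mut + ε)/(n_wt/N_wt + ε)]` with the exact signed-rank test
on the normalized differences; spreading is called from
`index = mean(log2 ratio, bins 1–5) − mean(bins 6–10)` against a ±0.5
threshold.

## Worked example

```r
library(piRNAspread)

cons <- sensor_construct()          # GFP::his-58::site±50bp::3'UTR reporter
sim  <- simulate_sensor_scenario(sim_config(seed = 1, depth = 1e5),
                                 "wild_type", cons)
sim$reads
#> <read_set> 5281 reads [wild_type]
#>   lengths 21-23 nt; 71.5% 5'-G

hits <- align_exact(sim$reads, cons)
raw  <- positional_profile(filter_hits(hits), cons, mode = "raw")
pd   <- proximal_distal(raw, cons$target_site_interval)
c(proximal = pd$proximal, distal = pd$distal, ratio = pd$distal / pd$proximal)
#> proximal   distal    ratio
#> 1031.000 2213.000    2.146
```

A wild-type library has abundant distal (tertiary) signal — here about
twice the proximal count. Re-running with `"hrde-1"` collapses the ratio to
~0.02 (distal reads at background), while `"prg-1"` leaves only ~30
background reads in total: the genetic fingerprint of the two populations.

The genome-scale analysis runs from one call and writes TSV/bedGraph/JSON
plus a markdown report:

```r
b <- run_genome_analysis(list(outdir = "out_panel", seed = 1))
b$calls[b$calls$label != "none", ]
#>   cluster n_genes   index       label
#> 1       1      96  2.33   loss_3prime
#> 5       5     164 -2.97   loss_5prime
b$enrichment$cluster5
#> 3'-half site enrichment: log2 = 8.463, Fisher p = 2.046e-82 (binomial p = 4.682e-97)
#>   cluster 3'/5' = 320/0; background 3'/5' = 35/135
```

One cluster (here cluster 5, all 150 planted 3′-sited genes) loses its 5′
reads in the nuclear RNAi mutant and is strongly 3′-enriched for predicted
piRNA sites; the mirrored cluster shows the opposite. The per-gene prg-1/WT
signed-rank test for the 5′-loss cluster gives p ≈ 2×10⁻¹⁴ with a median
log2 change of −1.36.

`reproduce_sensor(outdir, seed)` and `reproduce_panel(outdir, seed)` run
the two full preset analyses; identical seeds give byte-identical outputs.
A thin command-line wrapper over the same functions is at
`inst/scripts/pirnaspread.R`.

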