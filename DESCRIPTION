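Package: piRNAspread
Title: Positional Analysis of Secondary and Tertiary 22G-RNAs at piRNA Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for distinguishing secondary (target-site proximal) from
    tertiary (distal) 22G-RNAs at piRNA target genes in C. elegans small
    RNA sequencing data. Provides antisense positional profiling of 22G
    reads on transgene constructs and spliced transcripts with his-58 or
    per-million normalization, length-normalized 10-bin summaries with
    k-means clustering of spreading patterns across genotypes, piRNA
    target-site prediction by ungapped antisense matching with mismatches,
    positional (5'/3'-half) enrichment statistics, Argonaute IP fold
    enrichment, exact Fisher and Wilcoxon signed-rank tests, and a
    genotype-aware synthetic small-RNA read generator so the full analysis
    can be exercised without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
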