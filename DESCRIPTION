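Package: haplokit
Title: Haplotype-Resolved Targeted Assembly and Aneuploidy Profiling on Simulated Diploid Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for haplotype-resolved assembly of a
    targeted polymorphic genomic region and its downstream characterization.
    Includes a diploid region simulator (heterozygous SNVs and indels,
    planted structural variants, haplotype copy numbers, long and paired
    short reads), consensus phasing by callset intersection, allele-voting
    read haplotagging with per-window longest-read downsampling, a two-round
    greedy overlap-layout-consensus assembler with supplementary-read
    rescue, k-mer based assembly evaluation (collision-aware optimal k,
    completeness, consensus QV, NGA50, duplication ratio), assembly-to-
    reference variant and structural-variant calling via unique-anchor
    chaining, and personal-reference aneuploidy profiling through smoothed
    log2 depth ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
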