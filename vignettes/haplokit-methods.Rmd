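---
title: "haplokit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{haplokit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package models

haplokit is a desk-scale re-creation of a targeted haplotype-resolved
sequencing workflow for a highly polymorphic diploid locus of the kind
exemplified by the human MHC region (~4.5 Mb on chr6, dense heterozygous
SNVs/indels, occasional kb-scale structural variants, and frequent
copy-number imbalance in tumor-derived cell lines). Every stage of the
computational arm is implemented and exercised on synthetic data from a
bundled simulator, so the whole pipeline is testable without any
sequencing download:

1. **Consensus phasing** — two independently noised heterozygous
   callsets are normalized and intersected into a reliable phased set;
   a heterozygosity-density rule decides diploid vs haploid (loss of
   heterozygosity) processing.
2. **Read partitioning** — long reads vote at phased SNVs and are
   assigned to a haplotype by majority; each partition is merged with
   untagged reads and downsampled per 10 kb window to 30x by keeping the
   longest reads.
3. **Two-round assembly** — a greedy overlap-layout-consensus assembler
   builds preliminary contigs; contigs under 50 kb are dropped; reads
   that never aligned to the reference are rescued against the
   preliminary contigs and the union is re-assembled.
4. **Evaluation** — collision-aware optimal k, k-mer completeness and
   consensus QV, NGA50/LGA50, duplication ratio and reference coverage.
5. **Variant calling** — each assembled haplotype is aligned to the
   reference by unique-anchor chaining; within-block mismatches become
   SNVs, small inter-anchor gaps are resolved by local alignment, and
   net gaps of at least 50 bp become structural variants.
6. **Aneuploidy profiling** — short reads are filtered to zero-edit,
   haplotype-unique alignments; per-base depth is projected onto
   reference coordinates and summarized as a smoothed log2 depth-ratio
   profile with an overall copy-ratio estimate.

## The simulator and what it does (not) emulate

The simulator is first-class, tested code; its defaults define the
study conditions for every acceptance-style check.

* **Ancestral sequence**: i.i.d. bases at a chosen GC content. Real MHC
  sequence has repeats, segmental duplications and gene clusters; an
  i.i.d. background makes 31-mers almost surely unique, which flatters
  the anchor chainer and the assembler. Passing tests therefore
  demonstrate contract correctness, not robustness to repeat structure.
* **Heterozygosity**: SNVs at `snv_rate` (default 1/kb — a realistic
  round figure for a polymorphic locus; no per-cell-line rate is
  implied), small indels at `indel_rate` with geometric lengths (p =
  0.5) capped at 10 bp so they stay well below the 50 bp SV threshold.
  SVs are only ever planted explicitly, never drawn, so the truth set
  is exactly known.
* **Long reads**: truncated-normal lengths (default 10 +/- 1 kb,
  clamped to [1 kb, 4x mean], matching a size-selected HiFi-like
  library), uniform starts, forward strand, substitution-only errors.
  No homopolymer bias, chimeras, or indel errors — which is what lets
  overlap verification and the rescue mapper be ungapped (Hamming).
* **Short reads**: error-free 150 bp pairs drawn per haplotype in
  proportion to `copies * depth_per_copy`, emulating WGS of aneuploid
  cells at exactly known copy ratios (1:1, 2:1, 3:1 in the bundled
  checks).
* **Alignment records**: reference alignments of simulated reads are
  produced by exact coordinate liftover through the truth chains (the
  package's `aln_chain` structure), playing the role of an external
  aligner. Haplotagging itself only ever sees read bases and phased
  alleles, never truth labels. The second sequencing platform of the
  real workflow is represented only by a second, independently noised
  callset fed to the consensus intersection.

Each stochastic operation draws from its own RNG stream keyed by
`(seed, operation)`, so re-running one stage never perturbs another and
full-pipeline manifests are byte-identical under a fixed seed.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| downsampling window | 10 000 | bp | per-window coverage uniformity |
| downsampling target | 30 | fold | assembly coverage operating point |
| contig filter | 50 000 | bp | preliminary-assembly noise floor |
| SV threshold | 50 | bp | standard indel/SV boundary, tested exactly |
| collision rate `e` | 0.001 | — | optimal k = log4(L(1-e)/e); 16.04 at L = 4 548 949 |
| reliable k-mer multiplicity | >= 2 | count | excludes singleton error k-mers |
| haploid threshold | 0.05 | het/kb | qualitative LOH judgement made explicit |
| rescue floor | 95% id over 80% length | — | keeps unrelated (decoy) reads out |
| anchor k | 31 | bp | unique at 1 SNV/kb divergence on desk-scale regions |
| min chain span | 10 000 | bp | suppresses calls from fragmentary alignments |
| ratio pseudo-depth `eps` | 0.5 | fold | guards zero division at uncovered sites |

The haploid threshold, rescue floor, and `eps` have no published
values; they are package choices, exposed as arguments.

## Numerical and design choices

* **Coordinates** are 0-based half-open everywhere internally; emitted
  VCF converts to 1-based. One convention end-to-end avoids off-by-one
  drift between the simulator, chains, and callers.
* **Normalization** is vt-style: trim shared suffixes (extending left
  with reference bases when an allele would empty), then shared
  prefixes. The result is the unique leftmost minimal representation —
  verified in tests against brute-force enumeration of all equivalent
  representations — and makes `(pos, ref, alt)` a sound intersection
  key.
* **Consensus phase orientation** follows callset `a` (by convention
  the long-read callset); which platform's phase should win is a free
  choice and is configurable.
* **Tie votes are untagged.** A read voting equally for both
  haplotypes carries no net phase information; assigning it either way
  would inject noise into both partitions.
* **Downsampling uses union semantics.** A read kept for any window is
  kept globally: per-window "keep the longest until the target" is
  well-defined inside a window, but reads span windows, and dropping a
  read kept elsewhere would punch holes in the layout the assembler
  needs. Consequence: saturated windows can exceed the target by up to
  `max_read_len / window_size` fold from their own selection, plus
  whatever neighbouring windows keep.
* **Assembler determinism**: reads are ordered by length (descending,
  ties by id) before greedy extension; candidate overlaps are ranked by
  overlap length with the same tie-break. Contained reads are absorbed
  so each read contributes to at most one contig. The assembler is a
  contract-equivalent stand-in for a production long-read assembler;
  `assemble_haplotype()` is the seam where one would substitute it.
* **Round 2 does not re-downsample.** The supplementary reads exist
  precisely because they were invisible to the reference; thinning them
  again would re-create the gaps the rescue is meant to close.
* **Complex gaps** (reference and query gap both >= 50 bp) are emitted
  as a paired deletion + insertion at the same anchor — a breakend-free
  representation that keeps sizes exact without inversion calling.
* **Ratio smoothing logs first.** Per-position ratios are
  log2-transformed and then averaged within windows. Besides matching
  the stated order of operations of the workflow being modeled, the log
  transform cancels the upward Jensen bias of averaging raw Poisson
  depth ratios (at 20x per copy, ratio-averaging alone overestimates a
  1:1 state by ~5%). Mean-of-ratios-then-log remains available via
  `average = "ratio"`.
* **Gap filling** propagates the nearest computed window's value with
  left (carry-forward) precedence; leading windows take the first
  computed value. Filled windows can therefore never leave the range of
  computed windows. The overall ratio is `2^median` over all windows
  (median for robustness to focal events).
* **Windows are non-overlapping tiles** both for downsampling and for
  ratio smoothing; "sliding" smoothing with a step is a possible
  extension but tiles keep every window's value independent.

## Problem sizes used by the test suite

Module tests run on 20–200 kb regions; the end-to-end checks use the
sizes the behaviors are specified at: 500 kb diploid regions at 20x per
copy for the 1:1 / 2:1 / 3:1 copy-ratio recovery (accepted within 5%),
and 300 kb diploid regions at 30x error-free long reads for exact
recovery of the planted 1469 bp deletion (haplotype 1) and 968 bp
insertion (haplotype 2) through the full
partition-assemble-align-call path. These sizes were chosen as the
smallest at which window counts and variant densities make the
statistics meaningful (50 smoothing windows, ~500 heterozygous sites).

## Known limitations

* The i.i.d. background sequence understates repeat-induced failure
  modes of anchor uniqueness, haplotagging and assembly.
* Substitution-only error models mean the ungapped (Hamming) overlap
  and rescue verification would need replacing with gapped alignment
  for real indel-rich long reads.
* No inversion or translocation calling; complex gaps become paired
  DEL+INS records.
* No GC-bias or mappability correction in depth profiles; no purity or
  subclonality modeling in the overall ratio.
* The whole-genome context of personal-reference mapping is reduced to
  the target region (plus optional decoy flanks); genome-wide mapping
  rate shifts are out of scope.
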