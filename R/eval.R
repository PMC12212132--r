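#' Collision-aware optimal k-mer size
#'
#' For a target of length L and a tolerated random-collision rate e, the
#' smallest k at which a random k-mer is expected to collide with the
#' target at rate at most e satisfies 4^k = L (1 - e) / e, i.e.
#' k = log4(L (1 - e) / e). For the 4,548,949 bp target at the default
#' e = 0.001 this evaluates to 16.04; the integer k used for counting is
#' the rounded value.
#'
#' @param region_length target region length in bp (>= 1).
#' @param collision_rate tolerated collision rate in (0, 1).
#' @return list with `k` (two decimals), `counting_k` (rounded integer),
#'   and `k_exact`.
#' @export
optimal_k <- function(region_length, collision_rate = 0.001) {
  if (region_length < 1) stop("region_length must be >= 1")
  if (collision_rate <= 0 || collision_rate >= 1)
    stop("collision_rate must be in (0, 1)")
  k <- log(region_length * (1 - collision_rate) / collision_rate, base = 4)
  list(k = round(k, 2), counting_k = as.integer(round(k)), k_exact = k)
}

#' Canonical k-mer statistics of an assembly against its read set
#'
#' Counts canonical (strand-minimal) k-mers in the read set and the
#' assembly. Read k-mers with multiplicity >= `min_mult` are "reliable"
#' (singletons are mostly sequencing errors); assembly k-mers absent from
#' the read set altogether are unsupported and drive the consensus QV.
#'
#' @param read_seqs character vector of read sequences.
#' @param asm_seqs character vector of assembly contig sequences.
#' @param k k-mer size (2-31).
#' @param min_mult reliability multiplicity threshold (default 2).
#' @return a `kmer_stats` list: `k`, `read_kmers_total`,
#'   `read_kmers_reliable`, `asm_kmers_total`, `asm_only_kmers`,
#'   `shared_reliable`.
#' @export
kmer_stats <- function(read_seqs, asm_seqs, k, min_mult = 2) {
  s <- cpp_kmer_stats(read_seqs, asm_seqs, as.integer(k),
                      as.integer(min_mult))
  structure(c(list(k = as.integer(k)), s), class = "kmer_stats")
}

#' k-mer completeness of an assembly
#'
#' Fraction of reliable read k-mers present in the assembly:
#' `shared_reliable / read_kmers_reliable`. 1.0 means every reliably
#' sequenced k-mer made it into the consensus.
#'
#' @param stats a [kmer_stats()] object.
#' @return a fraction in \[0, 1\].
#' @export
kmer_completeness <- function(stats) {
  if (stats$read_kmers_reliable <= 0) stop("no reliable read k-mers")
  stats$shared_reliable / stats$read_kmers_reliable
}

#' Consensus quality value (QV) from unsupported assembly k-mers
#'
#' Converts the fraction of assembly k-mers unsupported by the reads into
#' a phred-scaled per-base consensus error estimate: with p =
#' asm_only / asm_total, the per-base error is E = 1 - (1 - p)^(1/k) and
#' QV = -10 log10(E). A perfectly supported assembly (zero unsupported
#' k-mers) is reported at the cap.
#'
#' @param stats a [kmer_stats()] object.
#' @param cap QV ceiling (default 99).
#' @return the QV (phred scale).
#' @export
consensus_qv <- function(stats, cap = 99) {
  if (stats$asm_kmers_total <= 0) stop("assembly has no k-mers")
  if (stats$asm_only_kmers == 0) return(cap)
  p <- stats$asm_only_kmers / stats$asm_kmers_total
  err <- 1 - (1 - p)^(1 / stats$k)
  min(-10 * log10(err), cap)
}

#' NGA50 and LGA50 of aligned blocks
#'
#' Sorts aligned block lengths in decreasing order and returns the length
#' at which the cumulative aligned length first reaches half the
#' reference (NGA50), together with the number of blocks needed (LGA50).
#' Returns 0/NA when 50% is never covered.
#'
#' @param blocks data frame with a `length` column (aligned block
#'   lengths, reference bp), or a numeric vector of lengths.
#' @param reference_length reference region length (> 0).
#' @return list with `nga50` and `lga50`.
#' @export
nga50 <- function(blocks, reference_length) {
  if (reference_length <= 0) stop("reference_length must be positive")
  lens <- if (is.data.frame(blocks)) blocks$length else as.numeric(blocks)
  lens <- sort(lens[lens > 0], decreasing = TRUE)
  cum <- cumsum(lens)
  i <- which(cum >= reference_length / 2)
  if (!length(i)) return(list(nga50 = 0, lga50 = NA_integer_))
  list(nga50 = lens[i[1]], lga50 = i[1])
}

covered_ref_bases <- function(blocks) {
  if (!nrow(blocks)) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(start = blocks$ref_start + 1L,
                                         end = blocks$ref_end))
  sum(as.numeric(IRanges::width(ir)))
}

#' Duplication ratio and reference coverage of aligned blocks
#'
#' Coverage is the unioned reference bases covered by any block divided
#' by the reference length; duplication is total aligned query bases over
#' covered reference bases (1.0 = no redundantly assembled sequence).
#'
#' @param blocks block data frame with `ref_start`, `ref_end`,
#'   `qry_start`, `qry_end`.
#' @param reference_length reference region length.
#' @return `duplication_ratio()`: a ratio >= 1 when coverage > 0;
#'   `coverage_fraction()`: a fraction in \[0, 1\].
#' @export
duplication_ratio <- function(blocks, reference_length) {
  cov <- covered_ref_bases(blocks)
  if (cov == 0) return(NA_real_)
  sum(as.numeric(blocks$qry_end - blocks$qry_start)) / cov
}

#' @rdname duplication_ratio
#' @export
coverage_fraction <- function(blocks, reference_length) {
  covered_ref_bases(blocks) / reference_length
}
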