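#' Greedy overlap-layout-consensus assembly of long reads
#'
#' A minimal deterministic assembler for low-error long reads: reads are
#' ordered by length (descending, ties by id), exact k-mer seeds sampled
#' along each read locate candidate overlaps, and the contig is extended
#' greedily by the read with the longest Hamming-verified overlap
#' (substitution-tolerant up to `max_mismatch_frac`). Contained reads are
#' absorbed into the growing contig, so each read contributes to at most
#' one contig. An external production assembler can be substituted
#' upstream; correctness here is defined against simulator truth.
#'
#' @param reads data frame with `read_id` and `sequence` (or a named
#'   character vector).
#' @param min_overlap minimum suffix-prefix overlap in bp (>= 500).
#' @param max_mismatch_frac maximum mismatch fraction inside an overlap.
#' @param seed_k exact seed k-mer size.
#' @param seed_stride spacing of sampled seeds along each read.
#' @param round assembly round label stored on the contigs.
#' @return a contig data frame: `contig_id`, `sequence`, `length`,
#'   `round`, and a `member_reads` list-column of contributing read ids.
#' @export
greedy_olc_assemble <- function(reads, min_overlap = 2000,
                                max_mismatch_frac = 0.01, seed_k = 21,
                                seed_stride = 200, round = 1L) {
  if (is.character(reads))
    reads <- data.frame(read_id = names(reads), sequence = unname(reads),
                        stringsAsFactors = FALSE)
  if (!nrow(reads)) stop("no reads to assemble")
  if (min_overlap < 500) stop("min_overlap must be >= 500")
  ord <- order(-nchar(reads$sequence), reads$read_id)
  reads <- reads[ord, , drop = FALSE]
  res <- cpp_greedy_assemble(reads$sequence, as.integer(min_overlap),
                             max_mismatch_frac, as.integer(seed_k),
                             as.integer(seed_stride))
  seqs <- res$contigs
  members <- lapply(res$members, function(ix) reads$read_id[ix])
  out <- data.frame(contig_id = sprintf("ctg%03d_r%d", seq_along(seqs),
                                        round),
                    sequence = as.character(seqs),
                    length = nchar(as.character(seqs)),
                    round = as.integer(round),
                    stringsAsFactors = FALSE)
  out$member_reads <- members
  # deterministic report order: longest first
  out <- out[order(-out$length, out$contig_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude short contigs
#'
#' Drops contigs shorter than `min_len` (default 50 kb, the preliminary
#' assembly filter), preserving order. Never increases contig count or
#' total length.
#'
#' @param contigs contig data frame from [greedy_olc_assemble()].
#' @param min_len minimum retained contig length in bp.
#' @return the filtered contig data frame.
#' @export
filter_contigs <- function(contigs, min_len = 50000) {
  out <- contigs[contigs$length >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rescue reads unaligned to the reference via the preliminary assembly
#'
#' Realigns all reads against the preliminary contigs and returns those
#' that were not recruited by the original reference alignment but map to
#' the assembly above the identity/length floor — reads from segments
#' absent from the reference (e.g. insertions) that would otherwise leave
#' assembly gaps.
#'
#' @param all_reads full read data frame (`read_id`, `sequence`).
#' @param preliminary preliminary contig data frame.
#' @param reference_aligned_ids ids of reads with a primary reference
#'   alignment (the originally recruited set).
#' @param min_identity minimum alignment identity (default 0.95).
#' @param min_cov minimum aligned fraction of the read length (default
#'   0.8).
#' @param seed_k,seed_stride seed parameters of the ungapped mapper.
#' @return character vector of rescued read ids (disjoint from
#'   `reference_aligned_ids`).
#' @export
rescue_supplementary_reads <- function(all_reads, preliminary,
                                       reference_aligned_ids,
                                       min_identity = 0.95, min_cov = 0.8,
                                       seed_k = 21, seed_stride = 100) {
  if (!nrow(preliminary)) stop("preliminary assembly is empty")
  cand <- all_reads[!(all_reads$read_id %in% reference_aligned_ids), ,
                    drop = FALSE]
  if (!nrow(cand)) return(character(0))
  hits <- cpp_map_ungapped(cand$sequence, preliminary$sequence,
                           as.integer(seed_k), as.integer(seed_stride))
  alen <- hits[, "alen"]
  rlen <- nchar(cand$sequence)
  ok <- hits[, "target"] > 0 & alen >= min_cov * rlen &
    (alen - hits[, "mismatches"]) >= min_identity * alen
  cand$read_id[ok]
}

#' Two-round haplotype assembly with supplementary-read rescue
#'
#' Round 1 assembles the haplotype partition merged with untagged reads
#' (downsampled to the per-window coverage target) and drops short
#' contigs. Reads without a reference alignment are then rescued against
#' the preliminary contigs and the union is re-assembled in round 2; with
#' nothing to rescue, the round-1 assembly is returned unchanged.
#' Downsampling is not re-applied in round 2.
#'
#' @param partition_ids,untagged_ids read ids of the haplotype partition
#'   and the untagged set.
#' @param reads full long-read data frame.
#' @param alignments `read_alignments` for the recruited reads (used for
#'   windowed downsampling intervals).
#' @param haplotype haplotype label for the resulting assembly.
#' @param target_cov per-window downsampling target (fold).
#' @param window_size downsampling window (bp).
#' @param min_contig_len contig filter threshold (bp).
#' @param min_overlap,max_mismatch_frac assembler parameters.
#' @param rescue run the supplementary-read rescue round (logical).
#' @return an `assembly` list: `haplotype`, `contigs` (data frame),
#'   `total_length`, `n_rescued`, `rounds`.
#' @export
assemble_haplotype <- function(partition_ids, untagged_ids, reads,
                               alignments, haplotype = "hap1",
                               target_cov = 30, window_size = 10000,
                               min_contig_len = 50000, min_overlap = 2000,
                               max_mismatch_frac = 0.01, rescue = TRUE) {
  recruit <- union(partition_ids, untagged_ids)
  if (!length(recruit)) stop("empty read input")
  ivals <- alignments[alignments$read_id %in% recruit & alignments$aligned, ,
                      drop = FALSE]
  ivals$read_len <- nchar(reads$sequence[match(ivals$read_id,
                                               reads$read_id)])
  kept <- downsample_longest_per_window(ivals, window_size, target_cov)
  round1_reads <- reads[reads$read_id %in% kept, , drop = FALSE]
  ctg1 <- greedy_olc_assemble(round1_reads, min_overlap, max_mismatch_frac,
                              round = 1L)
  ctg1 <- filter_contigs(ctg1, min_contig_len)
  rescued <- character(0)
  if (rescue && nrow(ctg1)) {
    aligned_ids <- alignments$read_id[alignments$aligned]
    rescued <- rescue_supplementary_reads(reads, ctg1, aligned_ids)
  }
  if (length(rescued)) {
    final_reads <- reads[reads$read_id %in% union(kept, rescued), ,
                         drop = FALSE]
    ctg <- greedy_olc_assemble(final_reads, min_overlap, max_mismatch_frac,
                               round = 2L)
    ctg <- filter_contigs(ctg, min_contig_len)
    rounds <- 2L
  } else {
    ctg <- ctg1
    rounds <- 1L
  }
  structure(list(haplotype = haplotype, contigs = ctg,
                 total_length = sum(ctg$length),
                 n_rescued = length(rescued), rounds = rounds),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf(
    "assembly [%s]: %d contig(s), total %d bp, largest %d bp (round %d, %d rescued)\n",
    x$haplotype, nrow(x$contigs), x$total_length,
    if (nrow(x$contigs)) max(x$contigs$length) else 0L, x$rounds,
    x$n_rescued))
  invisible(x)
}

#' Table-style assembly report
#'
#' Summarizes one or more assemblies with the standard columns: contig
#' count, largest contig, total length, and (when chains against the
#' reference are supplied) coverage, NGA50, LGA50 and duplication ratio.
#'
#' @param assemblies list of `assembly` objects.
#' @param blocks optional list (parallel to `assemblies`) of alignment
#'   block tables from [chain_to_blocks()].
#' @param reference_length reference region length (bp).
#' @return a data frame, one row per assembly.
#' @export
assembly_report <- function(assemblies, blocks = NULL,
                            reference_length = NULL) {
  rows <- lapply(seq_along(assemblies), function(i) {
    a <- assemblies[[i]]
    row <- data.frame(haplotype = a$haplotype,
                      contigs = nrow(a$contigs),
                      largest_contig = if (nrow(a$contigs))
                        max(a$contigs$length) else 0L,
                      total_length = a$total_length,
                      stringsAsFactors = FALSE)
    if (!is.null(blocks) && !is.null(reference_length)) {
      b <- blocks[[i]]
      ng <- nga50(b, reference_length)
      row$coverage_pct <- 100 * coverage_fraction(b, reference_length)
      row$nga50 <- ng$nga50
      row$lga50 <- ng$lga50
      row$duplication_ratio <- duplication_ratio(b, reference_length)
    }
    row
  })
  do.call(rbind, rows)
}
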