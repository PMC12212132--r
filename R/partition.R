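#' Reference alignments of simulated reads via truth liftover
#'
#' Converts each read's truth interval on its source haplotype into a
#' reference interval through the haplotype-to-reference truth chain,
#' playing the role of an external aligner for simulated data. Reads
#' drawn entirely from haplotype-only (inserted) sequence have no
#' reference image and are flagged unaligned — exactly the reads the
#' supplementary-read rescue stage is meant to recover.
#'
#' @param reads a long-read data frame from [simulate_long_reads()].
#' @param chains list with `hap1` and `hap2` [aln_chain()]s
#'   (haplotype -> reference), e.g. from [derive_haplotypes()].
#' @return a `read_alignments` data frame (`read_id`, `ref_start`,
#'   `ref_end`, `hap_start`, `hap_end`, `source_hap`, `aligned`) with the
#'   chains attached as an attribute.
#' @export
alignments_from_truth <- function(reads, chains) {
  n <- nrow(reads)
  rs <- re <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ch <- chains[[reads$truth_haplotype[i]]]
    p <- chain_project_interval(ch, reads$start[i], reads$end[i])
    rs[i] <- p$ref_start; re[i] <- p$ref_end
  }
  out <- data.frame(read_id = reads$read_id, ref_start = rs, ref_end = re,
                    hap_start = reads$start, hap_end = reads$end,
                    source_hap = reads$truth_haplotype,
                    aligned = !is.na(rs), stringsAsFactors = FALSE)
  attr(out, "chains") <- chains
  class(out) <- c("read_alignments", "data.frame")
  out
}

#' Assign reads to haplotypes by allele voting at heterozygous sites
#'
#' For every phased heterozygous SNV a read covers, the read votes for
#' the haplotype whose allele it carries; a base matching neither allele
#' contributes no vote. The majority haplotype wins; a tie or zero
#' informative sites leaves the read untagged. Only aligned reads are
#' tagged.
#'
#' @param alignments a `read_alignments` object
#'   ([alignments_from_truth()]).
#' @param reads the matching read data frame (for read sequences).
#' @param variants consensus [phased_variants()]; only SNV records are
#'   used for voting.
#' @return data frame with `read_id`, `assignment`
#'   (`"hap1"`/`"hap2"`/`"untagged"`), `votes_hap1`, `votes_hap2`,
#'   `sites_covered`.
#' @export
haplotag_reads <- function(alignments, reads, variants) {
  aln <- alignments[alignments$aligned, , drop = FALSE]
  res <- data.frame(read_id = aln$read_id, assignment = "untagged",
                    votes_hap1 = 0L, votes_hap2 = 0L, sites_covered = 0L,
                    stringsAsFactors = FALSE)
  snv <- variants[nchar(variants$ref) == 1 & nchar(variants$alt) == 1, ,
                  drop = FALSE]
  if (!nrow(snv) || !nrow(aln)) return(res)
  chains <- attr(alignments, "chains")
  seqs <- setNames(reads$sequence, reads$read_id)
  e1 <- ifelse(snv$hap1_allele == "alt", snv$alt, snv$ref)
  e2 <- ifelse(snv$hap2_allele == "alt", snv$alt, snv$ref)
  qpos <- list(hap1 = chain_ref_to_qry(chains$hap1, snv$pos),
               hap2 = chain_ref_to_qry(chains$hap2, snv$pos))
  ov <- IRanges::findOverlaps(
    IRanges::IRanges(start = snv$pos + 1L, width = 1L),
    IRanges::IRanges(start = aln$ref_start + 1L,
                     end = pmax(aln$ref_end, aln$ref_start + 1L)))
  vi <- S4Vectors::queryHits(ov)
  ri <- S4Vectors::subjectHits(ov)
  if (length(vi)) {
    src <- aln$source_hap[ri]
    qp <- ifelse(src == "hap1", qpos$hap1[vi], qpos$hap2[vi])
    off <- qp - aln$hap_start[ri]  # 0-based offset within the read
    ok <- !is.na(qp) & off >= 0 & off < (aln$hap_end - aln$hap_start)[ri]
    vi <- vi[ok]; ri <- ri[ok]; off <- off[ok]
    base <- substr_vec(seqs[aln$read_id[ri]], off, 1L)
    m1 <- base == e1[vi]
    m2 <- base == e2[vi]
    res$sites_covered <- as.integer(tabulate(ri, nbins = nrow(aln)))
    res$votes_hap1 <- as.integer(tabulate(ri[m1], nbins = nrow(aln)))
    res$votes_hap2 <- as.integer(tabulate(ri[m2], nbins = nrow(aln)))
    res$assignment <- ifelse(res$votes_hap1 > res$votes_hap2, "hap1",
                             ifelse(res$votes_hap2 > res$votes_hap1,
                                    "hap2", "untagged"))
  }
  res
}

#' Partition aligned reads into haplotype and untagged sets
#'
#' @inheritParams haplotag_reads
#' @return list of read-id vectors: `hap1`, `hap2`, `untagged` (aligned
#'   but uninformative), and `unaligned` (no reference alignment; counted
#'   separately, excluded from the three partitions).
#' @export
partition_reads <- function(alignments, reads, variants) {
  tags <- haplotag_reads(alignments, reads, variants)
  list(hap1 = tags$read_id[tags$assignment == "hap1"],
       hap2 = tags$read_id[tags$assignment == "hap2"],
       untagged = tags$read_id[tags$assignment == "untagged"],
       unaligned = alignments$read_id[!alignments$aligned],
       tags = tags)
}

#' Downsample by keeping the longest reads per window
#'
#' Tiles the reference region into fixed non-overlapping windows and, in
#' each window, ranks overlapping reads by length (descending, ties by
#' read id) and marks reads kept until the window's overlap bases first
#' reach `target_cov * window_size` (or reads run out). A read kept for
#' any window is kept globally, preserving contiguity for assembly;
#' windows at or below the target keep all their reads.
#'
#' @param intervals data frame with `read_id`, `ref_start`, `ref_end`
#'   (0-based half-open reference intervals) and optionally `read_len`
#'   (defaults to the interval span).
#' @param window_size window size in bp (default 10 kb).
#' @param target_cov per-window coverage target in fold (default 30).
#' @param region_length region length; defaults to `max(ref_end)`.
#' @return character vector of kept read ids.
#' @export
downsample_longest_per_window <- function(intervals, window_size = 10000,
                                          target_cov = 30,
                                          region_length = NULL) {
  if (window_size <= 0) stop("window_size must be positive")
  if (!nrow(intervals)) return(character(0))
  if (is.null(intervals$read_len))
    intervals$read_len <- intervals$ref_end - intervals$ref_start
  if (is.null(region_length)) region_length <- max(intervals$ref_end)
  starts <- seq(0L, max(0L, region_length - 1L), by = window_size)
  keep <- logical(nrow(intervals))
  ord_all <- order(-intervals$read_len, intervals$read_id)
  budget <- target_cov * window_size
  for (ws in starts) {
    we <- min(ws + window_size, region_length)
    idx <- ord_all[intervals$ref_start[ord_all] < we &
                     intervals$ref_end[ord_all] > ws]
    if (!length(idx)) next
    ovl <- pmin(intervals$ref_end[idx], we) - pmax(intervals$ref_start[idx], ws)
    cum <- cumsum(as.numeric(ovl))
    cut <- which(cum >= budget)
    n_keep <- if (length(cut)) cut[1] else length(idx)
    keep[idx[seq_len(n_keep)]] <- TRUE
  }
  unique(intervals$read_id[keep])
}
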