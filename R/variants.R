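#' Anchor-based alignment of an assembled haplotype to the reference
#'
#' Finds k-mers unique in both sequences, keeps the longest strictly
#' co-linear subset (longest-increasing-subsequence chaining by anchor
#' count), and merges same-diagonal anchors into ungapped blocks. If the
#' reverse complement of the query yields more anchors, the chain is
#' built on the opposite strand (the returned chain coordinates refer to
#' the reverse-complemented query; see the `strand` attribute).
#'
#' @param qry assembled haplotype/contig sequence.
#' @param ref reference region sequence.
#' @param anchor_k anchor k-mer size (default 31).
#' @return an [aln_chain()] (query -> reference) with attributes
#'   `strand`, `ref_len`, `qry_len`.
#' @export
anchor_align <- function(qry, ref, anchor_k = 31) {
  if (nchar(qry) < anchor_k || nchar(ref) < anchor_k)
    stop("sequences must be at least anchor_k long")
  fwd <- cpp_unique_anchors(ref, qry, as.integer(anchor_k))
  rc <- revcomp(qry)
  rev <- cpp_unique_anchors(ref, rc, as.integer(anchor_k))
  if (nrow(rev) > nrow(fwd)) {
    anchors <- rev; strand <- "-"; qseq <- rc
  } else {
    anchors <- fwd; strand <- "+"; qseq <- qry
  }
  if (!nrow(anchors)) stop("no anchors found between query and reference")
  chain_ix <- cpp_lis_chain(anchors[, 2])
  a <- anchors[chain_ix, , drop = FALSE]
  k <- anchor_k
  rs <- re <- qs <- qe <- integer(0)
  cur <- c(a[1, 1], a[1, 1] + k, a[1, 2], a[1, 2] + k)
  for (i in seq_len(nrow(a))[-1]) {
    rp <- a[i, 1]; qp <- a[i, 2]
    same_diag <- (qp - rp) == (cur[3] - cur[1])
    if (same_diag && rp <= cur[2]) {
      cur[2] <- rp + k; cur[4] <- qp + k
    } else if (rp >= cur[2] && qp >= cur[4]) {
      if (same_diag) {  # same diagonal with a (mismatch) gap: still ungapped
        cur[2] <- rp + k; cur[4] <- qp + k
      } else {
        rs <- c(rs, cur[1]); re <- c(re, cur[2])
        qs <- c(qs, cur[3]); qe <- c(qe, cur[4])
        cur <- c(rp, rp + k, qp, qp + k)
      }
    }
    # anchors overlapping the previous block on a new diagonal are skipped
  }
  rs <- c(rs, cur[1]); re <- c(re, cur[2])
  qs <- c(qs, cur[3]); qe <- c(qe, cur[4])
  aln_chain(data.frame(ref_start = rs, ref_end = re,
                       qry_start = qs, qry_end = qe),
            strand = strand, ref_len = nchar(ref), qry_len = nchar(qry))
}

called_variant_row <- function(pos, ref, alt, haplotype) {
  size <- abs(nchar(alt) - nchar(ref))
  vclass <- if (size >= 50) {
    if (nchar(ref) > nchar(alt)) "SV-DEL" else "SV-INS"
  } else if (size > 0) "indel" else "SNV"
  data.frame(pos = as.integer(pos), ref = ref, alt = alt, vclass = vclass,
             size = as.integer(size), haplotype = haplotype,
             stringsAsFactors = FALSE)
}

empty_calls <- function() {
  data.frame(pos = integer(0), ref = character(0), alt = character(0),
             vclass = character(0), size = integer(0),
             haplotype = character(0), stringsAsFactors = FALSE)
}

# decompose a pairwise global alignment of two gap substrings into
# SNV/indel records; ref_offset0 is the 0-based reference position of the
# first gap base (the gap is always flanked left by a block, so
# ref_offset0 >= 1 and indels can be anchored on the preceding base)
align_gap_calls <- function(qgap, rgap, ref_offset0, reference, haplotype) {
  al <- Biostrings::pairwiseAlignment(qgap, rgap, type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  calls <- list()
  rpos0 <- ref_offset0  # 0-based position of the next reference base
  i <- 1
  while (i <= length(p)) {
    if (p[i] != "-" && s[i] != "-") {
      if (p[i] != s[i])
        calls[[length(calls) + 1]] <-
          called_variant_row(rpos0, s[i], p[i], haplotype)
      rpos0 <- rpos0 + 1; i <- i + 1
    } else if (s[i] == "-") {           # insertion in query
      j <- i
      while (j <= length(p) && s[j] == "-") j <- j + 1
      ins <- paste(p[i:(j - 1)], collapse = "")
      anchor <- substr(reference, rpos0, rpos0)  # 0-based rpos0 - 1
      calls[[length(calls) + 1]] <-
        called_variant_row(rpos0 - 1, anchor, paste0(anchor, ins),
                           haplotype)
      i <- j
    } else {                            # deletion in query
      j <- i
      while (j <= length(p) && p[j] == "-") j <- j + 1
      del <- paste(s[i:(j - 1)], collapse = "")
      anchor <- substr(reference, rpos0, rpos0)
      calls[[length(calls) + 1]] <-
        called_variant_row(rpos0 - 1, paste0(anchor, del), anchor,
                           haplotype)
      rpos0 <- rpos0 + (j - i); i <- j
    }
  }
  calls
}

#' Call variants from an anchor chain
#'
#' Within-block mismatches become SNVs. Inter-block gaps are classified
#' by the net length difference: a difference of at least `sv_threshold`
#' (50 bp) is a structural variant (deletion when the reference gap is
#' larger, insertion when the query gap is larger, a paired DEL+INS when
#' both gaps are themselves SV-sized); smaller gaps are resolved by
#' global alignment of the two gap substrings into SNV and indel calls.
#' Chains spanning less than `min_region` emit no calls. All calls are
#' normalized (left-aligned, minimal) against the reference.
#'
#' @param chain an [anchor_align()] chain.
#' @param qry,ref the two sequences (query in chain orientation).
#' @param min_region minimum chain reference span to emit calls (bp).
#' @param sv_threshold SV size threshold (bp, default 50).
#' @param haplotype haplotype label attached to the calls.
#' @return a called-variant data frame: `pos` (0-based reference), `ref`,
#'   `alt`, `vclass` (`SNV`/`indel`/`SV-DEL`/`SV-INS`), `size`,
#'   `haplotype`.
#' @export
call_variants <- function(chain, qry, ref, min_region = 10000,
                          sv_threshold = 50, haplotype = "hap1") {
  if (attr(chain, "strand") == "-") qry <- revcomp(qry)
  span <- max(chain$ref_end) - min(chain$ref_start)
  if (span < min_region) return(empty_calls())
  calls <- list()
  for (i in seq_len(nrow(chain))) {
    rseq <- substr(ref, chain$ref_start[i] + 1, chain$ref_end[i])
    qseq <- substr(qry, chain$qry_start[i] + 1, chain$qry_end[i])
    mism <- which(utf8ToInt(rseq) != utf8ToInt(qseq))
    for (m in mism)
      calls[[length(calls) + 1]] <-
        called_variant_row(chain$ref_start[i] + m - 1,
                           substr(rseq, m, m), substr(qseq, m, m),
                           haplotype)
  }
  if (nrow(chain) > 1) for (i in seq_len(nrow(chain) - 1)) {
    rg <- chain$ref_start[i + 1] - chain$ref_end[i]
    qg <- chain$qry_start[i + 1] - chain$qry_end[i]
    if (rg == 0 && qg == 0) next
    anchor_pos <- chain$ref_end[i] - 1  # 0-based base before the gap
    anchor <- substr(ref, anchor_pos + 1, anchor_pos + 1)
    rgap <- substr(ref, chain$ref_end[i] + 1, chain$ref_start[i + 1])
    qgap <- substr(qry, chain$qry_end[i] + 1, chain$qry_start[i + 1])
    if (abs(rg - qg) >= sv_threshold) {
      if (min(rg, qg) >= sv_threshold) {
        # complex gap: breakend-free paired DEL + INS representation
        calls[[length(calls) + 1]] <-
          called_variant_row(anchor_pos, paste0(anchor, rgap), anchor,
                             haplotype)
        calls[[length(calls) + 1]] <-
          called_variant_row(anchor_pos, anchor, paste0(anchor, qgap),
                             haplotype)
      } else {
        calls[[length(calls) + 1]] <-
          called_variant_row(anchor_pos, paste0(anchor, rgap),
                             paste0(anchor, qgap), haplotype)
      }
    } else if (rg == 0 || qg == 0) {
      calls[[length(calls) + 1]] <-
        called_variant_row(anchor_pos, paste0(anchor, rgap),
                           paste0(anchor, qgap), haplotype)
    } else {
      calls <- c(calls, align_gap_calls(qgap, rgap, chain$ref_end[i],
                                        ref, haplotype))
    }
  }
  if (!length(calls)) return(empty_calls())
  out <- do.call(rbind, calls)
  for (i in seq_len(nrow(out))) {
    n <- normalize_variant(out$pos[i], out$ref[i], out$alt[i], ref)
    out$pos[i] <- n$pos; out$ref[i] <- n$ref; out$alt[i] <- n$alt
  }
  out <- out[order(out$pos, out$ref, out$alt), , drop = FALSE]
  out <- out[!duplicated(out[c("pos", "ref", "alt")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-window variant counts by class
#'
#' Tallies calls into fixed windows (default 100 kb) per variant class;
#' the grand total equals the number of calls.
#'
#' @param calls called-variant data frame (possibly several haplotypes).
#' @param window window size in bp.
#' @param region_length region length; defaults to covering the last
#'   call.
#' @return data frame with `window_start`, `window_end`, and one count
#'   column per class present.
#' @export
variant_summary <- function(calls, window = 100000, region_length = NULL) {
  if (is.null(region_length))
    region_length <- if (nrow(calls)) max(calls$pos) + 1L else window
  starts <- seq(0L, max(0L, region_length - 1L), by = window)
  classes <- c("SNV", "indel", "SV-DEL", "SV-INS")
  out <- data.frame(window_start = starts,
                    window_end = pmin(starts + window, region_length))
  for (cl in classes) {
    p <- calls$pos[calls$vclass == cl]
    out[[cl]] <- vapply(seq_along(starts), function(i)
      sum(p >= out$window_start[i] & p < out$window_end[i]), integer(1))
  }
  out
}
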