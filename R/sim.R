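#' Specify a synthetic target region
#'
#' @param length region length in bp (> 0).
#' @param gc_content GC fraction in \[0, 1\].
#' @param seed integer seed driving all draws derived from this region.
#' @return a `region_spec` list.
#' @export
region_spec <- function(length, gc_content = 0.41, seed = 1L) {
  stopifnot(is.numeric(length), length >= 1)
  if (gc_content < 0 || gc_content > 1) stop("gc_content must be in [0, 1]")
  structure(list(length = as.integer(length), gc_content = gc_content,
                 seed = as.integer(seed)),
            class = "region_spec")
}

#' Simulate an ancestral (reference) sequence
#'
#' Draws an i.i.d. nucleotide sequence at the requested GC content. This
#' stands in for the reference copy of the targeted region; haplotypes are
#' derived from it by [derive_haplotypes()].
#'
#' @param spec a [region_spec()].
#' @return a single uppercase A/C/G/T string of length `spec$length`.
#' @export
simulate_ancestral <- function(spec) {
  stopifnot(inherits(spec, "region_spec"))
  if (spec$length <= 0) stop("region length must be positive")
  gc <- spec$gc_content
  with_op_seed(spec$seed, "simulate_ancestral", {
    bases <- sample(c("A", "C", "G", "T"), spec$length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    paste(bases, collapse = "")
  })
}

#' Truth structural-variant constructors
#'
#' Build anchored deletion/insertion records against an ancestral
#' sequence, for planting known SVs into a haplotype. Alleles follow the
#' VCF convention of sharing the anchor base at `pos`.
#'
#' @param ancestral ancestral sequence string.
#' @param pos 0-based anchor position.
#' @param size event size in bp (net length difference).
#' @param genotype which haplotype carries the alternate allele
#'   (`"hap1"`, `"hap2"`, or `"both"`).
#' @param insert_seq for insertions, the inserted bases; if `NULL`, drawn
#'   uniformly using `seed`.
#' @param seed seed for a random insertion sequence.
#' @return a one-row truth-variant data frame.
#' @export
sv_deletion <- function(ancestral, pos, size, genotype = "hap1") {
  L <- nchar(ancestral)
  if (pos < 0 || pos + size + 1 > L) stop("SV outside region")
  data.frame(pos = as.integer(pos),
             ref = substr(ancestral, pos + 1, pos + 1 + size),
             alt = substr(ancestral, pos + 1, pos + 1),
             genotype = genotype, vclass = "SV",
             stringsAsFactors = FALSE)
}

#' @rdname sv_deletion
#' @export
sv_insertion <- function(ancestral, pos, size, genotype = "hap2",
                         insert_seq = NULL, seed = 1L) {
  L <- nchar(ancestral)
  if (pos < 0 || pos + 1 > L) stop("SV outside region")
  if (is.null(insert_seq)) {
    insert_seq <- with_op_seed(seed, "sv_insertion", {
      paste(sample(c("A", "C", "G", "T"), size, replace = TRUE),
            collapse = "")
    })
  }
  if (nchar(insert_seq) != size) stop("insert_seq length must equal size")
  anchor <- substr(ancestral, pos + 1, pos + 1)
  data.frame(pos = as.integer(pos), ref = anchor,
             alt = paste0(anchor, insert_seq),
             genotype = genotype, vclass = "SV",
             stringsAsFactors = FALSE)
}

#' Derive two haplotypes from an ancestral sequence
#'
#' Plants heterozygous SNVs and small indels at the given per-bp rates and
#' applies any explicitly listed structural variants. Small indels are
#' 1-10 bp (geometric length, p = 0.5), below the 50 bp SV threshold; SVs
#' are never drawn at random so the truth set is exactly known.
#'
#' @param ancestral ancestral sequence string.
#' @param snv_rate,indel_rate per-bp heterozygous variant rates in
#'   \[0, 0.05\].
#' @param sv_list a truth-variant data frame of structural variants (see
#'   [sv_deletion()]), or `NULL`.
#' @param seed integer seed.
#' @return a list with `hap1`, `hap2` (sequences), `truth` (variant data
#'   frame sorted by `pos`), and `chain_hap1`/`chain_hap2` (alignment
#'   chains mapping each haplotype to ancestral coordinates).
#' @export
derive_haplotypes <- function(ancestral, snv_rate = 0.001, indel_rate = 0,
                              sv_list = NULL, seed = 1L) {
  L <- nchar(ancestral)
  if (snv_rate < 0 || snv_rate > 0.05 || indel_rate < 0 || indel_rate > 0.05)
    stop("variant rates must be in [0, 0.05]")
  sv <- if (is.null(sv_list)) empty_truth() else sv_list
  if (nrow(sv)) {
    if (any(sv$pos < 0 | sv$pos + nchar(sv$ref) > L)) stop("SV outside region")
    sv <- sv[order(sv$pos), , drop = FALSE]
    if (nrow(sv) > 1 &&
        any(sv$pos[-1] < (sv$pos + nchar(sv$ref))[-nrow(sv)]))
      stop("overlapping SVs")
    if (any(substring(ancestral, sv$pos + 1, sv$pos + nchar(sv$ref)) != sv$ref))
      stop("SV ref allele does not match ancestral sequence")
  }

  small <- with_op_seed(seed, "derive_haplotypes", {
    snv_pos <- which(runif(L) < snv_rate) - 1L
    ind_pos <- which(runif(L) < indel_rate) - 1L
    n_snv <- length(snv_pos)
    rows <- list()
    if (n_snv) {
      ref_b <- substr_vec(ancestral, snv_pos, 1L)
      alt_b <- vapply(ref_b, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1),
        USE.NAMES = FALSE)
      rows$snv <- data.frame(pos = snv_pos, ref = ref_b, alt = alt_b,
                             genotype = sample(c("hap1", "hap2"), n_snv,
                                               replace = TRUE),
                             vclass = "SNV", stringsAsFactors = FALSE)
    }
    if (length(ind_pos)) {
      lens <- pmin(rgeom(length(ind_pos), 0.5) + 1L, 10L)
      is_del <- runif(length(ind_pos)) < 0.5
      keep <- !is_del | (ind_pos + lens + 1L <= L)
      ind_pos <- ind_pos[keep]; lens <- lens[keep]; is_del <- is_del[keep]
      if (length(ind_pos)) {
        anchor <- substr_vec(ancestral, ind_pos, 1L)
        ref <- ifelse(is_del, substr_vec(ancestral, ind_pos, lens + 1L), anchor)
        ins <- vapply(lens, function(l)
          paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
                collapse = ""), character(1))
        alt <- ifelse(is_del, anchor, paste0(anchor, ins))
        rows$ind <- data.frame(pos = ind_pos, ref = ref, alt = alt,
                               genotype = sample(c("hap1", "hap2"),
                                                 length(ind_pos),
                                                 replace = TRUE),
                               vclass = "indel", stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else empty_truth()
  })

  # SVs take precedence: drop small variants touching any SV footprint,
  # then resolve collisions among the small variants themselves
  if (nrow(sv) && nrow(small)) {
    in_sv <- vapply(seq_len(nrow(small)), function(i) {
      s <- small$pos[i]; e <- s + nchar(small$ref[i])
      any(s < sv$pos + nchar(sv$ref) & e > sv$pos)
    }, logical(1))
    small <- small[!in_sv, , drop = FALSE]
  }
  if (nrow(small) > 1) {
    small <- small[order(small$pos), , drop = FALSE]
    keep <- logical(nrow(small))
    last_end <- -1L
    for (i in seq_len(nrow(small))) {
      if (small$pos[i] > last_end) {
        keep[i] <- TRUE
        last_end <- small$pos[i] + nchar(small$ref[i]) - 1L
      }
    }
    small <- small[keep, , drop = FALSE]
  }
  truth <- rbind(sv, small)
  truth <- truth[order(truth$pos), , drop = FALSE]
  rownames(truth) <- NULL

  list(hap1 = apply_truth(ancestral, truth, "hap1"),
       hap2 = apply_truth(ancestral, truth, "hap2"),
       truth = truth,
       chain_hap1 = truth_chain(truth, L, "hap1"),
       chain_hap2 = truth_chain(truth, L, "hap2"))
}

empty_truth <- function() {
  data.frame(pos = integer(0), ref = character(0), alt = character(0),
             genotype = character(0), vclass = character(0),
             stringsAsFactors = FALSE)
}

# vectorized substr at 0-based positions
substr_vec <- function(x, pos0, len) {
  substring(x, pos0 + 1L, pos0 + len)
}

#' Apply a truth variant set to the ancestral sequence
#'
#' Reconstructs one haplotype from the ancestral sequence and the subset
#' of truth variants it carries; the round-trip
#' `apply_truth(ancestral, truth, h) == hap_h` holds bit-exactly for
#' [derive_haplotypes()] output.
#'
#' @param ancestral ancestral sequence string.
#' @param truth truth-variant data frame.
#' @param haplotype `"hap1"` or `"hap2"`.
#' @return the haplotype sequence.
#' @export
apply_truth <- function(ancestral, truth, haplotype) {
  v <- truth[truth$genotype %in% c(haplotype, "both"), , drop = FALSE]
  if (!nrow(v)) return(ancestral)
  v <- v[order(v$pos), , drop = FALSE]
  pieces <- character(2 * nrow(v) + 1)
  cursor <- 0L
  for (i in seq_len(nrow(v))) {
    pieces[2 * i - 1] <- substr(ancestral, cursor + 1, v$pos[i])
    pieces[2 * i] <- v$alt[i]
    cursor <- v$pos[i] + nchar(v$ref[i])
  }
  pieces[2 * nrow(v) + 1] <- substr(ancestral, cursor + 1, nchar(ancestral))
  paste(pieces, collapse = "")
}

#' Truth alignment chain of a haplotype against the ancestral sequence
#'
#' Builds the exact block structure (0-based, half-open, query = haplotype,
#' reference = ancestral) implied by the truth variants a haplotype
#' carries. Length-preserving variants stay inside blocks; indels and SVs
#' break them.
#'
#' @inheritParams apply_truth
#' @param ref_len ancestral sequence length.
#' @return an `aln_chain` data frame.
#' @export
truth_chain <- function(truth, ref_len, haplotype) {
  v <- truth[truth$genotype %in% c(haplotype, "both"), , drop = FALSE]
  v <- v[nchar(v$ref) != nchar(v$alt), , drop = FALSE]
  v <- v[order(v$pos), , drop = FALSE]
  rs <- qs <- re <- qe <- integer(0)
  rc <- qc <- 0L
  if (nrow(v)) for (i in seq_len(nrow(v))) {
    rlen <- nchar(v$ref[i]); alen <- nchar(v$alt[i])
    common <- min(rlen, alen)  # anchored alleles share their prefix
    block_re <- v$pos[i] + common
    rs <- c(rs, rc); re <- c(re, block_re)
    qs <- c(qs, qc); qe <- c(qe, qc + (block_re - rc))
    qc <- qc + (block_re - rc) + (alen - common)
    rc <- v$pos[i] + rlen
  }
  rs <- c(rs, rc); re <- c(re, ref_len)
  qs <- c(qs, qc); qe <- c(qe, qc + (ref_len - rc))
  keep <- re > rs | qe > qs
  aln_chain(data.frame(ref_start = rs, ref_end = re,
                       qry_start = qs, qry_end = qe)[keep, , drop = FALSE],
            strand = "+", ref_len = ref_len, qry_len = qe[length(qe)])
}

#' Phased heterozygous small variants implied by a truth set
#'
#' Restricts a truth set to heterozygous SNVs and small indels and
#' expresses them as phased variants (the unit of haplotagging), with one
#' phase set covering the region.
#'
#' @param truth truth-variant data frame.
#' @param phase_set phase-set label.
#' @return a phased-variant data frame with `pos`, `ref`, `alt`,
#'   `hap1_allele`, `hap2_allele`, `phase_set`.
#' @export
truth_phased_variants <- function(truth, phase_set = "PS1") {
  v <- truth[truth$vclass %in% c("SNV", "indel") &
               truth$genotype %in% c("hap1", "hap2"), , drop = FALSE]
  phased_variants(pos = v$pos, ref = v$ref, alt = v$alt,
                  hap1_allele = ifelse(v$genotype == "hap1", "alt", "ref"),
                  hap2_allele = ifelse(v$genotype == "hap2", "alt", "ref"),
                  phase_set = phase_set)
}
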