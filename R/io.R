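#' Sequence and table IO
#'
#' Thin wrappers around Biostrings/vcfR for the package's on-disk
#' formats: FASTA for haplotypes and contigs, FASTQ for simulated reads,
#' VCF 4.2 with phased genotypes for variant sets, and TSV sidecars for
#' truth labels and alignment intervals.
#'
#' @param seqs named character vector of sequences.
#' @param path output/input file path.
#' @name haplokit-io
NULL

#' @rdname haplokit-io
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname haplokit-io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname haplokit-io
#' @param reads read data frame (`read_id`, `sequence`).
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' @rdname haplokit-io
#' @export
write_truth_tsv <- function(reads, path) {
  write.table(reads[c("read_id", "truth_haplotype", "start", "end")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname haplokit-io
#' @export
read_truth_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write phased heterozygous variants as VCF 4.2
#'
#' Positions convert from the package's 0-based convention to 1-based
#' VCF; genotypes are phased (`1|0` when haplotype 1 carries the
#' alternate allele) with a PS tag. The file is bgzip-compressed by vcfR,
#' so `path` should end in `.vcf.gz`.
#'
#' @param variants a [phased_variants()] data frame.
#' @param path output path (`.vcf.gz`).
#' @param contig contig name used in CHROM.
#' @param contig_length contig length for the VCF header.
#' @param sample sample column name.
#' @export
write_phased_vcf <- function(variants, path, contig = "region",
                             contig_length = NA, sample = "SAMPLE") {
  meta <- c("##fileformat=VCFv4.2",
            sprintf("##contig=<ID=%s%s>", contig,
                    if (is.na(contig_length)) ""
                    else sprintf(",length=%d", as.integer(contig_length))),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            paste0("##FORMAT=<ID=PS,Number=1,Type=String,",
                   "Description=\"Phase set\">"))
  fix <- cbind(CHROM = rep(contig, nrow(variants)),
               POS = as.character(variants$pos + 1L),
               ID = rep(".", nrow(variants)),
               REF = variants$ref, ALT = variants$alt,
               QUAL = rep(".", nrow(variants)),
               FILTER = rep("PASS", nrow(variants)),
               INFO = rep(".", nrow(variants)))
  gt_str <- paste0(ifelse(variants$hap1_allele == "alt", "1|0", "0|1"),
                   ":", variants$phase_set)
  gt <- cbind(FORMAT = rep("GT:PS", nrow(variants)), gt_str)
  colnames(gt)[2] <- sample
  v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                    meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, path)
  invisible(path)
}

#' Read a phased VCF back into a phased-variant table
#'
#' Multi-allelic records are split into bi-allelic ones before use;
#' unphased or homozygous genotypes are dropped with a warning.
#'
#' @param path a VCF (optionally gzipped) with a single sample and
#'   phased GT (and optional PS) entries.
#' @return a [phased_variants()] data frame (0-based positions).
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  ps <- tryCatch(vcfR::extract.gt(v, element = "PS"),
                 error = function(e) NULL)
  pos <- integer(0); ref <- alt <- h1 <- h2 <- psv <- character(0)
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    g <- gt_raw[i, 1]
    if (is.na(g) || !grepl("|", g, fixed = TRUE)) next
    al <- as.integer(strsplit(g, "|", fixed = TRUE)[[1]])
    if (length(al) != 2 || al[1] == al[2]) next
    # split multi-allelic: keep the two alleles actually carried
    carried <- unique(al[al > 0])
    for (a in carried) {
      pos <- c(pos, as.integer(fix[i, "POS"]) - 1L)
      ref <- c(ref, fix[i, "REF"])
      alt <- c(alt, alts[a])
      h1 <- c(h1, if (al[1] == a) "alt" else "ref")
      h2 <- c(h2, if (al[2] == a) "alt" else "ref")
      psv <- c(psv, if (!is.null(ps) && !is.na(ps[i, 1])) ps[i, 1]
               else "PS1")
    }
  }
  phased_variants(pos = pos, ref = ref, alt = alt, hap1_allele = h1,
                  hap2_allele = h2, phase_set = psv)
}

#' Write/read alignment intervals as a simplified PAF-like TSV
#'
#' Columns: read_id, target, start, end, strand, cigar (`<n>M` for the
#' reference span). The reverse direction reconstructs the interval table
#' used by [downsample_longest_per_window()].
#'
#' @param alignments a `read_alignments` data frame.
#' @param path file path.
#' @export
write_alignments_tsv <- function(alignments, path) {
  a <- alignments[alignments$aligned, , drop = FALSE]
  df <- data.frame(read_id = a$read_id, target = "ref",
                   start = a$ref_start, end = a$ref_end, strand = "+",
                   cigar = sprintf("%dM", a$ref_end - a$ref_start),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignments_tsv
#' @export
read_alignments_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  data.frame(read_id = df$read_id, ref_start = df$start,
             ref_end = df$end, stringsAsFactors = FALSE)
}

#' Write chain blocks as PAF
#'
#' One PAF line per ungapped block (matches = block length, mapq 60).
#'
#' @param chain an [aln_chain()].
#' @param qname,tname query/target names.
#' @param path file path.
#' @export
write_chain_paf <- function(chain, qname, tname, path) {
  b <- as.data.frame(chain)
  df <- data.frame(qname = qname, qlen = attr(chain, "qry_len"),
                   qstart = b$qry_start, qend = b$qry_end,
                   strand = attr(chain, "strand"),
                   tname = tname, tlen = attr(chain, "ref_len"),
                   tstart = b$ref_start, tend = b$ref_end,
                   nmatch = b$ref_end - b$ref_start,
                   alen = b$ref_end - b$ref_start, mapq = 60L)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
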