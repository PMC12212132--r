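#' Construct a phased heterozygous variant table
#'
#' The unit record of consensus phasing and haplotagging: a heterozygous
#' site with its reference/alternate alleles, the allele carried by each
#' haplotype, and a phase-set label. Positions are 0-based.
#'
#' @param pos 0-based positions.
#' @param ref,alt allele strings (non-empty).
#' @param hap1_allele,hap2_allele `"ref"` or `"alt"`; the two must differ
#'   at every site (heterozygosity).
#' @param phase_set phase-set identifier(s).
#' @return a `phased_variants` data frame sorted by position.
#' @export
phased_variants <- function(pos, ref, alt, hap1_allele, hap2_allele,
                            phase_set = "PS1") {
  n <- length(pos)
  rec <- function(x) if (length(x) == 1 && n != 1) rep(x, n) else x
  ref <- rec(ref); alt <- rec(alt)
  hap1_allele <- rec(hap1_allele); hap2_allele <- rec(hap2_allele)
  phase_set <- rec(phase_set)
  if (n == 0) phase_set <- phase_set[0]
  stopifnot(length(ref) == n, length(alt) == n)
  if (any(nchar(ref) == 0) || any(nchar(alt) == 0))
    stop("alleles must be non-empty")
  if (any(hap1_allele == hap2_allele))
    stop("phased variants must be heterozygous (hap1_allele != hap2_allele)")
  df <- data.frame(pos = as.integer(pos), ref = as.character(ref),
                   alt = as.character(alt),
                   hap1_allele = hap1_allele, hap2_allele = hap2_allele,
                   phase_set = phase_set, stringsAsFactors = FALSE)
  df <- df[order(df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("phased_variants", "data.frame")
  df
}

#' Normalize a variant to its left-aligned, minimal representation
#'
#' Applies the standard normalization used before callset comparison:
#' shared suffix bases are trimmed (extending left with reference bases
#' whenever an allele would empty), then shared prefix bases are trimmed.
#' The result is unique and normalization is idempotent, which makes
#' position/allele intersection of two callsets well defined.
#'
#' @param pos 0-based position.
#' @param ref,alt allele strings; `ref` must match the reference at
#'   `pos`.
#' @param reference the reference sequence.
#' @return list with normalized `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(pos, ref, alt, reference) {
  if (substr(reference, pos + 1, pos + nchar(ref)) != ref)
    stop("ref allele does not match reference at pos ", pos)
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0 && na > 0 &&
        substr(ref, nr, nr) == substr(alt, na, na) && (nr > 1 || na > 1)) {
      if (nr == 1 || na == 1) {
        if (pos == 0) break
        b <- substr(reference, pos, pos)
        ref <- paste0(b, ref); alt <- paste0(b, alt)
        pos <- pos - 1L
        nr <- nr + 1L; na <- na + 1L
      }
      ref <- substr(ref, 1, nr - 1)
      alt <- substr(alt, 1, na - 1)
    } else break
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
           substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

#' Normalize every variant of a callset
#'
#' @param variants a [phased_variants()] (or truth/called variant) data
#'   frame with `pos`, `ref`, `alt`.
#' @param reference the reference sequence.
#' @return the data frame with normalized records, re-sorted by position.
#' @export
normalize_callset <- function(variants, reference) {
  if (!nrow(variants)) return(variants)
  for (i in seq_len(nrow(variants))) {
    n <- normalize_variant(variants$pos[i], variants$ref[i],
                           variants$alt[i], reference)
    variants$pos[i] <- n$pos
    variants$ref[i] <- n$ref
    variants$alt[i] <- n$alt
  }
  variants <- variants[order(variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  variants
}

#' Intersect two phased callsets into a consensus set
#'
#' Emulates building a reliable heterozygous set from two sequencing
#' platforms: both callsets are normalized against the same reference and
#' matched on the `(pos, ref, alt)` key; only sites present in both are
#' kept. Phase orientation (which allele sits on which haplotype) is taken
#' from callset `a`, conventionally the long-read callset.
#'
#' @param a,b phased-variant data frames.
#' @param reference reference sequence used for normalization; if `NULL`
#'   the callsets are assumed already normalized (an error is raised when
#'   a record is detected non-normalized).
#' @return consensus [phased_variants()] data frame (subset of `a`).
#' @export
intersect_callsets <- function(a, b, reference = NULL) {
  if (!is.null(reference)) {
    a <- normalize_callset(a, reference)
    b <- normalize_callset(b, reference)
  }
  key <- function(v) paste(v$pos, v$ref, v$alt, sep = ":")
  out <- a[key(a) %in% key(b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Decide diploid vs haploid processing from heterozygosity density
#'
#' A region whose consensus heterozygous-variant density falls below the
#' threshold is treated as haploid (loss of heterozygosity), in which
#' case partitioning is skipped and all reads are assembled together.
#'
#' @param consensus consensus phased-variant data frame.
#' @param region_length region length in bp (> 0).
#' @param threshold haploid-call threshold in heterozygous sites per kb
#'   (strict `<`; a density exactly at threshold is diploid).
#' @return list with `mode` (`"diploid"`/`"haploid"`), `n_het`, and
#'   `density` (het per kb).
#' @export
classify_ploidy <- function(consensus, region_length, threshold = 0.05) {
  if (region_length <= 0) stop("region_length must be positive")
  n <- nrow(consensus)
  density <- n / (region_length / 1000)
  list(mode = if (density < threshold) "haploid" else "diploid",
       n_het = n, density = density)
}
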