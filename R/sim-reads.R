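#' Simulate long reads from one haplotype
#'
#' HiFi-like reads: lengths drawn from a truncated normal (clamped to
#' \[1 kb, 4 x mean\] and to the haplotype length), start positions
#' uniform, substitution errors at a fixed per-base rate (no indel or
#' chimeric errors), forward strand. Reads are drawn until the total base
#' count reaches `depth * nchar(hap)`.
#'
#' @param hap haplotype sequence string.
#' @param depth target fold coverage (> 0).
#' @param mean_len,len_sd read length distribution in bp (`mean_len` >=
#'   1000).
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @param hap_label truth haplotype label recorded with each read.
#' @return data frame with `read_id`, `sequence`, `truth_haplotype`,
#'   `start`, `end` (0-based half-open on the source haplotype), and
#'   `error_rate_applied`.
#' @export
simulate_long_reads <- function(hap, depth, mean_len = 10000, len_sd = 1000,
                                error_rate = 0, seed = 1L,
                                hap_label = "hap1") {
  if (depth <= 0) stop("depth must be positive")
  if (mean_len < 1000) stop("mean_len must be >= 1000")
  L <- nchar(hap)
  target <- depth * L
  with_op_seed(seed, paste0("simulate_long_reads_", hap_label), {
    n_guess <- max(1L, ceiling(target / mean_len * 1.3) + 10L)
    lens <- pmin(pmax(round(rnorm(n_guess, mean_len, len_sd)), 1000L),
                 4L * mean_len, L)
    n <- which(cumsum(as.numeric(lens)) >= target)[1]
    if (is.na(n)) n <- n_guess
    lens <- lens[seq_len(n)]
    starts <- floor(runif(n, 0, L - lens + 1))
    seqs <- substring(hap, starts + 1, starts + lens)
    if (error_rate > 0) {
      seqs <- vapply(seqs, function(s) {
        nm <- rbinom(1, nchar(s), error_rate)
        if (nm == 0) return(s)
        at <- sample.int(nchar(s), nm)
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        ch[at] <- vapply(ch[at], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    data.frame(read_id = sprintf("%s_r%06d", hap_label, seq_len(n)),
               sequence = seqs, truth_haplotype = hap_label,
               start = as.integer(starts),
               end = as.integer(starts + lens),
               error_rate_applied = error_rate,
               stringsAsFactors = FALSE)
  })
}

#' Simulate diploid long-read sequencing
#'
#' Convenience wrapper drawing `depth`-fold reads from each haplotype and
#' concatenating the two read sets.
#'
#' @inheritParams simulate_long_reads
#' @param hap1,hap2 haplotype sequences.
#' @return a combined long-read data frame.
#' @export
simulate_diploid_long_reads <- function(hap1, hap2, depth, mean_len = 10000,
                                        len_sd = 1000, error_rate = 0,
                                        seed = 1L) {
  rbind(simulate_long_reads(hap1, depth, mean_len, len_sd, error_rate,
                            seed, "hap1"),
        simulate_long_reads(hap2, depth, mean_len, len_sd, error_rate,
                            seed, "hap2"))
}

#' Simulate copy-number-weighted paired short-read WGS
#'
#' Draws read pairs uniformly along each haplotype in proportion to
#' `copies * depth_per_copy`, emulating whole-genome sequencing of a cell
#' with unequal haplotype copy numbers. Mate 2 is reported
#' reverse-complemented (sequencing orientation). Reads are error-free by
#' default so that the zero-edit unique filter behaves as in an ideal
#' aligner.
#'
#' @param hap1,hap2 haplotype sequences.
#' @param cn integer vector `c(copies_hap1, copies_hap2)`; not both zero.
#' @param depth_per_copy fold coverage contributed by each copy.
#' @param read_len read length in bp (>= 50).
#' @param insert_mean,insert_sd fragment length distribution.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return data frame with `read_id`, `mate` (1/2), `sequence`,
#'   `truth_haplotype`, `start`, `end` (0-based half-open, source
#'   haplotype forward strand).
#' @export
simulate_short_read_wgs <- function(hap1, hap2, cn = c(1L, 1L),
                                    depth_per_copy = 20, read_len = 150,
                                    insert_mean = 400, insert_sd = 50,
                                    error_rate = 0, seed = 1L) {
  if (read_len < 50) stop("read_len must be >= 50")
  if (length(cn) != 2 || any(cn < 0) || sum(cn) == 0)
    stop("cn must be two non-negative copies, not both zero")
  if (depth_per_copy == 0)
    return(data.frame(read_id = character(0), mate = integer(0),
                      sequence = character(0), truth_haplotype = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  one_hap <- function(hap, copies, label) {
    L <- nchar(hap)
    n_pairs <- round(copies * depth_per_copy * L / (2 * read_len))
    if (n_pairs == 0)
      return(NULL)
    with_op_seed(seed, paste0("simulate_short_read_wgs_", label), {
      frag <- pmin(pmax(round(rnorm(n_pairs, insert_mean, insert_sd)),
                        2L * read_len), L)
      fstart <- floor(runif(n_pairs, 0, L - frag + 1))
      s1 <- fstart; e1 <- fstart + read_len
      e2 <- fstart + frag; s2 <- e2 - read_len
      m1 <- substring(hap, s1 + 1, e1)
      m2 <- revcomp(substring(hap, s2 + 1, e2))
      mutate <- function(seqs) {
        if (error_rate <= 0) return(seqs)
        vapply(seqs, function(s) {
          nm <- rbinom(1, nchar(s), error_rate)
          if (nm == 0) return(s)
          at <- sample.int(nchar(s), nm)
          ch <- strsplit(s, "", fixed = TRUE)[[1]]
          ch[at] <- vapply(ch[at], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
          paste(ch, collapse = "")
        }, character(1), USE.NAMES = FALSE)
      }
      ids <- sprintf("%s_p%07d", label, seq_len(n_pairs))
      data.frame(read_id = c(ids, ids), mate = rep(1:2, each = n_pairs),
                 sequence = c(mutate(m1), mutate(m2)),
                 truth_haplotype = label,
                 start = as.integer(c(s1, s2)),
                 end = as.integer(c(e1, e2)),
                 stringsAsFactors = FALSE)
    })
  }
  out <- rbind(one_hap(hap1, cn[1], "hap1"), one_hap(hap2, cn[2], "hap2"))
  rownames(out) <- NULL
  out
}

#' Fabricate a noised copy of a phased callset
#'
#' Stands in for an independent sequencing platform's variant calls:
#' each true variant is dropped with probability `fn_rate` and false
#' positive SNVs are sprinkled at rate `fp_rate` per bp at positions not
#' already carrying a variant. Phase of false positives is random.
#'
#' @param variants a phased-variant data frame (see [phased_variants()]).
#' @param reference the reference sequence the callset is expressed on.
#' @param fn_rate per-variant false-negative probability.
#' @param fp_rate per-bp false-positive rate.
#' @param seed integer seed.
#' @param label op label so two calls with the same seed give independent
#'   noise.
#' @return a phased-variant data frame.
#' @export
perturb_callset <- function(variants, reference, fn_rate = 0.05,
                            fp_rate = 1e-5, seed = 1L, label = "a") {
  L <- nchar(reference)
  with_op_seed(seed, paste0("perturb_callset_", label), {
    keep <- runif(nrow(variants)) >= fn_rate
    out <- variants[keep, , drop = FALSE]
    n_fp <- rpois(1, fp_rate * L)
    if (n_fp > 0) {
      cand <- sample.int(L, min(n_fp * 3L, L)) - 1L
      cand <- setdiff(cand, variants$pos)[seq_len(min(n_fp, 1e6))]
      cand <- cand[!is.na(cand)]
      if (length(cand)) {
        ref_b <- substr_vec(reference, cand, 1L)
        alt_b <- vapply(ref_b, function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1),
          USE.NAMES = FALSE)
        flip <- runif(length(cand)) < 0.5
        fp <- phased_variants(pos = cand, ref = ref_b, alt = alt_b,
                              hap1_allele = ifelse(flip, "alt", "ref"),
                              hap2_allele = ifelse(flip, "ref", "alt"),
                              phase_set = "PS1")
        out <- rbind(out, fp)
      }
    }
    out <- out[order(out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
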