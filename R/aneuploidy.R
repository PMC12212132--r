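#' Build a personal (haplotype-embedded) reference pair
#'
#' Excises the target interval from the reference and embeds each
#' assembled haplotype in its place, giving two haplotype-specific
#' references whose flanks are bit-identical to the original reference.
#'
#' @param reference reference sequence string.
#' @param interval 0-based half-open `c(start, end)` of the target region
#'   within the reference; must be non-empty and in bounds.
#' @param hap1,hap2 haplotype sequences (non-empty).
#' @return a `personal_reference` list with `hap1_ref`, `hap2_ref`,
#'   `interval`.
#' @export
build_personal_reference <- function(reference, interval, hap1, hap2) {
  L <- nchar(reference)
  if (length(interval) != 2 || interval[1] < 0 || interval[2] > L ||
        interval[2] <= interval[1])
    stop("interval out of bounds or empty")
  if (nchar(hap1) == 0 || nchar(hap2) == 0)
    stop("haplotypes must be non-empty")
  left <- substr(reference, 1, interval[1])
  right <- substr(reference, interval[2] + 1, L)
  out <- list(hap1_ref = paste0(left, hap1, right),
              hap2_ref = paste0(left, hap2, right),
              interval = as.integer(interval))
  stopifnot(nchar(out$hap1_ref) ==
              L - (interval[2] - interval[1]) + nchar(hap1))
  class(out) <- "personal_reference"
  out
}

#' Keep reads uniquely and perfectly aligned to one haplotype
#'
#' The depth signal behind the aneuploidy profile: a read is kept for a
#' haplotype if it has a zero-edit (exact, either strand) alignment to
#' that haplotype and none to the other; reads matching both (from
#' segments identical between the haplotypes) or neither are dropped.
#' All reads must share one length (exact matching is done with a
#' constant-width dictionary).
#'
#' @param reads short-read data frame from [simulate_short_read_wgs()]
#'   (`read_id`, `mate`, `sequence`).
#' @param hap1,hap2 haplotype (or personal reference) sequences.
#' @return list with `hap1` and `hap2` hit data frames (`read_id`,
#'   `mate`, `start`, `end`, 0-based half-open) and `n_dropped`.
#' @export
unique_zero_edit_filter <- function(reads, hap1, hap2) {
  if (!nrow(reads))
    return(list(hap1 = empty_hits(), hap2 = empty_hits(), n_dropped = 0L))
  w <- nchar(reads$sequence)
  if (length(unique(w)) != 1) stop("reads must have constant length")
  dict_f <- Biostrings::PDict(Biostrings::DNAStringSet(reads$sequence))
  dict_r <- Biostrings::PDict(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads$sequence)))
  first_hit <- function(hap) {
    subj <- Biostrings::DNAString(hap)
    hf <- Biostrings::matchPDict(dict_f, subj)
    hr <- Biostrings::matchPDict(dict_r, subj)
    sf <- Biostrings::startIndex(hf)
    sr <- Biostrings::startIndex(hr)
    pos <- rep(NA_integer_, nrow(reads))
    has_f <- lengths(sf) > 0
    pos[has_f] <- vapply(sf[has_f], `[`, integer(1), 1L)
    has_r <- is.na(pos) & lengths(sr) > 0
    pos[has_r] <- vapply(sr[has_r], `[`, integer(1), 1L)
    pos  # 1-based start or NA
  }
  p1 <- first_hit(hap1)
  p2 <- first_hit(hap2)
  only1 <- !is.na(p1) & is.na(p2)
  only2 <- !is.na(p2) & is.na(p1)
  mk <- function(sel, pos) {
    data.frame(read_id = reads$read_id[sel], mate = reads$mate[sel],
               start = pos[sel] - 1L, end = pos[sel] - 1L + w[sel],
               stringsAsFactors = FALSE)
  }
  list(hap1 = mk(only1, p1), hap2 = mk(only2, p2),
       n_dropped = sum(!only1 & !only2))
}

empty_hits <- function() {
  data.frame(read_id = character(0), mate = integer(0), start = integer(0),
             end = integer(0), stringsAsFactors = FALSE)
}

#' Per-base depth of aligned reads over a haplotype
#'
#' @param hits hit data frame (`start`, `end`, 0-based half-open), e.g.
#'   one element of [unique_zero_edit_filter()]'s result.
#' @param hap_length haplotype length in bp.
#' @return integer vector of per-base depth (length `hap_length`); its
#'   sum equals the total aligned bases.
#' @export
depth_profile <- function(hits, hap_length) {
  if (!nrow(hits)) return(integer(hap_length))
  cov <- IRanges::coverage(IRanges::IRanges(start = hits$start + 1L,
                                            end = hits$end),
                           width = hap_length)
  as.integer(cov)
}

#' Project haplotype depth onto reference coordinates
#'
#' Positions inside aligned chain blocks map one-to-one onto the
#' reference; depth over haplotype-only segments (insertions) is dropped,
#' and reference-only segments (deletions in the haplotype) are `NA`
#' (undefined; gap-filled downstream). Depth sums are conserved over
#' block interiors.
#'
#' @param depth per-base depth vector over the haplotype.
#' @param chain an [aln_chain()] mapping haplotype (query) to reference.
#' @param ref_len reference length; defaults to the chain's `ref_len`
#'   attribute.
#' @return numeric vector of length `ref_len` with `NA` at unmapped
#'   positions.
#' @export
project_depth <- function(depth, chain, ref_len = attr(chain, "ref_len")) {
  if (!nrow(chain)) stop("empty chain")
  if (is.na(ref_len)) ref_len <- max(chain$ref_end)
  out <- rep(NA_real_, ref_len)
  for (i in seq_len(nrow(chain))) {
    if (chain$ref_end[i] > chain$ref_start[i])
      out[(chain$ref_start[i] + 1):chain$ref_end[i]] <-
        depth[(chain$qry_start[i] + 1):chain$qry_end[i]]
  }
  out
}

#' Smoothed log2 depth-ratio profile and overall haplotype copy ratio
#'
#' At every variant position the haplotype depth ratio
#' `(d1 + eps) / (d2 + eps)` is log2-transformed; per-position values are
#' then smoothed over fixed windows (default 10 kb) in reference
#' coordinates. Windows without any variant position are gap-filled by
#' propagating the nearest computed window's value from the window
#' endpoints (carry-forward from the left, with the first computed window
#' propagated backwards at the profile start). The overall ratio is
#' `2^median` of the per-window log2 ratios.
#'
#' @param depth1_ref,depth2_ref per-base depth in reference coordinates
#'   (`NA` allowed at unmapped positions), equal length.
#' @param variant_positions 0-based reference positions of heterozygous
#'   variants between the haplotypes.
#' @param window window size in bp (default 10 kb).
#' @param eps pseudo-depth guarding division by zero (default 0.5).
#' @param average `"log"` (default): windows average the per-position
#'   log2 ratios; `"ratio"`: windows average the raw ratios and take log2
#'   of the mean.
#' @return a `copy_ratio_profile` list: `windows` data frame
#'   (`window_start`, `window_end`, `log2_ratio`, `n_positions`,
#'   `gap_filled`) and `overall_ratio`.
#' @export
log2_ratio_profile <- function(depth1_ref, depth2_ref, variant_positions,
                               window = 10000, eps = 0.5,
                               average = c("log", "ratio")) {
  average <- match.arg(average)
  stopifnot(length(depth1_ref) == length(depth2_ref))
  L <- length(depth1_ref)
  vp <- sort(unique(as.integer(variant_positions)))
  vp <- vp[vp >= 0 & vp < L]
  d1 <- depth1_ref[vp + 1]; d2 <- depth2_ref[vp + 1]
  ok <- !is.na(d1) & !is.na(d2)
  vp <- vp[ok]; d1 <- d1[ok]; d2 <- d2[ok]
  if (!length(vp)) stop("no usable variant positions")
  ratio <- (d1 + eps) / (d2 + eps)
  starts <- seq(0L, max(0L, L - 1L), by = window)
  win <- findInterval(vp, starts)
  val <- rep(NA_real_, length(starts))
  npos <- integer(length(starts))
  for (i in unique(win)) {
    r <- ratio[win == i]
    npos[i] <- length(r)
    val[i] <- if (average == "log") mean(log2(r)) else log2(mean(r))
  }
  filled <- is.na(val)
  if (any(filled)) {
    comp <- which(!filled)
    for (i in which(filled)) {
      left <- comp[comp < i]
      val[i] <- if (length(left)) val[max(left)] else val[min(comp)]
    }
  }
  windows <- data.frame(window_start = starts,
                        window_end = pmin(starts + window, L),
                        log2_ratio = val, n_positions = npos,
                        gap_filled = filled)
  structure(list(windows = windows,
                 overall_ratio = 2^median(val)),
            class = "copy_ratio_profile")
}

#' @export
print.copy_ratio_profile <- function(x, ...) {
  cat(sprintf(
    "copy_ratio_profile: %d windows (%d gap-filled), overall ratio %.3f\n",
    nrow(x$windows), sum(x$windows$gap_filled), x$overall_ratio))
  invisible(x)
}

#' Read-recruitment gain of a personal reference over the generic one
#'
#' @param reads_generic,reads_personal read counts recruited to the
#'   target region under the generic and personal references (both > 0).
#' @return percent gain, `100 * (personal - generic) / generic`.
#' @export
mhc_alignment_gain <- function(reads_generic, reads_personal) {
  if (reads_generic <= 0) stop("generic read count must be positive")
  100 * (reads_personal - reads_generic) / reads_generic
}

#' End-to-end aneuploidy profiling on simulated short reads
#'
#' Convenience wrapper chaining the aneuploidy stages: zero-edit unique
#' filtering of the short reads against the two haplotypes, per-base
#' depth, depth projection onto reference coordinates through the
#' haplotype chains, and the smoothed log2 ratio profile at heterozygous
#' variant positions.
#'
#' @param short_reads data frame from [simulate_short_read_wgs()].
#' @param hap1,hap2 haplotype sequences.
#' @param chains list of `hap1`/`hap2` chains (haplotype -> reference).
#' @param variant_positions 0-based reference positions of heterozygous
#'   variants.
#' @inheritParams log2_ratio_profile
#' @return a `copy_ratio_profile`.
#' @export
aneuploidy_profile <- function(short_reads, hap1, hap2, chains,
                               variant_positions, window = 10000,
                               eps = 0.5, average = c("log", "ratio")) {
  flt <- unique_zero_edit_filter(short_reads, hap1, hap2)
  d1 <- depth_profile(flt$hap1, nchar(hap1))
  d2 <- depth_profile(flt$hap2, nchar(hap2))
  d1r <- project_depth(d1, chains$hap1)
  d2r <- project_depth(d2, chains$hap2)
  log2_ratio_profile(d1r, d2r, variant_positions, window = window,
                     eps = eps, average = average)
}
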