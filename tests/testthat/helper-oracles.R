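# Shared fixtures and independent oracles used across test files.

# Small diploid simulation shared by several suites.
small_sim <- function(length = 100000, snv_rate = 0.001, indel_rate = 0,
                      sv_list = NULL, seed = 42) {
  anc <- simulate_ancestral(region_spec(length, seed = seed))
  hp <- derive_haplotypes(anc, snv_rate, indel_rate, sv_list, seed = seed)
  c(list(ancestral = anc), hp)
}

# Brute-force variant-representation oracle: every (pos, ref, alt) that
# turns `reference` into `mutated`, restricted to ref allele lengths up
# to max_len; the normalized representation is the minimal-total-length
# one at the smallest position.
enumerate_representations <- function(reference, mutated, max_len = 6) {
  L <- nchar(reference); M <- nchar(mutated)
  reps <- list()
  for (p in 0:(L - 1)) {
    for (lr in 1:min(max_len, L - p)) {
      la <- M - (L - lr)
      if (la < 1 || la > max_len) next
      a <- substr(mutated, p + 1, p + la)
      r <- substr(reference, p + 1, p + lr)
      cand <- paste0(substr(reference, 1, p), a,
                     substr(reference, p + lr + 1, L))
      if (cand == mutated && r != a)
        reps[[length(reps) + 1]] <- list(pos = p, ref = r, alt = a)
    }
  }
  reps
}

leftmost_minimal <- function(reps) {
  tot <- vapply(reps, function(x) nchar(x$ref) + nchar(x$alt), numeric(1))
  reps <- reps[tot == min(tot)]
  pos <- vapply(reps, `[[`, numeric(1), "pos")
  reps[[which.min(pos)]]
}

# O(n^2)-style interval-union oracle for covered reference bases.
covered_bases_oracle <- function(starts, ends) {
  covered <- logical(max(ends))
  for (i in seq_along(starts))
    covered[(starts[i] + 1):ends[i]] <- TRUE
  sum(covered)
}

# Brute-force NGA50: scan decreasing lengths until half-cover.
nga50_oracle <- function(lens, ref_len) {
  lens <- sort(lens, decreasing = TRUE)
  tot <- 0
  for (l in lens) {
    tot <- tot + l
    if (tot >= ref_len / 2) return(l)
  }
  0
}

# Exact k-mer set arithmetic on small sequences (canonical).
kmer_set <- function(seq, k) {
  n <- nchar(seq)
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  unique(pmin(kmers, rc))
}

# Deterministic error-free tiling reads (exact reconstruction cases).
tiling_reads <- function(hap, read_len = 10000, step = 2000,
                         label = "hap1") {
  L <- nchar(hap)
  starts <- seq(0, max(0, L - read_len), by = step)
  if (max(starts) + read_len < L) starts <- c(starts, L - read_len)
  data.frame(read_id = sprintf("%s_t%05d", label, seq_along(starts)),
             sequence = substring(hap, starts + 1, starts + read_len),
             truth_haplotype = label, start = as.integer(starts),
             end = as.integer(starts + read_len),
             error_rate_applied = 0, stringsAsFactors = FALSE)
}
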