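test_that("personal references embed haplotypes between exact flanks", {
  ref <- simulate_ancestral(region_spec(50000, seed = 61))
  iv <- c(10000L, 40000L)
  seg <- substr(ref, 10001, 40000)
  pr <- build_personal_reference(ref, iv, seg, seg)
  expect_identical(pr$hap1_ref, ref)  # hap == excised segment

  hp <- derive_haplotypes(ref, snv_rate = 0,
                          sv_list = sv_deletion(ref, 20000, 1469, "hap1"),
                          seed = 61)
  seg1 <- substr(hp$hap1, 10001, nchar(hp$hap1) - 10000)
  pr2 <- build_personal_reference(ref, iv, seg1, seg)
  expect_equal(nchar(pr2$hap1_ref), nchar(ref) - 1469)
  expect_identical(substr(pr2$hap1_ref, 1, 10000), substr(ref, 1, 10000))
  expect_identical(substr(pr2$hap1_ref, nchar(pr2$hap1_ref) - 9999,
                          nchar(pr2$hap1_ref)),
                   substr(ref, 40001, 50000))
  expect_error(build_personal_reference(ref, c(100L, 100L), seg, seg),
               "interval")
  expect_error(build_personal_reference(ref, c(-1L, 100L), seg, seg),
               "interval")
})

test_that("zero-edit unique filtering keeps only discriminating reads", {
  hap1 <- simulate_ancestral(region_spec(4000, seed = 62))
  hap2 <- hap1
  substr(hap2, 2000, 2000) <- setdiff(c("A", "C", "G", "T"),
                                      substr(hap1, 2000, 2000))[1]
  reads <- data.frame(
    read_id = c("u1", "shared", "u2", "mm", "rc1"),
    mate = 1L,
    sequence = c(substr(hap1, 1951, 2050),   # spans the het: hap1-only
                 substr(hap1, 100, 199),     # identical region: both
                 substr(hap2, 1951, 2050),   # hap2-only
                 paste0("A", substr(hap1, 1952, 2050)),  # mismatch to both
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(substr(hap1, 1951, 2050))))),
    stringsAsFactors = FALSE)
  # ensure the engineered mismatch read really mismatches
  if (substr(hap1, 1951, 1951) == "A")
    reads$sequence[4] <- paste0("C", substr(hap1, 1952, 2050))
  flt <- unique_zero_edit_filter(reads, hap1, hap2)
  expect_setequal(flt$hap1$read_id, c("u1", "rc1"))  # either strand
  expect_equal(flt$hap2$read_id, "u2")
  expect_equal(flt$n_dropped, 2L)
  expect_equal(flt$hap1$start[flt$hap1$read_id == "u1"], 1950L)
})

test_that("depth profiles conserve aligned bases and project correctly", {
  hits <- data.frame(read_id = c("a", "b"), mate = 1L,
                     start = c(0L, 50L), end = c(100L, 150L))
  d <- depth_profile(hits, 200L)
  expect_equal(sum(d), 200)
  expect_equal(d[60], 2L)
  expect_equal(d[160], 0L)

  # identity chain: projection is the identity
  idchain <- aln_chain(data.frame(ref_start = 0L, ref_end = 200L,
                                  qry_start = 0L, qry_end = 200L),
                       ref_len = 200L, qry_len = 200L)
  expect_equal(project_depth(as.numeric(d), idchain), as.numeric(d))

  # deletion chain: reference positions inside the deletion are NA and
  # block-interior sums are conserved
  sim <- small_sim(50000, snv_rate = 0.001, indel_rate = 2e-4, seed = 63,
                   sv_list = NULL)
  del <- sv_deletion(sim$ancestral, 20000, 1469, "hap1")
  hp <- derive_haplotypes(sim$ancestral, 0.001, 2e-4, del, seed = 63)
  dep <- rep(1, nchar(hp$hap1))
  proj <- project_depth(dep, hp$chain_hap1)
  ch <- hp$chain_hap1
  gap_i <- which(ch$ref_start[-1] - ch$ref_end[-nrow(ch)] == 1469)[1]
  expect_true(all(is.na(proj[(ch$ref_end[gap_i] + 1):
                               ch$ref_start[gap_i + 1]])))
  for (i in seq_len(nrow(ch))) {
    if (ch$ref_end[i] > ch$ref_start[i])
      expect_equal(sum(proj[(ch$ref_start[i] + 1):ch$ref_end[i]]),
                   sum(dep[(ch$qry_start[i] + 1):ch$qry_end[i]]))
  }
  expect_error(project_depth(dep, idchain[0, ]), "empty")
})

test_that("log2 ratio profiles recover flat and 3:1 depth tracks", {
  vp <- seq(100, 49900, by = 800)
  d <- rep(1000, 50000)
  p11 <- log2_ratio_profile(d, d, vp)
  expect_true(all(p11$windows$log2_ratio == 0))
  expect_equal(p11$overall_ratio, 1.0)

  p31 <- log2_ratio_profile(3 * d, d, vp)
  expect_lt(abs(p31$windows$log2_ratio[1] - log2(3)), 0.01)
  expect_lt(abs(p31$overall_ratio - 3.0), 0.01)
  expect_error(log2_ratio_profile(d, d, integer(0)), "variant positions")
})

test_that("gap-filled windows propagate neighbours and stay in range", {
  d1 <- rep(c(10, 40), each = 25000)
  d2 <- rep(10, 50000)
  vp <- c(2500, 42500)  # only windows 1 and 5 computed
  p <- log2_ratio_profile(d1, d2, vp, window = 10000)
  w <- p$windows
  expect_equal(sum(!w$gap_filled), 2)
  expect_equal(w$log2_ratio[2], w$log2_ratio[1])  # carry-forward left
  expect_equal(w$log2_ratio[4], w$log2_ratio[1])
  rng <- range(w$log2_ratio[!w$gap_filled])
  expect_true(all(w$log2_ratio >= rng[1] & w$log2_ratio <= rng[2]))
  # leading gap takes the first computed window
  p2 <- log2_ratio_profile(d1, d2, c(42500), window = 10000)
  expect_true(all(p2$windows$log2_ratio == p2$windows$log2_ratio[5]))
})

test_that("profiles are antisymmetric under haplotype swap", {
  sim <- small_sim(100000, seed = 64)
  sr <- simulate_short_read_wgs(sim$hap1, sim$hap2, c(2, 1),
                                depth_per_copy = 10, seed = 64)
  pv <- truth_phased_variants(sim$truth)
  chains <- list(hap1 = sim$chain_hap1, hap2 = sim$chain_hap2)
  p <- aneuploidy_profile(sr, sim$hap1, sim$hap2, chains, pv$pos)
  chains_sw <- list(hap1 = sim$chain_hap2, hap2 = sim$chain_hap1)
  p_sw <- aneuploidy_profile(sr, sim$hap2, sim$hap1, chains_sw, pv$pos)
  expect_equal(p_sw$windows$log2_ratio, -p$windows$log2_ratio,
               tolerance = 1e-12)
  expect_equal(p_sw$overall_ratio, 1 / p$overall_ratio,
               tolerance = 1e-12)
})

test_that("the full aneuploidy path recovers a simulated 2:1 state", {
  sim <- small_sim(300000, seed = 65)
  sr <- simulate_short_read_wgs(sim$hap1, sim$hap2, c(2, 1),
                                depth_per_copy = 20, seed = 65)
  pv <- truth_phased_variants(sim$truth)
  p <- aneuploidy_profile(sr, sim$hap1, sim$hap2,
                          list(hap1 = sim$chain_hap1,
                               hap2 = sim$chain_hap2), pv$pos)
  expect_lt(abs(p$overall_ratio - 2), 0.1)
})

test_that("alignment gain is plain percent arithmetic with a sign check", {
  expect_equal(mhc_alignment_gain(10000, 10000), 0)
  expect_equal(mhc_alignment_gain(10000, 10300), 3.0)
  expect_error(mhc_alignment_gain(0, 10), "positive")
  # divergent haplotypes recruit more reads under the personal reference
  sim <- small_sim(60000, snv_rate = 0.005, seed = 66)
  sr <- simulate_short_read_wgs(sim$hap1, sim$hap2, c(1, 1),
                                depth_per_copy = 5, seed = 66)
  dict_f <- Biostrings::PDict(Biostrings::DNAStringSet(sr$sequence))
  dict_r <- Biostrings::PDict(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sr$sequence)))
  hit_any <- function(target) {
    subj <- Biostrings::DNAString(target)
    lengths(Biostrings::startIndex(
      Biostrings::matchPDict(dict_f, subj))) > 0 |
      lengths(Biostrings::startIndex(
        Biostrings::matchPDict(dict_r, subj))) > 0
  }
  n_generic <- sum(hit_any(sim$ancestral))
  n_personal <- sum(hit_any(sim$hap1) | hit_any(sim$hap2))
  expect_gt(mhc_alignment_gain(n_generic, n_personal), 0)
})
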