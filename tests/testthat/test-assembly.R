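test_that("single reads and disconnected groups assemble trivially", {
  sim <- small_sim(60000, seed = 31)
  one <- data.frame(read_id = "r1",
                    sequence = substr(sim$hap1, 1, 20000))
  ctg <- greedy_olc_assemble(one, min_overlap = 2000)
  expect_equal(nrow(ctg), 1)
  expect_identical(ctg$sequence, one$sequence)
  expect_identical(ctg$member_reads[[1]], "r1")

  # two groups with no overlap >= min_overlap give two contigs
  two <- data.frame(read_id = c("a1", "a2", "b1", "b2"),
                    sequence = c(substr(sim$hap1, 1, 12000),
                                 substr(sim$hap1, 8001, 20000),
                                 substr(sim$hap1, 40001, 52000),
                                 substr(sim$hap1, 48001, 60000)))
  ctg2 <- greedy_olc_assemble(two, min_overlap = 2000)
  expect_equal(nrow(ctg2), 2)
  expect_setequal(vapply(ctg2$member_reads, length, integer(1)), c(2L, 2L))
  expect_error(greedy_olc_assemble(one, min_overlap = 100), "min_overlap")
})

test_that("error-free tiling reads reconstruct the haplotype exactly", {
  sim <- small_sim(200000, snv_rate = 0.001, seed = 32)
  reads <- tiling_reads(sim$hap1, read_len = 10000, step = 2000)
  ctg <- greedy_olc_assemble(reads, min_overlap = 2000)
  expect_equal(nrow(ctg), 1)
  expect_identical(ctg$sequence, sim$hap1)
  expect_setequal(ctg$member_reads[[1]], reads$read_id)

  # with uniform random reads, round-1 contigs are exact substrings
  rnd <- simulate_long_reads(sim$hap1, depth = 20, mean_len = 8000,
                             len_sd = 800, seed = 32)
  ctgr <- greedy_olc_assemble(rnd, min_overlap = 2000)
  big <- ctgr[ctgr$length >= 20000, ]
  expect_gt(nrow(big), 0)
  for (s in big$sequence)
    expect_true(grepl(s, sim$hap1, fixed = TRUE))
})

test_that("assembly is deterministic and reads join at most one contig", {
  sim <- small_sim(80000, seed = 33)
  reads <- simulate_long_reads(sim$hap2, depth = 15, mean_len = 6000,
                               len_sd = 600, error_rate = 0.002, seed = 33)
  c1 <- greedy_olc_assemble(reads, min_overlap = 2000)
  c2 <- greedy_olc_assemble(reads[sample.int(nrow(reads)), ],
                            min_overlap = 2000)
  expect_identical(c1$sequence, c2$sequence)  # input order irrelevant
  members <- unlist(c1$member_reads)
  expect_equal(anyDuplicated(members), 0)
})

test_that("contig filter keeps >= 50 kb and never grows the set", {
  mk <- function(lens) data.frame(
    contig_id = sprintf("c%d", seq_along(lens)),
    sequence = strrep("A", 1), length = lens, round = 1L)
  ctg <- mk(c(30000, 50000, 120000, 800000))
  kept <- filter_contigs(ctg)
  expect_equal(kept$length, c(50000, 120000, 800000))
  expect_equal(min(kept$length), 50000)  # threshold is "shorter than"
  expect_equal(nrow(filter_contigs(ctg[0, ])), 0)
  all_big <- mk(c(60000, 70000))
  expect_identical(filter_contigs(all_big)$length, all_big$length)
  expect_lte(nrow(kept), nrow(ctg))
  expect_lte(sum(kept$length), sum(ctg$length))
})

test_that("supplementary rescue recovers insertion reads and rejects decoys", {
  anc <- simulate_ancestral(region_spec(150000, seed = 34))
  ins <- sv_insertion(anc, 75000, 5000, "hap1", seed = 34)
  hp <- derive_haplotypes(anc, snv_rate = 0.001, sv_list = ins, seed = 34)
  reads <- simulate_long_reads(hp$hap1, depth = 30, mean_len = 1500,
                               len_sd = 150, seed = 34)
  aln <- alignments_from_truth(reads, list(hap1 = hp$chain_hap1,
                                           hap2 = hp$chain_hap2))
  recruited <- aln$read_id[aln$aligned]
  expect_gt(sum(!aln$aligned), 10)  # reads fully inside the insertion

  ctg1 <- greedy_olc_assemble(reads[reads$read_id %in% recruited, ],
                              min_overlap = 500)
  ctg1 <- filter_contigs(ctg1, 50000)
  rescued <- rescue_supplementary_reads(reads, ctg1, recruited)
  expect_gt(length(rescued), 0)
  expect_length(intersect(rescued, recruited), 0)
  # every rescued read really comes from the inserted segment
  qa <- chain_ref_to_qry(hp$chain_hap1, 75000L)  # hap pos of the anchor
  rr <- reads[reads$read_id %in% rescued, ]
  expect_true(all(rr$start > qa & rr$end <= qa + 1 + 5000))

  # decoy reads from an unrelated sequence fail the identity floor
  decoy_src <- simulate_ancestral(region_spec(30000, seed = 99))
  decoys <- simulate_long_reads(decoy_src, depth = 2, mean_len = 1500,
                                len_sd = 150, seed = 99,
                                hap_label = "decoy")
  all_reads <- rbind(reads, decoys)
  rescued2 <- rescue_supplementary_reads(all_reads, ctg1, recruited)
  expect_length(grep("^decoy", rescued2), 0)

  # everything recruited: nothing to rescue
  expect_length(
    rescue_supplementary_reads(reads, ctg1, reads$read_id), 0)
})

test_that("two-round haplotype assembly covers the truth haplotype", {
  sim <- small_sim(150000, snv_rate = 0.001, seed = 35)
  reads <- simulate_diploid_long_reads(sim$hap1, sim$hap2, depth = 30,
                                       seed = 35)
  aln <- alignments_from_truth(reads, list(hap1 = sim$chain_hap1,
                                           hap2 = sim$chain_hap2))
  pv <- truth_phased_variants(sim$truth)
  p <- partition_reads(aln, reads, pv)
  for (h in c("hap1", "hap2")) {
    a <- assemble_haplotype(p[[h]], p$untagged, reads, aln, h)
    truth_hap <- sim[[h]]
    cov <- sum(vapply(a$contigs$sequence, function(s) {
      ch <- anchor_align(s, truth_hap)
      sum(ch$ref_end - ch$ref_start)
    }, numeric(1))) / nchar(truth_hap)
    expect_gte(cov, 0.95)
    expect_equal(a$total_length, sum(a$contigs$length))
  }
  # nothing rescuable: the round-1 assembly is returned as final
  a1 <- assemble_haplotype(p$hap1, p$untagged, reads, aln, "hap1")
  expect_equal(a1$rounds, 1L)
  expect_equal(a1$n_rescued, 0L)
  expect_error(assemble_haplotype(character(0), character(0), reads, aln),
               "empty")
})
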