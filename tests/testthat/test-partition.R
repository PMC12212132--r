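make_partition_fixture <- function(length = 80000, seed = 21,
                                   error_rate = 0, depth = 10) {
  sim <- small_sim(length, seed = seed)
  reads <- simulate_diploid_long_reads(sim$hap1, sim$hap2, depth,
                                       mean_len = 5000, len_sd = 500,
                                       error_rate = error_rate, seed = seed)
  aln <- alignments_from_truth(reads, list(hap1 = sim$chain_hap1,
                                           hap2 = sim$chain_hap2))
  list(sim = sim, reads = reads, aln = aln,
       pv = truth_phased_variants(sim$truth))
}

test_that("error-free reads covering >= 2 sites are tagged 100% correctly", {
  fx <- make_partition_fixture()
  tags <- haplotag_reads(fx$aln, fx$reads, fx$pv)
  src <- fx$reads$truth_haplotype[match(tags$read_id, fx$reads$read_id)]
  informative <- tags$sites_covered >= 2
  expect_gt(sum(informative), 100)
  expect_true(all(tags$assignment[informative] == src[informative]))
  # votes are one-sided for error-free reads
  expect_true(all(tags$votes_hap1[informative] == 0 |
                    tags$votes_hap2[informative] == 0))
})

test_that("zero sites or tied votes leave a read untagged", {
  fx <- make_partition_fixture()
  empty <- phased_variants(integer(0), character(0), character(0),
                           character(0), character(0))
  tags0 <- haplotag_reads(fx$aln, fx$reads, empty)
  expect_true(all(tags0$assignment == "untagged"))

  # engineer a tie: flip one covered allele of a 2-site read to the other
  # haplotype's allele
  tags <- haplotag_reads(fx$aln, fx$reads, fx$pv)
  cand <- which(tags$sites_covered == 2 & tags$votes_hap1 == 2)[1]
  expect_false(is.na(cand))  # fixture always contains 2-site hap1 reads
  rid <- tags$read_id[cand]
  i <- match(rid, fx$reads$read_id)
  a <- fx$aln[match(rid, fx$aln$read_id), ]
  snv <- fx$pv[fx$pv$pos >= a$ref_start & fx$pv$pos < a$ref_end &
                 nchar(fx$pv$ref) == 1 & nchar(fx$pv$alt) == 1, ]
  qp <- chain_ref_to_qry(fx$sim$chain_hap1, snv$pos[1]) - a$hap_start
  other <- ifelse(snv$hap2_allele[1] == "alt", snv$alt[1], snv$ref[1])
  substr(fx$reads$sequence[i], qp + 1, qp + 1) <- other
  tags2 <- haplotag_reads(fx$aln, fx$reads, fx$pv)
  expect_equal(tags2$assignment[match(rid, tags2$read_id)], "untagged")
  expect_equal(tags2$votes_hap1[match(rid, tags2$read_id)],
               tags2$votes_hap2[match(rid, tags2$read_id)])
})

test_that("haplotag is symmetric under swapping the allele columns", {
  fx <- make_partition_fixture(seed = 22)
  tags <- haplotag_reads(fx$aln, fx$reads, fx$pv)
  swapped <- fx$pv
  swapped[c("hap1_allele", "hap2_allele")] <-
    swapped[c("hap2_allele", "hap1_allele")]
  tags_sw <- haplotag_reads(fx$aln, fx$reads, swapped)
  expect_identical(tags_sw$votes_hap1, tags$votes_hap2)
  expect_identical(tags_sw$votes_hap2, tags$votes_hap1)
  flip <- c(hap1 = "hap2", hap2 = "hap1", untagged = "untagged")
  expect_identical(tags_sw$assignment, unname(flip[tags$assignment]))
})

test_that("partitions are disjoint and cover all aligned reads", {
  fx <- make_partition_fixture(seed = 23, error_rate = 0.002)
  p <- partition_reads(fx$aln, fx$reads, fx$pv)
  sets <- list(p$hap1, p$hap2, p$untagged)
  expect_equal(sum(lengths(sets)), sum(fx$aln$aligned))
  expect_equal(length(unique(unlist(sets))), sum(lengths(sets)))
  # at 1 SNV/kb and 0.2% error, >= 99% of tagged assignments are correct
  tags <- p$tags[p$tags$assignment != "untagged", ]
  src <- fx$reads$truth_haplotype[match(tags$read_id, fx$reads$read_id)]
  expect_gte(mean(tags$assignment == src), 0.99)
})

test_that("downsampling keeps everything under the target and exactly 30x on a saturated tiling", {
  # 20x input < 30 target: output == input
  fx <- make_partition_fixture(seed = 24, depth = 10)  # 10x per hap, 20x total
  ivals <- fx$aln[fx$aln$aligned, ]
  kept <- downsample_longest_per_window(ivals, 10000, 30, 80000)
  expect_setequal(kept, ivals$read_id)

  # 100 identical 10 kb reads tiling one window: exactly 30 kept
  tile <- data.frame(read_id = sprintf("r%03d", 1:100),
                     ref_start = 0L, ref_end = 10000L)
  kept30 <- downsample_longest_per_window(tile, 10000, 30, 10000)
  expect_length(kept30, 30)
  expect_identical(sort(kept30), sprintf("r%03d", 1:30))  # id tie-break
})

test_that("downsampling is idempotent, greedy-by-length, and bounded", {
  set.seed(25)
  n <- 400
  starts <- sample(0:90000, n, replace = TRUE)
  lens <- sample(2000:12000, n, replace = TRUE)
  ivals <- data.frame(read_id = sprintf("r%04d", 1:n),
                      ref_start = starts,
                      ref_end = pmin(starts + lens, 100000L))
  kept <- downsample_longest_per_window(ivals, 10000, 5, 100000)
  sub <- ivals[ivals$read_id %in% kept, ]
  again <- downsample_longest_per_window(sub, 10000, 5, 100000)
  expect_setequal(again, kept)
  expect_true(all(kept %in% ivals$read_id))

  # brute-force per-window selection: a globally excluded read must rank
  # below every read the window's own length-ordered selection kept
  lens_by_id <- setNames(ivals$ref_end - ivals$ref_start, ivals$read_id)
  for (ws in seq(0, 90000, by = 10000)) {
    we <- ws + 10000
    in_win <- ivals[ivals$ref_start < we & ivals$ref_end > ws, ]
    in_win <- in_win[order(-(in_win$ref_end - in_win$ref_start),
                           in_win$read_id), ]
    ovl <- pmin(in_win$ref_end, we) - pmax(in_win$ref_start, ws)
    cut <- which(cumsum(ovl) >= 5 * 10000)
    own <- if (length(cut)) in_win$read_id[seq_len(cut[1])] else
      in_win$read_id
    excl <- setdiff(in_win$read_id, kept)
    expect_length(intersect(own, excl), 0)  # own selection always kept
    if (length(excl) && length(own))
      expect_lte(max(lens_by_id[excl]), min(lens_by_id[own]))
  }

  # saturated windows retain at least the target after downsampling
  cov_in <- function(ids, ws, we) {
    s <- ivals[ivals$read_id %in% ids & ivals$ref_start < we &
                 ivals$ref_end > ws, ]
    sum(pmin(s$ref_end, we) - pmax(s$ref_start, ws)) / (we - ws)
  }
  for (ws in seq(0, 90000, by = 10000)) {
    full <- cov_in(ivals$read_id, ws, ws + 10000)
    if (full > 5 + 12000 / 10000)
      expect_gte(cov_in(kept, ws, ws + 10000), 5)
  }

  # isolated saturated window: coverage in [target, target + max_len/win)
  set.seed(26)
  s1 <- sample(0:8000, 300, replace = TRUE)
  one <- data.frame(read_id = sprintf("w%03d", 1:300), ref_start = s1,
                    ref_end = pmin(s1 + sample(1000:4000, 300, TRUE),
                                   10000L))
  kept1 <- downsample_longest_per_window(one, 10000, 5, 10000)
  cov1 <- sum(one$ref_end[one$read_id %in% kept1] -
                one$ref_start[one$read_id %in% kept1]) / 10000
  expect_gte(cov1, 5)
  expect_lt(cov1, 5 + 4000 / 10000)
})
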