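#' Pipeline configuration
#'
#' Collects every stage parameter with defaults matching the workflow's
#' stated operating points: 10 kb downsampling windows at a 30x target,
#' 50 kb preliminary contig filter, 50 bp SV threshold, 0.001 k-mer
#' collision rate, 10 kb ratio-smoothing windows.
#'
#' @param region_length simulated region length (bp).
#' @param gc_content ancestral GC fraction.
#' @param snv_rate,indel_rate heterozygous variant rates per bp.
#' @param sv_spec list of planted SVs, each
#'   `list(type = "DEL"|"INS", pos =, size =, genotype =)`.
#' @param cn haplotype copy numbers `c(n1, n2)` for the short-read arm.
#' @param long_depth,long_mean_len,long_len_sd,long_error long-read
#'   simulation parameters.
#' @param short_depth_per_copy,short_read_len short-read parameters.
#' @param fn_rate,fp_rate noise rates of the two fabricated callsets.
#' @param haploid_threshold het/kb below which the region is processed
#'   haploid.
#' @param window_size,target_cov downsampling window and coverage target.
#' @param min_contig_len preliminary contig filter (bp).
#' @param min_overlap assembler minimum overlap (bp).
#' @param anchor_k variant-caller anchor k-mer size.
#' @param min_region minimum chain span emitting variant calls (bp).
#' @param sv_threshold SV size threshold (bp).
#' @param collision_rate optimal-k collision rate.
#' @param ratio_window aneuploidy smoothing window (bp).
#' @param eps ratio pseudo-depth.
#' @param seed master seed; every stage derives its own stream from it.
#' @param stages character vector of stages to run, in pipeline order.
#' @return a `run_config` list.
#' @export
run_config <- function(region_length = 200000, gc_content = 0.41,
                       snv_rate = 0.001, indel_rate = 0, sv_spec = list(),
                       cn = c(1L, 1L), long_depth = 30,
                       long_mean_len = 10000, long_len_sd = 1000,
                       long_error = 0, short_depth_per_copy = 20,
                       short_read_len = 150, fn_rate = 0.02,
                       fp_rate = 1e-6, haploid_threshold = 0.05,
                       window_size = 10000, target_cov = 30,
                       min_contig_len = 50000, min_overlap = 2000,
                       anchor_k = 31, min_region = 10000,
                       sv_threshold = 50, collision_rate = 0.001,
                       ratio_window = 10000, eps = 0.5, seed = 1L,
                       stages = c("simulate", "phase", "partition",
                                  "assemble", "evaluate", "callvars",
                                  "aneuploidy")) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in order on a fully simulated dataset and
#' returns a manifest with every parameter, per-stage counts, and the
#' metric tables. Identical config and seed give an identical manifest.
#' If `out_dir` is given, haplotypes/contigs (FASTA), reads (FASTQ),
#' consensus variants (VCF) and the manifest (JSON) are written there.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return the manifest (a nested list).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  st <- config$stages
  manifest <- list(params = unclass(config), stages = list())
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # --- simulate -------------------------------------------------------
  sim <- NULL
  if ("simulate" %in% st) sim <- run_stage("simulate", function() {
    spec <- region_spec(config$region_length, config$gc_content,
                        config$seed)
    anc <- simulate_ancestral(spec)
    svs <- do.call(rbind, lapply(config$sv_spec, function(s) {
      if (s$type == "DEL") sv_deletion(anc, s$pos, s$size, s$genotype)
      else sv_insertion(anc, s$pos, s$size, s$genotype, seed = config$seed)
    }))
    hp <- derive_haplotypes(anc, config$snv_rate, config$indel_rate,
                            svs, seed = config$seed)
    lr <- simulate_diploid_long_reads(hp$hap1, hp$hap2, config$long_depth,
                                      config$long_mean_len,
                                      config$long_len_sd,
                                      config$long_error, config$seed)
    sr <- simulate_short_read_wgs(hp$hap1, hp$hap2, config$cn,
                                  config$short_depth_per_copy,
                                  config$short_read_len,
                                  seed = config$seed)
    manifest$stages$simulate <<- list(
      region_length = nchar(anc), n_truth_variants = nrow(hp$truth),
      n_long_reads = nrow(lr), n_short_reads = nrow(sr))
    list(ancestral = anc, hp = hp, long_reads = lr, short_reads = sr)
  })

  # --- phase ----------------------------------------------------------
  phase <- NULL
  if ("phase" %in% st && !is.null(sim)) phase <- run_stage("phase", function() {
    truth_pv <- truth_phased_variants(sim$hp$truth)
    a <- perturb_callset(truth_pv, sim$ancestral, config$fn_rate,
                         config$fp_rate, config$seed, "a")
    b <- perturb_callset(truth_pv, sim$ancestral, config$fn_rate,
                         config$fp_rate, config$seed, "b")
    consensus <- intersect_callsets(a, b, sim$ancestral)
    ploidy <- classify_ploidy(consensus, config$region_length,
                              config$haploid_threshold)
    manifest$stages$phase <<- list(n_callset_a = nrow(a),
                                   n_callset_b = nrow(b),
                                   n_consensus = nrow(consensus),
                                   ploidy = ploidy)
    list(consensus = consensus, ploidy = ploidy)
  })

  # --- partition ------------------------------------------------------
  part <- NULL
  if ("partition" %in% st && !is.null(phase))
    part <- run_stage("partition", function() {
      chains <- list(hap1 = sim$hp$chain_hap1, hap2 = sim$hp$chain_hap2)
      aln <- alignments_from_truth(sim$long_reads, chains)
      p <- partition_reads(aln, sim$long_reads, phase$consensus)
      manifest$stages$partition <<- list(
        n_hap1 = length(p$hap1), n_hap2 = length(p$hap2),
        n_untagged = length(p$untagged), n_unaligned = length(p$unaligned))
      list(alignments = aln, parts = p)
    })

  # --- assemble -------------------------------------------------------
  asms <- NULL
  if ("assemble" %in% st && !is.null(part))
    asms <- run_stage("assemble", function() {
      mk <- function(ids, label)
        assemble_haplotype(ids, part$parts$untagged, sim$long_reads,
                           part$alignments, label, config$target_cov,
                           config$window_size, config$min_contig_len,
                           config$min_overlap)
      out <- if (phase$ploidy$mode == "haploid") {
        all_ids <- part$alignments$read_id[part$alignments$aligned]
        list(hap1 = assemble_haplotype(all_ids, character(0),
                                       sim$long_reads, part$alignments,
                                       "haploid", config$target_cov,
                                       config$window_size,
                                       config$min_contig_len,
                                       config$min_overlap))
      } else {
        list(hap1 = mk(part$parts$hap1, "hap1"),
             hap2 = mk(part$parts$hap2, "hap2"))
      }
      manifest$stages$assemble <<- lapply(out, function(a)
        list(contigs = nrow(a$contigs), total_length = a$total_length,
             n_rescued = a$n_rescued, rounds = a$rounds))
      out
    })

  # --- evaluate -------------------------------------------------------
  chains_by_hap <- NULL
  if ("evaluate" %in% st && !is.null(asms))
    run_stage("evaluate", function() {
      ok <- optimal_k(config$region_length, config$collision_rate)
      chains_by_hap <<- lapply(asms, function(a)
        lapply(a$contigs$sequence, function(s)
          tryCatch(anchor_align(s, sim$ancestral, config$anchor_k),
                   error = function(e) NULL)))
      blocks <- lapply(chains_by_hap, function(chl) {
        bl <- lapply(chl[!vapply(chl, is.null, logical(1))],
                     chain_to_blocks)
        if (length(bl)) do.call(rbind, bl) else
          data.frame(ref_start = integer(0), ref_end = integer(0),
                     qry_start = integer(0), qry_end = integer(0),
                     length = integer(0), identity = numeric(0))
      })
      ks <- lapply(asms, function(a)
        kmer_stats(sim$long_reads$sequence, a$contigs$sequence,
                   ok$counting_k))
      report <- assembly_report(asms, blocks, config$region_length)
      report$kmer_completeness <- vapply(ks, kmer_completeness, numeric(1))
      report$qv <- vapply(ks, consensus_qv, numeric(1))
      manifest$stages$evaluate <<- list(optimal_k = ok$k,
                                        counting_k = ok$counting_k,
                                        report = report)
      NULL
    })

  # --- callvars -------------------------------------------------------
  calls <- NULL
  if ("callvars" %in% st && !is.null(asms))
    calls <- run_stage("callvars", function() {
      out <- lapply(names(asms), function(h) {
        a <- asms[[h]]
        do.call(rbind, lapply(a$contigs$sequence, function(s) {
          ch <- tryCatch(anchor_align(s, sim$ancestral, config$anchor_k),
                         error = function(e) NULL)
          if (is.null(ch)) return(empty_calls())
          call_variants(ch, s, sim$ancestral, config$min_region,
                        config$sv_threshold, haplotype = h)
        }))
      })
      out <- do.call(rbind, out)
      manifest$stages$callvars <<- list(
        n_calls = nrow(out), by_class = as.list(table(out$vclass)),
        summary = variant_summary(out, region_length =
                                    config$region_length))
      out
    })

  # --- aneuploidy -----------------------------------------------------
  if ("aneuploidy" %in% st && !is.null(phase)) {
    if (phase$ploidy$mode == "haploid") {
      manifest$stages$aneuploidy <- list(
        skipped = TRUE,
        notice = "region classified haploid; no haplotype depth ratio")
    } else {
      run_stage("aneuploidy", function() {
        prof <- aneuploidy_profile(
          sim$short_reads, sim$hp$hap1, sim$hp$hap2,
          list(hap1 = sim$hp$chain_hap1, hap2 = sim$hp$chain_hap2),
          phase$consensus$pos, window = config$ratio_window,
          eps = config$eps)
        manifest$stages$aneuploidy <<- list(
          skipped = FALSE, overall_ratio = prof$overall_ratio,
          n_windows = nrow(prof$windows),
          n_gap_filled = sum(prof$windows$gap_filled))
        NULL
      })
    }
  }

  if (!is.null(out_dir)) {
    if (!is.null(sim)) {
      write_fasta(c(ancestral = sim$ancestral, hap1 = sim$hp$hap1,
                    hap2 = sim$hp$hap2),
                  file.path(out_dir, "haplotypes.fasta"))
      write_fastq(sim$long_reads, file.path(out_dir, "long_reads.fastq"))
      write_truth_tsv(sim$long_reads,
                      file.path(out_dir, "long_reads_truth.tsv"))
    }
    if (!is.null(phase) && nrow(phase$consensus))
      write_phased_vcf(phase$consensus,
                       file.path(out_dir, "consensus.vcf.gz"),
                       contig_length = config$region_length)
    if (!is.null(asms))
      for (h in names(asms))
        write_fasta(setNames(asms[[h]]$contigs$sequence,
                             asms[[h]]$contigs$contig_id),
                    file.path(out_dir, sprintf("assembly_%s.fasta", h)))
    if (!is.null(calls))
      write.table(calls, file.path(out_dir, "called_variants.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  manifest
}
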