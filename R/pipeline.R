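## End-to-end pipeline: simulate -> fish -> structure -> map ->
## introns/editing/operons (-> divergence), with a checksum manifest so a
## run is reproducible bit-for-bit from its config and seed.

default_config <- function() {
  list(
    seed = 1L,
    outdir = "chloroplastr_run",
    scale = 1 / 10,
    simulate = list(
      enabled = TRUE,
      n_genomic_reads = 300L, genomic_mean_len = 1500L,
      genomic_error = 0.12,
      isoseq_depth = 50L, isoseq_error = 0.01, retain_prob = 0.5,
      decoy_fraction = 0.5, decoy_len = 30000L
    ),
    fish = list(enabled = TRUE, k = 15L, min_frac = 0.02, min_hits = 25L),
    structure = list(enabled = TRUE, min_ir = 1000L),
    map = list(enabled = TRUE, k = 13L, min_intron = 50L, max_intron = 5000L),
    features = list(
      enabled = TRUE,
      intron_min_support = 3L,
      editing_min_cov = 10L, editing_min_eff = 0.10, editing_err = 0.02,
      editing_alpha = 0.05,
      operon_min_genes = 2L, operon_min_support = 3L, operon_cds_cov = 0.5
    ),
    divergence = list(enabled = FALSE, msa_dir = NULL, deletion = "pairwise")
  )
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (!k %in% names(base)) {
      stop("unknown configuration key: ", k)
    }
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Validate and complete a pipeline configuration
#'
#' @param config a (possibly partial) nested list, or path to a YAML file.
#'   Unknown keys are errors, not warnings.
#' @return the completed configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  merge_config(default_config(), config)
}

#' Run the full synthetic analysis pipeline
#'
#' Stages: simulate (genome + reads + transcripts), fish (k-mer read
#' classification against the simulated plastome), structure (quadripartite
#' partition + summary), map (spliced transcript alignment, SAM), features
#' (introns, editing, operons), and optionally divergence over a directory
#' of aligned marker FASTAs. Every output is listed in a checksum manifest;
#' identical config + seed give identical checksums.
#'
#' @param config see [pipeline_config()].
#' @return invisible list with the in-memory results, file paths, and the
#'   manifest data.frame.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  res <- list(config = cfg)
  path_of <- function(f) file.path(cfg$outdir, f)
  emit <- function(f) { paths <<- c(paths, path_of(f)); path_of(f) }
  seed_note <- sprintf("seed=%d", cfg$seed)

  if (cfg$simulate$enabled) {
    spec <- plastome_spec(scale = cfg$scale, seed = cfg$seed)
    sim <- generate_genome(spec)
    res$sim <- sim
    write_genome_fasta(sim$genome, emit("genome.fasta"))
    write_gff3(sim$annotation, emit("annotation.gff3"), seqid = sim$genome$id)
    write_genbank(sim$genome, sim$annotation, emit("genome.gb"))
    write_tsv(sim$truth$editing, emit("truth_editing.tsv"))
    write_tsv(sim$truth$introns, emit("truth_introns.tsv"))
    write_tsv(sim$truth$units, emit("truth_units.tsv"))
    greads <- simulate_genomic_reads(
      sim$genome, n = cfg$simulate$n_genomic_reads,
      mean_len = cfg$simulate$genomic_mean_len,
      error_rate = cfg$simulate$genomic_error,
      seed = child_seed(cfg$seed, 1L)
    )
    if (cfg$simulate$decoy_fraction > 0) {
      decoy <- simulate_decoy_genome(cfg$simulate$decoy_len,
                                     seed = child_seed(cfg$seed, 2L))
      greads <- mix_decoy_reads(greads, decoy, cfg$simulate$decoy_fraction,
                                error_rate = cfg$simulate$genomic_error,
                                seed = child_seed(cfg$seed, 3L))
    }
    res$genomic_reads <- greads
    write_fastq(greads, emit("genomic_reads.fastq"), comment = seed_note)
    write_truth_sam(greads[greads$origin == sim$genome$id, , drop = FALSE],
                    sim$genome, emit("genomic_reads_truth.sam"))
    iso <- simulate_isoseq(sim$genome, sim$truth,
                           depth = cfg$simulate$isoseq_depth,
                           error_rate = cfg$simulate$isoseq_error,
                           retain_prob = cfg$simulate$retain_prob,
                           seed = child_seed(cfg$seed, 4L))
    res$isoseq <- iso
    write_fastq(iso, emit("isoseq.fastq"), comment = seed_note)
  } else {
    stop("run_pipeline currently requires the simulate stage (synthetic inputs)")
  }

  if (cfg$fish$enabled) {
    idx <- build_kmer_index(res$sim$genome, k = cfg$fish$k)
    fished <- filter_pool(res$genomic_reads, idx,
                          min_frac = cfg$fish$min_frac,
                          min_hits = cfg$fish$min_hits)
    res$fish <- fished
    write_tsv(fished$report, emit("fish_report.tsv"))
    write_fastq(fished$accepted, emit("selected_reads.fastq"),
                comment = seed_note)
  }

  if (cfg$structure$enabled) {
    part <- partition_quadripartite(res$sim$genome,
                                    min_ir = cfg$structure$min_ir)
    res$partition <- part
    write_partition_bed(part, emit("partition.bed"))
    summ <- genome_summary(res$sim$genome, part,
                           reads = res$fish$accepted %||% res$genomic_reads,
                           annotation = res$sim$annotation)
    res$summary <- summ
    write_tsv(as.data.frame(summ), emit("genome_summary.tsv"))
  }

  if (cfg$map$enabled) {
    tgt <- spliced_target(res$sim$genome, k = cfg$map$k)
    alns <- spliced_map_pool(res$isoseq, tgt,
                             min_intron = cfg$map$min_intron,
                             max_intron = cfg$map$max_intron)
    res$alignments <- alns
    write_sam(alns, res$sim$genome, emit("isoseq.sam"))
  }

  if (cfg$features$enabled) {
    fz <- cfg$features
    introns <- call_introns(res$alignments, res$sim$annotation,
                            min_support = fz$intron_min_support,
                            min_len = cfg$map$min_intron,
                            max_len = cfg$map$max_intron,
                            genome = res$sim$genome)
    res$introns <- introns
    write_tsv(introns, emit("introns.tsv"))
    editing <- call_editing(res$alignments, res$sim$genome,
                            res$sim$annotation,
                            min_cov = fz$editing_min_cov,
                            min_eff = fz$editing_min_eff,
                            err = fz$editing_err, alpha = fz$editing_alpha,
                            introns = introns)
    res$editing <- editing
    write_tsv(editing, emit("editing.tsv"))
    operons <- call_operons(res$alignments, res$sim$annotation,
                            min_genes = fz$operon_min_genes,
                            min_support = fz$operon_min_support,
                            cds_cov = fz$operon_cds_cov)
    res$operons <- operons
    write_tsv(operons, emit("operons.tsv"))
  }

  if (cfg$divergence$enabled && !is.null(cfg$divergence$msa_dir)) {
    files <- list.files(cfg$divergence$msa_dir, pattern = "\\.fa(sta)?$",
                        full.names = TRUE)
    recs <- do.call(rbind, lapply(files, function(f) {
      divergence_record(read_marker_alignment(f),
                        deletion = cfg$divergence$deletion)
    }))
    res$divergence <- rank_markers(recs)
    write_tsv(res$divergence, emit("divergence.tsv"))
  }

  manifest <- data.frame(
    file = basename(paths),
    bytes = file.size(paths),
    md5 = unname(tools::md5sum(paths)),
    stringsAsFactors = FALSE
  )
  res$manifest <- manifest
  write_tsv(manifest, path_of("manifest.tsv"))
  log <- c(sprintf("chloroplastr %s",
                   as.character(utils::packageVersion("chloroplastr"))),
           seed_note,
           sprintf("config_md5=%s",
                   digest_config(cfg)),
           sprintf("artifacts=%d", nrow(manifest)))
  writeLines(log, path_of("run_log.txt"))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

digest_config <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  yaml::write_yaml(cfg, tf)
  unname(tools::md5sum(tf))
}
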