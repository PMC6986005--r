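test_that("generated genome has the planned quadripartite layout", {
  sim <- sim_default()
  spec <- sim$truth$spec
  g <- sim$genome
  expect_s3_class(g, "plastome")
  expect_equal(nchar(g$seq),
               spec$lsc_len + spec$ssc_len + 2L * spec$ir_len)
  p <- sim$truth$partition
  ## reconstruction: concatenating LSC+IRa+SSC+IRb reproduces the sequence
  pieces <- vapply(p, function(iv) substr(g$seq, iv[1L] + 1L, iv[2L]),
                   character(1))
  expect_identical(paste(pieces, collapse = ""), g$seq)
  ## the IRb interval is the exact reverse complement of IRa
  expect_identical(revcomp(pieces[["ira"]]), pieces[["irb"]])
})

test_that("per-region GC of the generated genome is close to target", {
  sim <- sim_default()
  spec <- sim$truth$spec
  p <- sim$truth$partition
  for (r in c("lsc", "ssc")) {
    iv <- p[[r]]
    gc <- 100 * chloroplastr:::gc_fraction(substr(sim$genome$seq, iv[1] + 1, iv[2]))
    expect_lt(abs(gc - 100 * spec$gc_by_region[[r]]), 1.5)
  }
  iv <- p$ira
  gc <- 100 * chloroplastr:::gc_fraction(substr(sim$genome$seq, iv[1] + 1, iv[2]))
  expect_lt(abs(gc - 100 * spec$gc_by_region[["ir"]]), 1.5)
})

test_that("genes do not overlap and introns sit inside their host genes", {
  sim <- sim_default()
  sp <- gene_spans(sim$annotation)
  sp <- sp[order(sp$start), ]
  expect_true(all(diff(sp$start) > 0))
  expect_true(all(sp$end[-nrow(sp)] <= sp$start[-1L]))
  tr <- sim$truth$introns
  expect_equal(nrow(tr), 9L)
  expect_equal(length(unique(tr$gene)), 7L)
  for (i in seq_len(nrow(tr))) {
    host <- sp[sp$gene == tr$gene[i], ]
    expect_true(host$start <= tr$donor[i] && tr$acceptor[i] <= host$end)
  }
})

test_that("planted introns carry group-II boundary motifs", {
  sim <- sim_default()
  chars <- strsplit(sim$genome$seq, "")[[1]]
  tr <- sim$truth$introns
  for (i in seq_len(nrow(tr))) {
    expect_equal(
      chloroplastr:::intron_motif_score(chars, tr$donor[i], tr$acceptor[i],
                                        tr$strand[i]),
      2L
    )
  }
})

test_that("every planted editing site is a C on its annotated strand", {
  for (seed in c(7L, 19L)) {
    sim <- if (seed == 7L) sim_default() else
      generate_genome(plastome_spec(scale = 1 / 10, seed = seed))
    ed <- sim$truth$editing
    base <- substring(sim$genome$seq, ed$pos + 1L, ed$pos + 1L)
    onstrand <- ifelse(ed$strand == "+", base, complement(base))
    expect_true(all(onstrand == "C"))
    expect_true(all(ed$efficiency > 0 & ed$efficiency <= 1))
  }
})

test_that("intron-free plan yields no planted introns", {
  plan <- light_plan()
  plan$n_introns <- 0L
  sim <- generate_genome(plastome_spec(
    scale = 1 / 20, seed = 3L, gene_plan = plan,
    editing_n = c(cds = 0L, intron = 0L, intergenic = 0L)
  ))
  expect_equal(nrow(sim$truth$introns), 0L)
  expect_equal(nrow(sim$truth$editing), 0L)
})

test_that("an infeasible gene plan raises a sizing error naming the region", {
  plan <- light_plan()
  plan$len <- c(6000L, 6000L, 150L)  # LSC at 1/20 scale is 4,560 bp
  expect_error(
    generate_genome(plastome_spec(
      scale = 1 / 20, seed = 1L, gene_plan = plan,
      editing_n = c(cds = 0L, intron = 0L, intergenic = 0L))),
    "lsc"
  )
})

test_that("spec invariants are validated", {
  expect_error(plastome_spec(scale = 1 / 10, ir_len = 500), "ir_len")
  expect_error(plastome_spec(scale = 1 / 10, editing_eff = c(0.5, 1.2)))
  plan <- light_plan(); plan$len[1] <- 100L  # CDS not a codon multiple
  expect_error(plastome_spec(scale = 1 / 10, gene_plan = plan), "multiple")
})

test_that("error-free genomic reads are exact substrings of the doubled genome", {
  sim <- sim_default()
  reads <- simulate_genomic_reads(sim$genome, n = 40L, mean_len = 800L,
                                  error_rate = 0, seed = 5L)
  doubled <- paste0(sim$genome$seq, sim$genome$seq)
  fwd <- ifelse(reads$strand == "-", revcomp(reads$seq), reads$seq)
  expect_true(all(vapply(fwd, function(s) grepl(s, doubled, fixed = TRUE),
                         logical(1))))
  ## and the recorded truth interval reproduces each read
  for (i in seq_len(nrow(reads))) {
    expect_identical(substr(doubled, reads$true_start[i] + 1L,
                            reads$true_end[i]), fwd[i])
  }
})

test_that("read lengths track the requested mean and wrap the origin", {
  sim <- sim_default()
  reads <- simulate_genomic_reads(sim$genome, n = 1000L, mean_len = 1000L,
                                  error_rate = 0, seed = 8L)
  m <- sum(reads$true_end - reads$true_start) / nrow(reads)
  expect_gte(m, 950); expect_lte(m, 1050)
  glen <- nchar(sim$genome$seq)
  expect_gt(sum(reads$true_end > glen), 0L)  # origin-spanning reads exist
  expect_equal(nrow(simulate_genomic_reads(sim$genome, n = 0L)), 0L)
})

test_that("indel-dominated errors change read lengths more than content", {
  sim <- sim_default()
  reads <- simulate_genomic_reads(sim$genome, n = 200L, mean_len = 1000L,
                                  error_rate = 0.12, seed = 9L)
  true_len <- reads$true_end - reads$true_start
  ## insertions and deletions at 2/5 weight each cancel in expectation but
  ## individually perturb lengths; substitutions alone would keep them equal
  expect_gt(sd(nchar(reads$seq) - true_len), 0)
  expect_lt(abs(mean(nchar(reads$seq) - true_len)), 0.05 * 1000)
})

test_that("full-efficiency editing sites are edited on every clean transcript", {
  plan <- light_plan()
  sim <- generate_genome(plastome_spec(
    scale = 1 / 20, seed = 11L, gene_plan = plan,
    editing_n = c(cds = 2L, intron = 0L, intergenic = 0L),
    editing_eff = c(1.0, 1.0)
  ))
  iso <- simulate_isoseq(sim$genome, sim$truth, depth = 15L, error_rate = 0,
                         seed = 12L)
  ed <- sim$truth$editing
  for (i in seq_len(nrow(ed))) {
    u <- sim$truth$genes$unit[sim$truth$genes$gene == ed$gene[i]][1L]
    reads <- iso[iso$unit == u, ]
    fwd <- ifelse(reads$strand == "-", revcomp(reads$seq), reads$seq)
    off <- ed$pos[i] - reads$span_start
    b <- substring(fwd, off + 1L, off + 1L)
    want <- if (ed$strand[i] == "+") "T" else "A"
    expect_true(all(b == want))
  }
})

test_that("each transcription unit yields depth transcripts spanning its genes", {
  sim <- sim_default()
  iso <- simulate_isoseq(sim$genome, sim$truth, depth = 4L, error_rate = 0,
                         seed = 13L)
  units <- sim$truth$units
  for (i in seq_len(nrow(units))) {
    u <- iso[iso$unit == units$unit[i], ]
    expect_equal(nrow(u), 4L)
    expect_true(all(u$span_start <= units$start[i]))
    expect_true(all(u$span_end >= units$end[i]))
  }
})

test_that("decoy mixing preserves pool size and labels true origins", {
  sim <- sim_default()
  reads <- simulate_genomic_reads(sim$genome, n = 400L, mean_len = 600L,
                                  error_rate = 0, seed = 21L)
  decoy <- simulate_decoy_genome(20000L, seed = 22L)
  expect_identical(mix_decoy_reads(reads, decoy, 0, seed = 23L), reads)
  all_decoy <- mix_decoy_reads(reads, decoy, 1, error_rate = 0, seed = 23L)
  expect_equal(nrow(all_decoy), nrow(reads))
  expect_true(all(all_decoy$origin == "decoy"))
  half <- mix_decoy_reads(reads, decoy, 0.5, error_rate = 0, seed = 24L)
  expect_identical(half$id, reads$id)  # order preserved
  n_decoy <- sum(half$origin == "decoy")
  expect_gte(n_decoy, 400 * 0.5 - 0.13 * 400)  # binomial 99% band
  expect_lte(n_decoy, 400 * 0.5 + 0.13 * 400)
})

test_that("strand closure: reverse-complementing the genome mirrors the truth", {
  sim <- sim_light(31L)
  g2 <- plastome(revcomp(sim$genome$seq), id = "rc")
  n <- nchar(g2$seq)
  sp <- gene_spans(sim$annotation)
  for (i in seq_len(nrow(sp))) {
    s2 <- n - sp$end[i]; e2 <- n - sp$start[i]
    seq1 <- substr(sim$genome$seq, sp$start[i] + 1L, sp$end[i])
    seq2 <- substr(g2$seq, s2 + 1L, e2)
    expect_identical(revcomp(seq1), seq2)
  }
})
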