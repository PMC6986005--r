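test_that("nine planted introns in seven genes are called with exact boundaries", {
  pool <- aligned_pool_clean()
  calls <- call_introns(pool$alns, pool$sim$annotation,
                        genome = pool$sim$genome)
  truth <- pool$sim$truth$introns
  expect_equal(nrow(calls), 9L)
  expect_equal(length(unique(calls$gene)), 7L)
  counts <- sort(as.integer(table(calls$gene)), decreasing = TRUE)
  expect_equal(counts, c(2L, 2L, 1L, 1L, 1L, 1L, 1L))
  m <- merge(calls, truth, by = c("donor", "acceptor"))
  expect_equal(nrow(m), 9L)            # base-exact boundaries
  expect_true(all(m$gene.x == m$gene.y))
  expect_true(all(calls$motif_match))
  expect_true(all(calls$length == calls$acceptor - calls$donor))
})

test_that("intron-free data yields no intron calls and low support is suppressed", {
  plan <- light_plan(); plan$n_introns <- 0L
  sim <- generate_genome(plastome_spec(
    scale = 1 / 20, seed = 41L, gene_plan = plan,
    editing_n = c(cds = 0L, intron = 0L, intergenic = 0L)))
  iso <- simulate_isoseq(sim$genome, sim$truth, depth = 5L, error_rate = 0,
                         seed = 42L)
  alns <- spliced_map_pool(iso, spliced_target(sim$genome))
  expect_equal(nrow(call_introns(alns, sim$annotation)), 0L)
  ## support below min_support: depth 2 with full splicing
  sim2 <- sim_light(43L)
  iso2 <- simulate_isoseq(sim2$genome, sim2$truth, depth = 2L,
                          error_rate = 0, retain_prob = 0, seed = 44L)
  alns2 <- spliced_map_pool(iso2, spliced_target(sim2$genome))
  expect_equal(nrow(call_introns(alns2, sim2$annotation, min_support = 3L)),
               0L)
  expect_gte(nrow(call_introns(alns2, sim2$annotation, min_support = 2L)), 1L)
})

test_that("cross-species intron tables report lengths and absences", {
  simA <- sim_light(45L)
  planB <- light_plan(); planB$n_introns <- 0L
  simB <- generate_genome(plastome_spec(
    scale = 1 / 20, seed = 46L, gene_plan = planB,
    editing_n = c(cds = 0L, intron = 0L, intergenic = 0L)))
  tab <- compare_intron_lengths(list(spA = simA$annotation,
                                     spB = simB$annotation))
  ## geneA is the only multi-exon gene anywhere
  expect_setequal(unique(tab$gene), "geneA")
  a <- tab[tab$species == "spA", ]
  expect_equal(a$status, "present")
  tr <- simA$truth$introns
  expect_equal(a$intron_len, tr$acceptor - tr$donor)
  b <- tab[tab$species == "spB", ]
  expect_equal(b$status, "absent")
  expect_true(is.na(b$intron_len))
  ## intron length equals the inter-exon gap of the parsed annotation
  ex <- simA$annotation[simA$annotation$gene == "geneA", ]
  ex <- ex[order(ex$exon), ]
  gap <- if (ex$strand[1] == "+") ex$start[2] - ex$end[1] else
    ex$start[1] - ex$end[2]
  expect_equal(a$intron_len, gap)
})

test_that("intron lengths survive a GenBank round trip", {
  sim <- sim_light(47L)
  tf <- withr::local_tempfile(fileext = ".gb")
  write_genbank(sim$genome, sim$annotation, tf)
  gb <- parse_genbank(tf)
  t1 <- compare_intron_lengths(list(x = sim$annotation))
  t2 <- compare_intron_lengths(list(x = gb$annotation))
  expect_equal(t1$intron_len, t2$intron_len)
})

test_that("a fully edited planted site is called at efficiency 1", {
  plan <- light_plan()
  sim <- generate_genome(plastome_spec(
    scale = 1 / 20, seed = 48L, gene_plan = plan,
    editing_n = c(cds = 1L, intron = 0L, intergenic = 0L),
    editing_eff = 1.0))
  iso <- simulate_isoseq(sim$genome, sim$truth, depth = 50L, error_rate = 0,
                         seed = 49L)
  alns <- spliced_map_pool(iso, spliced_target(sim$genome))
  sites <- call_editing(alns, sim$genome, sim$annotation)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$pos, sim$truth$editing$pos)
  expect_equal(sites$efficiency, 1.0)
  expect_equal(sites$category, "CDS")
})

test_that("the binomial filter matches an exact tail computation", {
  ## pileup 30 covering / 6 edited at err = 0.02
  p_tail <- sum(vapply(6:30, function(x)
    choose(30, x) * 0.02^x * 0.98^(30 - x), numeric(1)))
  expect_equal(pbinom(5, 30, 0.02, lower.tail = FALSE), p_tail,
               tolerance = 1e-12)
  expect_lt(p_tail, 0.05)
  expect_equal(6 / 30, 0.2)
  ## so a 6/30 pileup is called iff min_eff <= 0.2: check through the caller
  sim <- sim_light(50L)
  glen <- nchar(sim$genome$seq)
  ## a plus-strand C position inside geneB (single-exon, no splicing)
  ann <- sim$annotation
  gb <- ann[ann$gene == "geneB", ]
  chars <- strsplit(sim$genome$seq, "")[[1]]
  want <- if (gb$strand == "+") "C" else "G"
  pos <- which(chars[(gb$start + 10):(gb$end - 10)] == want)[1] + gb$start + 8L
  mk_aln <- function(edit) {
    structure(list(
      qname = "r", strand = gb$strand,
      blocks = data.frame(qstart = 0L, qend = gb$end - gb$start,
                          tstart = gb$start, tend = gb$end),
      introns = data.frame(donor = numeric(0), acceptor = numeric(0),
                           q_split = numeric(0)),
      mismatches = if (edit) data.frame(
        tpos = pos, ref = want, alt = if (want == "C") "T" else "A",
        stringsAsFactors = FALSE)
      else data.frame(tpos = integer(0), ref = character(0),
                      alt = character(0)),
      cigar = sprintf("%dM", gb$end - gb$start), score = 100L,
      rname = sim$genome$id, qlen = gb$end - gb$start, qseq = ""
    ), class = "transcript_aln")
  }
  alns <- c(replicate(6, mk_aln(TRUE), simplify = FALSE),
            replicate(24, mk_aln(FALSE), simplify = FALSE))
  called <- call_editing(alns, sim$genome, sim$annotation, min_cov = 10L,
                         min_eff = 0.10)
  expect_true(pos %in% called$pos)
  expect_equal(called$efficiency[called$pos == pos], 0.2)
  not_called <- call_editing(alns, sim$genome, sim$annotation,
                             min_cov = 10L, min_eff = 0.25)
  expect_false(pos %in% not_called$pos)
})

test_that("amino-acid consequences follow translation table 11", {
  ## build a tiny genome with a known codon layout: ATG TCA CTC TAA
  gseq <- paste0(strrep("A", 30), "ATGTCACTCTAA", strrep("G", 30))
  pad <- withr::with_seed(1, chloroplastr:::random_seq_exact_gc(3000, 0.4))
  g <- plastome(paste0(gseq, pad), circular = FALSE)
  ann <- data.frame(gene = "toy", type = "CDS", strand = "+", exon = 1L,
                    start = 30L, end = 42L, stringsAsFactors = FALSE)
  ## TCA -> TTA at codon position 2: S -> L
  s1 <- annotate_editing(list(pos = 34L, strand = "+"), ann, g)
  expect_equal(s1$category, "CDS")
  expect_equal(s1$codon_pos, 2L)
  expect_equal(s1$aa_change, "S>L")
  ## CTC -> CTT at codon position 3: L -> L, synonymous
  s2 <- annotate_editing(list(pos = 38L, strand = "+"), ann, g)
  expect_equal(s2$codon_pos, 3L)
  expect_equal(s2$aa_change, "L>L (syn)")
  ## a site whose base is not C on its strand violates the invariant
  expect_error(annotate_editing(list(pos = 30L, strand = "+"), ann, g),
               "not C")
})

test_that("site categories agree with planted truth on a full run", {
  pool <- aligned_pool_deep()
  sites <- call_editing(pool$alns, pool$sim$genome, pool$sim$annotation,
                        introns = pool$sim$truth$introns)
  truth <- pool$sim$truth$editing
  m <- merge(sites, truth, by = "pos")
  expect_equal(nrow(m), nrow(truth))
  expect_true(all(m$category.x == m$category.y))
  summ <- editing_summary(sites)
  expect_equal(summ$n, nrow(sites))
  expect_equal(unname(summ$by_category[["CDS"]]), sum(truth$category == "CDS"))
  expect_equal(summ$efficiency[["max"]], max(sites$efficiency))
  ## empty input
  empty <- editing_summary(sites[0, ])
  expect_equal(empty$n, 0L)
})

test_that("editing-set arithmetic counts overlaps once", {
  new <- 1:37
  prior <- c(1:29, 101:137)
  cmb <- combine_editing_sets(new, prior)
  expect_equal(cmb$n_overlap, 29L)
  expect_equal(cmb$n_combined, 37L + 66L - 29L)
  expect_equal(combine_editing_sets(integer(0), prior)$n_combined, 66L)
})

test_that("operons are recovered with exact ordered gene lists and names", {
  pool <- aligned_pool_clean()
  ops <- call_operons(pool$alns, pool$sim$annotation, min_support = 3L)
  expect_equal(nrow(ops), 9L)
  truth_units <- pool$sim$truth$units
  tu <- truth_units[truth_units$n_genes >= 2L, ]
  genes <- pool$sim$truth$genes
  for (i in seq_len(nrow(tu))) {
    members <- genes[genes$unit == tu$unit[i], ]
    members <- members[!duplicated(members$gene), ]
    members <- members[order(members$start), ]
    glist <- if (tu$strand[i] == "+") members$gene else rev(members$gene)
    expect_true(paste(glist, collapse = "+") %in% ops$genes)
  }
  ## family naming with ordinals (two Atp units, two Psb units, two Rpl)
  expect_setequal(
    ops$name,
    c("Atp_1", "Atp_2", "Psb_1", "Psb_2", "Psa", "Ndh", "Rpl_1", "Rpl_2",
      "Rpo")
  )
  ## the 8-gene ribosomal-protein unit keeps transcription order
  big <- ops[ops$n_genes == 8L, ]
  expect_equal(big$genes,
               "rpl22+rps3+rpl16+rpl14+rps8+rpl36+rps11+rpoA")
})

test_that("monocistronic-only data yields no operons; subsets stay separate", {
  sim <- sim_light(60L)
  iso <- simulate_isoseq(sim$genome, sim$truth, depth = 6L, error_rate = 0,
                         seed = 61L)
  alns <- spliced_map_pool(iso, spliced_target(sim$genome))
  expect_equal(nrow(call_operons(alns, sim$annotation)), 0L)
  ## transcripts covering {A,B} and {A,B,C} form distinct evidence sets
  pool <- aligned_pool_clean()
  sp <- gene_spans(pool$sim$annotation)
  unit <- pool$sim$truth$units
  u <- unit[unit$n_genes == 4L, ][1L, ]
  members <- pool$sim$truth$genes[pool$sim$truth$genes$unit == u$unit, ]
  members <- members[!duplicated(members$gene), ]
  members <- members[order(members$start), ]
  sub_end <- members$end[2L]
  ## truncated synthetic transcripts covering only the first two genes
  g <- pool$sim$genome
  q <- substr(g$seq, u$start + 1L, sub_end)
  if (u$strand == "-") q <- revcomp(q)
  subs <- lapply(1:4, function(i) spliced_map(q, g, qname = paste0("sub", i)))
  ops <- call_operons(c(pool$alns, subs), pool$sim$annotation)
  expect_equal(nrow(ops), 10L)
  small <- ops[ops$support == 4L & ops$n_genes == 2L, ]
  expect_equal(nrow(small), 1L)
  expect_false(is.na(small$subset_of))
})
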