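test_that("exact genomic intervals map as a single clean block", {
  sim <- sim_default()
  g <- sim$genome
  q <- substr(g$seq, 2001, 3200)
  a <- spliced_map(q, g)
  expect_equal(nrow(a$blocks), 1L)
  expect_equal(a$blocks$tstart, 2000)
  expect_equal(a$blocks$tend, 3200)
  expect_equal(nrow(a$mismatches), 0L)
  expect_equal(a$strand, "+")
  ## reverse complement: single minus-strand block at the same interval
  b <- spliced_map(revcomp(q), g)
  expect_equal(b$strand, "-")
  expect_equal(b$blocks$tstart, 2000)
  expect_equal(b$blocks$tend, 3200)
})

test_that("unrelated sequence returns no hit, short queries error", {
  sim <- sim_default()
  junk <- withr::with_seed(1, chloroplastr:::random_seq_exact_gc(500, 0.4))
  expect_null(spliced_map(junk, sim$genome))
  expect_error(spliced_map("ACGT", sim$genome), "shorter")
})

test_that("error-free transcripts recover every planted junction exactly", {
  pool <- aligned_pool_clean()
  truth <- pool$sim$truth$introns
  truth_key <- paste(truth$donor, truth$acceptor)
  seen <- character(0)
  for (a in pool$alns) {
    if (nrow(a$introns) == 0L) next
    k <- paste(a$introns$donor, a$introns$acceptor)
    expect_true(all(k %in% truth_key))
    seen <- union(seen, k)
  }
  expect_setequal(seen, truth_key)
})

test_that("at 2% error nearly all junction observations stay base-exact", {
  sim <- sim_default()
  iso <- simulate_isoseq(sim$genome, sim$truth, depth = 20L,
                         error_rate = 0.02, seed = 303L)
  alns <- spliced_map_pool(iso, spliced_target(sim$genome))
  truth <- sim$truth$introns
  n_exact <- 0L; n_total <- 0L; max_shift <- 0L
  for (a in alns) {
    for (j in seq_len(nrow(a$introns))) {
      d <- a$introns$donor[j]; ac <- a$introns$acceptor[j]
      shifts <- abs(truth$donor - d) + abs(truth$acceptor - ac)
      n_total <- n_total + 1L
      if (min(shifts) == 0L) n_exact <- n_exact + 1L
      max_shift <- max(max_shift, min(abs(truth$donor - d)))
    }
  }
  expect_gte(n_total, 80L)
  expect_gte(n_exact / n_total, 0.95)
  expect_lte(max_shift, 10L)
})

test_that("appending matching sequence never lowers the score", {
  sim <- sim_default()
  g <- sim$genome
  base <- substr(g$seq, 5001, 5600)
  s1 <- spliced_map(base, g)$score
  s2 <- spliced_map(substr(g$seq, 5001, 5900), g)$score
  s3 <- spliced_map(substr(g$seq, 5001, 6400), g)$score
  expect_gte(s2, s1)
  expect_gte(s3, s2)
})

test_that("SAM round-trip preserves blocks, strand and mismatches", {
  pool <- aligned_pool_deep()
  alns <- pool$alns[seq_len(100L)]
  tf <- withr::local_tempfile(fileext = ".sam")
  write_sam(alns, pool$sim$genome, tf)
  back <- read_sam(tf)
  expect_equal(length(back), length(alns))
  for (i in seq_along(alns)) {
    a <- alns[[i]]; b <- back[[i]]
    expect_identical(a$qname, b$qname)
    expect_identical(a$strand, b$strand)
    expect_equal(b$blocks, a$blocks, ignore_attr = TRUE)
    am <- a$mismatches[order(a$mismatches$tpos), ]
    bm <- b$mismatches[order(b$mismatches$tpos), ]
    expect_same_table(am, bm)
    expect_equal(b$introns[, c("donor", "acceptor")],
                 a$introns[, c("donor", "acceptor")], ignore_attr = TRUE)
    expect_equal(b$score, a$score)
  }
})

test_that("emitted SAM is readable by samtools", {
  pool <- aligned_pool_clean()
  tf <- withr::local_tempfile(fileext = ".sam")
  write_sam(pool$alns[1:20], pool$sim$genome, tf)
  n <- system2("samtools", c("view", "-c", tf), stdout = TRUE, stderr = TRUE)
  expect_equal(as.integer(tail(n, 1L)), 20L)
})

test_that("an empty alignment set writes a header-only SAM", {
  sim <- sim_default()
  tf <- withr::local_tempfile(fileext = ".sam")
  write_sam(list(), sim$genome, tf)
  lines <- readLines(tf)
  expect_true(all(startsWith(lines, "@")))
  expect_equal(length(read_sam(tf)), 0L)
})

test_that("origin-wrapping alignments split into a supplementary pair", {
  sim <- sim_light(12L)
  g <- sim$genome
  n <- nchar(g$seq)
  q <- paste0(substr(g$seq, n - 399L, n), substr(g$seq, 1L, 400L))
  aln <- structure(list(
    qname = "wrap", strand = "+",
    blocks = data.frame(qstart = 0L, qend = 800L, tstart = n - 400L,
                        tend = n + 400L),
    introns = data.frame(donor = numeric(0), acceptor = numeric(0),
                         q_split = numeric(0)),
    mismatches = data.frame(tpos = integer(0), ref = character(0),
                            alt = character(0)),
    cigar = "800M", score = 800L, rname = g$id, qlen = 800L, qseq = q
  ), class = "transcript_aln")
  tf <- withr::local_tempfile(fileext = ".sam")
  write_sam(list(aln), g, tf)
  back <- read_sam(tf)
  expect_equal(length(back), 2L)
  expect_false(back[[1L]]$supplementary)
  expect_true(back[[2L]]$supplementary)
  expect_equal(back[[1L]]$blocks$tstart, n - 400L)
  expect_equal(back[[1L]]$blocks$tend, n)
  expect_equal(back[[2L]]$blocks$tstart, 0L)
  expect_equal(back[[2L]]$blocks$tend, 400L)
})

test_that("malformed SAM records raise a parse error naming the line", {
  tf <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "broken\trecord"), tf)
  expect_error(read_sam(tf), "line 2")
})
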