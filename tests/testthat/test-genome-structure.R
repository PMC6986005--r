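make_random_seq <- function(len, seed, gc = 0.4) {
  withr::with_seed(seed, chloroplastr:::random_seq_exact_gc(len, gc))
}

test_that("a planted inverted repeat is found at its exact coordinates", {
  withr::with_seed(42, {
    X <- chloroplastr:::random_seq_exact_gc(2000, 0.4)
    R <- chloroplastr:::random_seq_exact_gc(500, 0.4)
    Y <- chloroplastr:::random_seq_exact_gc(2000, 0.4)
  })
  ## pin the flanking bases so the planted pair cannot extend by chance
  Y <- paste0("A", substr(Y, 2, 1999), "A")
  g <- plastome(paste0(X, R, Y, revcomp(R)), circular = FALSE)
  irs <- find_inverted_repeats(g, min_len = 100)
  expect_equal(nrow(irs), 1L)
  expect_equal(irs$start1, 2000L)
  expect_equal(irs$start2, 4500L)
  expect_equal(irs$length, 500L)
})

test_that("inverted-repeat search matches the Biostrings palindrome finder", {
  ## independent oracle on genomes <= 10 kb
  for (seed in c(1L, 2L)) {
    sim <- sim_light(seed)
    g <- sim$genome
    expect_lte(nchar(g$seq), 10000L)
    irs <- find_inverted_repeats(g, min_len = 200)
    pal <- Biostrings::findPalindromes(
      Biostrings::DNAString(g$seq),
      min.armlength = 200, max.looplength = nchar(g$seq)
    )
    arm <- Biostrings::palindromeArmLength(pal)
    keep <- which(arm >= 200)
    expect_equal(nrow(irs), length(keep))
    if (length(keep) == 1L) {
      expect_equal(irs$length[1L], arm[keep])
      expect_equal(irs$start1[1L], Biostrings::start(pal)[keep] - 1L)
    }
  }
})

test_that("repeat-free sequence yields no inverted repeats", {
  g <- plastome(make_random_seq(10000, 77), circular = FALSE)
  expect_equal(nrow(find_inverted_repeats(g, min_len = 100)), 0L)
})

test_that("an immediate palindrome is one pair, not a self-pairing", {
  R <- make_random_seq(300, 5)
  X <- paste0(substr(make_random_seq(1000, 6), 1, 999), "A")
  Y <- paste0("A", substr(make_random_seq(1000, 8), 2, 1000))
  g <- plastome(paste0(X, R, revcomp(R), Y), circular = FALSE)
  irs <- find_inverted_repeats(g, min_len = 100)
  expect_equal(nrow(irs), 1L)
  expect_equal(irs$start1, 1000L)
  expect_equal(irs$start2, 1300L)
  expect_equal(irs$length, 300L)
})

test_that("quadripartite partition recovers planted truth over many seeds", {
  for (seed in 1:20) {
    sim <- sim_light(seed)
    part <- partition_quadripartite(sim$genome)
    truth <- sim$truth$partition
    expect_equal(part$canonical_offset, 0L)
    expect_equal(part$lsc, truth$lsc, ignore_attr = TRUE)
    expect_equal(part$ira, truth$ira, ignore_attr = TRUE)
    expect_equal(part$ssc, truth$ssc, ignore_attr = TRUE)
    expect_equal(part$irb, truth$irb, ignore_attr = TRUE)
    ## tiling invariant
    expect_equal(diff(part$lsc) + diff(part$ssc) + 2L * part$ir_length,
                 nchar(sim$genome$seq))
  }
})

test_that("partition is invariant to rotation and strand", {
  sim <- sim_light(9L)
  part <- partition_quadripartite(sim$genome)
  for (off in c(137L, 5000L)) {
    rot <- plastome(chloroplastr:::rotate_seq(sim$genome$seq, off), id = "rot")
    p2 <- partition_quadripartite(rot)
    expect_equal(region_lengths(p2), region_lengths(part))
    expect_identical(p2$canonical_seq, part$canonical_seq)
  }
  rc <- plastome(revcomp(sim$genome$seq), id = "rc")
  p3 <- partition_quadripartite(rc)
  expect_equal(region_lengths(p3), region_lengths(part))
})

test_that("genomes without a large inverted repeat raise a structured error", {
  g <- plastome(make_random_seq(8000, 55))
  err <- tryCatch(partition_quadripartite(g, min_ir = 1000),
                  error = function(e) e)
  expect_s3_class(err, "no_ir_error")
})

test_that("equal-length single-copy arcs break the tie lexicographically", {
  R <- make_random_seq(1200, 70)
  ## boundary bases pinned so the planted IR pair cannot extend by chance
  A <- paste0("AAAA", make_random_seq(2995, 71), "G")
  B <- paste0("TTTT", make_random_seq(2995, 72), "C")
  g <- plastome(paste0(A, R, B, revcomp(R)))
  part <- partition_quadripartite(g)
  lsc_seq <- substr(part$canonical_seq, part$lsc[1] + 1L, part$lsc[2])
  expect_identical(substr(lsc_seq, 1, 4), "AAAA")
  expect_equal(diff(part$lsc), diff(part$ssc))
})

test_that("region GC handles degenerate compositions", {
  at <- strrep("AT", 2500)
  g <- plastome(paste0(at, make_random_seq(1200, 80), at,
                       revcomp(make_random_seq(1200, 80))))
  ## synthetic check of the accessor only: all-AT windows score 0
  expect_equal(chloroplastr:::gc_fraction(at), 0)
  expect_equal(chloroplastr:::gc_fraction(strrep("ACGT", 100)), 0.5)
  expect_equal(chloroplastr:::gc_fraction("ANNNG"), 0.5)  # N excluded
})

test_that("length-weighted overall GC reproduces the published arithmetic", {
  ## region GC 40.06 (IR x2), 33.47 (LSC), 30.17 (SSC)
  overall <- weighted_overall_gc(
    gc_percent = c(40.06, 40.06, 33.47, 30.17),
    lengths = c(31844, 31844, 91210, 14058)
  )
  expect_equal(round(overall, 2), 35.68)
})

test_that("planted tandem duplications of 45 and 48 bp are found exactly", {
  withr::with_seed(99, {
    chars <- strsplit(chloroplastr:::random_cds(6930, 0.4), "")[[1]]
    chars <- chloroplastr:::plant_tandem_repeat(chars, 2598L, 45L)
    chars <- chloroplastr:::plant_tandem_repeat(chars, 5064L, 48L)
  })
  g <- plastome(paste(chars, collapse = ""), circular = FALSE)
  dr <- find_direct_repeats(g, window = 100, min_len = 40)
  expect_setequal(dr$length, c(45L, 48L))
  expect_equal(dr$start1[dr$length == 45L], 2598L)
  expect_equal(dr$start2[dr$length == 45L], 2643L)
  expect_equal(dr$start1[dr$length == 48L], 5064L)
  expect_true(all(dr$gap == 0L))  # tandem
  ## brute-force absence oracle on a repeat-free sequence
  g2 <- plastome(make_random_seq(2000, 101), circular = FALSE)
  expect_equal(nrow(find_direct_repeats(g2, window = 500, min_len = 20)), 0L)
  ## min_len above the planted lengths hides them
  expect_equal(nrow(find_direct_repeats(g, window = 100, min_len = 60)), 0L)
})

test_that("direct repeats agree with a brute-force scan on a small instance", {
  withr::with_seed(7, {
    base <- chloroplastr:::random_seq_exact_gc(600, 0.45)
  })
  core <- substr(base, 101, 132)  # 32 bp
  seq <- paste0(substr(base, 1, 300), core, substr(base, 301, 600))
  g <- plastome(seq, circular = FALSE)
  dr <- find_direct_repeats(g, window = 400, min_len = 25)
  ## brute force: all maximal same-strand pairs >= 25 bp
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  brute <- list()
  for (i in seq_len(n - 25L)) {
    for (j in (i + 1L):(n - 24L)) {
      if (j - i > 400L + 25L) break
      len <- 0L
      while (j + len <= n && chars[i + len] == chars[j + len]) len <- len + 1L
      if (len >= 25L &&
          (i == 1L || chars[i - 1L] != chars[j - 1L])) {
        brute[[length(brute) + 1L]] <- c(i - 1L, j - 1L, len)
      }
    }
  }
  brute <- unique(do.call(rbind, brute))
  expect_equal(nrow(dr), nrow(brute))
  expect_setequal(dr$length, brute[, 3L])
})

test_that("coverage accounting is exact for simple and wrapped intervals", {
  glen <- 1000L
  whole <- data.frame(start = 0L, end = 1000L)
  cs <- coverage_stats(whole, glen)
  expect_equal(cs$mean, 1.0)
  expect_true(all(cs$depth == 1L))
  halves <- data.frame(start = c(0L, 500L), end = c(500L, 1000L))
  expect_equal(coverage_stats(halves, glen)$mean, 1.0)
  wrap <- data.frame(start = 900L, end = 1100L)  # wraps the origin
  d <- coverage_stats(wrap, glen)$depth
  expect_true(all(d[901:1000] == 1L))
  expect_true(all(d[1:100] == 1L))
  expect_true(all(d[101:900] == 0L))
})

test_that("simulated nominal 20x depth lands between 19x and 21x", {
  sim <- sim_light(3L)
  glen <- nchar(sim$genome$seq)
  pool <- simulate_genomic_reads(sim$genome, n = 1500L, mean_len = 400L,
                                 error_rate = 0, seed = 30L)
  ## nominal 20x: take reads until the true intervals total 20 genome copies
  keep <- cumsum(pool$true_end - pool$true_start) <= 20 * glen
  reads <- pool[keep, ]
  cs <- coverage_stats(reads, glen, rname = sim$genome$id)
  expect_gte(cs$mean, 19); expect_lte(cs$mean, 21)
  expect_error(coverage_stats(reads, glen, rname = "other_genome"),
               "different sequence")
})

test_that("genome summary reproduces mean read length from totals", {
  sim <- sim_light(4L)
  part <- partition_quadripartite(sim$genome)
  summ <- genome_summary(sim$genome, part,
                         reads = list(count = 239086, total_nt = 2579414638))
  expect_equal(summ$mean_read_length, 10789)
  empty <- genome_summary(sim$genome, part,
                          reads = simulate_genomic_reads(sim$genome, 0L))
  expect_true(is.na(empty$read_count))
  expect_equal(empty$genome_size, nchar(sim$genome$seq))
})
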