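## Long-read and full-length cDNA simulators.
##
## The sequencing error model is indel-dominated (substitution : insertion :
## deletion = 1 : 2 : 2), read lengths are log-normal truncated to
## [300 bp, 3 x mean], and every read records its true source interval so
## downstream callers can be scored against planted truth.

ERR_WEIGHTS <- c(sub = 1, ins = 2, del = 2)

## apply sequencing errors to one sequence (character scalar)
mutate_seq <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  hit <- which(runif(n) < error_rate)
  if (length(hit) == 0L) return(seq)
  op <- sample(names(ERR_WEIGHTS), length(hit), replace = TRUE,
               prob = ERR_WEIGHTS / sum(ERR_WEIGHTS))
  out <- as.list(chars)
  for (j in seq_along(hit)) {
    i <- hit[j]
    if (op[j] == "sub") {
      out[[i]] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
    } else if (op[j] == "ins") {
      out[[i]] <- c(chars[i], sample(DNA_BASES, 1L))
    } else {
      out[[i]] <- character(0)
    }
  }
  paste(unlist(out), collapse = "")
}

## truncated log-normal read lengths
draw_read_lengths <- function(n, mean_len) {
  sdlog <- 0.5
  meanlog <- log(mean_len) - sdlog^2 / 2
  lens <- integer(0)
  while (length(lens) < n) {
    x <- round(rlnorm(2L * (n - length(lens)) + 10L, meanlog, sdlog))
    x <- x[x >= 300 & x <= 3 * mean_len]
    lens <- c(lens, x)
  }
  lens[seq_len(n)]
}

#' Simulate long genomic reads from a circular genome
#'
#' Reads start uniformly on the circle (and may wrap the origin), come from
#' either strand, and carry indel-dominated errors. Each read records its
#' true source interval (`true_start`/`true_end`, 0-based on the circle;
#' `true_end` may exceed the genome length for origin-wrapping reads).
#'
#' @param genome a [plastome()] (or DNA string).
#' @param n number of reads; 0 yields an empty set.
#' @param mean_len target mean read length, bp.
#' @param error_rate per-base error rate in `[0, 0.3)`.
#' @param seed integer seed.
#' @return data.frame of class `read_set`: `id`, `seq`, `true_start`,
#'   `true_end`, `strand`, `origin`.
#' @export
simulate_genomic_reads <- function(genome, n, mean_len = 1000L,
                                   error_rate = 0.12, seed = 1L) {
  genome <- as_plastome(genome)
  stopifnot(error_rate >= 0, error_rate < 0.3, n >= 0)
  empty <- data.frame(id = character(0), seq = character(0),
                      true_start = integer(0), true_end = integer(0),
                      strand = character(0), origin = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("read_set", "data.frame")
  if (n == 0L) return(empty)
  withr::with_seed(seed, {
    glen <- nchar(genome$seq)
    doubled <- paste0(genome$seq, genome$seq)
    lens <- draw_read_lengths(n, mean_len)
    lens <- pmin(lens, if (genome$circular) glen else glen)
    starts <- sample.int(glen, n, replace = TRUE) - 1L
    if (!genome$circular) {
      starts <- pmin(starts, glen - lens)
      starts <- pmax(starts, 0L)
    }
    strands <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- substr0(doubled, starts, starts + lens)
    seqs <- ifelse(strands == "-", revcomp(seqs), seqs)
    if (error_rate > 0) {
      seqs <- vapply(seqs, mutate_seq, character(1), error_rate = error_rate,
                     USE.NAMES = FALSE)
    }
    out <- data.frame(
      id = sprintf("gread_%05d", seq_len(n)), seq = seqs,
      true_start = starts, true_end = starts + lens,
      strand = strands, origin = genome$id, stringsAsFactors = FALSE
    )
    class(out) <- c("read_set", "data.frame")
    out
  })
}

#' Simulate full-length cDNA (Iso-Seq style) reads
#'
#' Each transcription unit of the truth (operons and single-gene units) is
#' transcribed `depth` times with a fixed UTR extension at both ends.
#' Planted introns are spliced out, except that each intron is retained
#' (unspliced pre-mRNA) independently with probability `retain_prob` —
#' intron retention is common in plastid full-length cDNA pools and is what
#' makes intronic editing sites observable. At every planted editing site a
#' covering transcript carries T instead of C (in transcript sense) with
#' probability equal to the site's efficiency. Reads from minus-strand units
#' are emitted as the reverse complement of the forward-strand projection.
#'
#' @param genome a [plastome()].
#' @param truth ground truth from [generate_genome()].
#' @param depth transcripts per transcription unit (>= 1).
#' @param error_rate per-base sequencing error rate.
#' @param retain_prob per-intron probability that a transcript retains it.
#' @param seed integer seed.
#' @return data.frame of class `transcript_set`: `id`, `seq`, `unit`,
#'   `strand`, `span_start`, `span_end` (the true genomic span including
#'   UTRs, 0-based half-open).
#' @export
simulate_isoseq <- function(genome, truth, depth = 50L, error_rate = 0.01,
                            retain_prob = 0.5, seed = 1L) {
  genome <- as_plastome(genome)
  stopifnot(depth >= 1)
  withr::with_seed(seed, {
    units <- truth$units
    out <- vector("list", nrow(units))
    for (i in seq_len(nrow(units))) {
      u <- units[i, ]
      span <- c(max(0L, u$start - truth$utr_len),
                min(nchar(genome$seq), u$end + truth$utr_len))
      base_chars <- strsplit(substr0(genome$seq, span[1L], span[2L]), "")[[1]]
      ## introns of genes inside this unit (forward coords, unit-local)
      ui <- truth$introns[truth$introns$gene %in%
                            truth$genes$gene[truth$genes$unit == u$unit], , drop = FALSE]
      ## editing sites covered by this unit's span (edits are applied to the
      ## pre-mRNA, so intronic sites show up on intron-retaining transcripts)
      es <- truth$editing[truth$editing$pos >= span[1L] &
                            truth$editing$pos < span[2L] &
                            truth$editing$strand == u$strand, , drop = FALSE]
      mk <- function() {
        chars <- base_chars
        if (nrow(es) > 0L) {
          edited <- runif(nrow(es)) < es$efficiency
          if (any(edited)) {
            p <- es$pos[edited] - span[1L] + 1L
            ## transcript-sense C->T projects to forward C->T (+) or G->A (-)
            chars[p] <- if (u$strand == "+") "T" else "A"
          }
        }
        keep <- rep(TRUE, length(chars))
        if (nrow(ui) > 0L) {
          spliced <- runif(nrow(ui)) >= retain_prob
          for (j in which(spliced)) {
            keep[(ui$donor[j] - span[1L] + 1L):(ui$acceptor[j] - span[1L])] <- FALSE
          }
        }
        s <- paste(chars[keep], collapse = "")
        if (u$strand == "-") s <- revcomp(s)
        if (error_rate > 0) s <- mutate_seq(s, error_rate)
        s
      }
      seqs <- vapply(seq_len(depth), function(k) mk(), character(1))
      out[[i]] <- data.frame(
        id = sprintf("iso_%s_%03d", u$unit, seq_len(depth)),
        seq = seqs, unit = u$unit, strand = u$strand,
        span_start = span[1L], span_end = span[2L], stringsAsFactors = FALSE
      )
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    class(res) <- c("transcript_set", "data.frame")
    res
  })
}

#' Replace a fraction of a read pool with decoy reads
#'
#' Each read is independently swapped, with the given probability, for a
#' read simulated from the decoy genome with the same length. Pool size and
#' order are preserved; `origin` labels the true source of every read.
#'
#' @param reads a `read_set` from [simulate_genomic_reads()].
#' @param decoy_genome a [plastome()] (or DNA string) to draw decoys from.
#' @param fraction probability in `[0, 1]` that a read is replaced.
#' @param error_rate error rate applied to decoy reads.
#' @param seed integer seed.
#' @return the mixed `read_set`.
#' @export
mix_decoy_reads <- function(reads, decoy_genome, fraction, error_rate = 0.12,
                            seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (nrow(reads) == 0L || fraction == 0) return(reads)
  decoy_genome <- as_plastome(decoy_genome)
  withr::with_seed(seed, {
    swap <- runif(nrow(reads)) < fraction
    if (!any(swap)) return(reads)
    glen <- nchar(decoy_genome$seq)
    doubled <- paste0(decoy_genome$seq, decoy_genome$seq)
    lens <- pmin(nchar(reads$seq[swap]), glen)
    starts <- sample.int(glen, sum(swap), replace = TRUE) - 1L
    seqs <- substr0(doubled, starts, starts + lens)
    strands <- sample(c("+", "-"), sum(swap), replace = TRUE)
    seqs <- ifelse(strands == "-", revcomp(seqs), seqs)
    if (error_rate > 0) {
      seqs <- vapply(seqs, mutate_seq, character(1), error_rate = error_rate,
                     USE.NAMES = FALSE)
    }
    reads$seq[swap] <- seqs
    reads$true_start[swap] <- starts
    reads$true_end[swap] <- starts + lens
    reads$strand[swap] <- strands
    reads$origin[swap] <- decoy_genome$id
    reads
  })
}

#' Simulate an unrelated (decoy) genome
#'
#' @param len length in bp.
#' @param gc GC fraction.
#' @param seed integer seed.
#' @param id sequence id.
#' @return a [plastome()] (linear).
#' @export
simulate_decoy_genome <- function(len, gc = 0.4, seed = 1L, id = "decoy") {
  withr::with_seed(seed, plastome(random_seq_exact_gc(len, gc), id = id,
                                  circular = FALSE))
}
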