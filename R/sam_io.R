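## Plain-text SAM encoding of spliced transcript alignments.
##
## Introns are encoded with the N (reference-skip) CIGAR operation,
## substitutions with an MD tag, the chain score with AS. Alignments that
## wrap the circular origin are split at the origin into a primary plus a
## supplementary record sharing the read name.

parse_cigar <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (length(toks) == 0L || m[1L] == -1L) stop("bad CIGAR: ", cigar)
  data.frame(
    len = as.integer(sub("[A-Z=]$", "", toks)),
    op = sub("^\\d+", "", toks), stringsAsFactors = FALSE
  )
}

## MD tag from a walk over the CIGAR, the mismatch list and the reference
make_md <- function(cig, tstart, mismatches, ref_chars) {
  md <- character(0)
  run <- 0L
  t <- tstart
  mm <- mismatches[order(mismatches$tpos), , drop = FALSE]
  for (i in seq_len(nrow(cig))) {
    op <- cig$op[i]; len <- cig$len[i]
    if (op == "M") {
      seg <- mm[mm$tpos >= t & mm$tpos < t + len, , drop = FALSE]
      cur <- t
      for (j in seq_len(nrow(seg))) {
        run <- run + (seg$tpos[j] - cur)
        md <- c(md, as.character(run), seg$ref[j])
        run <- 0L
        cur <- seg$tpos[j] + 1L
      }
      run <- run + (t + len - cur)
      t <- t + len
    } else if (op == "D") {
      md <- c(md, as.character(run),
              paste0("^", paste(ref_chars[(t + 1L):(t + len)], collapse = "")))
      run <- 0L
      t <- t + len
    } else if (op == "N") {
      t <- t + len
    }
    ## I consumes query only
  }
  md <- c(md, as.character(run))
  paste(md, collapse = "")
}

sam_record <- function(a, flag_extra = 0L) {
  flag <- flag_extra + if (a$strand == "-") 16L else 0L
  nm <- nrow(a$mismatches) +
    sum(parse_cigar(a$cigar)$len[parse_cigar(a$cigar)$op %in% c("I", "D")])
  paste(
    a$qname, flag, a$rname, a$blocks$tstart[1L] + 1L, 60L, a$cigar,
    "*", 0L, 0L, a$qseq, "*",
    sprintf("NM:i:%d", nm), sprintf("MD:Z:%s", a$md),
    sprintf("AS:i:%d", a$score),
    sep = "\t"
  )
}

## split an origin-wrapping alignment into two target-local parts
split_wrapped <- function(a, n) {
  cig <- parse_cigar(a$cigar)
  t <- a$blocks$tstart[1L]; q <- 0L
  ops1 <- list(); ops2 <- list()
  q_split <- NA_integer_
  for (i in seq_len(nrow(cig))) {
    op <- cig$op[i]; len <- cig$len[i]
    tc <- if (op %in% c("M", "D", "N")) len else 0L
    qc <- if (op %in% c("M", "I")) len else 0L
    if (t + tc <= n) {
      ops1[[length(ops1) + 1L]] <- c(len, op)
    } else if (t >= n) {
      if (is.na(q_split)) q_split <- q
      ops2[[length(ops2) + 1L]] <- c(len, op)
    } else {
      l1 <- n - t
      ops1[[length(ops1) + 1L]] <- c(l1, op)
      if (is.na(q_split)) q_split <- q + if (op == "M") l1 else 0L
      ops2[[length(ops2) + 1L]] <- c(len - l1, op)
    }
    t <- t + tc; q <- q + qc
  }
  fmt <- function(ops) paste(vapply(ops, function(x) paste0(x[1L], x[2L]),
                                    character(1)), collapse = "")
  list(cigar1 = fmt(ops1), cigar2 = fmt(ops2), q_split = q_split)
}

#' Write spliced alignments as SAM 1.6
#'
#' @param alignments list of `transcript_aln`.
#' @param target the reference [plastome()] (for the `@SQ` header and MD
#'   reference bases).
#' @param path output path or connection.
#' @return the path, invisibly.
#' @export
write_sam <- function(alignments, target, path) {
  target <- as_plastome(target)
  n <- nchar(target$seq)
  ref_chars <- strsplit(paste0(target$seq, target$seq), "")[[1]]
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", target$id, n),
             "@PG\tID:chloroplastr\tPN:chloroplastr")
  for (a in alignments) {
    if (is.null(a)) next
    tend_max <- max(a$blocks$tend)
    if (a$blocks$tstart[1L] < n && tend_max > n) {
      sp <- split_wrapped(a, n)
      a1 <- a; a1$cigar <- sp$cigar1
      a1$mismatches <- a$mismatches[a$mismatches$tpos < n, , drop = FALSE]
      a1$qseq <- substr0(a$qseq, 0L, sp$q_split)
      a1$md <- make_md(parse_cigar(a1$cigar), a$blocks$tstart[1L],
                       a1$mismatches, ref_chars)
      a2 <- a; a2$cigar <- sp$cigar2
      a2$blocks <- data.frame(qstart = 0L, qend = a$qlen - sp$q_split,
                              tstart = 0L, tend = tend_max - n)
      mm2 <- a$mismatches[a$mismatches$tpos >= n, , drop = FALSE]
      mm2$tpos <- mm2$tpos - n
      a2$mismatches <- mm2
      a2$qseq <- substr0(a$qseq, sp$q_split, nchar(a$qseq))
      a2$md <- make_md(parse_cigar(a2$cigar), 0L, mm2, ref_chars)
      lines <- c(lines, sam_record(a1), sam_record(a2, flag_extra = 2048L))
    } else {
      a$md <- make_md(parse_cigar(a$cigar), a$blocks$tstart[1L],
                      a$mismatches, ref_chars)
      lines <- c(lines, sam_record(a))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

parse_md <- function(md) {
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-Z]+|[A-Z]", md))[[1]]
  toks
}

#' Read a SAM file of spliced alignments
#'
#' Reconstructs blocks from the CIGAR (N ops delimit introns) and the
#' substitution list from the MD tag plus SEQ.
#'
#' @param path SAM file.
#' @return list of `transcript_aln` (supplementary records appear as their
#'   own entries with `supplementary = TRUE`).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  out <- list()
  for (li in seq_along(body)) {
    f <- strsplit(body[li], "\t")[[1]]
    if (length(f) < 11L) stop(sprintf("malformed SAM record at line %d",
                                      li + sum(startsWith(lines, "@"))))
    flag <- as.integer(f[2L])
    tstart <- as.integer(f[4L]) - 1L
    cig <- parse_cigar(f[6L])
    seq <- f[10L]
    tags <- f[-(1:11)]
    md <- sub("^MD:Z:", "", grep("^MD:Z:", tags, value = TRUE))
    as_tag <- sub("^AS:i:", "", grep("^AS:i:", tags, value = TRUE))
    ## walk CIGAR: blocks + per-column ref->query map for MD resolution
    t <- tstart; q <- 0L
    blocks <- list(); bs_t <- t; bs_q <- q
    map_t <- integer(0); map_q <- integer(0)  # M and D columns, MD order
    introns <- list()
    for (i in seq_len(nrow(cig))) {
      op <- cig$op[i]; len <- cig$len[i]
      if (op == "M") {
        map_t <- c(map_t, t:(t + len - 1L))
        map_q <- c(map_q, q:(q + len - 1L))
        t <- t + len; q <- q + len
      } else if (op == "I") {
        q <- q + len
      } else if (op == "D") {
        map_t <- c(map_t, t:(t + len - 1L))
        map_q <- c(map_q, rep(NA_integer_, len))
        t <- t + len
      } else if (op == "N") {
        blocks[[length(blocks) + 1L]] <- data.frame(
          qstart = bs_q, qend = q, tstart = bs_t, tend = t)
        introns[[length(introns) + 1L]] <- data.frame(
          donor = t, acceptor = t + len, q_split = q)
        t <- t + len
        bs_t <- t; bs_q <- q
      } else if (op %in% c("S", "H")) {
        if (op == "S") q <- q + len
      } else stop("unsupported CIGAR op in record: ", op)
    }
    blocks[[length(blocks) + 1L]] <- data.frame(qstart = bs_q, qend = q,
                                                tstart = bs_t, tend = t)
    blocks <- do.call(rbind, blocks)
    introns <- if (length(introns)) do.call(rbind, introns) else
      data.frame(donor = numeric(0), acceptor = numeric(0),
                 q_split = numeric(0))
    mismatches <- data.frame(tpos = integer(0), ref = character(0),
                             alt = character(0), stringsAsFactors = FALSE)
    if (length(md) == 1L) {
      toks <- parse_md(md)
      cursor <- 0L
      mm <- list()
      for (tk in toks) {
        if (grepl("^\\d+$", tk)) {
          cursor <- cursor + as.integer(tk)
        } else if (startsWith(tk, "^")) {
          cursor <- cursor + nchar(tk) - 1L
        } else {
          qpos <- map_q[cursor + 1L]
          mm[[length(mm) + 1L]] <- data.frame(
            tpos = map_t[cursor + 1L], ref = tk,
            alt = substr0(seq, qpos, qpos + 1L), stringsAsFactors = FALSE)
          cursor <- cursor + 1L
        }
      }
      if (length(mm)) mismatches <- do.call(rbind, mm)
    }
    out[[length(out) + 1L]] <- structure(list(
      qname = f[1L], strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
      blocks = blocks, introns = introns, mismatches = mismatches,
      cigar = f[6L],
      score = if (length(as_tag) == 1L) as.integer(as_tag) else NA_integer_,
      rname = f[3L], qlen = nchar(seq), qseq = seq,
      supplementary = bitwAnd(flag, 2048L) > 0L
    ), class = "transcript_aln")
  }
  out
}

#' Write a read set's true source intervals as simple SAM records
#'
#' One `M`-only record per read from the simulator's truth fields (the
#' per-base error operations are not retained by the simulator, so these
#' records describe the true source interval, not a base-level alignment).
#' Origin-wrapping reads split into a primary plus supplementary record.
#'
#' @param reads a `read_set`.
#' @param genome the source [plastome()].
#' @param path output path.
#' @export
write_truth_sam <- function(reads, genome, path) {
  genome <- as_plastome(genome)
  n <- nchar(genome$seq)
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", genome$id, n),
             "@PG\tID:chloroplastr\tPN:chloroplastr")
  for (i in seq_len(nrow(reads))) {
    L <- nchar(reads$seq[i])
    s <- reads$true_start[i]; e <- reads$true_end[i]
    flag0 <- if (reads$strand[i] == "-") 16L else 0L
    if (e <= n) {
      lines <- c(lines, paste(reads$id[i], flag0, genome$id, s + 1L, 60L,
                              sprintf("%dM", L), "*", 0L, 0L, reads$seq[i],
                              "*", sep = "\t"))
    } else {
      l1 <- n - s
      l2 <- L - l1
      if (l2 < 1L || l1 < 1L) next
      lines <- c(lines,
                 paste(reads$id[i], flag0, genome$id, s + 1L, 60L,
                       sprintf("%dM%dS", l1, l2), "*", 0L, 0L, reads$seq[i],
                       "*", sep = "\t"),
                 paste(reads$id[i], flag0 + 2048L, genome$id, 1L, 60L,
                       sprintf("%dS%dM", l1, l2), "*", 0L, 0L, reads$seq[i],
                       "*", sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
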