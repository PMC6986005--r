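## Quadripartite structure resolution and genome-level statistics.
##
## Inverted repeats are found by exact seed-and-extend (k = 21) on the
## circular sequence; the quadripartite partition takes the longest IR pair
## and names the longer inter-IR arc the LSC. All coordinates are 0-based
## half-open on the canonical rotation (position 0 = LSC start, layout
## LSC + IRa + SSC + IRb).

IR_SEED_K <- 21L

#' Find maximal exact inverted-repeat pairs
#'
#' Reports every maximal pair of intervals `[start1, start1+length)`,
#' `[start2, start2+length)` (0-based, on the circle) whose sequences are
#' exact reverse complements of each other, inextensible in either
#' direction, with `length >= min_len`. Sorted by length, descending.
#'
#' @param genome a [plastome()] or DNA string.
#' @param min_len minimum repeat length (>= 50).
#' @return data.frame with columns `start1`, `start2`, `length`.
#' @export
find_inverted_repeats <- function(genome, min_len = 1000L) {
  genome <- as_plastome(genome)
  stopifnot(min_len >= 50)
  S <- genome$seq
  n <- nchar(S)
  k <- IR_SEED_K
  if (n < 2L * k) return(data.frame(start1 = integer(0), start2 = integer(0),
                                    length = integer(0)))
  D <- if (genome$circular) paste0(S, substr0(S, 0L, k - 1L)) else S
  km <- kmers_of(D, k)
  starts <- seq_along(km) - 1L
  dt <- data.table(kmer = km, i = starts)
  rc <- data.table(kmer = revcomp(km), j = starts)
  hits <- merge(dt, rc, by = "kmer", allow.cartesian = TRUE)
  if (nrow(hits) == 0L) return(data.frame(start1 = integer(0),
                                          start2 = integer(0),
                                          length = integer(0)))
  ## seed (i, j) means S[i, i+k) == revcomp(S[j, j+k)); skip degenerate
  ## self-centered seeds where the two windows coincide
  hits <- hits[hits$i != hits$j, ]
  chars <- strsplit(S, "")[[1]]
  comp_chars <- chartr("ACGTN", "TGCAN", chars)
  ## vectorised run length of matches S[a + t] == comp(S[b - t]), t = 0,1,...
  match_run <- function(a, b, cap) {
    run <- 0L
    chunk <- 2048L
    while (run < cap) {
      m <- min(chunk, cap - run)
      ia <- ((a + run + seq_len(m) - 1L) %% n) + 1L
      ib <- ((b - run - seq_len(m) + 1L) %% n) + 1L
      neq <- which(chars[ia] != comp_chars[ib])
      if (length(neq) > 0L) return(run + neq[1L] - 1L)
      run <- run + m
    }
    cap
  }
  found <- list()
  seen_key <- character(0)
  ord <- order(hits$i)
  covered <- function(i, j) {
    for (f in found) {
      di <- (i - f$s1) %% n
      dj <- (j - f$s2) %% n
      if (di < f$len && dj < f$len && (di + dj) == (f$len - k)) return(TRUE)
      ## same pair seen with the two copies in swapped roles
      di <- (i - f$s2) %% n
      dj <- (j - f$s1) %% n
      if (di < f$len && dj < f$len && (di + dj) == (f$len - k)) return(TRUE)
    }
    FALSE
  }
  for (idx in ord) {
    i <- hits$i[idx]; j <- hits$j[idx]
    if (covered(i, j)) next
    ## extend: S[i + t] must equal comp(S[j + k - 1 - t])
    s1 <- i; e1 <- i + k  # half-open on the (virtually) unrolled circle
    s2 <- j; e2 <- j + k
    max_ext <- n - k
    cap1 <- if (genome$circular) max_ext else min(max_ext, n - e1, s2)
    ext <- match_run(e1, s2 - 1L, cap1)
    e1 <- e1 + ext; s2 <- s2 - ext
    cap2 <- if (genome$circular) max_ext else min(max_ext, n - e2, s1)
    ext <- match_run(e2, s1 - 1L, cap2)  # symmetric: left of s1 vs right of e2
    s1 <- s1 - ext; e2 <- e2 + ext
    ## palindromic self-overlap: trim symmetrically so the two intervals are
    ## disjoint (adjacent halves), never pairing an interval with itself
    if (s1 <= s2 && e1 > s2) {
      t <- as.integer(ceiling((e1 - s2) / 2))
      e1 <- e1 - t; s2 <- s2 + t
    } else if (s2 < s1 && e2 > s1) {
      t <- as.integer(ceiling((e2 - s1) / 2))
      e2 <- e2 - t; s1 <- s1 + t
    }
    len <- e1 - s1
    a <- s1 %% n; b <- s2 %% n
    lo <- min(a, b); hi <- max(a, b)
    key <- paste(lo, hi, len)
    if (!(key %in% seen_key)) {
      seen_key <- c(seen_key, key)
      found[[length(found) + 1L]] <- list(s1 = a, s2 = b, len = len,
                                          lo = lo, hi = hi)
    }
  }
  if (length(found) == 0L) return(data.frame(start1 = integer(0),
                                             start2 = integer(0),
                                             length = integer(0)))
  out <- data.frame(
    start1 = vapply(found, function(f) f$lo, integer(1)),
    start2 = vapply(found, function(f) f$hi, integer(1)),
    length = vapply(found, function(f) f$len, integer(1))
  )
  out <- out[!duplicated(out[, c("start1", "start2", "length")]), ]
  out <- out[out$length >= min_len, , drop = FALSE]
  out <- out[order(-out$length, out$start1), ]
  rownames(out) <- NULL
  out
}

#' Resolve the quadripartite LSC/IRa/SSC/IRb partition
#'
#' Takes the longest exact inverted-repeat pair of at least `min_ir` bp; the
#' two arcs between the IR copies become the single-copy regions, the longer
#' one the LSC (ties broken by the lexicographically smaller single-copy
#' sequence). The rotation is normalised so that position 0 is the LSC start
#' adjacent to the IRb end, giving the canonical layout LSC+IRa+SSC+IRb.
#'
#' @param genome a circular [plastome()].
#' @param min_ir minimum IR length, bp.
#' @return an object of class `quadripartite`: intervals `lsc`, `ira`,
#'   `ssc`, `irb` (0-based half-open on the canonical rotation),
#'   `canonical_offset` (bp rotation applied), and `canonical_seq`.
#' @export
partition_quadripartite <- function(genome, min_ir = 1000L) {
  genome <- as_plastome(genome)
  if (!genome$circular) stop("partition requires a circular genome")
  n <- nchar(genome$seq)
  irs <- find_inverted_repeats(genome, min_len = max(50L, min_ir))
  if (nrow(irs) == 0L) {
    stop(structure(
      class = c("no_ir_error", "error", "condition"),
      list(message = sprintf("no inverted repeat of >= %d bp found", min_ir),
           call = sys.call(-1))
    ))
  }
  top <- irs[1L, ]
  l <- top$length
  a1 <- top$start1; a2 <- top$start2
  arc_len <- function(from, to) (to - from) %% n
  ## arcs between the two IR copies
  arcA <- c((a1 + l) %% n, a2)            # from end of copy1 to start of copy2
  arcB <- c((a2 + l) %% n, a1)            # from end of copy2 to start of copy1
  lenA <- arc_len(arcA[1L], arcA[2L])
  lenB <- arc_len(arcB[1L], arcB[2L])
  if (lenA + lenB + 2L * l != n) {
    stop(structure(
      class = c("no_ir_error", "error", "condition"),
      list(message = "inverted-repeat copies overlap; no quadripartite structure",
           call = sys.call(-1))
    ))
  }
  seq_arc <- function(arc, len) {
    substr0(paste0(genome$seq, genome$seq), arc[1L], arc[1L] + len)
  }
  if (lenA > lenB) {
    lsc_start <- arcA[1L]; lsc_len <- lenA; ssc_len <- lenB
  } else if (lenB > lenA) {
    lsc_start <- arcB[1L]; lsc_len <- lenB; ssc_len <- lenA
  } else {
    sA <- seq_arc(arcA, lenA); sB <- seq_arc(arcB, lenB)
    if (sA <= sB) { lsc_start <- arcA[1L]; lsc_len <- lenA; ssc_len <- lenB }
    else { lsc_start <- arcB[1L]; lsc_len <- lenB; ssc_len <- lenA }
  }
  offset <- lsc_start %% n
  canonical_seq <- rotate_seq(genome$seq, offset)
  part <- structure(list(
    lsc = c(0L, lsc_len),
    ira = c(lsc_len, lsc_len + l),
    ssc = c(lsc_len + l, lsc_len + l + ssc_len),
    irb = c(lsc_len + l + ssc_len, n),
    canonical_offset = offset,
    ir_length = l,
    genome_id = genome$id,
    canonical_seq = canonical_seq
  ), class = "quadripartite")
  ## sanity: the canonical IRb must be the exact revcomp of the canonical IRa
  ira_seq <- substr0(canonical_seq, part$ira[1L], part$ira[2L])
  irb_seq <- substr0(canonical_seq, part$irb[1L], part$irb[2L])
  stopifnot(identical(revcomp(ira_seq), irb_seq))
  part
}

#' @export
print.quadripartite <- function(x, ...) {
  cat(sprintf(
    "<quadripartite> %s\n  LSC %s bp | IR %s bp (x2) | SSC %s bp | offset %d\n",
    x$genome_id,
    format(diff(x$lsc), big.mark = ","),
    format(x$ir_length, big.mark = ","),
    format(diff(x$ssc), big.mark = ","),
    x$canonical_offset
  ))
  invisible(x)
}

#' Region lengths of a quadripartite partition
#' @param partition a `quadripartite` object.
#' @return named integer vector `lsc`, `ssc`, `ir`.
#' @export
region_lengths <- function(partition) {
  c(lsc = diff(partition$lsc), ssc = diff(partition$ssc),
    ir = partition$ir_length)
}

#' Per-region and overall GC content
#'
#' G and C are counted case-insensitively; N is excluded from numerator and
#' denominator. The overall value is the length-weighted mean across the
#' four regions (equivalently, the GC of the whole genome).
#'
#' @param genome a [plastome()] whose sequence is in the canonical rotation,
#'   or `NULL` to use `partition$canonical_seq`.
#' @param partition a `quadripartite` object.
#' @return data.frame with columns `region`, `length`, `gc_percent`; the
#'   overall percentage is attached as attribute `overall` and as the
#'   `"overall"` row.
#' @export
region_gc <- function(genome = NULL, partition) {
  seq <- if (is.null(genome)) partition$canonical_seq else {
    g <- as_plastome(genome)
    rotate_seq(g$seq, partition$canonical_offset)
  }
  regions <- list(lsc = partition$lsc, ira = partition$ira,
                  ssc = partition$ssc, irb = partition$irb)
  gc <- vapply(regions, function(iv) gc_fraction(substr0(seq, iv[1L], iv[2L])),
               numeric(1))
  lens <- vapply(regions, diff, numeric(1))
  overall <- 100 * gc_fraction(seq)
  out <- data.frame(
    region = c(names(regions), "overall"),
    length = c(lens, sum(lens)),
    gc_percent = c(100 * gc, overall),
    row.names = NULL
  )
  attr(out, "overall") <- overall
  out
}

#' Length-weighted overall GC from per-region statistics
#'
#' @param gc_percent per-region GC percentages.
#' @param lengths region lengths, bp (same order; duplicated regions such as
#'   the two IR copies must appear once per copy or carry doubled length).
#' @return overall GC percentage.
#' @export
weighted_overall_gc <- function(gc_percent, lengths) {
  stopifnot(length(gc_percent) == length(lengths))
  sum(gc_percent * lengths) / sum(lengths)
}

#' Find same-strand (direct) repeat pairs
#'
#' Exact maximal duplications whose two copies start within `window` bp of
#' each other; tandem (adjacent) duplications are included.
#'
#' @param genome a [plastome()] or DNA string (treated linearly if the
#'   `plastome` is linear; circular genomes are scanned on the doubled
#'   sequence and reported modulo the genome length).
#' @param window maximum gap between the two copies, bp.
#' @param min_len minimum repeat length (>= 20).
#' @return data.frame `start1`, `start2`, `length`, `gap` sorted by length
#'   descending.
#' @export
find_direct_repeats <- function(genome, window = 5000L, min_len = 20L) {
  genome <- as_plastome(genome)
  stopifnot(min_len >= 20)
  S <- genome$seq
  n <- nchar(S)
  k <- min(20L, min_len)
  scan <- if (genome$circular) paste0(S, substr0(S, 0L, min(n, window + min_len) - 1L)) else S
  km <- kmers_of(scan, k)
  dt <- data.table(kmer = km, pos = seq_along(km) - 1L)
  dt <- dt[, if (.N >= 2L && .N <= 100L) list(pos = list(pos)) else NULL, by = "kmer"]
  if (nrow(dt) == 0L) return(data.frame(start1 = integer(0), start2 = integer(0),
                                        length = integer(0), gap = integer(0)))
  pairs <- list()
  for (pl in dt$pos) {
    pl <- sort(pl)
    for (ii in seq_len(length(pl) - 1L)) {
      for (jj in (ii + 1L):length(pl)) {
        if (pl[jj] - pl[ii] > window + min_len) break
        pairs[[length(pairs) + 1L]] <- c(pl[ii], pl[jj])
      }
    }
  }
  if (length(pairs) == 0L) return(data.frame(start1 = integer(0),
                                             start2 = integer(0),
                                             length = integer(0),
                                             gap = integer(0)))
  pm <- unique(do.call(rbind, pairs))
  chars <- strsplit(scan, "")[[1]]
  m <- length(chars)
  out <- list()
  seen <- character(0)
  ## collapse seeds on the same diagonal into maximal extensions
  ord <- order(pm[, 2L] - pm[, 1L], pm[, 1L])
  for (r in ord) {
    i <- pm[r, 1L]; j <- pm[r, 2L]
    s1 <- i; s2 <- j; len <- k
    while (s1 > 0L && chars[s1] == chars[s2]) { s1 <- s1 - 1L; s2 <- s2 - 1L; len <- len + 1L }
    while (s2 + len < m && chars[s1 + len + 1L] == chars[s2 + len + 1L]) len <- len + 1L
    key <- paste(s1, s2, len)
    if (key %in% seen) next
    seen <- c(seen, key)
    if (len < min_len) next
    gap <- s2 - (s1 + len)
    if (gap > window) next
    if (genome$circular && s1 >= n) next  # duplicate image from the unrolled copy
    out[[length(out) + 1L]] <- data.frame(start1 = s1 %% n, start2 = s2 %% n,
                                          length = len, gap = gap)
  }
  if (length(out) == 0L) return(data.frame(start1 = integer(0),
                                           start2 = integer(0),
                                           length = integer(0),
                                           gap = integer(0)))
  res <- unique(do.call(rbind, out))
  res <- res[order(-res$length, res$start1), ]
  rownames(res) <- NULL
  res
}

#' Per-base coverage depth and mean from alignment intervals
#'
#' @param x coverage evidence: a data.frame of reference intervals with
#'   columns `start`,`end` (0-based half-open; `end` may exceed the genome
#'   length for origin-wrapping alignments, which accrue to both ends), a
#'   `read_set` (uses `true_start`/`true_end`), or a list of
#'   `transcript_aln` objects (uses their blocks).
#' @param genome_len reference length, bp.
#' @param rname reference name to check against, if `x` carries one.
#' @return list with `depth` (integer vector of length `genome_len`) and
#'   `mean` (total aligned reference bases / `genome_len`).
#' @export
coverage_stats <- function(x, genome_len, rname = NULL) {
  iv <- NULL
  if (is.data.frame(x)) {
    if (all(c("true_start", "true_end") %in% names(x))) {
      if (!is.null(rname) && "origin" %in% names(x) && nrow(x) > 0L &&
          !all(x$origin == rname)) {
        stop("alignments reference a different sequence than the genome")
      }
      iv <- data.frame(start = x$true_start, end = x$true_end)
    } else if (all(c("start", "end") %in% names(x))) {
      iv <- x[, c("start", "end")]
    } else stop("cannot interpret coverage input")
  } else if (is.list(x)) {
    blocks <- lapply(x, function(a) {
      if (!is.null(rname) && !is.null(a$rname) && a$rname != rname) {
        stop("alignments reference a different sequence than the genome")
      }
      a$blocks[, c("tstart", "tend")]
    })
    bl <- do.call(rbind, blocks)
    iv <- data.frame(start = bl$tstart, end = bl$tend)
  } else stop("cannot interpret coverage input")
  depth_acc <- integer(genome_len + 1L)
  if (nrow(iv) > 0L) {
    for (r in seq_len(nrow(iv))) {
      s <- iv$start[r] %% genome_len
      e <- iv$end[r]
      len <- e - iv$start[r]
      if (len <= 0) next
      e <- s + len
      if (e <= genome_len) {
        depth_acc[s + 1L] <- depth_acc[s + 1L] + 1L
        depth_acc[e + 1L] <- depth_acc[e + 1L] - 1L
      } else {
        depth_acc[s + 1L] <- depth_acc[s + 1L] + 1L
        depth_acc[genome_len + 1L] <- depth_acc[genome_len + 1L] - 1L
        wrap <- e - genome_len
        depth_acc[1L] <- depth_acc[1L] + 1L
        depth_acc[wrap + 1L] <- depth_acc[wrap + 1L] - 1L
      }
    }
  }
  depth <- cumsum(depth_acc[seq_len(genome_len)])
  list(depth = depth, mean = sum(as.numeric(depth)) / genome_len)
}

#' Summarise a genome, its partition and a read set
#'
#' @param genome a [plastome()].
#' @param partition a `quadripartite` partition of it.
#' @param reads either a `read_set`, a list with `count` and `total_nt`
#'   (e.g. published sequencing totals), or `NULL`.
#' @param annotation optional exon-level annotation for gene counts.
#' @return a list of class `plastome_summary`.
#' @export
genome_summary <- function(genome, partition, reads = NULL, annotation = NULL) {
  genome <- as_plastome(genome)
  gc <- region_gc(genome, partition)
  rl <- region_lengths(partition)
  read_count <- total_nt <- mean_read_length <- NA_real_
  if (!is.null(reads)) {
    if (is.data.frame(reads)) {
      if (nrow(reads) > 0L) {
        read_count <- nrow(reads)
        total_nt <- sum(nchar(reads$seq))
        mean_read_length <- round(total_nt / read_count)
      }
    } else {
      read_count <- reads$count
      total_nt <- reads$total_nt
      mean_read_length <- round(total_nt / read_count)
    }
  }
  genes <- NULL
  if (!is.null(annotation)) {
    sp <- gene_spans(annotation)
    genes <- c(total = nrow(sp), table(factor(sp$type, levels = c("CDS", "tRNA", "rRNA"))))
  }
  structure(list(
    genome_id = genome$id,
    genome_size = nchar(genome$seq),
    lsc = unname(rl["lsc"]), ssc = unname(rl["ssc"]), ir = unname(rl["ir"]),
    gc = gc,
    overall_gc = attr(gc, "overall"),
    read_count = read_count, total_nt = total_nt,
    mean_read_length = mean_read_length,
    genes = genes
  ), class = "plastome_summary")
}

#' @export
print.plastome_summary <- function(x, ...) {
  cat(sprintf("Genome %s: %s bp (LSC %s / SSC %s / IR %s x2)\n",
              x$genome_id, format(x$genome_size, big.mark = ","),
              format(x$lsc, big.mark = ","), format(x$ssc, big.mark = ","),
              format(x$ir, big.mark = ",")))
  cat(sprintf("GC: overall %.2f%% (LSC %.2f / SSC %.2f / IR %.2f)\n",
              x$overall_gc,
              x$gc$gc_percent[x$gc$region == "lsc"],
              x$gc$gc_percent[x$gc$region == "ssc"],
              x$gc$gc_percent[x$gc$region == "ira"]))
  if (!is.na(x$read_count)) {
    cat(sprintf("Reads: %s (total %s nt, mean length %s bp)\n",
                format(x$read_count, big.mark = ","),
                format(x$total_nt, big.mark = ","),
                format(x$mean_read_length, big.mark = ",")))
  }
  if (!is.null(x$genes)) {
    cat(sprintf("Genes: %d (%d CDS, %d tRNA, %d rRNA)\n",
                x$genes[["total"]], x$genes[["CDS"]],
                x$genes[["tRNA"]], x$genes[["rRNA"]]))
  }
  invisible(x)
}

#' @method as.data.frame plastome_summary
#' @export
as.data.frame.plastome_summary <- function(x, ...) {
  data.frame(
    field = c("genome_id", "genome_size", "lsc", "ssc", "ir", "overall_gc",
              "read_count", "total_nt", "mean_read_length"),
    value = c(x$genome_id, x$genome_size, x$lsc, x$ssc, x$ir,
              sprintf("%.2f", x$overall_gc), x$read_count, x$total_nt,
              x$mean_read_length),
    stringsAsFactors = FALSE
  )
}
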