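## Spliced mapping of full-length cDNAs to a circular plastome.
##
## Strategy: exact k-mer seeds (both strands, circular target via doubling),
## diagonal clustering and co-linear chaining; target gaps >= min_intron
## with near-zero query gaps become introns; each splice junction is then
## refined with a small "glue" dynamic program that allows indels on both
## sides of the junction, with equal-scoring placements resolved by the
## group-II boundary motif (5' GTGYG ... AY 3' in transcript sense) and
## otherwise slid leftmost. Blocks are materialised by stitching exact seed
## anchors with tiny Needleman-Wunsch patches over the inter-anchor gaps,
## so the per-read cost stays near-linear in read length.

#' Build a reusable k-mer index of a spliced-mapping target
#'
#' @param target a [plastome()] or DNA string.
#' @param k seed length.
#' @return object of class `spliced_target`.
#' @export
spliced_target <- function(target, k = 13L) {
  target <- as_plastome(target)
  n <- nchar(target$seq)
  D <- if (target$circular) paste0(target$seq, target$seq) else target$seq
  km <- kmers_of(D, k)
  env <- new.env(hash = TRUE, size = as.integer(2 * length(km)), parent = emptyenv())
  for (i in seq_along(km)) {
    key <- km[i]
    prev <- env[[key]]
    env[[key]] <- if (is.null(prev)) i - 1L else c(prev, i - 1L)
  }
  structure(list(id = target$id, seq = target$seq, n = n, doubled = D,
                 chars = strsplit(D, "")[[1]], k = k, index = env,
                 circular = target$circular),
            class = "spliced_target")
}

## seed hits of a query (already strand-adjusted) against the target index.
## Every circular k-mer position has a window starting inside [0, n) on the
## doubled sequence, so hits are restricted to that canonical image.
seed_hits <- function(qseq, tgt) {
  qk <- kmers_of(qseq, tgt$k)
  if (length(qk) == 0L) return(NULL)
  hl <- mget(qk, envir = tgt$index, ifnotfound = list(NULL))
  lens <- lengths(hl)
  if (sum(lens) == 0L) return(NULL)
  h <- data.frame(qpos = rep(seq_along(qk) - 1L, lens),
                  tpos = unlist(hl, use.names = FALSE))
  h <- h[h$tpos < tgt$n, , drop = FALSE]
  if (nrow(h) == 0L) NULL else h
}

## group hits into co-linear segments (similar diagonal, advancing qpos)
hits_to_segments <- function(hits, k) {
  hits$diag <- hits$tpos - hits$qpos
  hits <- hits[order(hits$qpos, hits$tpos), ]
  brk <- c(TRUE, abs(diff(hits$diag)) > 20L | diff(hits$qpos) > 60L)
  hits$seg <- cumsum(brk)
  dt <- as.data.table(hits)
  segs <- as.data.frame(dt[, list(qlo = min(qpos), qhi = max(qpos),
                                  tlo = min(tpos), thi = max(tpos),
                                  nhits = .N), by = "seg"])
  keep <- segs$nhits >= 2L | (segs$qhi - segs$qlo) >= 4L
  list(segs = segs[keep, , drop = FALSE],
       hits = hits[hits$seg %in% segs$seg[keep], c("qpos", "tpos", "seg")])
}

## best co-linear chain of segments (small O(m^2) DP on hit counts)
chain_segments <- function(segs, max_intron) {
  segs <- segs[order(segs$qlo, segs$tlo), ]
  m <- nrow(segs)
  if (m == 0L) return(segs)
  score <- segs$nhits
  prev <- rep(NA_integer_, m)
  for (i in seq_len(m)) {
    for (j in seq_len(i - 1L)) {
      qgap <- segs$qlo[i] - segs$qhi[j]
      tgap <- segs$tlo[i] - segs$thi[j]
      if (qgap > -30L && tgap > -30L && tgap <= max_intron &&
          segs$thi[i] > segs$thi[j] && segs$qhi[i] > segs$qhi[j]) {
        cand <- score[j] + segs$nhits[i]
        if (cand > score[i]) { score[i] <- cand; prev[i] <- j }
      }
    }
  }
  best <- which.max(score)
  path <- integer(0)
  while (!is.na(best)) { path <- c(best, path); best <- prev[best] }
  segs[path, , drop = FALSE]
}

## Needleman-Wunsch prefix matrix: pattern prefixes (cols) vs subject
## prefixes (rows). match +1 / mismatch -1 / gap -2.
nw_prefix <- function(pat, sub) {
  C <- length(pat); X <- length(sub)
  M <- matrix(0, nrow = X + 1L, ncol = C + 1L)
  M[1L, ] <- -2 * (0:C)
  M[, 1L] <- -2 * (0:X)
  for (x in seq_len(X)) {
    sx <- sub[x]
    prev <- M[x, ]
    cur <- M[x + 1L, ]
    for (c in seq_len(C)) {
      cur[c + 1L] <- max(prev[c] + (if (sx == pat[c]) 1 else -1),
                         prev[c + 1L] - 2,
                         cur[c] - 2)
    }
    M[x + 1L, ] <- cur
  }
  M
}

## tiny global aligner with traceback; returns character vector of ops
## ("M" both, "I" pattern-only/insertion, "D" subject-only/deletion)
nw_ops <- function(pat, sub) {
  C <- length(pat); X <- length(sub)
  if (C == 0L) return(rep("D", X))
  if (X == 0L) return(rep("I", C))
  M <- nw_prefix(pat, sub)
  ops <- character(0)
  x <- X; c <- C
  while (x > 0L || c > 0L) {
    if (x > 0L && c > 0L &&
        M[x + 1L, c + 1L] == M[x, c] + (if (sub[x] == pat[c]) 1 else -1)) {
      ops <- c("M", ops); x <- x - 1L; c <- c - 1L
    } else if (x > 0L && M[x + 1L, c + 1L] == M[x, c + 1L] - 2) {
      ops <- c("D", ops); x <- x - 1L
    } else {
      ops <- c("I", ops); c <- c - 1L
    }
  }
  ops
}

## does target interval [d, a) look like a group-II intron on `strand`?
intron_motif_score <- function(chars, d, a, strand) {
  if (a - d < 8L) return(0L)
  s <- 0L
  if (strand == "+") {
    don <- chars[(d + 1L):(d + 5L)]
    acc <- chars[(a - 1L):a]
    if (don[1L] == "G" && don[2L] == "T" && don[3L] == "G" &&
        don[4L] %in% c("C", "T") && don[5L] == "G") s <- s + 1L
    if (acc[1L] == "A" && acc[2L] %in% c("C", "T")) s <- s + 1L
  } else {
    ## transcript-sense motif on the reverse strand, read on forward coords
    don <- chars[(a - 4L):a]            # revcomp("GTGYG") = C R C A C
    acc <- chars[(d + 1L):(d + 2L)]     # revcomp("AY") = R T
    if (don[1L] == "C" && don[2L] %in% c("A", "G") && don[3L] == "C" &&
        don[4L] == "A" && don[5L] == "C") s <- s + 1L
    if (acc[1L] %in% c("A", "G") && acc[2L] == "T") s <- s + 1L
  }
  s
}

## refine one splice junction between anchored seeds.
## (qa,ta): a seed known exact in the left block; (qb,tb): in the right
## block. Returns list(q_split, donor, acceptor), or NULL when no candidate
## yields an intron within [min_intron, max_intron].
refine_junction <- function(qchars, tchars, qa, ta, qb, tb, k,
                            min_intron, max_intron, strand) {
  qL <- qa; qR <- min(length(qchars), qb + k)
  Qw <- qchars[(qL + 1L):qR]
  C <- length(Qw)
  if (C > 240L) return(NULL)
  slack <- 10L
  X <- C - k + slack
  TL <- tchars[(ta + 1L):min(length(tchars), ta + X)]
  tr_end <- tb + k
  tr_start <- max(0L, tr_end - X)
  TR <- tchars[(tr_start + 1L):tr_end]
  M1 <- nw_prefix(Qw, TL)
  M2 <- nw_prefix(rev(Qw), rev(TR))
  E1 <- apply(M1, 2L, max)
  E2r <- apply(M2, 2L, max)
  ## split after c query bases: left score E1[c+1], right uses suffix C-c
  total <- E1 + rev(E2r)
  best <- max(total)
  ## enumerate all near-optimal (split, donor, acceptor) combinations: a
  ## sequencing indel right at the junction can make the true placement
  ## score up to one gap worse than the optimum, and the boundary motif is
  ## then the better arbiter
  margin <- 3 + 1e-9
  cand_c <- which(total >= best - margin) - 1L
  cand <- do.call(rbind, lapply(cand_c, function(c) {
    col1 <- M1[, c + 1L]
    col2 <- M2[, C - c + 1L]
    xs <- which(col1 >= max(col1) - margin) - 1L
    ys <- which(col2 >= max(col2) - margin) - 1L
    grid <- expand.grid(x = xs, y = ys)
    sc <- col1[grid$x + 1L] + col2[grid$y + 1L]
    ok <- sc >= best - margin
    if (!any(ok)) return(NULL)
    cbind(c = c, d = ta + grid$x[ok], a = tr_end - grid$y[ok],
          score = sc[ok])
  }))
  if (is.null(cand)) return(NULL)
  cand <- cand[!duplicated(cand[, c("d", "a")]), , drop = FALSE]
  ilen <- cand[, "a"] - cand[, "d"]
  cand <- cand[ilen >= min_intron & ilen <= max_intron, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  ms <- vapply(seq_len(nrow(cand)), function(i) {
    intron_motif_score(tchars, cand[i, "d"], cand[i, "a"], strand)
  }, integer(1))
  strong <- ms == 2L
  if (any(strong)) {
    cand <- cand[strong, , drop = FALSE]
  } else {
    keep <- cand[, "score"] >= best - 1e-9
    cand <- cand[keep, , drop = FALSE]
    ms <- ms[keep]
    cand <- cand[ms == max(ms), , drop = FALSE]
  }
  cand <- cand[cand[, "score"] == max(cand[, "score"]), , drop = FALSE]
  pick <- cand[order(cand[, "d"], cand[, "c"])[1L], ]
  list(q_split = qL + unname(pick["c"]), donor = unname(pick["d"]),
       acceptor = unname(pick["a"]))
}

## pick non-overlapping, strictly increasing anchors from a block's hits
select_anchors <- function(hits, k, qs, qe, ts_min, te_max) {
  h <- hits[hits$qpos >= qs & hits$qpos + k <= qe &
              hits$tpos >= ts_min & hits$tpos + k <= te_max, , drop = FALSE]
  h <- h[order(h$qpos, h$tpos), ]
  if (nrow(h) == 0L) return(h)
  keep <- logical(nrow(h))
  last_q <- last_t <- last_d <- NA_integer_
  for (i in seq_len(nrow(h))) {
    d <- h$tpos[i] - h$qpos[i]
    if (is.na(last_q) ||
        (h$qpos[i] >= last_q + k && h$tpos[i] >= last_t + k &&
         abs(d - last_d) <= 30L)) {
      keep[i] <- TRUE
      last_q <- h$qpos[i]; last_t <- h$tpos[i]; last_d <- d
    }
  }
  h[keep, , drop = FALSE]
}

## align a segment pair and emit ops + mismatch positions.
## Returns list(ops, mism tpos/ref/alt vectors)
patch_ops <- function(qseg, tseg, toff) {
  lq <- length(qseg); lt <- length(tseg)
  if (lq == 0L && lt == 0L) {
    return(list(ops = character(0), tpos = integer(0), ref = character(0),
                alt = character(0)))
  }
  if (lq == lt) {
    neq <- which(qseg != tseg)
    if (length(neq) <= max(2L, lq %/% 10L)) {
      return(list(ops = rep("M", lq), tpos = toff + neq - 1L,
                  ref = tseg[neq], alt = qseg[neq]))
    }
  }
  ops <- nw_ops(qseg, tseg)
  qi <- cumsum(ops != "D")
  ti <- cumsum(ops != "I")
  at <- which(ops == "M")
  mm <- at[qseg[qi[at]] != tseg[ti[at]]]
  list(ops = ops, tpos = toff + ti[mm] - 1L, ref = tseg[ti[mm]],
       alt = qseg[qi[mm]])
}

## stitch one block from its anchors.
## ts_fixed/te_fixed: target boundaries imposed by junctions (NA = free).
stitch_block <- function(qchars, tchars, anchors, k, qs, qe, ts_fixed,
                         te_fixed) {
  stopifnot(nrow(anchors) > 0L)
  ops <- character(0)
  mm_t <- integer(0); mm_r <- character(0); mm_a <- character(0)
  add <- function(p) {
    ops <<- c(ops, p$ops)
    mm_t <<- c(mm_t, p$tpos); mm_r <<- c(mm_r, p$ref); mm_a <<- c(mm_a, p$alt)
  }
  a1q <- anchors$qpos[1L]; a1t <- anchors$tpos[1L]
  ## leading segment
  lead_q <- if (a1q > qs) qchars[(qs + 1L):a1q] else character(0)
  if (is.na(ts_fixed)) {
    ## free left target end: consume just enough subject, preferring an
    ## indel-free landing
    lw <- length(lead_q) + 8L
    tw_start <- max(0L, a1t - lw)
    tseg <- if (a1t > tw_start) tchars[(tw_start + 1L):a1t] else character(0)
    if (length(lead_q) == 0L) {
      tstart <- a1t
    } else {
      Mp <- nw_prefix(rev(lead_q), rev(tseg))
      col <- Mp[, length(lead_q) + 1L]
      x <- which.max(col) - 1L          # subject bases consumed
      tstart <- a1t - x
      sub <- if (x > 0L) tchars[(tstart + 1L):a1t] else character(0)
      add(patch_ops(lead_q, sub, tstart))
    }
    if (length(lead_q) == 0L) tstart <- a1t
  } else {
    tstart <- ts_fixed
    sub <- if (a1t > tstart) tchars[(tstart + 1L):a1t] else character(0)
    add(patch_ops(lead_q, sub, tstart))
  }
  ## anchors and inter-anchor patches
  for (i in seq_len(nrow(anchors))) {
    add(list(ops = rep("M", k), tpos = integer(0), ref = character(0),
             alt = character(0)))
    aq <- anchors$qpos[i] + k; at <- anchors$tpos[i] + k
    if (i < nrow(anchors)) {
      bq <- anchors$qpos[i + 1L]; bt <- anchors$tpos[i + 1L]
      qseg <- if (bq > aq) qchars[(aq + 1L):bq] else character(0)
      tseg <- if (bt > at) tchars[(at + 1L):bt] else character(0)
      add(patch_ops(qseg, tseg, at))
    }
  }
  ## trailing segment
  laq <- anchors$qpos[nrow(anchors)] + k
  lat <- anchors$tpos[nrow(anchors)] + k
  tail_q <- if (qe > laq) qchars[(laq + 1L):qe] else character(0)
  if (is.na(te_fixed)) {
    if (length(tail_q) == 0L) {
      tend <- lat
    } else {
      tw_end <- min(length(tchars), lat + length(tail_q) + 8L)
      tseg <- if (tw_end > lat) tchars[(lat + 1L):tw_end] else character(0)
      Mp <- nw_prefix(tail_q, tseg)
      col <- Mp[, length(tail_q) + 1L]
      x <- which.max(col) - 1L
      tend <- lat + x
      sub <- if (x > 0L) tchars[(lat + 1L):tend] else character(0)
      add(patch_ops(tail_q, sub, lat))
    }
  } else {
    tend <- te_fixed
    sub <- if (tend > lat) tchars[(lat + 1L):tend] else character(0)
    add(patch_ops(tail_q, sub, lat))
  }
  list(tstart = tstart, tend = tend, ops = ops,
       mism = data.frame(tpos = mm_t, ref = mm_r, alt = mm_a,
                         stringsAsFactors = FALSE))
}

#' Spliced-map one full-length cDNA to a circular genome
#'
#' @param query DNA string (the read).
#' @param target a [plastome()], DNA string, or prebuilt [spliced_target()].
#' @param min_intron,max_intron intron length bounds, bp.
#' @param k seed length.
#' @param qname read name recorded in the alignment.
#' @return an object of class `transcript_aln` (`qname`, `strand`, `blocks`,
#'   `introns`, `mismatches`, `cigar`, `score`, `rname`, `qseq` = the
#'   strand-adjusted query), or `NULL` when no seed chain is found.
#' @export
spliced_map <- function(query, target, min_intron = 50L, max_intron = 5000L,
                        k = 13L, qname = "query") {
  if (!inherits(target, "spliced_target")) target <- spliced_target(target, k)
  query <- toupper(query)
  if (nchar(query) < 100L) stop("query shorter than 100 bp")
  qf <- query; qr <- revcomp(query)
  hf <- seed_hits(qf, target)
  hr <- seed_hits(qr, target)
  nf <- if (is.null(hf)) 0L else nrow(hf)
  nr <- if (is.null(hr)) 0L else nrow(hr)
  if (max(nf, nr) < 4L) return(NULL)
  strand <- if (nf >= nr) "+" else "-"
  hits <- if (strand == "+") hf else hr
  qseq <- if (strand == "+") qf else qr
  n <- target$n
  k0 <- target$k
  hs <- hits_to_segments(hits, k0)
  segs <- hs$segs
  if (nrow(segs) == 0L) return(NULL)
  chain <- chain_segments(segs, max_intron)
  if (nrow(chain) == 0L) return(NULL)
  shift <- 0L
  if (target$circular && chain$tlo[1L] >= n) shift <- n
  qchars <- strsplit(qseq, "")[[1]]
  tchars <- target$chars
  ## decide junctions between consecutive chain segments
  groups <- list(); cur <- chain[1L, , drop = FALSE]
  junctions <- list()
  if (nrow(chain) > 1L) {
    for (i in 2L:nrow(chain)) {
      tgap <- chain$tlo[i] - (chain$thi[i - 1L] + k0)
      qgap <- chain$qlo[i] - (chain$qhi[i - 1L] + k0)
      jx <- NULL
      if (tgap - qgap >= min_intron - 20L) {
        jx <- refine_junction(qchars, tchars,
                              qa = cur$qhi[nrow(cur)], ta = cur$thi[nrow(cur)],
                              qb = chain$qlo[i], tb = chain$tlo[i],
                              k = k0, min_intron = min_intron,
                              max_intron = max_intron, strand = strand)
      }
      if (!is.null(jx)) {
        groups[[length(groups) + 1L]] <- cur
        junctions[[length(junctions) + 1L]] <- jx
        cur <- chain[i, , drop = FALSE]
      } else {
        cur <- rbind(cur, chain[i, ])
      }
    }
  }
  groups[[length(groups) + 1L]] <- cur

  qlen <- length(qchars)
  nb <- length(groups)
  blocks <- vector("list", nb)
  mms <- list(); all_ops <- list()
  for (b in seq_len(nb)) {
    g <- groups[[b]]
    qs <- if (b == 1L) 0L else junctions[[b - 1L]]$q_split
    qe <- if (b == nb) qlen else junctions[[b]]$q_split
    if (qe <= qs) return(NULL)  # degenerate split
    ts_fixed <- if (b == 1L) NA_integer_ else junctions[[b - 1L]]$acceptor
    te_fixed <- if (b == nb) NA_integer_ else junctions[[b]]$donor
    gh <- hs$hits[hs$hits$seg %in% g$seg, , drop = FALSE]
    anchors <- select_anchors(
      gh, k0, qs, qe,
      ts_min = if (is.na(ts_fixed)) -1e9 else ts_fixed,
      te_max = if (is.na(te_fixed)) 1e9 else te_fixed
    )
    if (nrow(anchors) == 0L) return(NULL)
    st <- stitch_block(qchars, tchars, anchors, k0, qs, qe, ts_fixed,
                       te_fixed)
    blocks[[b]] <- data.frame(qstart = qs, qend = qe,
                              tstart = st$tstart, tend = st$tend)
    mms[[b]] <- st$mism
    all_ops[[b]] <- st$ops
  }
  blocks <- do.call(rbind, blocks)
  introns <- if (length(junctions)) {
    data.frame(
      donor = vapply(junctions, function(j) j$donor, numeric(1)),
      acceptor = vapply(junctions, function(j) j$acceptor, numeric(1)),
      q_split = vapply(junctions, function(j) j$q_split, numeric(1))
    )
  } else data.frame(donor = numeric(0), acceptor = numeric(0),
                    q_split = numeric(0))
  mismatches <- do.call(rbind, mms)
  rownames(mismatches) <- NULL
  ## normalise out of the doubled-target image
  if (shift > 0L) {
    blocks$tstart <- blocks$tstart - shift
    blocks$tend <- blocks$tend - shift
    if (nrow(introns) > 0L) {
      introns$donor <- introns$donor - shift
      introns$acceptor <- introns$acceptor - shift
    }
    if (nrow(mismatches) > 0L) mismatches$tpos <- mismatches$tpos - shift
  }
  ## assemble CIGAR: per-block ops joined by N ops of intron length
  cigar <- character(0)
  nmatch <- 0L; nmis <- nrow(mismatches); ngap <- 0L
  for (b in seq_len(nb)) {
    r <- rle(all_ops[[b]])
    cigar <- c(cigar, sprintf("%d%s", r$lengths, r$values))
    nmatch <- nmatch + sum(all_ops[[b]] == "M")
    ngap <- ngap + sum(all_ops[[b]] != "M")
    if (b < nb) {
      cigar <- c(cigar,
                 sprintf("%dN", as.integer(introns$acceptor[b] - introns$donor[b])))
    }
  }
  nmatch <- nmatch - nmis
  structure(list(
    qname = qname, strand = strand, blocks = blocks, introns = introns,
    mismatches = mismatches, cigar = paste(cigar, collapse = ""),
    score = nmatch - 2L * nmis - 2L * ngap, rname = target$id, qlen = qlen,
    qseq = qseq
  ), class = "transcript_aln")
}

#' @export
print.transcript_aln <- function(x, ...) {
  cat(sprintf("<transcript_aln> %s -> %s (%s): %d block(s), %d mismatch(es), score %d\n",
              x$qname, x$rname, x$strand, nrow(x$blocks), nrow(x$mismatches),
              x$score))
  invisible(x)
}

#' Spliced-map a pool of transcripts
#'
#' @param transcripts a `transcript_set` (or character vector).
#' @param target a [plastome()] or [spliced_target()].
#' @param ... passed to [spliced_map()].
#' @return a list of `transcript_aln` (unmapped reads are dropped).
#' @export
spliced_map_pool <- function(transcripts, target, ...) {
  if (!inherits(target, "spliced_target")) {
    dots <- list(...)
    k <- if (!is.null(dots$k)) dots$k else 13L
    target <- spliced_target(target, k)
  }
  if (is.data.frame(transcripts)) {
    ids <- transcripts$id; seqs <- transcripts$seq
  } else {
    seqs <- transcripts
    ids <- sprintf("query_%05d", seq_along(seqs))
  }
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    out[[i]] <- spliced_map(seqs[i], target, qname = ids[i], ...)
  }
  out[!vapply(out, is.null, logical(1))]
}
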