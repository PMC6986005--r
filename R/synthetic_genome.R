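## Synthetic plastome generator.
##
## Produces a circular quadripartite genome (LSC + IRa + SSC + IRb, with the
## IRs exact reverse complements of one another), a gene annotation, and a
## ground-truth record of everything that was planted: gene models, group-II
## introns (5' GTGYG ... AY 3' boundary motifs), C-to-U editing sites with
## per-site efficiencies, and polycistronic transcription units.

STOP_CODONS <- c("TAA", "TAG", "TGA")

## Full-scale region lengths and per-region GC of the reference duckweed
## plastome; scaled specs divide the lengths by `1/scale`.
PLASTOME_LSC <- 91210L
PLASTOME_SSC <- 14058L
PLASTOME_IR  <- 31844L
PLASTOME_GC  <- c(lsc = 0.3347, ssc = 0.3017, ir = 0.4006)

#' Default gene/operon/intron plan for the synthetic duckweed-style plastome
#'
#' Nine polycistronic units (sizes 4,2,3,5,2,4,3,4,8) named after the plastid
#' gene families they carry, three intron-bearing monocistronic genes, and a
#' handful of single-gene transcription units. Nine group-II introns are
#' planted in seven genes (ycf3 and clpP carry two each). With `full = TRUE`
#' the plan is padded to 107 unique genes (78 CDS, 25 tRNA, 4 rRNA),
#' including a 6,930 bp ycf2-like CDS carrying planted 45 bp and 48 bp
#' tandem duplications; the full plan only fits a full-scale genome.
#'
#' @param full logical; pad the plan to the 107-gene complement.
#' @return a data.frame with one row per gene: `gene`, `type`, `len` (exonic
#'   bp), `region`, `n_introns`, `unit`.
#' @export
duckweed_gene_plan <- function(full = FALSE) {
  unit_genes <- list(
    atp1 = c("atpI", "atpH", "atpF", "atpA"),
    atp2 = c("atpB", "atpE"),
    psb1 = c("psbD", "psbC", "psbZ"),
    psb2 = c("psbB", "psbT", "psbH", "petB", "petD"),
    psa  = c("psaA", "psaB"),
    ndh  = c("rps15", "ndhH", "ndhA", "ndhI"),
    rpl1 = c("rpl23", "rpl2", "rps19"),
    rpo  = c("rpoB", "rpoC1", "rpoC2", "rps2"),
    rpl2u = c("rpl22", "rps3", "rpl16", "rpl14", "rps8", "rpl36", "rps11", "rpoA")
  )
  op <- data.frame(
    gene = unlist(unit_genes, use.names = FALSE),
    type = "CDS",
    len = 150L,
    region = "lsc",
    n_introns = 0L,
    unit = rep(names(unit_genes), lengths(unit_genes)),
    stringsAsFactors = FALSE
  )
  op$region[op$unit == "ndh"] <- "ssc"
  op$len[op$gene %in% c("atpA", "psaA", "psaB", "rpoB", "rpoC2")] <- 210L
  op$len[op$gene %in% c("psbT", "rpl36", "atpH")] <- 99L
  op$n_introns[op$gene %in% c("atpF", "rpoC1", "rpl2", "ndhA")] <- 1L
  mono <- data.frame(
    gene = c("ycf3", "clpP", "rps12", "rbcL", "matK", "psbA", "trnH", "trnK"),
    type = c(rep("CDS", 6), "tRNA", "tRNA"),
    len = c(150L, 150L, 150L, 210L, 150L, 150L, 75L, 75L),
    region = "lsc",
    n_introns = c(2L, 2L, 1L, 0L, 0L, 0L, 0L, 0L),
    unit = NA_character_,
    stringsAsFactors = FALSE
  )
  plan <- rbind(op, mono)
  if (full) {
    ycf2 <- data.frame(
      gene = "ycf2", type = "CDS", len = 6930L, region = "lsc",
      n_introns = 0L, unit = NA_character_, stringsAsFactors = FALSE
    )
    n_cds_extra <- 78L - sum(plan$type == "CDS") - 1L
    filler <- data.frame(
      gene = sprintf("orf%02d", seq_len(n_cds_extra)),
      type = "CDS",
      len = 3L * (100L + 200L * (seq_len(n_cds_extra) %% 3L)),
      region = "lsc", n_introns = 0L, unit = NA_character_,
      stringsAsFactors = FALSE
    )
    n_trna_extra <- 25L - sum(plan$type == "tRNA")
    trna <- data.frame(
      gene = sprintf("trn%02d", seq_len(n_trna_extra)),
      type = "tRNA", len = 75L, region = "lsc",
      n_introns = 0L, unit = NA_character_, stringsAsFactors = FALSE
    )
    rrna <- data.frame(
      gene = c("rrn16", "rrn23", "rrn4.5", "rrn5"),
      type = "rRNA", len = c(1491L, 2700L, 103L, 121L), region = "ssc",
      n_introns = 0L, unit = NA_character_, stringsAsFactors = FALSE
    )
    plan <- rbind(plan, ycf2, filler, trna, rrna)
  }
  plan
}

#' Default per-site editing efficiencies
#'
#' A fixed vector spanning 0.21 to 1.0 with median 0.93, matching the range
#' and central tendency expected of plastid C-to-U editing.
#'
#' @param n number of sites (default 37).
#' @return numeric vector of length `n` in (0, 1].
#' @export
default_editing_efficiencies <- function(n = 37L) {
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(0.93)
  n_lo <- (n - 1L) %/% 2L
  n_hi <- n - 1L - n_lo
  lo <- c(0.21, if (n_lo > 1L) seq(0.30, 0.90, length.out = n_lo - 1L))
  hi <- c(if (n_hi > 1L) seq(0.935, 0.995, length.out = n_hi - 1L), 1.0)
  sort(c(lo, 0.93, hi))
}

#' Specification of a synthetic plastome
#'
#' Region lengths default to the reference duckweed plastome (LSC 91,210 bp,
#' SSC 14,058 bp, IR 31,844 bp) multiplied by `scale`; per-region GC defaults
#' to IR 40.06%, LSC 33.47%, SSC 30.17%. The editing plan defaults to 37
#' sites: 30 in coding sequence, 1 in an intron and 6 intergenic (inside the
#' 30 bp UTR extensions of transcription units), with efficiencies from
#' [default_editing_efficiencies()].
#'
#' @param scale factor applied to the full-scale region lengths.
#' @param seed integer master seed; all randomness derives from it.
#' @param gene_plan gene plan data.frame, see [duckweed_gene_plan()].
#' @param gc_by_region named fractions for `lsc`, `ssc`, `ir`.
#' @param intron_len_range intron length range in bp.
#' @param editing_n named counts `cds`, `intron`, `intergenic`; any may be 0.
#' @param editing_eff efficiencies to assign to planted sites (recycled
#'   against the total editing count).
#' @param utr_len fixed UTR extension of each transcription unit, bp.
#' @param lsc_len,ssc_len,ir_len explicit region lengths (override `scale`).
#' @return an object of class `plastome_spec`.
#' @export
plastome_spec <- function(scale = 1 / 10, seed = 1L,
                          gene_plan = duckweed_gene_plan(full = scale >= 1),
                          gc_by_region = PLASTOME_GC,
                          intron_len_range = if (scale >= 1) c(500L, 1200L) else c(90L, 150L),
                          editing_n = c(cds = 30L, intron = 1L, intergenic = 6L),
                          editing_eff = default_editing_efficiencies(sum(editing_n)),
                          utr_len = 30L,
                          lsc_len = round(PLASTOME_LSC * scale),
                          ssc_len = round(PLASTOME_SSC * scale),
                          ir_len = round(PLASTOME_IR * scale)) {
  spec <- list(
    lsc_len = as.integer(lsc_len), ssc_len = as.integer(ssc_len),
    ir_len = as.integer(ir_len), gc_by_region = gc_by_region,
    gene_plan = gene_plan, intron_len_range = as.integer(intron_len_range),
    editing_n = editing_n, editing_eff = editing_eff,
    utr_len = as.integer(utr_len), seed = as.integer(seed), scale = scale
  )
  class(spec) <- "plastome_spec"
  validate_plastome_spec(spec)
  spec
}

validate_plastome_spec <- function(spec) {
  stopifnot(
    spec$lsc_len > 0, spec$ssc_len > 0, spec$ir_len >= 1000,
    all(spec$gc_by_region > 0), all(spec$gc_by_region < 1),
    all(c("lsc", "ssc", "ir") %in% names(spec$gc_by_region)),
    all(spec$editing_eff > 0), all(spec$editing_eff <= 1),
    spec$utr_len >= 0,
    all(spec$gene_plan$n_introns %in% 0:2),
    all(spec$gene_plan$len > 0),
    !anyDuplicated(spec$gene_plan$gene)
  )
  if (any(spec$gene_plan$type == "CDS" & spec$gene_plan$len %% 3L != 0L))
    stop("CDS lengths must be multiples of 3")
  invisible(spec)
}

## -------------------------------------------------------------------------
## sequence construction helpers

## random non-stop codons sampled with per-base GC probability `gc`
random_codons <- function(n, gc) {
  if (n <= 0L) return(character(0))
  draw <- function(m) {
    b <- matrix(
      sample(DNA_BASES, 3L * m, replace = TRUE,
             prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
      ncol = 3L
    )
    paste0(b[, 1L], b[, 2L], b[, 3L])
  }
  out <- draw(n)
  bad <- out %in% STOP_CODONS
  while (any(bad)) {
    out[bad] <- draw(sum(bad))
    bad <- out %in% STOP_CODONS
  }
  out
}

random_cds <- function(len, gc) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  paste0("ATG", paste(random_codons(len / 3L - 2L, gc), collapse = ""), "TAA")
}

## group-II intron in transcript sense: 5' GTGYG ... AY 3'
random_intron <- function(len, gc) {
  stopifnot(len >= 10L)
  y1 <- sample(c("C", "T"), 1L)
  y2 <- sample(c("C", "T"), 1L)
  paste0("GTG", y1, "G", random_seq_exact_gc(len - 7L, gc), "A", y2)
}

## duplicate the `len` bases downstream of `at` into [at, at+len), breaking
## flanking identity so the planted pair is maximal at exactly `len`
plant_tandem_repeat <- function(chars, at, len) {
  src <- chars[(at + len + 1L):(at + 2L * len)]
  chars[(at + 1L):(at + len)] <- src
  ## break left flank: chars[at] vs chars[at + len]
  if (at >= 1L && chars[at] == chars[at + len]) {
    chars[at] <- setdiff(DNA_BASES, chars[at])[1L]
  }
  ## break right flank: chars[at + len + 1 .. ] pair ends at (at+2len, at+3len)?
  ## extension right compares chars[at + len + 1] with chars[at + 2*len + 1]
  r1 <- at + len + 1L + len
  if (r1 <= length(chars) && chars[at + len + 1L] == chars[r1]) {
    chars[r1] <- setdiff(DNA_BASES, chars[r1])[1L]
  }
  chars
}

## -------------------------------------------------------------------------

#' Generate a ground-truthed synthetic plastome
#'
#' Lays the planned genes into the LSC and SSC (the IRs are exact mirrored
#' copies of random sequence), plants group-II introns with their boundary
#' motifs, forces a C (on the annotated strand) at every planned editing
#' site, and pads each region with composition-matched filler so the
#' per-region GC lands on its target.
#'
#' @param spec a [plastome_spec()].
#' @return a list with elements `genome` (a [plastome()]), `annotation`
#'   (exon-level data.frame: `gene`, `type`, `strand`, `exon`, `start`,
#'   `end`, 0-based half-open) and `truth` (partition coordinates, gene
#'   table, introns, editing sites, transcription units, seed).
#' @export
generate_genome <- function(spec) {
  validate_plastome_spec(spec)
  withr::with_seed(spec$seed, generate_genome_impl(spec))
}

generate_genome_impl <- function(spec) {
  plan <- spec$gene_plan
  plan$unit <- ifelse(is.na(plan$unit), plan$gene, plan$unit)
  units <- unique(plan$unit)
  unit_strand <- setNames(sample(c("+", "-"), length(units), replace = TRUE), units)

  region_len <- c(lsc = spec$lsc_len, ssc = spec$ssc_len)
  exons <- list()
  introns <- list()
  unit_span <- list()
  region_seq <- list()
  region_offset <- c(lsc = 0L, ssc = spec$lsc_len + spec$ir_len)

  for (region in c("lsc", "ssc")) {
    gc <- spec$gc_by_region[[region]]
    rl <- region_len[[region]]
    chars <- rep(NA_character_, rl)
    cursor <- spec$utr_len + 20L
    run_units <- units[units %in% plan$unit[plan$region == region]]
    for (u in run_units) {
      g <- plan[plan$unit == u & plan$region == region, , drop = FALSE]
      strand <- unit_strand[[u]]
      ## genomic placement order: reversed for minus-strand units so that
      ## transcription order matches the plan order
      order_idx <- if (strand == "+") seq_len(nrow(g)) else rev(seq_len(nrow(g)))
      u_start <- cursor
      for (i in order_idx) {
        glen <- g$len[i]
        n_int <- g$n_introns[i]
        if (g$type[i] == "CDS") {
          tseq <- random_cds(glen, gc)
        } else {
          tseq <- random_seq_exact_gc(glen, gc)
        }
        ## split into exons (transcript sense) and interleave introns
        if (n_int > 0L) {
          lo <- 45L
          repeat {
            cuts <- sort(sample(seq(lo, glen - lo), n_int))
            if (n_int == 1L || min(diff(cuts)) >= 60L) break
          }
          ex_b <- c(0L, cuts, glen)
          ilens <- sample(seq(spec$intron_len_range[1L], spec$intron_len_range[2L]),
                          n_int, replace = TRUE)
          pieces <- character(0)
          ex_iv <- matrix(0L, nrow = n_int + 1L, ncol = 2L)  # transcript-sense gene-local
          in_iv <- matrix(0L, nrow = n_int, ncol = 2L)
          pos <- 0L
          for (e in seq_len(n_int + 1L)) {
            exs <- substr0(tseq, ex_b[e], ex_b[e + 1L])
            pieces <- c(pieces, exs)
            ex_iv[e, ] <- c(pos, pos + nchar(exs))
            pos <- pos + nchar(exs)
            if (e <= n_int) {
              ins <- random_intron(ilens[e], gc)
              pieces <- c(pieces, ins)
              in_iv[e, ] <- c(pos, pos + nchar(ins))
              pos <- pos + nchar(ins)
            }
          }
          gseq_t <- paste(pieces, collapse = "")
        } else {
          gseq_t <- tseq
          ex_iv <- matrix(c(0L, nchar(tseq)), nrow = 1L)
          in_iv <- matrix(0L, nrow = 0L, ncol = 2L)
        }
        span <- nchar(gseq_t)
        if (g$gene[i] == "ycf2" && span >= 5200L) {
          cv <- strsplit(gseq_t, "")[[1]]
          cv <- plant_tandem_repeat(cv, 2598L, 45L)
          cv <- plant_tandem_repeat(cv, 5064L, 48L)
          gseq_t <- paste(cv, collapse = "")
        }
        gseq_fwd <- if (strand == "+") gseq_t else revcomp(gseq_t)
        if (cursor + span > rl - (spec$utr_len + 20L)) {
          stop(sprintf("gene plan does not fit region '%s' (%d bp): need > %d bp",
                       region, rl, cursor + span))
        }
        chars[(cursor + 1L):(cursor + span)] <- strsplit(gseq_fwd, "")[[1]]
        ## map transcript-sense gene-local intervals to forward genome coords
        to_fwd <- function(iv) {
          if (nrow(iv) == 0L) return(iv)
          if (strand == "+") {
            cbind(cursor + iv[, 1L], cursor + iv[, 2L])
          } else {
            cbind(cursor + span - iv[, 2L], cursor + span - iv[, 1L])
          }
        }
        exf <- to_fwd(ex_iv)
        inf <- to_fwd(in_iv)
        exons[[length(exons) + 1L]] <- data.frame(
          gene = g$gene[i], type = g$type[i], strand = strand,
          exon = seq_len(nrow(exf)),
          start = region_offset[[region]] + exf[, 1L],
          end = region_offset[[region]] + exf[, 2L],
          unit = u, region = region, stringsAsFactors = FALSE
        )
        if (nrow(inf) > 0L) {
          introns[[length(introns) + 1L]] <- data.frame(
            gene = g$gene[i], strand = strand, index = seq_len(nrow(inf)),
            donor = region_offset[[region]] + inf[, 1L],
            acceptor = region_offset[[region]] + inf[, 2L],
            len = inf[, 2L] - inf[, 1L], stringsAsFactors = FALSE
          )
        }
        gap <- sample(15:40, 1L)
        cursor <- cursor + span + gap
      }
      u_end <- cursor - gap  # last gene end
      unit_span[[u]] <- data.frame(
        unit = u, strand = strand,
        start = region_offset[[region]] + u_start,
        end = region_offset[[region]] + u_end,
        n_genes = nrow(g), stringsAsFactors = FALSE
      )
      ## between-unit gap leaves room for both units' UTR extensions
      cursor <- cursor - gap + sample((2L * spec$utr_len + 15L):(2L * spec$utr_len + 45L), 1L)
    }
    ## fill unassigned positions with composition-matched filler
    free <- which(is.na(chars))
    gc_have <- sum(chars %in% c("G", "C"), na.rm = TRUE)
    gc_need <- round(gc * rl) - gc_have
    gc_need <- max(0L, min(length(free), gc_need))
    fill <- c(sample(c("G", "C"), gc_need, replace = TRUE),
              sample(c("A", "T"), length(free) - gc_need, replace = TRUE))
    chars[free] <- sample(fill)
    region_seq[[region]] <- paste(chars, collapse = "")
  }

  ira <- random_seq_exact_gc(spec$ir_len, spec$gc_by_region[["ir"]])
  annotation <- do.call(rbind, exons)
  introns <- if (length(introns)) do.call(rbind, introns) else
    data.frame(gene = character(0), strand = character(0), index = integer(0),
               donor = integer(0), acceptor = integer(0), len = integer(0))
  units_df <- do.call(rbind, unit_span)
  rownames(annotation) <- rownames(introns) <- rownames(units_df) <- NULL

  ## plant editing sites (forces a C on the annotated strand)
  lsc_chars <- strsplit(region_seq$lsc, "")[[1]]
  ssc_chars <- strsplit(region_seq$ssc, "")[[1]]
  set_base <- function(pos, strand) {
    ## force genome forward base so the transcript-strand base is C
    base <- if (strand == "+") "C" else "G"
    if (pos < spec$lsc_len) {
      lsc_chars[pos + 1L] <<- base
    } else {
      p <- pos - region_offset[["ssc"]]
      stopifnot(p >= 0L, p < spec$ssc_len)
      ssc_chars[p + 1L] <<- base
    }
  }

  editing <- plant_editing_sites(spec, annotation, introns, units_df)
  if (nrow(editing) > 0L) {
    for (i in seq_len(nrow(editing))) set_base(editing$pos[i], editing$strand[i])
  }
  region_seq$lsc <- paste(lsc_chars, collapse = "")
  region_seq$ssc <- paste(ssc_chars, collapse = "")

  seq <- paste0(region_seq$lsc, ira, region_seq$ssc, revcomp(ira))
  ## break chance base-pair complementarity at the planted IR boundaries so
  ## the IR copies are maximal at exactly ir_len (edits touch gene-free
  ## margin filler only)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  L <- spec$lsc_len; ir <- spec$ir_len; ss <- spec$ssc_len
  if (chars[L] == complement(chars[1L])) {           # S[L-1] vs comp(S[0])
    chars[1L] <- setdiff(DNA_BASES, c(chars[1L], complement(chars[L])))[1L]
  }
  if (chars[L + ir + 1L] == complement(chars[L + ir + ss])) {  # SSC edges
    chars[L + ir + 1L] <-
      setdiff(DNA_BASES, c(chars[L + ir + 1L], complement(chars[L + ir + ss])))[1L]
  }
  seq <- paste(chars, collapse = "")
  genome <- plastome(seq, id = sprintf("synthetic_plastome_seed%d", spec$seed))

  partition <- list(
    lsc = c(0L, spec$lsc_len),
    ira = c(spec$lsc_len, spec$lsc_len + spec$ir_len),
    ssc = c(spec$lsc_len + spec$ir_len, spec$lsc_len + spec$ir_len + spec$ssc_len),
    irb = c(spec$lsc_len + spec$ir_len + spec$ssc_len, nchar(seq))
  )

  truth <- list(
    partition = partition, genes = annotation, introns = introns,
    editing = editing, units = units_df, utr_len = spec$utr_len,
    seed = spec$seed, spec = spec
  )
  class(truth) <- "plastome_truth"
  ann <- annotation[, c("gene", "type", "strand", "exon", "start", "end")]
  class(ann) <- c("plastome_annotation", "data.frame")
  list(genome = genome, annotation = ann, truth = truth)
}

## choose editing-site positions; bases are forced to C afterwards
plant_editing_sites <- function(spec, annotation, introns, units_df) {
  n <- spec$editing_n
  n <- setNames(as.integer(n), names(n))
  total <- sum(n)
  empty <- data.frame(pos = integer(0), strand = character(0),
                      efficiency = numeric(0), category = character(0),
                      gene = character(0))
  if (total == 0L) return(empty)
  eff <- rep_len(spec$editing_eff, total)
  out <- list()

  cds <- annotation[annotation$type == "CDS", , drop = FALSE]
  if (n[["cds"]] > 0L) {
    ## candidate positions: interior of CDS exons, clear of boundaries and of
    ## the first/last codon
    cand <- do.call(rbind, lapply(seq_len(nrow(cds)), function(i) {
      s <- cds$start[i] + 4L
      e <- cds$end[i] - 4L
      if (e <= s) return(NULL)
      data.frame(pos = s:(e - 1L), strand = cds$strand[i], gene = cds$gene[i],
                 stringsAsFactors = FALSE)
    }))
    pick <- cand[sample(nrow(cand), n[["cds"]]), , drop = FALSE]
    pick$category <- "CDS"
    out$cds <- pick
  }
  if (n[["intron"]] > 0L) {
    stopifnot(nrow(introns) > 0L)
    ii <- sample(nrow(introns), n[["intron"]], replace = nrow(introns) < n[["intron"]])
    pick <- do.call(rbind, lapply(ii, function(i) {
      ## stay clear of the boundary motifs
      lo <- introns$donor[i] + 8L
      hi <- introns$acceptor[i] - 8L
      data.frame(pos = sample(lo:(hi - 1L), 1L), strand = introns$strand[i],
                 gene = introns$gene[i], stringsAsFactors = FALSE)
    }))
    pick$category <- "intron"
    out$intron <- pick
  }
  if (n[["intergenic"]] > 0L) {
    ## UTR windows of transcription units (30 bp beyond each unit end)
    w <- rbind(
      data.frame(start = units_df$start - spec$utr_len, end = units_df$start,
                 strand = units_df$strand, unit = units_df$unit),
      data.frame(start = units_df$end, end = units_df$end + spec$utr_len,
                 strand = units_df$strand, unit = units_df$unit)
    )
    wi <- sample(nrow(w), n[["intergenic"]], replace = nrow(w) < n[["intergenic"]])
    pick <- do.call(rbind, lapply(wi, function(i) {
      data.frame(pos = sample((w$start[i] + 2L):(w$end[i] - 3L), 1L),
                 strand = w$strand[i], gene = NA_character_,
                 stringsAsFactors = FALSE)
    }))
    pick$category <- "intergenic"
    out$intergenic <- pick
  }
  sites <- do.call(rbind, out)
  rownames(sites) <- NULL
  ## de-duplicate improbable position collisions
  sites <- sites[!duplicated(sites$pos), , drop = FALSE]
  sites$efficiency <- sample(eff)[seq_len(nrow(sites))]
  sites[order(sites$pos), c("pos", "strand", "efficiency", "category", "gene")]
}

#' Gene spans from an exon-level annotation
#'
#' @param annotation exon-level annotation data.frame.
#' @return data.frame with one row per gene (`gene`, `type`, `strand`,
#'   `start`, `end`, `exonic_len`, `n_exons`), ordered by start.
#' @export
gene_spans <- function(annotation) {
  dt <- as.data.table(annotation)
  sp <- dt[, list(
    type = type[1L], strand = strand[1L],
    start = min(start), end = max(end),
    exonic_len = sum(end - start), n_exons = .N
  ), by = "gene"]
  sp <- as.data.frame(sp)
  sp[order(sp$start), ]
}

#' Extract the spliced coding sequence of a gene (transcript sense)
#'
#' @param genome a [plastome()].
#' @param annotation exon-level annotation.
#' @param gene gene name.
#' @return character scalar, the exon sequence in transcription order.
#' @export
gene_cds <- function(genome, annotation, gene) {
  genome <- as_plastome(genome)
  ex <- annotation[annotation$gene == gene, , drop = FALSE]
  if (nrow(ex) == 0L) stop("unknown gene: ", gene)
  ex <- ex[order(ex$exon), ]
  pieces <- substr0(genome$seq, ex$start, ex$end)
  if (ex$strand[1L] == "+") {
    paste(pieces, collapse = "")
  } else {
    ## exon rank is in transcription order; each piece is forward-strand
    paste(revcomp(pieces), collapse = "")
  }
}
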