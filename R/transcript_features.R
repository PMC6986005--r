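## Intron, C-to-U editing and operon calling from spliced transcript
## alignments plus a gene annotation.

#' Call introns from spliced transcript alignments
#'
#' Junction observations are taken from inter-block target gaps; an
#' observation only counts when the read extends at least 10 bp into both
#' flanking exons. Observations are clustered (junctions within 10 bp of a
#' cluster's modal junction are absorbed); the call's boundary is the modal
#' exact junction.
#'
#' @param alignments list of `transcript_aln`.
#' @param annotation exon-level annotation (host-gene assignment).
#' @param min_support minimum supporting reads per call.
#' @param min_len,max_len intron length bounds, bp.
#' @param genome optional [plastome()] for the boundary-motif flag.
#' @return data.frame: `gene`, `strand`, `donor`, `acceptor`, `length`,
#'   `support`, `motif_match`.
#' @export
call_introns <- function(alignments, annotation, min_support = 3L,
                         min_len = 50L, max_len = 5000L, genome = NULL) {
  obs <- list()
  for (a in alignments) {
    if (is.null(a) || nrow(a$introns) == 0L) next
    bl <- a$blocks
    for (j in seq_len(nrow(a$introns))) {
      if ((bl$tend[j] - bl$tstart[j]) < 10L) next
      if ((bl$tend[j + 1L] - bl$tstart[j + 1L]) < 10L) next
      obs[[length(obs) + 1L]] <- data.frame(
        donor = a$introns$donor[j], acceptor = a$introns$acceptor[j],
        strand = a$strand, stringsAsFactors = FALSE
      )
    }
  }
  empty <- data.frame(gene = character(0), strand = character(0),
                      donor = integer(0), acceptor = integer(0),
                      length = integer(0), support = integer(0),
                      motif_match = logical(0))
  if (length(obs) == 0L) return(empty)
  obs <- do.call(rbind, obs)
  dt <- as.data.table(obs)
  grp <- as.data.frame(dt[, list(n = .N), by = c("donor", "acceptor", "strand")])
  grp <- grp[order(-grp$n, grp$donor), ]
  calls <- list()
  while (nrow(grp) > 0L) {
    top <- grp[1L, ]
    near <- abs(grp$donor - top$donor) <= 10L &
      abs(grp$acceptor - top$acceptor) <= 10L & grp$strand == top$strand
    support <- sum(grp$n[near])
    calls[[length(calls) + 1L]] <- data.frame(
      donor = top$donor, acceptor = top$acceptor, strand = top$strand,
      support = support, stringsAsFactors = FALSE
    )
    grp <- grp[!near, , drop = FALSE]
  }
  calls <- do.call(rbind, calls)
  calls$length <- calls$acceptor - calls$donor
  calls <- calls[calls$support >= min_support &
                   calls$length >= min_len & calls$length <= max_len, ,
                 drop = FALSE]
  if (nrow(calls) == 0L) return(empty)
  sp <- gene_spans(annotation)
  calls$gene <- vapply(seq_len(nrow(calls)), function(i) {
    hit <- sp$start <= calls$donor[i] & sp$end >= calls$acceptor[i] &
      sp$strand == calls$strand[i]
    if (any(hit)) sp$gene[which(hit)[1L]] else NA_character_
  }, character(1))
  calls$motif_match <- if (!is.null(genome)) {
    genome <- as_plastome(genome)
    chars <- strsplit(genome$seq, "")[[1]]
    vapply(seq_len(nrow(calls)), function(i) {
      intron_motif_score(chars, calls$donor[i], calls$acceptor[i],
                         calls$strand[i]) == 2L
    }, logical(1))
  } else NA
  out <- calls[order(calls$donor),
               c("gene", "strand", "donor", "acceptor", "length", "support",
                 "motif_match")]
  rownames(out) <- NULL
  out
}

#' Compare intron lengths across species annotations
#'
#' @param annotations named list of exon-level annotations (names = species).
#' @param genes genes to report; defaults to the union of multi-exon genes.
#' @return long-format data.frame: `species`, `gene`, `intron_index`,
#'   `gene_span`, `exonic_len`, `intron_len`, `status` (`present`, `absent`
#'   when the species has the gene without that intron, `missing_gene`).
#' @export
compare_intron_lengths <- function(annotations, genes = NULL) {
  stopifnot(is.list(annotations), length(names(annotations)) == length(annotations))
  per_species <- lapply(annotations, function(ann) {
    dt <- as.data.table(ann)
    as.data.frame(dt[, list(
      strand = strand[1L], n_exons = .N,
      gene_span = max(end) - min(start),
      exonic_len = sum(end - start),
      starts = list(start[order(exon)]), ends = list(end[order(exon)])
    ), by = "gene"])
  })
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(per_species, function(x)
      x$gene[x$n_exons > 1L]))))
  }
  max_introns <- max(1L, max(unlist(lapply(per_species, function(x)
    x$n_exons)), na.rm = TRUE) - 1L)
  out <- list()
  for (sp in names(per_species)) {
    tab <- per_species[[sp]]
    for (g in genes) {
      row <- tab[tab$gene == g, , drop = FALSE]
      if (nrow(row) == 0L) {
        out[[length(out) + 1L]] <- data.frame(
          species = sp, gene = g, intron_index = NA_integer_,
          gene_span = NA_integer_, exonic_len = NA_integer_,
          intron_len = NA_integer_, status = "missing_gene")
        next
      }
      st <- row$starts[[1L]]; en <- row$ends[[1L]]
      n_int <- length(st) - 1L
      if (n_int == 0L) {
        out[[length(out) + 1L]] <- data.frame(
          species = sp, gene = g, intron_index = NA_integer_,
          gene_span = row$gene_span, exonic_len = row$exonic_len,
          intron_len = NA_integer_, status = "absent")
      } else {
        for (i in seq_len(n_int)) {
          ## exons are in transcription order; intron i separates exon i and
          ## i+1 (on the minus strand forward coordinates run downwards)
          ilen <- if (row$strand == "+") st[i + 1L] - en[i] else st[i] - en[i + 1L]
          out[[length(out) + 1L]] <- data.frame(
            species = sp, gene = g, intron_index = i,
            gene_span = row$gene_span, exonic_len = row$exonic_len,
            intron_len = ilen, status = "present")
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## per-strand coverage and C->T (transcript sense) edited counts
pileup_editing <- function(alignments, genome_len) {
  cov <- list("+" = integer(genome_len + 1L), "-" = integer(genome_len + 1L))
  edited <- list("+" = integer(genome_len), "-" = integer(genome_len))
  for (a in alignments) {
    if (is.null(a)) next
    s <- a$strand
    for (b in seq_len(nrow(a$blocks))) {
      ts <- a$blocks$tstart[b] %% genome_len
      te <- ts + (a$blocks$tend[b] - a$blocks$tstart[b])
      if (te <= genome_len) {
        cov[[s]][ts + 1L] <- cov[[s]][ts + 1L] + 1L
        cov[[s]][te + 1L] <- cov[[s]][te + 1L] - 1L
      } else {
        cov[[s]][ts + 1L] <- cov[[s]][ts + 1L] + 1L
        cov[[s]][genome_len + 1L] <- cov[[s]][genome_len + 1L] - 1L
        cov[[s]][1L] <- cov[[s]][1L] + 1L
        cov[[s]][(te - genome_len) + 1L] <- cov[[s]][(te - genome_len) + 1L] - 1L
      }
    }
    mm <- a$mismatches
    if (nrow(mm) > 0L) {
      want <- if (s == "+") mm$ref == "C" & mm$alt == "T" else
        mm$ref == "G" & mm$alt == "A"
      p <- (mm$tpos[want] %% genome_len) + 1L
      for (pp in p) edited[[s]][pp] <- edited[[s]][pp] + 1L
    }
  }
  list(
    cov = lapply(cov, function(x) cumsum(x[seq_len(genome_len)])),
    edited = edited
  )
}

#' Call C-to-U RNA editing sites from transcript alignments
#'
#' A site is called at a position whose reference base is C on the
#' transcript strand (genomic C for plus-strand transcripts, G for minus)
#' when it is covered by at least `min_cov` same-strand transcripts, the
#' edited fraction is at least `min_eff`, and a one-sided binomial test of
#' the edited count against the sequencing error rate `err` rejects at
#' Benjamini-Hochberg adjusted level `alpha` (the BH family is all candidate
#' C positions with coverage >= `min_cov`).
#'
#' @param alignments list of `transcript_aln`.
#' @param genome the reference [plastome()].
#' @param annotation exon-level annotation (site categories).
#' @param min_cov minimum covering transcripts.
#' @param min_eff minimum edited fraction.
#' @param err assumed per-base error rate of the null model.
#' @param alpha BH-adjusted significance level.
#' @param introns optional intron data.frame (from [call_introns()] or the
#'   simulation truth) used for the `intron` category.
#' @return data.frame: `pos`, `strand`, `ref`, `edited`, `covering`,
#'   `efficiency`, `p`, `q`, `category`, `gene`, `codon_pos`, `aa_change`.
#' @export
call_editing <- function(alignments, genome, annotation, min_cov = 10L,
                         min_eff = 0.10, err = 0.02, alpha = 0.05,
                         introns = NULL) {
  genome <- as_plastome(genome)
  n <- nchar(genome$seq)
  chars <- strsplit(genome$seq, "")[[1]]
  pu <- pileup_editing(alignments, n)
  cand_on <- function(base, s) {
    pos <- which(chars == base & pu$cov[[s]] >= min_cov) - 1L
    data.frame(pos = pos, strand = rep(s, length(pos)),
               stringsAsFactors = FALSE)
  }
  cand <- rbind(cand_on("C", "+"), cand_on("G", "-"))
  empty <- data.frame(pos = integer(0), strand = character(0),
                      ref = character(0), edited = integer(0),
                      covering = integer(0), efficiency = numeric(0),
                      p = numeric(0), q = numeric(0), category = character(0),
                      gene = character(0), codon_pos = integer(0),
                      aa_change = character(0))
  if (nrow(cand) == 0L) return(empty)
  cand$covering <- ifelse(cand$strand == "+",
                          pu$cov[["+"]][cand$pos + 1L],
                          pu$cov[["-"]][cand$pos + 1L])
  cand$edited <- ifelse(cand$strand == "+",
                        pu$edited[["+"]][cand$pos + 1L],
                        pu$edited[["-"]][cand$pos + 1L])
  cand$efficiency <- cand$edited / cand$covering
  cand$p <- pbinom(cand$edited - 1L, cand$covering, err, lower.tail = FALSE)
  cand$q <- p.adjust(cand$p, method = "BH")
  keep <- cand$efficiency >= min_eff & cand$q <= alpha & cand$edited > 0L
  sites <- cand[keep, , drop = FALSE]
  if (nrow(sites) == 0L) return(empty)
  sites$ref <- chars[sites$pos + 1L]
  ann <- lapply(seq_len(nrow(sites)), function(i) {
    annotate_editing(list(pos = sites$pos[i], strand = sites$strand[i]),
                     annotation, genome, introns = introns)
  })
  sites$category <- vapply(ann, function(x) x$category, character(1))
  sites$gene <- vapply(ann, function(x) x$gene, character(1))
  sites$codon_pos <- vapply(ann, function(x) x$codon_pos, integer(1))
  sites$aa_change <- vapply(ann, function(x) x$aa_change, character(1))
  out <- sites[order(sites$pos),
               c("pos", "strand", "ref", "edited", "covering", "efficiency",
                 "p", "q", "category", "gene", "codon_pos", "aa_change")]
  rownames(out) <- NULL
  out
}

#' Annotate a single editing site
#'
#' Classifies the site as `CDS`, `intron` or `intergenic` and, for CDS
#' sites, reports the codon position (1-3) and the amino-acid consequence
#' under the bacterial/plastid genetic code (translation table 11).
#'
#' @param site list or one-row data.frame with `pos` (0-based) and `strand`.
#' @param annotation exon-level annotation.
#' @param genome the reference [plastome()].
#' @param introns optional intron table (`donor`, `acceptor`, `strand`).
#' @return list: `category`, `gene`, `codon_pos`, `aa_change` (e.g. `"S>L"`,
#'   with `"(syn)"` appended when synonymous).
#' @export
annotate_editing <- function(site, annotation, genome, introns = NULL) {
  genome <- as_plastome(genome)
  pos <- as.integer(site$pos); strand <- as.character(site$strand)
  base <- substr0(genome$seq, pos, pos + 1L)
  strand_base <- if (strand == "+") base else complement(base)
  if (strand_base != "C") {
    stop(sprintf("position %d is %s on strand %s, not C", pos, strand_base,
                 strand))
  }
  res <- list(category = "intergenic", gene = NA_character_,
              codon_pos = NA_integer_, aa_change = NA_character_)
  cds <- annotation[annotation$type == "CDS" & annotation$strand == strand, ,
                    drop = FALSE]
  hit <- cds[cds$start <= pos & pos < cds$end, , drop = FALSE]
  if (nrow(hit) >= 1L) {
    g <- hit$gene[1L]
    ex <- annotation[annotation$gene == g, , drop = FALSE]
    ex <- ex[order(ex$exon), ]
    ## offset of the site within the spliced CDS (transcription sense)
    off <- 0L
    for (i in seq_len(nrow(ex))) {
      if (ex$start[i] <= pos && pos < ex$end[i]) {
        off <- off + if (strand == "+") pos - ex$start[i] else ex$end[i] - 1L - pos
        break
      }
      off <- off + (ex$end[i] - ex$start[i])
    }
    cds_seq <- gene_cds(genome, annotation, g)
    ci <- off %/% 3L
    cp <- off %% 3L + 1L
    codon <- substr0(cds_seq, 3L * ci, 3L * ci + 3L)
    edited <- codon
    substr(edited, cp, cp) <- "T"
    code <- Biostrings::getGeneticCode("11")
    aa1 <- unname(code[codon]); aa2 <- unname(code[edited])
    if (is.na(aa1)) aa1 <- "X"
    if (is.na(aa2)) aa2 <- "X"
    res$category <- "CDS"
    res$gene <- g
    res$codon_pos <- cp
    res$aa_change <- paste0(aa1, ">", aa2, if (aa1 == aa2) " (syn)" else "")
    return(res)
  }
  if (!is.null(introns) && nrow(introns) > 0L) {
    ihit <- introns$donor <= pos & pos < introns$acceptor &
      introns$strand == strand
    if (any(ihit)) {
      res$category <- "intron"
      if ("gene" %in% names(introns)) res$gene <- introns$gene[which(ihit)[1L]]
      return(res)
    }
  }
  ## non-CDS gene bodies (tRNA/rRNA) are still genic, not intergenic
  other <- annotation[annotation$type != "CDS" & annotation$strand == strand, ,
                      drop = FALSE]
  ohit <- other[other$start <= pos & pos < other$end, , drop = FALSE]
  if (nrow(ohit) >= 1L) {
    res$category <- "gene"
    res$gene <- ohit$gene[1L]
  }
  res
}

#' Summarise a set of editing sites
#'
#' @param sites data.frame from [call_editing()].
#' @return list: `n`, `by_category` (named counts over CDS/intron/intergenic
#'   and any others present), `by_gene`, `efficiency` (min/median/max).
#' @export
editing_summary <- function(sites) {
  if (nrow(sites) == 0L) {
    return(list(n = 0L,
                by_category = c(CDS = 0L, intron = 0L, intergenic = 0L),
                by_gene = integer(0),
                efficiency = c(min = NA_real_, median = NA_real_,
                               max = NA_real_)))
  }
  levs <- union(c("CDS", "intron", "intergenic"), unique(sites$category))
  list(
    n = nrow(sites),
    by_category = table(factor(sites$category, levels = levs)),
    by_gene = sort(table(sites$gene[!is.na(sites$gene)]), decreasing = TRUE),
    efficiency = c(min = min(sites$efficiency),
                   median = median(sites$efficiency),
                   max = max(sites$efficiency))
  )
}

#' Set arithmetic for editing-site catalogues
#'
#' @param new_pos positions called in the current study.
#' @param prior_pos positions from a previous catalogue.
#' @return list: `n_new`, `n_prior`, `n_overlap`, `n_combined`
#'   (`n_new + n_prior - n_overlap`).
#' @export
combine_editing_sets <- function(new_pos, prior_pos) {
  new_pos <- unique(new_pos); prior_pos <- unique(prior_pos)
  ov <- length(intersect(new_pos, prior_pos))
  list(n_new = length(new_pos), n_prior = length(prior_pos),
       n_overlap = ov,
       n_combined = length(new_pos) + length(prior_pos) - ov)
}

gene_family <- function(gene) sub("^([a-z]+).*$", "\\1", gene)

title_case <- function(x) paste0(toupper(substring(x, 1, 1)), substring(x, 2))

#' Call operons (polycistronic transcription units)
#'
#' A transcript covers a gene when its aligned blocks overlap at least
#' `cds_cov` of the gene's exonic span on the same strand. Transcripts
#' covering the identical ordered gene set are grouped; groups with at least
#' `min_genes` genes and `min_support` transcripts become calls. Calls are
#' named by the majority gene family of their members (title-cased, ties
#' broken by the first gene), with `_1`, `_2` ordinals in genome order when
#' a family yields several operons. A call whose gene list is a contiguous
#' subsequence of a larger call is cross-referenced in `subset_of`.
#'
#' @param alignments list of `transcript_aln`.
#' @param annotation exon-level annotation.
#' @param min_genes minimum genes per operon.
#' @param min_support minimum supporting transcripts.
#' @param cds_cov minimum covered fraction of a gene's exonic span.
#' @return data.frame: `name`, `genes` (transcription order, `+`-joined),
#'   `n_genes`, `strand`, `start`, `end`, `support`, `subset_of`.
#' @export
call_operons <- function(alignments, annotation, min_genes = 2L,
                         min_support = 3L, cds_cov = 0.5) {
  sp <- gene_spans(annotation)
  ex <- annotation
  keys <- character(0)
  strands <- character(0)
  for (a in alignments) {
    if (is.null(a)) next
    bl <- a$blocks
    covered <- vapply(seq_len(nrow(sp)), function(i) {
      if (sp$strand[i] != a$strand) return(FALSE)
      exi <- ex[ex$gene == sp$gene[i], , drop = FALSE]
      tot <- sum(exi$end - exi$start)
      ov <- 0L
      for (e in seq_len(nrow(exi))) {
        o <- pmin(bl$tend, exi$end[e]) - pmax(bl$tstart, exi$start[e])
        ov <- ov + sum(pmax(0L, o))
      }
      ov >= cds_cov * tot
    }, logical(1))
    g <- sp$gene[covered]
    if (length(g) == 0L) next
    ## sp is ordered by genomic start; transcription order reverses on minus
    if (a$strand == "-") g <- rev(g)
    keys <- c(keys, paste(g, collapse = "+"))
    strands <- c(strands, a$strand)
  }
  empty <- data.frame(name = character(0), genes = character(0),
                      n_genes = integer(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      support = integer(0), subset_of = character(0))
  if (length(keys) == 0L) return(empty)
  tab <- as.data.frame(table(key = keys, strand = strands),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  tab$n_genes <- lengths(strsplit(tab$key, "+", fixed = TRUE))
  tab <- tab[tab$n_genes >= min_genes & tab$Freq >= min_support, , drop = FALSE]
  if (nrow(tab) == 0L) return(empty)
  calls <- lapply(seq_len(nrow(tab)), function(i) {
    genes <- strsplit(tab$key[i], "+", fixed = TRUE)[[1]]
    gsp <- sp[match(genes, sp$gene), ]
    fams <- gene_family(genes)
    ft <- table(fams)
    top <- names(ft)[ft == max(ft)]
    fam <- if (length(top) == 1L) top else fams[1L]
    data.frame(
      family = fam, genes = tab$key[i], n_genes = tab$n_genes[i],
      strand = tab$strand[i], start = min(gsp$start), end = max(gsp$end),
      support = tab$Freq[i], stringsAsFactors = FALSE
    )
  })
  calls <- do.call(rbind, calls)
  calls <- calls[order(calls$start), ]
  ## ordinals per family, in genome order
  calls$name <- title_case(calls$family)
  for (f in unique(calls$family)) {
    ix <- which(calls$family == f)
    if (length(ix) > 1L) {
      calls$name[ix] <- sprintf("%s_%d", title_case(f), seq_along(ix))
    }
  }
  glists <- strsplit(calls$genes, "+", fixed = TRUE)
  calls$subset_of <- NA_character_
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(calls))) {
      if (i == j) next
      a <- glists[[i]]; b <- glists[[j]]
      if (length(a) >= length(b)) next
      hit <- which(b == a[1L])
      for (h in hit) {
        if (h + length(a) - 1L <= length(b) &&
            identical(b[h:(h + length(a) - 1L)], a)) {
          calls$subset_of[i] <- calls$name[j]
          break
        }
      }
      if (!is.na(calls$subset_of[i])) break
    }
  }
  out <- calls[, c("name", "genes", "n_genes", "strand", "start", "end",
                   "support", "subset_of")]
  rownames(out) <- NULL
  out
}
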