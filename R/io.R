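## File-format boundaries. Internal coordinates are 0-based half-open
## everywhere; conversion to/from 1-based inclusive happens only here
## (GFF3, GenBank, SAM) and nowhere else.

#' Write a genome as single-record FASTA
#'
#' The header carries a `topology=circular` flag for circular genomes.
#'
#' @param genome a [plastome()].
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- as_plastome(genome)
  ss <- Biostrings::DNAStringSet(genome$seq)
  names(ss) <- paste0(genome$id,
                      if (genome$circular) " topology=circular" else "")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA with a single record; a `topology=circular` header flag
#'   marks the genome circular.
#' @return a [plastome()].
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  if (length(ss) > 1L) stop("expected a single-record genome FASTA")
  hdr <- names(ss)[1L]
  plastome(as.character(ss[[1L]]),
           id = strsplit(hdr, "\\s+")[[1L]][1L],
           circular = grepl("topology=circular", hdr))
}

#' Write reads as FASTQ (constant quality)
#' @param reads `read_set`/`transcript_set` or named character vector.
#' @param path output path.
#' @param comment optional header comment (e.g. records the seed).
#' @export
write_fastq <- function(reads, path, comment = NULL) {
  if (is.data.frame(reads)) {
    seqs <- reads$seq; ids <- reads$id
  } else {
    seqs <- unname(reads); ids <- names(reads)
  }
  if (!is.null(comment)) ids <- paste(ids, comment)
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  Biostrings::writeXStringSet(
    ss, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(seqs)))
  )
  invisible(path)
}

#' Read a FASTQ (or FASTA) file into a read table
#' @param path input path.
#' @param format `"fastq"` or `"fasta"`.
#' @return data.frame with `id`, `seq`.
#' @export
read_fastq <- function(path, format = "fastq") {
  ss <- Biostrings::readDNAStringSet(path, format = format)
  data.frame(id = sub("\\s.*$", "", names(ss)), seq = as.character(ss),
             row.names = NULL, stringsAsFactors = FALSE)
}

gff3_escape <- function(x) gsub(";", "%3B", gsub("=", "%3D", x))

#' Write an exon-level annotation as GFF3
#'
#' Emits one `gene` feature per gene plus `exon` children (1-based
#' inclusive coordinates).
#'
#' @param annotation exon-level annotation data.frame.
#' @param path output path.
#' @param seqid sequence identifier.
#' @export
write_gff3 <- function(annotation, path, seqid = "plastome") {
  sp <- gene_spans(annotation)
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(sp))) {
    g <- sp$gene[i]
    lines <- c(lines, paste(
      seqid, "chloroplastr", "gene", sp$start[i] + 1L, sp$end[i], ".",
      sp$strand[i], ".",
      sprintf("ID=gene-%s;Name=%s;gene_biotype=%s", gff3_escape(g),
              gff3_escape(g), sp$type[i]),
      sep = "\t"
    ))
    ex <- annotation[annotation$gene == g, , drop = FALSE]
    ex <- ex[order(ex$exon), ]
    for (e in seq_len(nrow(ex))) {
      lines <- c(lines, paste(
        seqid, "chloroplastr", "exon", ex$start[e] + 1L, ex$end[e], ".",
        ex$strand[e], ".",
        sprintf("ID=exon-%s-%d;Parent=gene-%s;exon_number=%d;feature_type=%s",
                gff3_escape(g), ex$exon[e], gff3_escape(g), ex$exon[e],
                ex$type[e]),
        sep = "\t"
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 annotation back into the exon-level table
#'
#' @param path GFF3 written by [write_gff3()] (exon features carrying
#'   `Parent` and `exon_number` attributes).
#' @return exon-level annotation data.frame.
#' @export
read_gff3 <- function(path) {
  raw <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE,
                    col.names = c("seqid", "source", "type", "start", "end",
                                  "score", "strand", "phase", "attr"))
  get_attr <- function(attr, key) {
    m <- regmatches(attr, regexec(paste0("(?:^|;)", key, "=([^;]*)"), attr))
    vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
           character(1))
  }
  genes <- raw[raw$type == "gene", , drop = FALSE]
  gtype <- setNames(get_attr(genes$attr, "gene_biotype"),
                    get_attr(genes$attr, "Name"))
  ex <- raw[raw$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) stop("no exon features in ", path)
  gene <- sub("^gene-", "", get_attr(ex$attr, "Parent"))
  ft <- get_attr(ex$attr, "feature_type")
  out <- data.frame(
    gene = gene,
    type = ifelse(is.na(ft), unname(gtype[gene]), ft),
    strand = ex$strand,
    exon = as.integer(get_attr(ex$attr, "exon_number")),
    start = ex$start - 1L,
    end = ex$end,
    stringsAsFactors = FALSE
  )
  out[order(out$gene, out$exon), ]
}

#' Write a quadripartite partition as BED (0-based half-open)
#' @param partition a `quadripartite`.
#' @param path output path.
#' @param seqid sequence id.
#' @export
write_partition_bed <- function(partition, path, seqid = partition$genome_id) {
  iv <- rbind(
    c(partition$lsc, "LSC"), c(partition$ira, "IRa"),
    c(partition$ssc, "SSC"), c(partition$irb, "IRb")
  )
  writeLines(sprintf("%s\t%s\t%s\t%s", seqid, iv[, 1L], iv[, 2L], iv[, 3L]),
             path)
  invisible(path)
}

## ------------------------------------------------------------------ GenBank

wrap_location <- function(starts, ends, strand) {
  ## internal 0-based half-open -> GenBank 1-based inclusive
  segs <- sprintf("%d..%d", starts + 1L, ends)
  loc <- if (length(segs) == 1L) segs else
    sprintf("join(%s)", paste(segs, collapse = ","))
  if (strand == "-") sprintf("complement(%s)", loc) else loc
}

#' Write a minimal GenBank flat file
#'
#' Enough of the format for round-tripping gene models: LOCUS line with
#' length and topology, `gene` features plus typed features (CDS/tRNA/rRNA)
#' with `join()`/`complement()` locations, and the ORIGIN sequence block.
#'
#' @param genome a [plastome()].
#' @param annotation exon-level annotation.
#' @param path output path.
#' @export
write_genbank <- function(genome, annotation, path) {
  genome <- as_plastome(genome)
  n <- nchar(genome$seq)
  lines <- c(sprintf("LOCUS       %s %d bp    DNA     %s PLN",
                     genome$id, n,
                     if (genome$circular) "circular" else "linear"),
             sprintf("DEFINITION  %s, synthetic plastome.", genome$id),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", n))
  sp <- gene_spans(annotation)
  for (i in seq_len(nrow(sp))) {
    g <- sp$gene[i]
    ex <- annotation[annotation$gene == g, , drop = FALSE]
    ex <- ex[order(ex$start), ]  # genome order inside join()
    loc <- wrap_location(ex$start, ex$end, sp$strand[i])
    gene_loc <- wrap_location(sp$start[i], sp$end[i], sp$strand[i])
    ftype <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA")[sp$type[i]]
    lines <- c(lines,
               sprintf("     gene            %s", gene_loc),
               sprintf("                     /gene=\"%s\"", g),
               sprintf("     %-15s %s", ftype, loc),
               sprintf("                     /gene=\"%s\"", g))
    if (ftype == "CDS") {
      lines <- c(lines, "                     /codon_start=1",
                 "                     /transl_table=11")
    }
  }
  lines <- c(lines, "ORIGIN")
  seq <- tolower(genome$seq)
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substring(seq, p, min(n, p + 59L))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(nchar(chunk), seq(10L, nchar(chunk) + 9L, 10L)))
    lines <- c(lines, sprintf("%9d %s", p, paste(tens, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

parse_gb_location <- function(loc) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "+"
  if (startsWith(loc, "complement(")) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (startsWith(loc, "join(")) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  }
  segs <- strsplit(loc, ",")[[1]]
  m <- regmatches(segs, regexec("^(\\d+)\\.\\.(\\d+)$", segs))
  if (any(lengths(m) != 3L)) stop("cannot parse GenBank location: ", loc)
  start <- vapply(m, function(x) as.integer(x[2L]), integer(1)) - 1L
  end <- vapply(m, function(x) as.integer(x[3L]), integer(1))
  if (any(end <= start)) stop("coordinate overflow in GenBank location: ", loc)
  list(start = start, end = end, strand = strand)
}

#' Parse a (minimal) GenBank flat file
#'
#' Handles `join()` and `complement()` feature locations; exons of
#' minus-strand genes are returned in transcription order. Only `CDS`,
#' `tRNA` and `rRNA` features are retained (the `gene` features carry no
#' extra information here).
#'
#' @param path GenBank file.
#' @return list with `genome` (a [plastome()]) and `annotation`.
#' @export
parse_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)[1L]
  if (is.na(locus)) stop("not a GenBank file: no LOCUS line")
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  id <- toks[2L]
  circular <- any(grepl("circular", toks, ignore.case = TRUE))
  ori <- grep("^ORIGIN", lines)[1L]
  if (is.na(ori)) stop("no ORIGIN block in ", path)
  seq_lines <- lines[(ori + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  feat_start <- grep("^FEATURES", lines)[1L]
  feat_lines <- lines[(feat_start + 1L):(ori - 1L)]
  ## fold continuation lines of locations (21-space indent, no qualifier)
  recs <- list()
  cur_type <- NULL; cur_loc <- NULL; cur_gene <- NA_character_
  flush <- function() {
    if (!is.null(cur_type) && cur_type %in% c("CDS", "tRNA", "rRNA")) {
      recs[[length(recs) + 1L]] <<- list(type = cur_type, loc = cur_loc,
                                         gene = cur_gene)
    }
  }
  for (ln in feat_lines) {
    if (grepl("^ {5}\\S", ln)) {
      flush()
      cur_type <- trimws(substr(ln, 1L, 20L))
      cur_loc <- trimws(substring(ln, 22L))
      cur_gene <- NA_character_
    } else if (grepl("^ {21}/", ln)) {
      q <- trimws(substring(ln, 22L))
      if (startsWith(q, "/gene=")) {
        cur_gene <- gsub("\"", "", sub("^/gene=", "", q))
      }
    } else if (grepl("^ {21}\\S", ln) && !is.null(cur_loc)) {
      cur_loc <- paste0(cur_loc, trimws(ln))
    }
  }
  flush()
  if (length(recs) == 0L) stop("no gene features parsed from ", path)
  ann <- do.call(rbind, lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    p <- parse_gb_location(r$loc)
    if (any(p$end > nchar(seq))) {
      stop("coordinate overflow in locus ",
           if (is.na(r$gene)) sprintf("feature %d", i) else r$gene)
    }
    o <- order(p$start)
    if (p$strand == "-") o <- rev(o)  # transcription order
    data.frame(
      gene = if (is.na(r$gene)) sprintf("feature_%03d", i) else r$gene,
      type = r$type, strand = p$strand, exon = seq_along(o),
      start = p$start[o], end = p$end[o], stringsAsFactors = FALSE
    )
  }))
  rownames(ann) <- NULL
  list(genome = plastome(seq, id = id, circular = circular),
       annotation = ann)
}

#' Write a data.frame as TSV
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
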