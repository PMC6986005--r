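#' @importFrom data.table data.table := .N .SD setkey setkeyv as.data.table
#' @importFrom stats median p.adjust pbinom rbinom runif rlnorm setNames
#' @importFrom utils head tail modifyList write.table read.delim
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Operates on plain character scalars/vectors over the alphabet
#' `A,C,G,T,N` (case-insensitive; output is upper case).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", stringi::stri_reverse(toupper(x)))
}

#' Complement (no reversal)
#' @param x character vector of DNA sequences.
#' @return character vector of complements.
#' @export
complement <- function(x) chartr("ACGTN", "TGCAN", toupper(x))

## substring on 0-based half-open coordinates
substr0 <- function(seq, start, end) substring(seq, start + 1L, end)

## all k-mers of a sequence, 0-based start positions 0..(n-k)
kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

## canonical (strand-collapsed) form of each k-mer
canonical_kmers <- function(km) {
  rc <- revcomp(km)
  ifelse(km <= rc, km, rc)
}

## sample a random DNA sequence with an exact G+C count (shuffled composition)
random_seq_exact_gc <- function(len, gc) {
  if (len <= 0) return("")
  n_gc <- round(len * gc)
  n_at <- len - n_gc
  bases <- c(
    sample(c("G", "C"), n_gc, replace = TRUE),
    sample(c("A", "T"), n_at, replace = TRUE)
  )
  paste(sample(bases), collapse = "")
}

## GC fraction of a string (N excluded from numerator and denominator)
gc_fraction <- function(seq) {
  tab <- table(strsplit(toupper(seq), "")[[1]])
  gc <- sum(tab[names(tab) %in% c("G", "C")])
  acgt <- sum(tab[names(tab) %in% DNA_BASES])
  if (acgt == 0) return(NA_real_)
  gc / acgt
}

## rotate a circular sequence so that 0-based position `offset` becomes position 0
rotate_seq <- function(seq, offset) {
  n <- nchar(seq)
  offset <- offset %% n
  if (offset == 0) return(seq)
  paste0(substr0(seq, offset, n), substr0(seq, 0, offset))
}

## derive a child seed from a master seed (kept below 2^31)
child_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(stream) * 7L + 13L
}

#' Construct a circular (or linear) genome object
#'
#' @param seq DNA sequence as a single character string.
#' @param id sequence identifier.
#' @param circular logical; circular topology flag.
#' @return an object of class `plastome`.
#' @export
plastome <- function(seq, id = "plastome", circular = TRUE) {
  seq <- toupper(seq)
  stopifnot(nchar(seq) > 0)
  if (grepl("[^ACGTN]", seq)) stop("genome sequence contains characters outside A,C,G,T,N")
  structure(list(id = id, seq = seq, circular = circular), class = "plastome")
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf(
    "<plastome> %s: %s bp, %s\n", x$id,
    format(nchar(x$seq), big.mark = ","),
    if (x$circular) "circular" else "linear"
  ))
  invisible(x)
}

#' @export
length.plastome <- function(x) nchar(x$seq)

as_plastome <- function(x) {
  if (inherits(x, "plastome")) return(x)
  if (is.character(x) && length(x) == 1L) return(plastome(x))
  stop("expected a plastome object or a single DNA string")
}
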